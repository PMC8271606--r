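#' Parameters of the synthetic filming-rig scene
#'
#' Describes the appearance model used to render ground-truthed grayscale
#' time-lapse series of a single pharate adult, emulating the filming rig:
#' a rotating stage passing each animal under the camera 5 times per hour
#' (12-min cadence), a burst of images per pass with small centering jitter,
#' oblique illumination producing one bright smooth head reflection that
#' fragments into irregular patches as molting fluid is resorbed, wings that
#' darken over hours, and an abrupt switch to an empty-puparium appearance
#' at emergence.
#'
#' Images are 8-bit grayscale (values 0-255), default 200 x 200 px, row-major
#' with the origin at the top-left; the R API addresses pixels 1-based as
#' (row, col).
#'
#' @param frame_h,frame_w frame size, pixels.
#' @param body_center,body_axes,body_intensity puparium body ellipse
#'   (center (row, col), semi-axes (rows, cols) in px, fill intensity).
#' @param background background intensity.
#' @param head_roi,wing_roi [roi()] rectangles analysed downstream.
#' @param head_center,head_axes,head_intensity initial smooth head
#'   reflection ellipse.
#' @param head_edge_px width of the soft fall-off at the reflection edge.
#' @param frag_k maximum number of fragmentation patches at emergence.
#' @param frag_amp radial boundary-perturbation amplitude (fraction of the
#'   patch radius) reached at emergence.
#' @param frag_gap_px width (px) of the dark cracks separating patches.
#' @param wing_ramp_start_h,wing_ramp_dur_h wing darkening ramp: start
#'   (hours after the animal's pupariation offset) and duration.
#' @param wing_start_int,wing_end_int wing intensity before/after darkening.
#' @param post_head_int,post_wing_int head/wing intensity after emergence
#'   (empty puparium: head patchiness lost, wing region brightens).
#' @param noise_sd additive Gaussian pixel noise SD.
#' @param jitter_px maximum |translation| (px, per axis) of each burst image.
#' @param drift_amp,drift_period_h slow multiplicative illumination drift.
#' @param cadence_h stage pass interval, hours (0.2 h = 12 min).
#' @param burst_size images captured per pass.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(frame_h = 200, frame_w = 200,
                         body_center = c(100, 100), body_axes = c(70, 45),
                         body_intensity = 120, background = 30,
                         head_roi = roi(38, 76, 50, 50),
                         wing_roi = roi(120, 80, 40, 40),
                         head_center = c(62, 100), head_axes = c(16, 16),
                         head_intensity = 230, head_edge_px = 3,
                         frag_k = 12, frag_amp = 0.55, frag_gap_px = 2,
                         wing_ramp_start_h = 2, wing_ramp_dur_h = 10,
                         wing_start_int = 180, wing_end_int = 60,
                         post_head_int = 110, post_wing_int = 190,
                         noise_sd = 2, jitter_px = 2,
                         drift_amp = 0.02, drift_period_h = 24,
                         cadence_h = 0.2, burst_size = 10) {
  sc <- structure(as.list(environment()), class = "scene_params")
  stopifnot(sc$cadence_h > 0, sc$burst_size >= 1, sc$frag_k >= 1,
            sc$noise_sd >= 0, sc$jitter_px >= 0,
            roi_inside(sc$head_roi, c(frame_h, frame_w)),
            roi_inside(sc$wing_roi, c(frame_h, frame_w)))
  ints <- c(sc$body_intensity, sc$background, sc$head_intensity,
            sc$wing_start_int, sc$wing_end_int, sc$post_head_int,
            sc$post_wing_int)
  stopifnot(all(ints >= 0), all(ints <= 255))
  sc
}

# Pixel-coordinate grids for a frame, reused across renders.
scene_grid <- function(scene) {
  rows <- matrix(seq_len(scene$frame_h), scene$frame_h, scene$frame_w)
  cols <- matrix(seq_len(scene$frame_w), scene$frame_h, scene$frame_w,
                 byrow = TRUE)
  list(rows = rows, cols = cols)
}

ellipse_mask <- function(grid, center, axes) {
  ((grid$rows - center[1]) / axes[1])^2 +
    ((grid$cols - center[2]) / axes[2])^2 <= 1
}

# Smooth radial membership in [0, 1] for the head reflection: 1 well inside
# the ellipse, 0 outside, linear fall-off over edge_px.
soft_ellipse <- function(grid, center, axes, edge_px) {
  d <- sqrt(((grid$rows - center[1]) / axes[1])^2 +
              ((grid$cols - center[2]) / axes[2])^2)
  edge <- edge_px / mean(axes)
  pmin(1, pmax(0, (1 - d) / edge + 1))
}

# Per-animal fragmentation geometry: patch seed points inside the head
# ellipse (kept apart by a minimum separation, so that no two cells merge
# into one wide crack) and low-order radial perturbation coefficients.
frag_geometry <- function(scene, seed) {
  set.seed(seed)
  k <- scene$frag_k
  # aim for roughly even coverage: separation scaled to the per-seed share
  # of the ellipse area, and comfortably wider than the crack
  min_sep <- max(2 * scene$frag_gap_px,
                 0.6 * sqrt(pi * prod(scene$head_axes) / k))
  cen <- matrix(NA_real_, k, 2)
  got <- 0L; tries <- 0L
  while (got < k && tries < 20000L) {
    tries <- tries + 1L
    r <- stats::runif(1, -1, 1); c <- stats::runif(1, -1, 1)
    if (r * r + c * c > 0.9^2) next
    cand <- c(scene$head_center[1] + r * scene$head_axes[1],
              scene$head_center[2] + c * scene$head_axes[2])
    if (got > 0L) {
      d <- sqrt((cen[seq_len(got), 1] - cand[1])^2 +
                  (cen[seq_len(got), 2] - cand[2])^2)
      if (min(d) < min_sep) next
    }
    got <- got + 1L
    cen[got, ] <- cand
  }
  if (got < k)
    stop("could not place ", k, " patch seeds with separation ", min_sep,
         "; reduce frag_k or frag_gap_px")
  list(centers = cen,
       amp1 = stats::runif(k, 0.5, 1), ph1 = stats::runif(k, 0, 2 * pi),
       amp2 = stats::runif(k, 0.3, 0.8), ph2 = stats::runif(k, 0, 2 * pi))
}

# Head reflection at fragmentation progress u in [0, 1]: u = 0 one smooth
# soft-edged bright patch; u > 0 the reflection hardens and splits into the
# m(u) Voronoi cells of the patch seed points, separated by dark cracks
# carved along the cell boundaries, with the outer boundary radially
# wobbled by an amplitude growing with u. The Voronoi crack network only
# gains edges as m grows (seed points are nested), so the roughness indices
# rise monotonically between onset and emergence.
render_head <- function(scene, grid, geom, u) {
  if (u <= 0)
    return(soft_ellipse(grid, scene$head_center, scene$head_axes,
                        scene$head_edge_px))
  m <- round(1 + (scene$frag_k - 1) * u)
  dr_all <- grid$rows - scene$head_center[1]
  dc_all <- grid$cols - scene$head_center[2]
  dn <- sqrt((dr_all / scene$head_axes[1])^2 + (dc_all / scene$head_axes[2])^2)
  th <- atan2(dc_all, dr_all)
  amp <- scene$frag_amp * sqrt(u)
  wob <- amp * 0.25 * (geom$amp1[1] * sin(5 * th + geom$ph1[1]) +
                         geom$amp2[1] * sin(7 * th + geom$ph2[1]))
  out <- (dn <= 1 + wob) * 1
  idx <- which(out > 0)
  if (!length(idx) || m < 2L) return(out)
  pr <- grid$rows[idx]; pc <- grid$cols[idx]
  d1 <- rep(Inf, length(idx)); d2 <- rep(Inf, length(idx))
  for (j in seq_len(m)) {
    dj <- sqrt((pr - geom$centers[j, 1])^2 + (pc - geom$centers[j, 2])^2)
    upd <- dj < d1
    d2[upd] <- d1[upd]; d1[upd] <- dj[upd]
    upd2 <- !upd & dj < d2
    d2[upd2] <- dj[upd2]
  }
  # cracks between adjacent cells, with a wobbled width so borders are
  # irregular rather than straight
  crack_w <- scene$frag_gap_px *
    (1 + amp * 0.5 * sin(4 * atan2(pc - scene$head_center[2],
                                   pr - scene$head_center[1]) + geom$ph1[2]))
  out[idx][(d2 - d1) < crack_w] <- 0
  out
}

# Noise-free scene at time t for one animal's schedule; returns a matrix of
# intensities in [0, 255].
render_base_frame <- function(t_h, schedule, scene, grid, geom) {
  E <- schedule$emergence_t_h; O <- schedule$onset_t_h
  img <- matrix(scene$background, scene$frame_h, scene$frame_w)
  body <- ellipse_mask(grid, scene$body_center, scene$body_axes)
  img[body] <- scene$body_intensity
  if (t_h < E) {
    # wing darkening ramp, anchored to the animal's pupariation offset
    zt <- schedule$pupariation_zt_h
    if (is.null(zt) || is.na(zt)) zt <- 0
    ramp0 <- zt + scene$wing_ramp_start_h
    w <- (t_h - ramp0) / scene$wing_ramp_dur_h
    w <- min(1, max(0, w))
    wing_int <- scene$wing_start_int + w * (scene$wing_end_int - scene$wing_start_int)
    img[roi_rows(scene$wing_roi), roi_cols(scene$wing_roi)] <- wing_int
    u <- if (t_h < O) 0 else min(1, (t_h - O) / (E - O))
    head <- render_head(scene, grid, geom, u)
    img <- img * (1 - head) + scene$head_intensity * head
  } else {
    # empty puparium: wing region brightens, head reflection gone
    img[roi_rows(scene$wing_roi), roi_cols(scene$wing_roi)] <- scene$post_wing_int
    head <- soft_ellipse(grid, scene$head_center, scene$head_axes,
                         scene$head_edge_px)
    img <- img * (1 - head) + scene$post_head_int * head
  }
  img
}

#' Render a ground-truthed time-lapse series for one animal
#'
#' Renders frames from `t = 0` to two hours past the scheduled emergence at
#' the scene cadence; each timepoint is a burst of `burst_size` images with
#' independent integer translation jitter, slow illumination drift and
#' additive Gaussian noise. The head reflection is one smooth bright patch
#' before roughening onset, fragments into an increasing number of
#' rough-bordered patches between onset and emergence, and is replaced by
#' the empty-puparium appearance afterwards; the wing region darkens along
#' its ramp and brightens abruptly at emergence.
#'
#' @param schedule one row of a [simulate_cohort()] schedule (list or
#'   single-row data frame) with at least `onset_t_h` and `emergence_t_h`.
#' @param scene a [scene_params()] object.
#' @param seed integer seed; renders are reproducible for a fixed seed.
#' @param out_dir if non-`NULL`, frames are written there as PNG files and
#'   the manifest's `filename` column points at them; if `NULL`, frames are
#'   kept in memory and returned.
#' @param animal_id identifier used in the manifest.
#' @return A list with `manifest` (data frame: `animal_id`, `t_h`,
#'   `burst_index`, `filename`, plus the applied `jitter_dy`/`jitter_dx` as
#'   ground truth) and `images` (named list of matrices when
#'   `out_dir = NULL`).
#' @export
render_series <- function(schedule, scene, seed, out_dir = NULL,
                          animal_id = "animal1") {
  if (is.data.frame(schedule)) schedule <- as.list(schedule[1, ])
  if (is.null(schedule$pupariation_zt_h))
    schedule$pupariation_zt_h <- schedule$group_zt %||% 0
  if (schedule$emergence_t_h <= schedule$onset_t_h)
    stop("emergence must follow roughening onset")
  grid <- scene_grid(scene)
  geom <- frag_geometry(scene, substream_seed(seed, 1L))
  times <- seq(0, schedule$emergence_t_h + 2, by = scene$cadence_h)
  rows <- vector("list", length(times) * scene$burst_size)
  images <- if (is.null(out_dir)) vector("list", length(rows)) else NULL
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  set.seed(substream_seed(seed, 2L))
  k <- 0L
  for (ti in seq_along(times)) {
    t <- times[ti]
    base <- render_base_frame(t, schedule, scene, grid, geom)
    drift <- 1 + scene$drift_amp * sin(2 * pi * t / scene$drift_period_h)
    for (b in seq_len(scene$burst_size)) {
      k <- k + 1L
      jit <- if (scene$jitter_px > 0)
        sample(-scene$jitter_px:scene$jitter_px, 2, replace = TRUE)
      else c(0L, 0L)
      img <- shift_matrix(base * drift, jit[1], jit[2], scene$background)
      if (scene$noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, scene$noise_sd),
                            nrow(img))
      img <- pmin(pmax(img, 0), 255)
      fname <- sprintf("%s_t%07.2f_b%02d.png", animal_id, t, b)
      rows[[k]] <- data.frame(animal_id = animal_id, t_h = t,
                              burst_index = b, filename = fname,
                              jitter_dy = jit[1], jitter_dx = jit[2])
      if (is.null(out_dir)) {
        images[[k]] <- img
      } else {
        png::writePNG(round(img) / 255, file.path(out_dir, fname))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (is.null(out_dir)) names(images) <- manifest$filename
  list(manifest = manifest, images = images)
}
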