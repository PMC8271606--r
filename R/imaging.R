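#' Per-animal stabilized image series
#'
#' @param animal_id identifier.
#' @param t_h strictly increasing timestamps, hours.
#' @param frames list of grayscale matrices (0-255), all the same size.
#' @param head_roi,wing_roi [roi()] rectangles defined on the first frame.
#' @param shifts integer matrix (n x 2, columns dy/dx) of the cumulative
#'   shift applied to each frame, zero until [stabilize()] runs.
#' @return An object of class `animal_series`.
#' @export
animal_series <- function(animal_id, t_h, frames, head_roi = NULL,
                          wing_roi = NULL, shifts = NULL) {
  stopifnot(length(t_h) == length(frames), length(frames) >= 1)
  if (any(diff(t_h) <= 0)) stop("timestamps must be strictly increasing")
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) all(dim(f) == d), TRUE)))
    stop("all frames must have the same dimensions")
  if (is.null(shifts)) shifts <- matrix(0L, length(frames), 2)
  structure(list(animal_id = animal_id, t_h = t_h, frames = frames,
                 head_roi = head_roi, wing_roi = wing_roi, shifts = shifts,
                 flags = rep("", length(frames))),
            class = "animal_series")
}

#' @export
print.animal_series <- function(x, ...) {
  cat(sprintf("<animal_series> %s: %d frames (%dx%d), t = %.2f..%.2f h\n",
              x$animal_id, length(x$frames), nrow(x$frames[[1]]),
              ncol(x$frames[[1]]), x$t_h[1], x$t_h[length(x$t_h)]))
  invisible(x)
}

#' Read a burst manifest
#'
#' @param path CSV with columns `animal_id`, `t_h`, `burst_index`,
#'   `filename`.
#' @return A data frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "t_h", "burst_index", "filename")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("manifest lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$filename))
    stop("manifest filenames are not unique")
  df
}

# Fetch one frame, from an on-disk directory or an in-memory named list.
fetch_image <- function(images, filename) {
  if (is.character(images)) {
    path <- file.path(images, filename)
    if (!file.exists(path)) stop("unreadable image file: ", path)
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img * 255
  } else {
    img <- images[[filename]]
    if (is.null(img)) stop("image not found in memory: ", filename)
    img
  }
}

# Distance of the fly's intensity-weighted centroid from the frame center.
# Foreground = pixels above the frame's Otsu threshold.
centering_score <- function(frame) {
  thr <- EBImage::otsu(frame / 255, range = c(0, 1)) * 255
  fg <- frame > thr
  if (!any(fg)) return(Inf)
  w <- frame[fg]
  rows <- row(frame)[fg]; cols <- col(frame)[fg]
  cy <- sum(rows * w) / sum(w); cx <- sum(cols * w) / sum(w)
  sqrt((cy - (nrow(frame) + 1) / 2)^2 + (cx - (ncol(frame) + 1) / 2)^2)
}

#' Reconstruct one-frame-per-timepoint series from image bursts
#'
#' The filming rig captures a burst of images each time the rotating stage
#' carries an animal past the camera; the animal's position varies slightly
#' between burst images. For each burst this selects the image whose fly
#' centroid (intensity-weighted centroid of pixels above the frame's Otsu
#' threshold) lies nearest the frame center, breaking ties by lowest burst
#' index, and assembles the selected frames into one series per animal.
#'
#' @param manifest manifest data frame (see [read_manifest()]).
#' @param images directory containing the PNG frames, or a named list of
#'   matrices (as returned by [render_series()] with `out_dir = NULL`).
#' @param head_roi,wing_roi [roi()] rectangles to attach to each series.
#' @return A named list of [animal_series()], one per animal.
#' @export
reconstruct_series <- function(manifest, images, head_roi = NULL,
                               wing_roi = NULL) {
  out <- list()
  for (id in unique(manifest$animal_id)) {
    mi <- manifest[manifest$animal_id == id, ]
    times <- sort(unique(mi$t_h))
    frames <- vector("list", length(times))
    for (ti in seq_along(times)) {
      burst <- mi[mi$t_h == times[ti], ]
      if (nrow(burst) == 0)
        stop("empty burst for animal ", id, " at t = ", times[ti], " h")
      burst <- burst[order(burst$burst_index), ]
      scores <- vapply(burst$filename,
                       function(f) centering_score(fetch_image(images, f)), 0)
      best <- which.min(scores) # first minimum = lowest burst_index on ties
      frames[[ti]] <- fetch_image(images, burst$filename[best])
    }
    out[[id]] <- animal_series(id, times, frames, head_roi, wing_roi)
  }
  out
}

# Normalized cross-correlation of the overlap of two frames under an
# integer shift of `b` relative to `a`.
ncc_at_shift <- function(a, b, dy, dx) {
  h <- nrow(a); w <- ncol(a)
  ra <- max(1, 1 + dy):min(h, h + dy); ca <- max(1, 1 + dx):min(w, w + dx)
  rb <- ra - dy; cb <- ca - dx
  va <- as.vector(a[ra, ca]); vb <- as.vector(b[rb, cb])
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}

#' Stabilize an image series by integer translation
#'
#' Aligns each frame to its predecessor by the integer translation that
#' maximizes normalized cross-correlation within `+/-max_shift_px` per axis,
#' accumulating shifts so every frame is registered to the first. Subpixel
#' registration is deliberately not attempted: the rig jitter is a small
#' whole-pixel displacement of the camera crop. Ties prefer the smallest
#' displacement. A frame whose best shift sits on the search bound is
#' flagged (`flags` field) but still applied.
#'
#' @param series an [animal_series()].
#' @param max_shift_px search radius, pixels.
#' @return The stabilized [animal_series()]; `shifts` holds the detected
#'   (dy, dx) displacement of each raw frame relative to the first frame
#'   (the applied correction is its negative).
#' @export
stabilize <- function(series, max_shift_px = 5) {
  stopifnot(inherits(series, "animal_series"), length(series$frames) >= 1)
  n <- length(series$frames)
  shifts <- matrix(0L, n, 2)
  flags <- rep("", n)
  candidates <- expand.grid(dy = -max_shift_px:max_shift_px,
                            dx = -max_shift_px:max_shift_px)
  candidates <- candidates[order(candidates$dy^2 + candidates$dx^2,
                                 abs(candidates$dy), abs(candidates$dx)), ]
  frames <- series$frames
  ref <- frames[[1]]
  for (i in seq_len(n)[-1]) {
    cur <- frames[[i]]
    best <- c(0L, 0L); best_ncc <- -Inf
    for (k in seq_len(nrow(candidates))) {
      v <- ncc_at_shift(ref, cur, candidates$dy[k], candidates$dx[k])
      if (!is.na(v) && v > best_ncc + 1e-12) {
        best_ncc <- v; best <- c(candidates$dy[k], candidates$dx[k])
      }
    }
    if (is.infinite(best_ncc)) best <- c(0L, 0L) # degenerate constant frames
    if (any(abs(best) == max_shift_px))
      flags[i] <- "shift_at_bound"
    fill <- stats::median(cur)
    aligned <- shift_matrix(cur, best[1], best[2], fill)
    shifts[i, ] <- -best # detected displacement of the raw frame
    frames[[i]] <- aligned
    ref <- aligned
  }
  series$frames <- frames
  series$shifts <- shifts
  series$flags <- flags
  if (!is.null(series$head_roi) &&
      !roi_inside(series$head_roi, dim(frames[[1]])))
    stop("head ROI leaves the frame after stabilization")
  series
}
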