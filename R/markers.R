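#' Marker trace container
#'
#' A (time, value) series for one developmental-marker channel of one
#' animal: mean wing intensity (wing darkening; darker wings give smaller
#' values) or one of the two head-roughness indices.
#'
#' @param animal_id identifier.
#' @param t_h timestamps, hours.
#' @param value finite values; roughness channels must be non-negative.
#' @param channel `"wing_intensity"`, `"roughness_sd"` or
#'   `"roughness_borders"`.
#' @return A data frame of class `marker_trace` with attribute `channel`.
#' @export
marker_trace <- function(animal_id, t_h, value,
                         channel = c("wing_intensity", "roughness_sd",
                                     "roughness_borders")) {
  channel <- match.arg(channel)
  stopifnot(length(t_h) == length(value), all(is.finite(value)))
  if (channel != "wing_intensity" && any(value < 0))
    stop("roughness values must be non-negative")
  structure(data.frame(animal_id = animal_id, t_h = t_h, value = value),
            channel = channel, class = c("marker_trace", "data.frame"))
}

trace_channel <- function(trace) attr(trace, "channel")

#' @export
`[.marker_trace` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "channel") <- attr(x, "channel")
    class(out) <- c("marker_trace", "data.frame")
  }
  out
}

#' Wing-darkening trace
#'
#' Mean intensity of the wing region of interest on every frame of a
#' stabilized series. Wing darkening is a clock-independent marker of
#' developmental progress; the abrupt brightening at the end of the record
#' marks emergence (empty puparium).
#'
#' @param series a stabilized [animal_series()] with `wing_roi` set.
#' @return A [marker_trace()] with channel `"wing_intensity"`.
#' @export
wing_trace <- function(series) {
  if (is.null(series$wing_roi)) stop("series has no wing ROI")
  v <- vapply(series$frames,
              function(f) mean(extract_roi(f, series$wing_roi)), 0)
  marker_trace(series$animal_id, series$t_h, v, "wing_intensity")
}

# 3x3 box sum over the interior of a matrix (excludes the 1-pixel margin).
box3_sum <- function(m) {
  h <- nrow(m); w <- ncol(m)
  s <- matrix(0, h - 2L, w - 2L)
  for (dr in 0:2) for (dc in 0:2)
    s <- s + m[(1L + dr):(h - 2L + dr), (1L + dc):(w - 2L + dc), drop = FALSE]
  s
}

#' Local standard-deviation roughness index
#'
#' The "Standard deviation" roughness algorithm: for every interior pixel of
#' the region of interest, the population standard deviation of the nine
#' intensities in its 3x3 neighborhood (center included); the index is the
#' sum over interior pixels. A smooth reflection gives a low value; the
#' irregular patch borders that appear as molting fluid is resorbed drive it
#' up. Invariant to adding a constant to all intensities, and scales
#' linearly with a multiplicative intensity factor.
#'
#' `mode = "differences"` selects the alternative reading of the operator:
#' the population SD of the eight signed differences between each neighbor
#' and the center pixel.
#'
#' @param frame grayscale matrix (0-255).
#' @param roi a [roi()] at least 3x3.
#' @param mode `"neighborhood"` (default) or `"differences"`.
#' @return A single non-negative number.
#' @export
roughness_sd <- function(frame, roi, mode = c("neighborhood", "differences")) {
  mode <- match.arg(mode)
  if (roi$height < 3L || roi$width < 3L)
    stop("ROI must be at least 3x3 for the local-SD roughness index")
  x <- extract_roi(frame, roi)
  if (mode == "neighborhood") {
    s <- box3_sum(x); s2 <- box3_sum(x * x)
    v <- s2 / 9 - (s / 9)^2
    sum(sqrt(pmax(v, 0)))
  } else {
    h <- nrow(x); w <- ncol(x)
    ctr <- x[2:(h - 1L), 2:(w - 1L), drop = FALSE]
    sum_d <- matrix(0, h - 2L, w - 2L); sum_d2 <- sum_d
    for (dr in 0:2) for (dc in 0:2) {
      if (dr == 1 && dc == 1) next
      nb <- x[(1L + dr):(h - 2L + dr), (1L + dc):(w - 2L + dc), drop = FALSE]
      d <- nb - ctr
      sum_d <- sum_d + d; sum_d2 <- sum_d2 + d * d
    }
    v <- sum_d2 / 8 - (sum_d / 8)^2
    sum(sqrt(pmax(v, 0)))
  }
}

# 8-connected labeling of a logical matrix by breadth-first flood fill.
label8 <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  queue <- integer(h * w)
  for (start in which(bin)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    lab[start] <- nxt
    queue[1] <- start; qh <- 1L; qt <- 1L
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L
      pr <- ((p - 1L) %% h) + 1L; pc <- ((p - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r <- pr + dr; c <- pc + dc
        if (r < 1L || r > h || c < 1L || c > w) next
        q <- (c - 1L) * h + r
        if (bin[q] && lab[q] == 0L) {
          lab[q] <- nxt
          qt <- qt + 1L; queue[qt] <- q
        }
      }
    }
  }
  lab
}

#' Segment supra-threshold patches in a region of interest
#'
#' Patches are 8-connected components of pixels at or above a fixed
#' intensity threshold. The perimeter of a patch is its crack-edge count:
#' the number of pixel edges adjoining a sub-threshold or out-of-ROI pixel
#' (so a single pixel has perimeter 4, and splitting a patch in two always
#' increases total perimeter).
#'
#' @param frame grayscale matrix.
#' @param roi a [roi()].
#' @param threshold intensity threshold, held fixed across an animal's
#'   series (see [roughness_trace()]).
#' @return A data frame with one row per patch: `patch`, `area_px`,
#'   `perimeter_px`; the label matrix is attached as attribute `labels`.
#' @export
segment_patches <- function(frame, roi, threshold) {
  x <- extract_roi(frame, roi)
  bin <- x >= threshold
  lab <- label8(bin)
  n <- max(lab)
  if (n == 0L) {
    out <- data.frame(patch = integer(0), area_px = integer(0),
                      perimeter_px = integer(0))
    attr(out, "labels") <- lab
    return(out)
  }
  area <- tabulate(lab[lab > 0L], nbins = n)
  # internal 4-adjacencies per label; perimeter = 4*area - 2*adjacencies
  h <- nrow(lab); w <- ncol(lab)
  adj <- integer(n)
  if (w > 1L) {
    a <- lab[, 1:(w - 1L)]; b <- lab[, 2:w]
    same <- a > 0L & a == b
    adj <- adj + tabulate(a[same], nbins = n)
  }
  if (h > 1L) {
    a <- lab[1:(h - 1L), ]; b <- lab[2:h, ]
    same <- a > 0L & a == b
    adj <- adj + tabulate(a[same], nbins = n)
  }
  out <- data.frame(patch = seq_len(n), area_px = area,
                    perimeter_px = 4L * area - 2L * adj)
  attr(out, "labels") <- lab
  out
}

#' Patch-perimeter roughness index
#'
#' The "Borders" roughness algorithm: the sum of the crack-edge perimeters
#' of all supra-threshold patches in the region of interest (see
#' [segment_patches()]).
#'
#' @inheritParams segment_patches
#' @return A single non-negative number (0 when no patch exists).
#' @export
roughness_borders <- function(frame, roi, threshold) {
  sum(segment_patches(frame, roi, threshold)$perimeter_px)
}

#' Roughness trace of a stabilized series
#'
#' Applies one of the two roughness operators to the head region of every
#' frame. For the borders algorithm the patch threshold is computed once,
#' by Otsu's method on the head ROI of the first frame, and frozen for the
#' whole series, so that fragmentation is not confounded with slow
#' illumination drift.
#'
#' @param series a stabilized [animal_series()] with `head_roi` set.
#' @param algorithm `"sd"` or `"borders"`.
#' @param sd_mode passed to [roughness_sd()].
#' @param threshold optional fixed threshold overriding the Otsu rule.
#' @return A [marker_trace()].
#' @export
roughness_trace <- function(series, algorithm = c("sd", "borders"),
                            sd_mode = "neighborhood", threshold = NULL) {
  algorithm <- match.arg(algorithm)
  if (is.null(series$head_roi)) stop("series has no head ROI")
  if (algorithm == "sd") {
    v <- vapply(series$frames,
                function(f) roughness_sd(f, series$head_roi, sd_mode), 0)
    marker_trace(series$animal_id, series$t_h, v, "roughness_sd")
  } else {
    if (is.null(threshold)) {
      first <- extract_roi(series$frames[[1]], series$head_roi)
      threshold <- EBImage::otsu(first / 255, range = c(0, 1)) * 255
    }
    v <- vapply(series$frames,
                function(f) roughness_borders(f, series$head_roi, threshold), 0)
    marker_trace(series$animal_id, series$t_h, v, "roughness_borders")
  }
}

#' High-pass filter a marker trace
#'
#' Subtracts a centered moving average spanning `window_h` hours (truncated
#' at the record ends), removing the slow component of the trace so that
#' the start of roughening appears as a departure from a flat baseline.
#'
#' @param trace a [marker_trace()] with at least 3 samples.
#' @param window_h filter window, hours; must span at least 3 samples.
#' @return A [marker_trace()] on the same timestamps.
#' @export
highpass <- function(trace, window_h = 6) {
  if (nrow(trace) < 3L) stop("trace must have at least 3 samples")
  dt <- infer_dt(trace$t_h)
  half <- max(1L, round(window_h / (2 * dt)))
  if (2L * half + 1L < 3L) stop("window spans fewer than 3 samples")
  hp <- trace$value - moving_average(trace$value, half)
  out <- trace
  out$value <- hp
  out
}

#' Detect the onset of head roughening
#'
#' High-pass filters the trace (value minus centered moving average over
#' `window_h`), estimates the baseline noise level as the median absolute
#' deviation (MAD) over the first quarter of the record, and locates the
#' first sustained excursion of the filtered magnitude above
#' `k_mad * MAD` -- at least `min_run` consecutive samples. The onset is
#' the first local extremum of the filtered magnitude within that
#' excursion: a centered-window high-pass of a flat-then-rising trace
#' reaches its largest magnitude exactly at the corner where the rise
#' begins. Samples after the detected
#' emergence are excluded first. Returns `NA` (not an error) when no
#' sustained excursion exists; a zero baseline MAD falls back to the MAD of
#' the whole filtered record.
#'
#' @param trace a roughness [marker_trace()] covering at least 6 h of
#'   baseline before any rise.
#' @param window_h high-pass window, hours.
#' @param k_mad detection threshold in baseline-MAD units.
#' @param min_run required run length, samples.
#' @return Onset time in hours, or `NA_real_`.
#' @export
detect_onset <- function(trace, window_h = 6, k_mad = 4, min_run = 5L) {
  emergence <- detect_emergence(trace)
  keep <- if (is.na(emergence)) rep(TRUE, nrow(trace)) else trace$t_h < emergence
  tr <- trace[keep, , drop = FALSE]
  if (nrow(tr) < 3L) return(NA_real_)
  if (tr$t_h[nrow(tr)] - tr$t_h[1] < 6)
    warning("less than 6 h of record before emergence; onset may be unreliable")
  half <- max(1L, round(window_h / (2 * infer_dt(tr$t_h))))
  hp <- tr$value - moving_average(tr$value, half)
  nq <- max(2L, floor(nrow(tr) / 4))
  noise <- stats::mad(hp[seq_len(nq)], center = stats::median(hp[seq_len(nq)]))
  if (noise == 0) noise <- stats::mad(hp)
  if (noise == 0) return(NA_real_)
  above <- abs(hp) > k_mad * noise
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  first <- which(r$values & r$lengths >= min_run)
  if (!length(first)) return(NA_real_)
  i0 <- starts[first[1]]; i1 <- ends[first[1]]
  # walk to the excursion's first local extremum on a lightly smoothed
  # magnitude, so sample-level noise wiggles do not stop the walk early
  ahp <- moving_average(abs(hp), 2L)
  j <- i0
  while (j < i1 && ahp[j + 1L] > ahp[j]) j <- j + 1L
  tr$t_h[j]
}

#' Detect emergence from a marker trace
#'
#' Emergence is the largest single-step change of the channel's expected
#' sign -- a sudden brightening of the wing region (empty puparium) or a
#' sudden drop of a roughness index -- provided its magnitude exceeds
#' `k_jump` robust SDs (MAD scaled by 1.4826) of all step differences.
#' Returns `NA` when no step is large enough (e.g. a gentle monotone ramp).
#'
#' @param trace a [marker_trace()] with at least 3 samples.
#' @param k_jump detection threshold in robust-SD units.
#' @return Time (hours) of the first sample after the jump, or `NA_real_`.
#' @export
detect_emergence <- function(trace, k_jump = 6) {
  if (nrow(trace) < 3L) stop("trace must have at least 3 samples")
  d <- diff(trace$value)
  sign_ok <- if (trace_channel(trace) == "wing_intensity") d else -d
  scale <- stats::mad(d) # mad() already applies the 1.4826 scale
  # a (numerically) constant-slope ramp has MAD ~ 0 but a typical step of
  # |median|; it must not register as a jump
  med <- abs(stats::median(d))
  if (scale <= 1e-8 * max(med, 1e-300)) scale <- med
  i <- which.max(sign_ok)
  if (sign_ok[i] <= 0) return(NA_real_)
  if (abs(d[i]) < k_jump * scale) return(NA_real_)
  trace$t_h[i + 1L]
}

#' Per-animal onset and duration summaries
#'
#' For each animal's roughness trace, detects roughening onset and
#' emergence and reports the two quantities summarized in group analyses:
#' time to roughening start (hours from DD start to onset) and roughening
#' duration (hours from onset to emergence). Animals whose onset or
#' emergence cannot be detected, or whose detected emergence precedes
#' onset, are excluded with a reason.
#'
#' @param traces list of roughness [marker_trace()] objects (one per
#'   animal).
#' @param dd_start_t_h recording time of DD start, hours.
#' @param groups optional named vector mapping animal ids to group labels;
#'   adds quartile summaries per group.
#' @param ... passed to [detect_onset()].
#' @return A list with `animals` (data frame: `animal_id`, `onset_t_h`,
#'   `emergence_t_h`, `time_to_onset_h`, `duration_h`), `excluded` (data
#'   frame with reasons), and `group_summary` (quartiles per group, when
#'   groups are given).
#' @export
summarize_onsets <- function(traces, dd_start_t_h = 0, groups = NULL, ...) {
  rows <- list(); excl <- list()
  for (tr in traces) {
    id <- tr$animal_id[1]
    onset <- detect_onset(tr, ...)
    emergence <- detect_emergence(tr)
    if (is.na(onset) || is.na(emergence)) {
      excl[[length(excl) + 1L]] <-
        data.frame(animal_id = id,
                   reason = if (is.na(onset)) "no onset detected"
                            else "no emergence detected")
      next
    }
    if (emergence <= onset) {
      excl[[length(excl) + 1L]] <-
        data.frame(animal_id = id, reason = "emergence precedes onset")
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(animal_id = id, onset_t_h = onset,
                 emergence_t_h = emergence,
                 time_to_onset_h = onset - dd_start_t_h,
                 duration_h = emergence - onset)
  }
  animals <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal_id = character(0), onset_t_h = numeric(0),
               emergence_t_h = numeric(0), time_to_onset_h = numeric(0),
               duration_h = numeric(0))
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(animal_id = character(0), reason = character(0))
  group_summary <- NULL
  if (!is.null(groups) && nrow(animals)) {
    g <- groups[animals$animal_id]
    group_summary <- do.call(rbind, lapply(split(animals, g), function(a) {
      q1 <- stats::quantile(a$time_to_onset_h, c(.25, .5, .75))
      q2 <- stats::quantile(a$duration_h, c(.25, .5, .75))
      data.frame(group = g[match(a$animal_id[1], animals$animal_id)],
                 n = nrow(a),
                 onset_q1 = q1[1], onset_med = q1[2], onset_q3 = q1[3],
                 dur_q1 = q2[1], dur_med = q2[2], dur_q3 = q2[3],
                 row.names = NULL)
    }))
  }
  list(animals = animals, excluded = excluded, group_summary = group_summary)
}

# Compact-letter display from a logical "significantly different" matrix,
# by the usual insert-and-absorb construction: groups sharing a letter are
# not significantly different.
compact_letters <- function(diff_mat) {
  g <- rownames(diff_mat)
  sets <- list(g) # start with one letter covering everyone
  for (i in seq_along(g)) for (j in seq_len(i - 1L)) {
    if (!diff_mat[i, j]) next
    for (k in seq_along(sets)) {
      s <- sets[[k]]
      if (all(c(g[i], g[j]) %in% s)) {
        sets[[k]] <- setdiff(s, g[i])
        cand <- setdiff(s, g[j])
        dup <- any(vapply(sets, function(x) all(cand %in% x), TRUE))
        if (!dup) sets[[length(sets) + 1L]] <- cand
      }
    }
    sets <- sets[!vapply(sets, function(s)
      any(vapply(sets, function(x)
        length(s) < length(x) && all(s %in% x), TRUE)), TRUE)]
  }
  letters_out <- stats::setNames(rep("", length(g)), g)
  for (k in seq_along(sets))
    for (m in sets[[k]])
      letters_out[m] <- paste0(letters_out[m], letters[k])
  letters_out[order(names(letters_out))]
}

#' One-way ANOVA with Tukey HSD and compact-letter display
#'
#' Standard fixed-effects one-way analysis of variance followed by Tukey
#' honest-significant-difference pairwise comparisons at `alpha`; groups
#' that share a letter in the compact-letter display are not significantly
#' different.
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor), at least two groups with
#'   two values each.
#' @param alpha significance level for the pairwise comparisons.
#' @return A list with `F`, `df` (numerator, denominator), `p`, `tukey`
#'   (data frame of pairwise comparisons) and `letters`.
#' @examples
#' group_compare(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))$F # 1.5
#' @export
group_compare <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two values")
  if (all(vapply(split(values, groups), stats::var, 0) == 0) &&
      stats::var(tapply(values, groups, mean)) == 0)
    stop("zero within-group variance with equal means: F is undefined")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  cmp <- data.frame(comparison = rownames(tk), tk, row.names = NULL)
  names(cmp) <- c("comparison", "diff", "lwr", "upr", "p_adj")
  lv <- levels(groups)
  diff_mat <- matrix(FALSE, nlevels(groups), nlevels(groups),
                     dimnames = list(lv, lv))
  for (r in seq_len(nrow(cmp))) {
    pair <- strsplit(cmp$comparison[r], "-", fixed = TRUE)[[1]]
    sig <- cmp$p_adj[r] < alpha
    diff_mat[pair[1], pair[2]] <- sig
    diff_mat[pair[2], pair[1]] <- sig
  }
  list(F = tab[["F value"]][1],
       df = c(tab[["Df"]][1], tab[["Df"]][2]),
       p = tab[["Pr(>F)"]][1],
       tukey = cmp,
       letters = compact_letters(diff_mat))
}
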