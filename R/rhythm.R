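#' Autocorrelogram of an eclosion record
#'
#' Biased (divide-by-total-variance, non-circular) sample autocorrelation of
#' the binned counts:
#' \deqn{r(\ell) = \sum_t (x_t - \bar x)(x_{t+\ell} - \bar x) /
#'       \sum_t (x_t - \bar x)^2}
#' for lags 0..`max_lag_h` in bin steps. The biased estimator gives the
#' decaying peak envelope on which the rhythmicity index is defined; an
#' unbiased estimator would inflate coefficients at long lags.
#'
#' @param record an [event_record()] with positive count variance.
#' @param max_lag_h maximum lag, hours; at most half the record span.
#' @return An object of class `correlogram` with fields `lag_h`, `r`,
#'   `n_bins`, `bin_h`.
#' @export
autocorrelogram <- function(record, max_lag_h = 72) {
  stopifnot(inherits(record, "event_record"))
  x <- as.numeric(record$counts)
  n <- length(x)
  if (stats::var(x) == 0)
    stop("degenerate record: counts have zero variance")
  max_lag <- floor(max_lag_h / record$bin_h)
  if (max_lag > floor(n / 2)) {
    max_lag <- floor(n / 2)
    warning("max_lag_h capped at half the record span")
  }
  r <- as.vector(stats::acf(x, lag.max = max_lag, plot = FALSE,
                            demean = TRUE)$acf)
  structure(list(lag_h = (0:max_lag) * record$bin_h, r = r,
                 n_bins = n, bin_h = record$bin_h),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> %d lags up to %g h (bin %g h, N = %d bins)\n",
              length(x$lag_h), max(x$lag_h), x$bin_h, x$n_bins))
  invisible(x)
}

# Local maxima (with a simple prominence estimate) of a smoothed
# correlogram, lag 0 excluded. Prominence of a peak is its height above the
# higher of the two adjacent valleys. Peaks must also clear `min_height` on
# the raw coefficient -- by default the white-noise 95% significance line
# 1.96/sqrt(N) drawn on correlograms, without which small-lag noise bumps
# of a counts record qualify as peaks.
correlogram_peaks <- function(cg, smooth_lags = 3L, prominence = 0.02,
                              min_height = NULL) {
  if (is.null(min_height))
    min_height <- stats::qnorm(0.975) / sqrt(cg$n_bins)
  s <- moving_average(cg$r, half_width = (smooth_lags - 1L) %/% 2L)
  n <- length(s)
  peaks <- integer(0)
  for (i in 2:(n - 1L)) {
    if (s[i] > s[i - 1L] && s[i] >= s[i + 1L]) peaks <- c(peaks, i)
  }
  if (!length(peaks))
    return(data.frame(lag_h = numeric(0), r = numeric(0),
                      smoothed = numeric(0)))
  # refine each smoothed peak to the raw-coefficient maximum within the
  # smoothing window: a narrow spike's smoothed maximum can sit one lag off
  # the spike itself
  half <- (smooth_lags - 1L) %/% 2L
  refined <- vapply(peaks, function(i) {
    win <- max(2L, i - half):min(n, i + half)
    win[which.max(cg$r[win])]
  }, 0L)
  # textbook prominence: height above the higher of the two minima taken
  # between the peak and the nearest strictly higher point on each side
  keep <- logical(length(peaks))
  for (k in seq_along(peaks)) {
    i <- peaks[k]
    lo <- i; while (lo > 1L && s[lo] <= s[i]) lo <- lo - 1L
    hi <- i; while (hi < n && s[hi] <= s[i]) hi <- hi + 1L
    left_valley <- min(s[lo:i])
    right_valley <- min(s[i:hi])
    keep[k] <- (s[i] - max(left_valley, right_valley)) >= prominence &&
      cg$r[refined[k]] >= min_height
  }
  refined <- unique(refined[keep])
  data.frame(lag_h = cg$lag_h[refined], r = cg$r[refined],
             smoothed = s[refined])
}

#' Rhythmicity index, period and classification from a correlogram
#'
#' Finds the local maxima of the correlogram smoothed over `smooth_lags`
#' lags (lag 0 excluded, prominence at least `prominence`). The period
#' estimate is the lag of the first peak; the rhythmicity index (RI) is the
#' coefficient at the second peak -- the "third peak" of the correlogram
#' when lag 0 is counted first, the convention of correlogram-based RI
#' analysis (`ri_peak` switches to another peak). Classification follows
#' the standard cutoffs: rhythmic when RI > 0.3, weakly rhythmic for RI in
#' [0.1, 0.3], arrhythmic when RI < 0.1. A record with fewer than two
#' detectable peaks is flagged aperiodic and classified arrhythmic (RI is
#' `NA`).
#'
#' @param correlogram a [autocorrelogram()] result.
#' @param smooth_lags smoothing window for peak finding, lags.
#' @param prominence minimum peak prominence.
#' @param min_height minimum raw coefficient at a peak; defaults to the
#'   white-noise 95% significance line `1.96/sqrt(N)`.
#' @param ri_peak index of the non-zero-lag peak whose coefficient is
#'   reported as RI (default 2).
#' @param harmonic_tol relative tolerance of the aperiodicity check: in a
#'   genuinely periodic correlogram the second peak sits near twice the lag
#'   of the first, so a record whose second peak misses
#'   `2 * period * (1 +/- harmonic_tol)` is flagged "obviously aperiodic"
#'   and classified arrhythmic whatever the coefficient there.
#' @return An object of class `rhythm_result`: `ri`, `period_h`,
#'   `classification`, `aperiodic`, `peaks`.
#' @export
rhythm_analyze <- function(correlogram, smooth_lags = 3L, prominence = 0.02,
                           min_height = NULL, ri_peak = 2L,
                           harmonic_tol = 0.25) {
  stopifnot(inherits(correlogram, "correlogram"))
  pk <- correlogram_peaks(correlogram, smooth_lags, prominence, min_height)
  aperiodic <- nrow(pk) < 2L ||
    abs(pk$lag_h[2L] - 2 * pk$lag_h[1L]) > harmonic_tol * 2 * pk$lag_h[1L]
  if (aperiodic) {
    res <- list(ri = NA_real_,
                period_h = if (nrow(pk)) pk$lag_h[1] else NA_real_,
                classification = "arrhythmic", aperiodic = TRUE, peaks = pk)
    return(structure(res, class = "rhythm_result"))
  }
  ri <- pk$r[min(ri_peak, nrow(pk))]
  cls <- if (ri > 0.3) "rhythmic"
         else if (ri >= 0.1) "weakly_rhythmic"
         else "arrhythmic"
  structure(list(ri = ri, period_h = pk$lag_h[1], classification = cls,
                 aperiodic = FALSE, peaks = pk),
            class = "rhythm_result")
}

#' @export
print.rhythm_result <- function(x, ...) {
  cat(sprintf("<rhythm_result> RI = %s, period = %s h, %s%s\n",
              format(round(x$ri, 3)), format(round(x$period_h, 2)),
              x$classification,
              if (x$aperiodic) " (aperiodic)" else ""))
  invisible(x)
}

#' Classify a rhythmicity index
#'
#' The three-way cutoff rule on its own: RI > 0.3 rhythmic, 0.1 <= RI <=
#' 0.3 weakly rhythmic, RI < 0.1 arrhythmic.
#'
#' @param ri rhythmicity index (vectorized).
#' @return Character vector.
#' @export
classify_ri <- function(ri) {
  ifelse(is.na(ri), "arrhythmic",
         ifelse(ri > 0.3, "rhythmic",
                ifelse(ri >= 0.1, "weakly_rhythmic", "arrhythmic")))
}

#' Valley-spacing criterion for rhythmicity
#'
#' Rhythmic emergence records invariably contain recurring valleys --
#' sustained stretches during which few flies emerge -- spaced by about one
#' circadian period. The record is smoothed with a 3-h moving average;
#' valleys are maximal runs, lasting at least `min_valley_h`, in which the
#' smoothed counts stay below the 20th percentile of the smoothed values
#' over the span between the first and last nonzero bins. The criterion is
#' met when at least two valley centers exist and the median spacing of
#' consecutive centers lies within `expected_period_h +/- tol_h`.
#'
#' The duration floor keeps brief noise dips in an arrhythmic record from
#' counting as valleys; without it, any record has bins below its own 20th
#' percentile.
#'
#' @param record an [event_record()] spanning at least two expected
#'   periods.
#' @param expected_period_h expected circadian period, hours.
#' @param tol_h spacing tolerance, hours.
#' @param min_valley_h minimum valley duration, hours.
#' @return `TRUE` or `FALSE` (with a warning for an all-zero record).
#' @export
valley_criterion <- function(record, expected_period_h = 24, tol_h = 4,
                             min_valley_h = 6) {
  stopifnot(inherits(record, "event_record"))
  x <- as.numeric(record$counts)
  if (all(x == 0)) {
    warning("all-zero record: valley criterion is vacuous")
    return(FALSE)
  }
  span_h <- length(x) * record$bin_h
  if (span_h < 2 * expected_period_h)
    stop("record must span at least two expected periods")
  half <- max(1L, round(3 / record$bin_h / 2))
  s <- moving_average(x, half)
  nz <- range(which(x > 0))
  span <- nz[1]:nz[2]
  thr <- stats::quantile(s[span], 0.20, names = FALSE)
  # <= so that the long empty stretches of a strongly gated record (well
  # over a fifth of the span at zero) still count as valleys
  low <- s <= thr
  low[-span] <- FALSE
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_len <- max(1L, round(min_valley_h / record$bin_h))
  vi <- which(r$values & r$lengths >= min_len)
  if (length(vi) < 2L) return(FALSE)
  centers <- record$bin_start_t_h[starts[vi]] +
    (r$lengths[vi] * record$bin_h) / 2
  gaps <- diff(centers)
  abs(stats::median(gaps) - expected_period_h) <= tol_h
}

#' Full rhythmicity analysis of an eclosion record
#'
#' Convenience wrapper: autocorrelogram, rhythmicity index, period,
#' classification and valley criterion in one call.
#'
#' @param record an [event_record()].
#' @param max_lag_h maximum correlogram lag, hours.
#' @param expected_period_h expected period for the valley criterion.
#' @param ... passed to [rhythm_analyze()].
#' @return A `rhythm_result` with an extra `valleys_ok` field and the
#'   correlogram attached as `correlogram`.
#' @export
rhythm_report <- function(record, max_lag_h = 72, expected_period_h = 24,
                          ...) {
  cg <- autocorrelogram(record, max_lag_h)
  res <- rhythm_analyze(cg, ...)
  res$valleys_ok <- valley_criterion(record, expected_period_h)
  res$correlogram <- cg
  res
}
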