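#' Rectangular region of interest
#'
#' Builds a rectangle in matrix (row, column) coordinates, rows counted from
#' the top of the image. Used for the wing and head regions analysed along a
#' time-lapse series.
#'
#' @param row,col top-left corner (1-based).
#' @param height,width extent in pixels.
#' @return An object of class `roi`.
#' @export
roi <- function(row, col, height, width) {
  stopifnot(row >= 1, col >= 1, height >= 1, width >= 1)
  structure(list(row = as.integer(row), col = as.integer(col),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> rows %d..%d, cols %d..%d\n",
              x$row, x$row + x$height - 1L, x$col, x$col + x$width - 1L))
  invisible(x)
}

roi_rows <- function(r) seq.int(r$row, r$row + r$height - 1L)
roi_cols <- function(r) seq.int(r$col, r$col + r$width - 1L)

roi_inside <- function(r, dim_hw) {
  r$row >= 1 && r$col >= 1 &&
    r$row + r$height - 1L <= dim_hw[1] &&
    r$col + r$width - 1L <= dim_hw[2]
}

extract_roi <- function(frame, r) {
  if (!roi_inside(r, dim(frame)))
    stop("ROI extends outside the frame")
  frame[roi_rows(r), roi_cols(r), drop = FALSE]
}

# Integer translation of a matrix; vacated pixels take `fill`.
# Positive dy moves content down, positive dx moves it right.
shift_matrix <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# Centered moving average with the window truncated at both ends,
# so every output sample averages only observed values.
moving_average <- function(x, half_width) {
  n <- length(x)
  if (half_width <= 0L) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_width, 1L)
  hi <- pmin(i + half_width, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Sampling interval of a (supposedly) uniform time grid, with a tolerance
# check; cadence bookkeeping relies on this.
infer_dt <- function(t_h, tol = 1e-6) {
  d <- diff(t_h)
  if (length(d) == 0L) stop("need at least two samples to infer a cadence")
  if (any(d <= 0)) stop("timestamps must be strictly increasing")
  dt <- stats::median(d)
  if (any(abs(d - dt) > tol * max(1, dt)))
    warning("timestamps are not uniformly spaced; using the median interval")
  dt
}

# Deterministic per-unit sub-seed derived from a root seed, so that earlier
# units keep their random draws when more units are added.
substream_seed <- function(root_seed, index) {
  as.integer((as.double(root_seed) * 48271 + index * 16807) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
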