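#' Binned population emergence record
#'
#' Container for a population eclosion assay record: counts of flies
#' emerging in uniform half-open time bins under constant darkness, as
#' produced by an eclosion monitor.
#'
#' @param bin_start_t_h left edges of uniform bins, hours since DD start.
#' @param counts non-negative integer counts per bin.
#' @param bin_h bin width, hours.
#' @param meta list of light-schedule metadata (free text), e.g. DD start
#'   and prior LD phase.
#' @return An object of class `event_record`.
#' @export
event_record <- function(bin_start_t_h, counts, bin_h, meta = list()) {
  stopifnot(length(bin_start_t_h) == length(counts), bin_h > 0,
            all(counts >= 0))
  if (length(bin_start_t_h) > 1) {
    d <- diff(bin_start_t_h)
    if (any(abs(d - bin_h) > 1e-8))
      stop("bins must be uniform with width bin_h")
  }
  structure(list(bin_start_t_h = bin_start_t_h,
                 counts = as.integer(round(counts)),
                 bin_h = bin_h, meta = meta),
            class = "event_record")
}

#' @export
print.event_record <- function(x, ...) {
  cat(sprintf("<event_record> %d bins of %g h, %d events, t = [%g, %g) h\n",
              length(x$counts), x$bin_h, sum(x$counts),
              x$bin_start_t_h[1],
              x$bin_start_t_h[length(x$bin_start_t_h)] + x$bin_h))
  invisible(x)
}

#' Bin emergence event times into an eclosion record
#'
#' @param emergence_times_h event times, hours.
#' @param bin_h bin width, hours.
#' @param t_start,t_end recording window; bins are half-open `[b, b+bin_h)`
#'   and events outside `[t_start, t_end)` are dropped.
#' @param meta metadata list stored on the record.
#' @return An [event_record()].
#' @export
bin_events <- function(emergence_times_h, bin_h, t_start, t_end,
                       meta = list()) {
  stopifnot(bin_h > 0, t_start < t_end)
  edges <- seq(t_start, t_end, by = bin_h)
  if (edges[length(edges)] < t_end) edges <- c(edges, t_end)
  n_bins <- length(edges) - 1L
  keep <- emergence_times_h >= t_start & emergence_times_h < t_end
  idx <- floor((emergence_times_h[keep] - t_start) / bin_h) + 1L
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  event_record(edges[seq_len(n_bins)], counts, bin_h, meta)
}

#' Simulate a population eclosion monitor record
#'
#' Simulates a developing population with the gating model and bins its
#' emergence times, emulating the population assay: pupae accumulate over
#' several days (either continuously, as on an eclosion monitor loaded from
#' bottle cultures, or as synchronized white-prepupa collections), develop,
#' and emerge under the clock regime in `params`. The recording window
#' spans `n_days` days starting when the earliest cohorts complete
#' development.
#'
#' @param params a [gating_params()] object.
#' @param pupariation_zts collection Zeitgeber times; if `NULL` (default)
#'   pupariation times are drawn uniformly over the loading span, emulating
#'   an unsynchronized monitor population.
#' @param n total number of flies.
#' @param n_days length of the recording window, days.
#' @param bin_h bin width, hours.
#' @param seed integer root seed.
#' @return An [event_record()]; its `meta` carries the preset fields and the
#'   ground-truth schedule data frame (`meta$schedules`).
#' @examples
#' rec <- generate_event_record(gating_preset("wildtype"), n = 300,
#'                              n_days = 7, bin_h = 0.5, seed = 1)
#' sum(rec$counts)
#' @export
generate_event_record <- function(params, pupariation_zts = NULL, n = 300,
                                  n_days = 7, bin_h = 0.5, seed) {
  stopifnot(inherits(params, "gating_params"), n >= 0, n_days >= 1, bin_h > 0)
  if (missing(seed) || is.null(seed)) stop("an explicit integer seed is required")
  t_start <- bin_h * floor((params$commit_mean_h + params$rough_mean_h) / bin_h)
  t_end <- t_start + n_days * 24
  meta <- list(model = params$model, tau_h = params$tau_h,
               dd_start_t_h = 0, prior_ld = "12:12 LD before DD",
               n_flies = n)
  if (n == 0)
    return(bin_events(numeric(0), bin_h, t_start, t_end, meta))
  if (is.null(pupariation_zts)) {
    set.seed(substream_seed(seed, 0L))
    offsets <- stats::runif(n, 0, n_days * 24)
    sch <- simulate_cohort(params, seed = seed,
                           pupariation_offsets_h = offsets)
  } else {
    combos <- expand.grid(day = seq_len(n_days) - 1L, zt = pupariation_zts)
    per <- ceiling(n / nrow(combos))
    offsets <- rep(24 * combos$day + combos$zt, each = per)[seq_len(n)]
    sch <- simulate_cohort(params, seed = seed,
                           pupariation_offsets_h = offsets)
    sch$group_zt <- rep(combos$zt, each = per)[seq_len(n)]
  }
  rec <- bin_events(sch$emergence_t_h, bin_h, t_start, t_end, meta)
  rec$meta$schedules <- sch
  rec
}

#' Write a self-describing test fixture
#'
#' Generates, entirely from code, one of the small fixtures used by the test
#' suite: short rendered image series with their manifest and ground-truth
#' schedules, or simulated population event records under the three clock
#' regimes.
#'
#' @param kind one of `"images_small"`, `"images_cohorts"`, `"events_wt"`,
#'   `"events_short"`, `"events_arrhythmic"`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; regeneration with the same seed is
#'   byte-identical.
#' @return Invisibly, a character vector of files written.
#' @export
write_fixture <- function(kind = c("images_small", "images_cohorts",
                                   "events_wt", "events_short",
                                   "events_arrhythmic"),
                          out_dir, seed) {
  kind <- match.arg(kind)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (kind %in% c("images_small", "images_cohorts")) {
    n_animals <- if (kind == "images_small") 3L else 9L
    sch <- fixture_schedules(n_animals, seed)
    scene <- fixture_scene()
    files <- character(0)
    manifests <- vector("list", n_animals)
    for (i in seq_len(n_animals)) {
      rs <- render_series(sch[i, ], scene, seed = substream_seed(seed, 100 + i),
                          out_dir = out_dir, animal_id = sch$fly_id[i])
      manifests[[i]] <- rs$manifest
    }
    manifest <- do.call(rbind, manifests)
    mpath <- file.path(out_dir, "manifest.csv")
    utils::write.csv(manifest, mpath, row.names = FALSE)
    spath <- file.path(out_dir, "schedules.csv")
    write_schedules(sch, spath)
    invisible(c(mpath, spath, file.path(out_dir, manifest$filename)))
  } else {
    preset <- switch(kind, events_wt = "wildtype",
                     events_short = "short_period",
                     events_arrhythmic = "arrhythmic")
    zts <- if (kind == "events_wt") c(6, 12, 18) else NULL
    rec <- generate_event_record(gating_preset(preset),
                                 pupariation_zts = zts,
                                 n = 300, n_days = 7, bin_h = 0.5,
                                 seed = seed)
    path <- file.path(out_dir, paste0(kind, ".csv"))
    write_event_record(rec, path)
    invisible(path)
  }
}

# Short compressed schedules for image fixtures: same scheduling model, but
# development compressed so a rendered series spans ~20-30 h instead of
# several days (keeps fixtures regenerable in seconds).
fixture_schedules <- function(n_animals, seed) {
  p <- gating_params("developmental", tau_h = 24, gate_open_ct = 0,
                     gate_width_h = 10, commit_mean_h = 12, commit_sd_h = 2,
                     rough_mean_h = 10, rough_sd_h = 1, ct0_offset_h = 12)
  zts <- rep(c(0, 2, 4), length.out = n_animals)
  simulate_cohort(p, pupariation_offsets_h = zts, seed = seed)
}

# Compact scene used by fixtures: smaller frames and bursts than the rig
# defaults, same appearance model.
fixture_scene <- function(noise_sd = 2, jitter_px = 2, burst_size = 5) {
  scene_params(frame_h = 120, frame_w = 120,
               body_center = c(60, 60), body_axes = c(44, 28),
               head_roi = roi(20, 42, 36, 36), wing_roi = roi(70, 45, 28, 28),
               head_center = c(36, 60), head_axes = c(12, 12),
               noise_sd = noise_sd, jitter_px = jitter_px,
               burst_size = burst_size)
}

#' Read and write event-record CSV files
#'
#' Two dialects are understood on input, auto-detected from the header: a
#' binned record (`bin_start_h,count`) or raw event times (`t_h`), which are
#' binned with `bin_h`.
#'
#' @param record an [event_record()].
#' @param path CSV path.
#' @param bin_h bin width used when reading a raw event-time file.
#' @return `read_event_record()` returns an [event_record()].
#' @export
write_event_record <- function(record, path) {
  utils::write.csv(data.frame(bin_start_h = record$bin_start_t_h,
                              count = record$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_record
#' @export
read_event_record <- function(path, bin_h = 0.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("bin_start_h", "count") %in% names(df))) {
    w <- if (nrow(df) > 1) df$bin_start_h[2] - df$bin_start_h[1] else bin_h
    event_record(df$bin_start_h, df$count, w)
  } else if ("t_h" %in% names(df)) {
    t0 <- floor(min(df$t_h)); t1 <- ceiling(max(df$t_h) + 1e-9)
    bin_events(df$t_h, bin_h, t0, t1)
  } else {
    stop("unrecognized event CSV header: expected bin_start_h,count or t_h")
  }
}
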