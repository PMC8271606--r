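test_that("wing trace is the mean ROI intensity per frame", {
  f1 <- matrix(100, 20, 20); f2 <- matrix(50, 20, 20)
  ser <- animal_series("a", c(0, 0.2), list(f1, f2),
                       wing_roi = roi(5, 5, 8, 8))
  tr <- wing_trace(ser)
  expect_equal(tr$value, c(100, 50))
  expect_equal(attr(tr, "channel"), "wing_intensity")
})

test_that("local-SD roughness matches hand examples and the oracle", {
  r33 <- roi(1, 1, 3, 3)
  expect_equal(roughness_sd(matrix(7, 3, 3), r33), 0)
  f <- matrix(0, 3, 3); f[2, 2] <- 9
  expect_equal(roughness_sd(f, r33), sqrt(8))
  expect_error(roughness_sd(f, roi(1, 1, 2, 3)), "3x3")

  set.seed(10)
  for (i in 1:5) {
    img <- matrix(stats::runif(100, 0, 255), 10)
    r <- roi(1, 1, 10, 10)
    expect_equal(roughness_sd(img, r), oracle_roughness_sd(img, r),
                 tolerance = 1e-9)
    expect_equal(roughness_sd(img, r, mode = "differences"),
                 oracle_roughness_diff(img, r), tolerance = 1e-9)
    # offset invariance and linear scale behavior
    expect_equal(roughness_sd(img + 40, r), roughness_sd(img, r),
                 tolerance = 1e-9)
    expect_equal(roughness_sd(img * 2.5, r), 2.5 * roughness_sd(img, r),
                 tolerance = 1e-9)
  }
})

test_that("patch segmentation uses 8-connectivity and crack-edge perimeters", {
  r <- roi(1, 1, 10, 10)
  f <- matrix(0, 10, 10); f[5, 5] <- 10
  p <- segment_patches(f, r, 5)
  expect_equal(nrow(p), 1)
  expect_equal(p$perimeter_px, 4)

  f2 <- matrix(0, 10, 10); f2[4:6, 4:6] <- 10
  expect_equal(segment_patches(f2, r, 5)$perimeter_px, 12)

  f3 <- matrix(0, 10, 10); f3[4, 4] <- 10; f3[5, 5] <- 10
  p3 <- segment_patches(f3, r, 5)
  expect_equal(nrow(p3), 1) # diagonal contact joins under 8-connectivity
  expect_equal(p3$perimeter_px, 8)

  expect_equal(nrow(segment_patches(matrix(0, 5, 5), roi(1, 1, 5, 5), 5)), 0)
})

test_that("patch labels and perimeters match brute-force oracles", {
  set.seed(21)
  for (i in 1:8) {
    img <- matrix(stats::runif(100, 0, 255), 10)
    r <- roi(1, 1, 10, 10)
    thr <- 128
    p <- segment_patches(img, r, thr)
    bin <- img >= thr
    lab_oracle <- oracle_label8(bin)
    expect_equal(nrow(p), length(unique(lab_oracle[lab_oracle > 0])))
    expect_equal(sum(p$perimeter_px), oracle_total_perimeter(bin))
    expect_equal(sum(p$area_px), sum(bin))
    # structural invariants
    expect_true(all(p$perimeter_px >= 4))
    expect_true(all(p$perimeter_px %% 2 == 0))
  }
})

test_that("borders index grows when one patch splits in two", {
  r <- roi(1, 1, 12, 12)
  joined <- matrix(0, 12, 12); joined[5:6, 3:8] <- 10 # 2x6 block
  split <- matrix(0, 12, 12); split[5:6, 3:5] <- 10; split[5:6, 7:9] <- 10
  expect_equal(sum(joined >= 5), sum(split >= 5))
  expect_gt(roughness_borders(split, r, 5), roughness_borders(joined, r, 5))
  expect_equal(roughness_borders(matrix(0, 12, 12), r, 5), 0)
  # translation of content away from the ROI border leaves it unchanged
  moved <- matrix(0, 12, 12); moved[7:8, 4:9] <- 10
  expect_equal(roughness_borders(moved, r, 5),
               roughness_borders(joined, r, 5))
})

test_that("highpass removes constants and linear trends", {
  t_h <- seq(0, 20, by = 0.2)
  ct <- marker_trace("a", t_h, rep(5, length(t_h)), "roughness_sd")
  expect_equal(highpass(ct)$value, rep(0, length(t_h)))
  ramp <- marker_trace("a", t_h, 3 + 2 * t_h, "wing_intensity")
  hp <- highpass(ramp, window_h = 6)
  half <- round(6 / (2 * 0.2))
  interior <- (half + 1):(length(t_h) - half)
  expect_equal(hp$value[interior], rep(0, length(interior)),
               tolerance = 1e-9)
  # unit step: biphasic excursion with the extremum at the step sample
  v <- as.numeric(t_h >= 10)
  hp2 <- highpass(marker_trace("a", t_h, v, "roughness_sd"), 6)
  expected <- v - oracle_moving_average(v, half)
  expect_equal(hp2$value, expected, tolerance = 1e-12)
  expect_equal(t_h[which.max(hp2$value)], 10)
  expect_error(highpass(marker_trace("a", 1:2, c(1, 2), "roughness_sd")),
               "3 samples")
})

test_that("onset detection finds a corner and stays silent on flat noise", {
  set.seed(2)
  t_h <- seq(0, 40, by = 0.2)
  rise <- ifelse(t_h < 30, 0, (t_h - 30) * 50)
  tr <- marker_trace("a", t_h, pmax(rise + stats::rnorm(length(t_h)), 0),
                     "roughness_sd")
  onset <- detect_onset(tr)
  expect_lt(abs(onset - 30), 0.6)
  flat <- marker_trace("a", t_h, abs(stats::rnorm(length(t_h), 100, 1)),
                       "roughness_sd")
  expect_true(is.na(detect_onset(flat)))
})

test_that("emergence detection keys on the largest signed jump", {
  t_h <- seq(0, 20, by = 0.2)
  v <- c(rep(100, 50), rep(200, length(t_h) - 50))
  tr <- marker_trace("a", t_h, v, "wing_intensity")
  expect_equal(detect_emergence(tr), t_h[51])
  # roughness channels expect a drop, so a rise is not an emergence
  tr_r <- marker_trace("a", t_h, v, "roughness_sd")
  expect_true(is.na(detect_emergence(tr_r)))
  drop <- marker_trace("a", t_h, rev(v), "roughness_sd")
  expect_equal(detect_emergence(drop), t_h[length(t_h) - 49])
  ramp <- marker_trace("a", t_h, t_h, "wing_intensity")
  expect_true(is.na(detect_emergence(ramp)))
  expect_error(detect_emergence(marker_trace("a", 1:2, c(1, 2),
                                             "wing_intensity")),
               "3 samples")
})

test_that("onset summaries compute the Fig-style quantities and exclusions", {
  t_h <- seq(0, 50, by = 0.2)
  set.seed(3)
  mk <- function(id, onset, emergence) {
    v <- ifelse(t_h < onset, 0, (t_h - onset) * 40) +
      stats::rnorm(length(t_h), 0, 0.5)
    v[t_h >= emergence] <- 0
    marker_trace(id, t_h, pmax(v, 0), "roughness_sd")
  }
  traces <- list(mk("a1", 30, 43), mk("a2", 28, 41))
  res <- summarize_onsets(traces)
  expect_equal(nrow(res$animals), 2)
  expect_equal(res$animals$duration_h,
               res$animals$emergence_t_h - res$animals$onset_t_h)
  expect_lt(abs(res$animals$time_to_onset_h[1] - 30), 1)
  expect_lt(abs(res$animals$duration_h[1] - 13), 1.2)
  # an animal with no emergence jump is excluded with a reason
  flat <- marker_trace("a3", t_h, abs(stats::rnorm(length(t_h), 5, 0.5)),
                       "roughness_sd")
  res2 <- summarize_onsets(c(traces, list(flat)))
  expect_equal(res2$excluded$animal_id, "a3")
  empty <- summarize_onsets(list())
  expect_equal(nrow(empty$animals), 0)
})

test_that("group comparison reproduces hand-computed ANOVA results", {
  res <- group_compare(c(1, 2, 3, 2, 3, 4), rep(c("g1", "g2"), each = 3))
  expect_equal(res$F, 1.5)
  expect_equal(res$df, c(1, 4))
  res0 <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("g1", "g2"), each = 3))
  expect_equal(res0$F, 0)
  # a far-shifted group earns its own letter
  set.seed(5)
  vals <- c(stats::rnorm(8, 0), stats::rnorm(8, 0.2), stats::rnorm(8, 30))
  grp <- rep(c("a", "b", "c"), each = 8)
  res3 <- group_compare(vals, grp)
  expect_false(res3$letters[["c"]] %in% res3$letters[c("a", "b")])
  expect_equal(res3$letters[["a"]], res3$letters[["b"]])
  expect_error(group_compare(1:5, rep("a", 5)), "two groups")
  expect_error(group_compare(c(1, 1, 1, 1), rep(c("a", "b"), each = 2)),
               "undefined")
})
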