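blob_frame <- function(h, w, cy, cx, r = 6, fg = 200, bg = 10) {
  f <- matrix(bg, h, w)
  f[outer(seq_len(h), rep(1, w)) > 0] <- bg
  rows <- row(f); cols <- col(f)
  f[(rows - cy)^2 + (cols - cx)^2 <= r^2] <- fg
  f
}

test_that("burst selection picks the most centered frame", {
  h <- 41; w <- 41
  imgs <- list(
    "a_1.png" = blob_frame(h, w, 15, 21),
    "a_2.png" = blob_frame(h, w, 21, 21), # centroid exactly at center
    "a_3.png" = blob_frame(h, w, 21, 27))
  man <- data.frame(animal_id = "a", t_h = 0, burst_index = 1:3,
                    filename = names(imgs))
  ser <- reconstruct_series(man, imgs)
  expect_identical(ser$a$frames[[1]], imgs[["a_2.png"]])
})

test_that("ties are broken by the lowest burst index", {
  h <- 41; w <- 41
  imgs <- list(
    "a_1.png" = blob_frame(h, w, 21, 23),
    "a_2.png" = blob_frame(h, w, 21, 19)) # same centroid distance
  man <- data.frame(animal_id = "a", t_h = 0, burst_index = 1:2,
                    filename = names(imgs))
  ser <- reconstruct_series(man, imgs)
  expect_identical(ser$a$frames[[1]], imgs[["a_1.png"]])
})

test_that("burst selection recovers the minimum-jitter frame", {
  # bursts built from a centered base (as the rig trigger guarantees) with
  # known integer jitter and additive noise at the fixture level
  set.seed(17)
  h <- 61; w <- 61
  base <- blob_frame(h, w, 31, 31, r = 12, fg = 180, bg = 20)
  ok <- 0L; total <- 200L
  for (b in seq_len(total)) {
    jits <- cbind(sample(-2:2, 5, TRUE), sample(-2:2, 5, TRUE))
    imgs <- lapply(seq_len(5), function(k) {
      f <- eclosr:::shift_matrix(base, jits[k, 1], jits[k, 2], 20)
      pmin(pmax(f + matrix(stats::rnorm(h * w, 0, 2), h), 0), 255)
    })
    names(imgs) <- sprintf("b%03d_%d.png", b, 1:5)
    man <- data.frame(animal_id = "a", t_h = 0, burst_index = 1:5,
                      filename = names(imgs))
    ser <- reconstruct_series(man, imgs)[["a"]]
    chosen <- which(vapply(names(imgs), function(f)
      identical(imgs[[f]], ser$frames[[1]]), TRUE))[1]
    jit2 <- jits[, 1]^2 + jits[, 2]^2
    if (jit2[chosen] == min(jit2)) ok <- ok + 1L
  }
  expect_gte(ok / total, 0.99)
})

test_that("reconstruction errors identify the failing animal and file", {
  man <- data.frame(animal_id = "a", t_h = 0, burst_index = 1,
                    filename = "missing.png")
  expect_error(reconstruct_series(man, list()), "missing.png")
  d <- withr::local_tempdir()
  expect_error(reconstruct_series(man, d), "unreadable")
  man2 <- rbind(man, data.frame(animal_id = "a", t_h = 0, burst_index = 1,
                                filename = "missing.png"))
  expect_error(read_manifest_from <- {
    p <- file.path(d, "m.csv"); utils::write.csv(man2, p, row.names = FALSE)
    read_manifest(p)
  }, "not unique")
})

test_that("cadence arithmetic: 5 stage passes per hour give 12-min sampling", {
  sch <- make_test_schedules(1, seed = 6)[1, ]
  scene <- make_test_scene(burst_size = 2)
  passes_per_hour <- 1 / scene$cadence_h
  expect_equal(passes_per_hour, 5)
  rs <- render_series(sch, scene, seed = 3, animal_id = "a")
  ser <- reconstruct_series(rs$manifest, rs$images)[["a"]]
  intervals_min <- diff(ser$t_h) * 60
  expect_equal(unique(round(intervals_min, 9)), 12)
  # one frame per burst
  expect_equal(length(ser$frames), length(unique(rs$manifest$t_h)))
})

test_that("stabilization recovers known integer shifts exactly", {
  set.seed(4)
  base <- matrix(stats::runif(60 * 60, 0, 255), 60)
  base <- base + blob_frame(60, 60, 30, 30, r = 10, fg = 100, bg = 0)
  shifted <- eclosr:::shift_matrix(base, 3, -2, fill = stats::median(base))
  ser <- animal_series("a", c(0, 0.2), list(base, shifted))
  st <- stabilize(ser, max_shift_px = 5)
  expect_equal(st$shifts[2, ], c(3, -2))
  # identical frames: zero shift
  ser2 <- animal_series("a", c(0, 0.2), list(base, base))
  expect_equal(stabilize(ser2, 5)$shifts[2, ], c(0, 0))
  # idempotence: a stabilized series re-stabilizes to zero shifts
  st2 <- stabilize(st, max_shift_px = 5)
  expect_true(all(abs(st2$shifts) == 0))
})

test_that("a shift at the search bound is flagged", {
  set.seed(4)
  base <- matrix(stats::runif(60 * 60, 0, 255), 60)
  shifted <- eclosr:::shift_matrix(base, 2, 0, fill = stats::median(base))
  ser <- animal_series("a", c(0, 0.2), list(base, shifted))
  st <- stabilize(ser, max_shift_px = 2)
  expect_equal(st$flags[2], "shift_at_bound")
})

test_that("constant whole-series translation leaves ROI traces unchanged", {
  sch <- make_test_schedules(1, seed = 7)[1, ]
  scene <- make_test_scene(noise_sd = 0, jitter_px = 0, burst_size = 1)
  rs <- render_series(sch, scene, seed = 2, animal_id = "a")
  ser <- reconstruct_series(rs$manifest, rs$images,
                            head_roi = scene$head_roi,
                            wing_roi = scene$wing_roi)[["a"]]
  ser_shift <- ser
  ser_shift$frames <- lapply(ser$frames, function(f)
    eclosr:::shift_matrix(f, 2, -1, fill = scene$background))
  tr0 <- wing_trace(stabilize(ser, 3))
  # first frame anchors the registration, so align the shifted series back
  # to the original origin before comparing
  st <- stabilize(ser_shift, 3)
  st$frames <- lapply(st$frames, function(f)
    eclosr:::shift_matrix(f, -2, 1, fill = scene$background))
  tr1 <- wing_trace(st)
  expect_equal(tr1$value, tr0$value, tolerance = 1e-6)
})
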