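p_base <- function(model, commit_mean, ...) {
  gating_params(model, tau_h = 24, gate_open_ct = 0, gate_width_h = 10,
                commit_mean_h = commit_mean, commit_sd_h = 0,
                rough_mean_h = 12, rough_sd_h = 0, ct0_offset_h = 0, ...)
}

test_that("deterministic schedule arithmetic matches the gate logic", {
  # completion inside gate: no deferral under either gated model
  s <- simulate_cohort(p_base("developmental", 20),
                       pupariation_offsets_h = 0, seed = 1)
  expect_equal(s$onset_t_h, 20)
  expect_equal(s$emergence_t_h, 32) # CT8, inside [CT0, CT10)
  sp <- simulate_cohort(p_base("permissive", 20),
                        pupariation_offsets_h = 0, seed = 1)
  expect_equal(sp$onset_t_h, 20)
  expect_equal(sp$emergence_t_h, 32)

  # completion at CT11 (gate closed): developmental delays the onset,
  # permissive holds a finished fly; same emergence, onsets 13 h apart
  s2 <- simulate_cohort(p_base("developmental", 23),
                        pupariation_offsets_h = 0, seed = 1)
  expect_equal(s2$onset_t_h, 36)
  expect_equal(s2$emergence_t_h, 48)
  sp2 <- simulate_cohort(p_base("permissive", 23),
                         pupariation_offsets_h = 0, seed = 1)
  expect_equal(sp2$onset_t_h, 23)
  expect_equal(sp2$completion_t_h, 35)
  expect_equal(sp2$emergence_t_h, 48)

  # clock-less: emergence whenever development finishes
  sa <- simulate_cohort(p_base("arrhythmic", 23),
                        pupariation_offsets_h = 0, seed = 1)
  expect_equal(sa$emergence_t_h, sa$onset_t_h + sa$rough_duration_h)
})

test_that("half-open gate defers a completion exactly at gate close", {
  # completion at CT10 == gate close -> next opening
  s <- simulate_cohort(p_base("permissive", 22),
                       pupariation_offsets_h = 0, seed = 1)
  expect_equal(s$completion_t_h, 34) # CT10
  expect_equal(s$emergence_t_h, 48)
})

test_that("schedules match a minute-resolution exhaustive scan", {
  p <- gating_params("developmental", tau_h = 24, gate_open_ct = 3,
                     gate_width_h = 7, commit_mean_h = 90, commit_sd_h = 4,
                     rough_mean_h = 13, rough_sd_h = 1.5, ct0_offset_h = 5)
  for (model in c("developmental", "permissive", "arrhythmic")) {
    p$model <- model
    sch <- simulate_cohort(p, c(0, 6, 18), n_per_group = 5, seed = 11)
    for (i in seq_len(nrow(sch))) {
      ref <- oracle_schedule(p, sch$commitment_t_h[i],
                             sch$rough_duration_h[i])
      # the scan grid can overshoot an exact gate opening by < one step
      expect_lt(abs(sch$onset_t_h[i] - ref[["onset"]]), 1 / 60)
      expect_lt(abs(sch$emergence_t_h[i] - ref[["emergence"]]), 1 / 60)
    }
  }
})

test_that("model invariants hold on stochastic cohorts", {
  seeds <- 1:5
  for (seed in seeds) {
    pd <- gating_preset("wildtype")
    sd_ <- simulate_cohort(pd, c(6, 12, 18), n_per_group = 20, seed = seed)
    # developmental: no waiting, ever
    expect_equal(sd_$completion_t_h, sd_$emergence_t_h)
    expect_true(all(sd_$onset_t_h >= sd_$commitment_t_h - 1e-9))
    expect_true(all(in_gate(sd_$emergence_t_h, pd)))

    pp <- pd; pp$model <- "permissive"
    sp <- simulate_cohort(pp, c(6, 12, 18), n_per_group = 20, seed = seed)
    expect_equal(sp$onset_t_h, sp$commitment_t_h)
    wait <- sp$emergence_t_h - sp$completion_t_h
    expect_true(all(wait >= 0))
    expect_true(all(wait < pd$tau_h - pd$gate_width_h + 1e-9))
    expect_true(all(in_gate(sp$emergence_t_h, pp)))
    expect_true(all(sp$rough_duration_h > 0))
  }
})

test_that("per-fly substreams keep earlier flies fixed as the cohort grows", {
  p <- gating_preset("wildtype")
  small <- simulate_cohort(p, 6, n_per_group = 3, seed = 9)
  big <- simulate_cohort(p, 6, n_per_group = 8, seed = 9)
  expect_equal(small$emergence_t_h, big$emergence_t_h[1:3])
  expect_equal(small$rough_duration_h, big$rough_duration_h[1:3])
})

test_that("ready_fraction implements the ETH-probe responder logic", {
  sp2 <- simulate_cohort(p_base("permissive", 23),
                         pupariation_offsets_h = 0, seed = 1)
  expect_equal(ready_fraction(sp2, 40), 1) # finished at 35, held to 48
  s2 <- simulate_cohort(p_base("developmental", 23),
                        pupariation_offsets_h = 0, seed = 1)
  expect_equal(ready_fraction(s2, 40), 0) # completes only at emergence
  expect_equal(ready_fraction(sp2, 0), 0) # nothing can be ready yet
  expect_error(ready_fraction(sp2, 100), "unemerged")
})

test_that("a pre-gate probe separates permissive from developmental gating", {
  pd <- gating_preset("wildtype")
  pp <- pd; pp$model <- "permissive"
  for (seed in 1:3) {
    sd_ <- simulate_cohort(pd, c(6, 12, 18), n_per_group = 40, seed = seed)
    sp <- simulate_cohort(pp, c(6, 12, 18), n_per_group = 40, seed = seed)
    # probe one hour before the gate opening that follows the median
    # completion of the permissive cohort
    gate_open <- next_gate_time(stats::median(sp$completion_t_h), pd)
    probe <- gate_open - 1
    expect_gt(ready_fraction(sp, probe), 0.3)
    expect_equal(ready_fraction(sd_, probe), 0)
  }
})

test_that("compare_models flags onset shift but identical emergences at sd 0", {
  pd <- p_base("developmental", 23)
  pp <- p_base("permissive", 23)
  cm <- compare_models(pd, pp, pupariation_zts = c(0, 4), n_per_group = 5,
                       seed = 2)
  expect_equal(sort(cm$schedules$developmental$emergence_t_h),
               sort(cm$schedules$permissive$emergence_t_h))
  expect_gt(abs(cm$discriminators$onset_mean_shift_h), 1)
  expect_gt(cm$discriminators$max_ready_fraction_gap, 0.5)
  pd2 <- pd; pd2$tau_h <- 23
  expect_error(compare_models(pd2, pp, seed = 2), "share")
})

test_that("parameter validation rejects inconsistent gating setups", {
  expect_error(gating_params("nonsense"))
  expect_error(gating_params(tau_h = -1))
  expect_error(gating_params(gate_open_ct = 30))
  expect_error(gating_params(gate_width_h = 24))
  expect_error(simulate_cohort(gating_preset("wildtype"), 6,
                               n_per_group = 0, seed = 1))
  expect_error(simulate_cohort(gating_preset("wildtype"), 6,
                               n_per_group = 2), "seed")
})

test_that("schedule CSV round-trips", {
  sch <- simulate_cohort(gating_preset("wildtype"), c(6, 12), 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedules(sch, path)
  back <- read_schedules(path)
  expect_equal(back$emergence_t_h, sch$emergence_t_h)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_schedules(bad), "lacks columns")
})
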