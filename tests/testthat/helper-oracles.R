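# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by the slowest, most literal route available.

# Population SD of the 3x3 neighborhood of every interior ROI pixel,
# summed; triple loop.
oracle_roughness_sd <- function(frame, r) {
  x <- frame[r$row:(r$row + r$height - 1), r$col:(r$col + r$width - 1)]
  total <- 0
  for (i in 2:(nrow(x) - 1)) for (j in 2:(ncol(x) - 1)) {
    nb <- as.vector(x[(i - 1):(i + 1), (j - 1):(j + 1)])
    total <- total + sqrt(mean((nb - mean(nb))^2))
  }
  total
}

# SD of the 8 signed neighbor-minus-center differences, summed.
oracle_roughness_diff <- function(frame, r) {
  x <- frame[r$row:(r$row + r$height - 1), r$col:(r$col + r$width - 1)]
  total <- 0
  for (i in 2:(nrow(x) - 1)) for (j in 2:(ncol(x) - 1)) {
    nb <- as.vector(x[(i - 1):(i + 1), (j - 1):(j + 1)])
    d <- nb[-5] - x[i, j]
    total <- total + sqrt(mean((d - mean(d))^2))
  }
  total
}

# 8-connected components by iterated label propagation; returns label
# matrix with 0 background.
oracle_label8 <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  lab <- matrix(0L, h, w)
  lab[bin] <- seq_len(sum(bin))
  repeat {
    changed <- FALSE
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (!bin[i, j]) next
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > h || jj < 1 || jj > w) next
        if (bin[ii, jj] && lab[ii, jj] < lab[i, j]) {
          lab[i, j] <- lab[ii, jj]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# Total crack-edge perimeter of all supra-threshold patches: count, for
# every foreground pixel, its 4-neighbor edges facing background/outside.
oracle_total_perimeter <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  total <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!bin[i, j]) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > h || jj < 1 || jj > w || !bin[ii, jj])
        total <- total + 1L
    }
  }
  total
}

# Biased non-circular autocorrelation by explicit double loop.
oracle_acf <- function(x, max_lag) {
  n <- length(x); xm <- mean(x)
  denom <- sum((x - xm)^2)
  vapply(0:max_lag, function(l) {
    s <- 0
    for (t in seq_len(n - l)) s <- s + (x[t] - xm) * (x[t + l] - xm)
    s / denom
  }, 0)
}

# Centered moving average with truncated windows, by explicit loop.
oracle_moving_average <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), 0)
}

# Minute-resolution exhaustive scan for the gated schedules: smallest onset
# O >= C whose completion O + R falls inside a gate (developmental), and
# the first in-gate instant at or after completion (permissive).
oracle_schedule <- function(params, C, R, step = 1 / 60) {
  grid <- seq(C, C + 2 * params$tau_h, by = step)
  if (params$model == "developmental") {
    ok <- in_gate(grid + R, params)
    O <- grid[which(ok)[1]]
    c(onset = O, emergence = O + R)
  } else if (params$model == "permissive") {
    comp <- C + R
    grid2 <- seq(comp, comp + 2 * params$tau_h, by = step)
    E <- grid2[which(in_gate(grid2, params))[1]]
    c(onset = C, emergence = E)
  } else {
    c(onset = C, emergence = C + R)
  }
}

# Shared compact rendering setup for pipeline tests.
make_test_scene <- function(...) eclosr:::fixture_scene(...)
make_test_schedules <- function(n, seed) eclosr:::fixture_schedules(n, seed)

render_and_measure <- function(schedule, scene, seed) {
  rs <- render_series(schedule, scene, seed = seed, animal_id = "a")
  ser <- reconstruct_series(rs$manifest, rs$images,
                            head_roi = scene$head_roi,
                            wing_roi = scene$wing_roi)[[1]]
  st <- stabilize(ser, max_shift_px = 3)
  list(rendered = rs, series = st,
       rough = roughness_trace(st, "sd"),
       borders = roughness_trace(st, "borders"),
       wing = wing_trace(st))
}
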