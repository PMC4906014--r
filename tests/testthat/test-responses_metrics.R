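trial_fixture <- function(T = 6, ...) {
  m <- model_default(T = T)
  run_trial(m, scene_layout("flee", 0, 0), trace = TRUE, ...)
}

test_that("raster layout is fully determined by the factor and T", {
  for (T in c(2L, 4L, 6L)) {
    tr <- trial_fixture(T = T)
    n_el <- tr$n_epochs
    r <- firing_raster(tr, "context")
    expect_equal(dim(r), c(3L * T, 16L * n_el))
    expect_true(all(r >= 0 & r <= 1))
    tm <- attr(r, "time")
    expect_true(all(diff(tm) > 0))
    expect_equal(diff(tm)[1], 0.25 / 16)
    r2 <- firing_raster(tr, "location")
    expect_equal(dim(r2), c(8L * T, 16L * n_el))
  }
  # a 6-epoch trial yields the 18 x 96 context raster
  tr6 <- trial_fixture(T = 6)
  expect_equal(dim(firing_raster(tr6, "context")), c(18L, 96L))
})

test_that("diagonal blocks track the current epoch's beliefs", {
  tr <- trial_fixture()
  r <- firing_raster(tr, "location")
  # during epoch t the belief about the current location is (close to) the
  # observed location by the end of the 16 bins
  for (t in seq_len(tr$n_epochs)) {
    obs_loc <- tr$observations[[t]]$where
    rows <- (t - 1L) * 8L + seq_len(8L)
    col <- t * 16L
    expect_equal(unname(which.max(r[rows, col])), obs_loc)
  }
})

test_that("LFPs are rate changes; constant rates give zero LFP", {
  tr <- trial_fixture()
  r <- firing_raster(tr, "context")
  l <- simulated_lfp(r)
  expect_equal(dim(l$lfp), dim(r))
  expect_equal(l$lfp[, 1], rep(0, nrow(r)), ignore_attr = TRUE)
  expect_equal(l$lfp[, 2], r[, 2] - r[, 1], ignore_attr = TRUE)

  flat <- matrix(0.4, 6, 64)
  attr(flat, "time") <- (1:64 - 0.5) * 0.25 / 16
  lf <- simulated_lfp(flat)
  expect_true(all(lf$lfp == 0))
  expect_true(all(abs(lf$lfp_avg_filtered) < 1e-12))

  # a single belief jump produces an impulse at that bin
  step <- flat
  step[, 33:64] <- 0.9
  ls <- simulated_lfp(step)
  expect_equal(which(abs(ls$lfp_avg) > 1e-12), 33L)
})

test_that("the band-limiting filter passes 4 Hz and rejects the stopbands", {
  # transfer function of the implemented filter, from its impulse response
  n <- 1024L
  mid <- 512L
  x <- matrix(0, 1, n)
  x[1, mid:n] <- 1  # a unit step; its rate of change is a clean impulse
  attr(x, "time") <- (1:n - 0.5) * 0.25 / 16
  h <- simulated_lfp(x)$lfp_avg_filtered
  gain <- Mod(stats::fft(h))^2
  freq <- (seq_len(n) - 1) * 64 / n
  at <- function(f) gain[which.min(abs(freq - f))]
  # the passband peaks at the 4 Hz center ...
  half <- freq <= 32
  expect_equal(freq[half][which.max(gain[half])], 4, tolerance = 0.6)
  # ... and energy above 8 Hz (and below 2 Hz) is strongly attenuated
  expect_lt(at(16) / at(4), 0.2)
  expect_lt(at(24) / at(4), 0.1)
  expect_lt(at(0.5) / at(4), 0.1)
  # zero phase: the impulse response is symmetric about the impulse
  k <- 1:200
  expect_lt(max(abs(h[mid + k] - h[mid - k])) / max(abs(h)), 0.02)
})

test_that("dopamine mixes precision with its rate of change", {
  expect_equal(dopamine_signal(rep(2, 10)), rep(2, 10))
  g <- c(rep(1, 5), rep(1.5, 5))
  da <- dopamine_signal(g, mix = 4)
  expect_equal(da[6], 1.5 + 4 * 0.5)  # transient burst at the step
  expect_equal(da[10], 1.5)           # raised baseline afterwards
  expect_error(dopamine_signal(c(1, -1)))
})

test_that("trial scoring implements the accuracy/decision-time conventions", {
  m <- model_default()
  tr <- run_trial(m, scene_layout("flee", 0, 0), trace = FALSE,
                  stop_at_choice = TRUE)
  s <- score_trial(tr)
  expect_true(s$correct)
  expect_equal(s$decision_time, tr$decision_saccade)
  expect_gt(s$reaction_time, 0)

  # no-choice trials count as incorrect with decision time = max saccades
  tr0 <- run_trial(m, scene_layout("flee", 0, 0), max_saccades = 0,
                   trace = FALSE)
  expect_length(tr0$actions, 0)
  expect_length(tr0$observations, 1)
  s0 <- score_trial(tr0)
  expect_false(s0$correct)
  expect_equal(s0$decision_time, 0L)
  expect_equal(s0$utility, 0)  # only the null fixation cue was observed
})

test_that("small sweeps are reproducible and carry the grid structure", {
  sw1 <- run_sweep(2, c_levels = c(0, 2), precision_levels = c(1, 0.25),
                   seed = 7, T = 4)
  sw2 <- run_sweep(2, c_levels = c(0, 2), precision_levels = c(1, 0.25),
                   seed = 7, T = 4)
  expect_identical(as.data.frame(sw1), as.data.frame(sw2))
  expect_equal(nrow(sw1), 4L)
  expect_true(all(sw1$accuracy >= 0 & sw1$accuracy <= 100))
  expect_true(all(sw1$n == 2))
  expect_s3_class(sw1, "forage_sweep")
})
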