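# Simulated electrophysiology and behavioral metrics. Belief trajectories
# are read out as firing rates of units tuned to (state, represented epoch);
# local field potentials are their temporal derivatives; the precision
# trace plays the role of a dopaminergic signal. Outcomes are sampled every
# 250 ms, divided into 16 belief-update bins.

EPOCH_SECONDS <- 0.25
N_BINS <- 16L
BIN_SECONDS <- EPOCH_SECONDS / N_BINS
FS_HZ <- 1 / BIN_SECONDS  # 64 Hz sampling rate of the belief-update bins

#' Firing-rate raster of belief-encoding units
#'
#' Arranges the per-iteration belief snapshots of a trial as a raster:
#' rows are (represented epoch x state) blocks, columns are (elapsed epoch
#' x 16 iteration bins). Blocks on the diagonal are beliefs about the
#' current state; blocks above it are postdictions about the past, blocks
#' below it predictions about the future.
#'
#' @param trial A [run_trial()] result with `trace = TRUE`.
#' @param factor Hidden-state factor name (default `"context"`).
#' @return A matrix with `n_states * T` rows and `16 * n_epochs` columns,
#'   with a `time` attribute (seconds, bin centers) and row labels.
#' @export
firing_raster <- function(trial, factor = "context") {
  stopifnot(inherits(trial, "forage_trial"))
  if (is.null(trial$trace)) {
    stop("trial was simulated with trace = FALSE", call. = FALSE)
  }
  factor <- match.arg(factor, FACTORS)
  xn <- trial$trace[[factor]]  # (state, represented epoch, bin, elapsed)
  d <- dim(xn)
  n_states <- d[1]; T <- d[2]; n_elapsed <- d[4]
  raster <- matrix(0, n_states * T, N_BINS * n_elapsed)
  for (tau in seq_len(T)) {
    for (t in seq_len(n_elapsed)) {
      rows <- (tau - 1L) * n_states + seq_len(n_states)
      cols <- (t - 1L) * N_BINS + seq_len(N_BINS)
      raster[rows, cols] <- xn[, tau, , t]
    }
  }
  raster <- pmin(pmax(raster, 0), 1)  # shave float residue off the mixture
  labs <- switch(factor, context = CONTEXTS, location = LOCATIONS,
                 flip_lr = c("no-flip", "flip"), flip_ud = c("no-flip", "flip"))
  rownames(raster) <- paste0(rep(labs, T), "@", rep(seq_len(T), each = n_states))
  attr(raster, "time") <- (seq_len(ncol(raster)) - 0.5) * BIN_SECONDS
  attr(raster, "factor") <- factor
  raster
}

#' Simulated local field potentials
#'
#' The LFP of each unit is the first temporal difference of its firing
#' rate. The unit-average is returned raw and band-limited around 4 Hz
#' (zero-phase second-order Butterworth band-pass with half-power points at
#' 2 and 8 Hz, applied forward and backward).
#'
#' @param raster A [firing_raster()] matrix.
#' @return A list with `lfp` (units x time matrix of rate changes),
#'   `lfp_avg` (unit mean), `lfp_avg_filtered` (band-limited mean), and
#'   `time` (seconds).
#' @export
simulated_lfp <- function(raster) {
  stopifnot(is.matrix(raster))
  lfp <- t(apply(raster, 1, function(x) c(0, diff(x))))
  lfp_avg <- colMeans(lfp)
  bf <- signal::butter(1, c(2, 8) / (FS_HZ / 2), type = "pass")
  filt <- if (length(lfp_avg) > 9) {
    as.numeric(signal::filtfilt(bf, lfp_avg))
  } else {
    lfp_avg * 0
  }
  list(lfp = lfp, lfp_avg = lfp_avg, lfp_avg_filtered = filt,
       time = attr(raster, "time"))
}

#' Simulated dopamine signal
#'
#' A mixture of the precision trace and its rate of change:
#' `dopamine(t) = gamma(t) + mix * delta gamma(t)`. Phasic deflections of
#' this signal mark changes in the confidence about policies.
#'
#' @param gamma_trace Positive numeric vector (per-bin or per-epoch
#'   precision expectations, e.g. `trial$gamma_bins`).
#' @param mix Weight of the rate-of-change component.
#' @return Numeric vector of the same length.
#' @export
dopamine_signal <- function(gamma_trace, mix = 4) {
  stopifnot(all(gamma_trace > 0))
  gamma_trace + mix * c(0, diff(gamma_trace))
}

#' Score a simulated trial
#'
#' @param trial A [run_trial()] result.
#' @return A one-row tibble: `correct` (right feedback received and no
#'   wrong feedback ever; a trial with no choice counts as incorrect),
#'   `decision_time` (saccades until the first choice, `max_saccades` if
#'   none), `utility` (time-average preference value of the observed
#'   outcomes), and `reaction_time` (mean variational iterations per
#'   epoch -- a hardware-independent proxy for processing time).
#' @export
score_trial <- function(trial) {
  stopifnot(inherits(trial, "forage_trial"))
  whats <- vapply(trial$observations, `[[`, integer(1), "what")
  correct <- any(whats == 5L) && !any(whats == 6L)
  decision_time <- if (!is.na(trial$decision_saccade)) {
    trial$decision_saccade
  } else {
    trial$max_saccades
  }
  C1 <- c(0, 0, 0, 0, trial$params$c, -2 * trial$params$c)
  tibble::tibble(
    correct = correct,
    decision_time = as.integer(decision_time),
    utility = mean(C1[whats]),
    reaction_time = trial$iterations_total / trial$n_epochs
  )
}

#' Preference-by-precision performance sweep
#'
#' Runs `n_trials` randomly generated scenes through the agent for every
#' combination of preference strength `c` and prior temperature `beta`,
#' and aggregates accuracy (percent correct), mean decision time
#' (saccades), and mean reaction time (variational iterations per epoch).
#' The same scenes (drawn once from `seed`) are used in every cell, so the
#' grids are reproducible and order-independent.
#'
#' @param n_trials Trials per grid cell.
#' @param c_levels Preference strengths (default 8 equally spaced values
#'   from 0 to 4).
#' @param precision_levels Prior temperatures `beta` (default log-spaced
#'   over `2^6 .. 2^-4`, chosen so the implied precisions span near-uniform
#'   to near-deterministic policy selection at the expected-free-energy
#'   spreads this task produces; small `beta` = high precision).
#' @param seed Integer seed for scene generation.
#' @param T Epochs per trial (default 9: up to 8 saccades).
#' @param action_mode,action_precision Passed to [run_trial()]. Sweeps
#'   default to `"sampled"` (saccades drawn from `softmax(-alpha KL)`), so
#'   that a low prior precision genuinely disperses behavior; with
#'   deterministic `"argmin"` selection the KL-minimizing action is
#'   executed no matter how flat the policy posterior is, and prior
#'   precision would lose most of its behavioral effect. Per-trial seeds
#'   are derived from `seed` by a counter, so grids are reproducible and
#'   independent of trial order.
#' @return A tibble of class `forage_sweep` with one row per (c, beta)
#'   cell: `accuracy` (%), `decision_time`, `reaction_time`, `n`.
#' @export
run_sweep <- function(n_trials, c_levels = seq(0, 4, length.out = 8),
                      precision_levels = 2^seq(6, -4, length.out = 8),
                      seed = 1L, T = 9L, action_mode = "sampled",
                      action_precision = 1) {
  stopifnot(n_trials >= 1)
  set.seed(seed)
  scenes <- sample_scenes(n_trials)
  cells <- tidyr::expand_grid(c = c_levels, beta = precision_levels)
  cells$cell <- seq_len(nrow(cells))
  res <- purrr::pmap(cells, function(c, beta, cell) {
    model <- build_scene_model(c = c, beta_prior = beta, T = T)
    scores <- purrr::imap(scenes, function(sc, k) {
      score_trial(run_trial(model, sc,
                            seed = seed * 1000L + cell * 301L + k,
                            max_saccades = T - 1L,
                            action_mode = action_mode,
                            action_precision = action_precision,
                            trace = FALSE, stop_at_choice = TRUE))
    })
    scores <- dplyr::bind_rows(scores)
    tibble::tibble(
      accuracy = 100 * mean(scores$correct),
      decision_time = mean(scores$decision_time),
      reaction_time = mean(scores$reaction_time),
      n = n_trials
    )
  })
  cells$cell <- NULL
  out <- dplyr::bind_cols(cells, dplyr::bind_rows(res))
  class(out) <- c("forage_sweep", class(out))
  attr(out, "seed") <- seed
  attr(out, "T") <- T
  out
}
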