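# broom-style tabular views and ggplot2 methods for trials and sweeps.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' One-row summary of a trial
#'
#' @param x A [run_trial()] object.
#' @param ... Unused.
#' @return A tibble with the scene, choice, feedback, decision time,
#'   iteration count, and final precision.
#' @export
glance.forage_trial <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      context = x$scene$context, flip_lr = x$scene$flip_lr,
      flip_ud = x$scene$flip_ud,
      n_saccades = length(x$actions),
      choice = x$choice_label, feedback = x$feedback
    ),
    score_trial(x),
    tibble::tibble(gamma_final = x$gamma[length(x$gamma)])
  )
}

#' Per-epoch tidy view of a trial
#'
#' One row per (epoch, policy): the action sequence taken so far, each
#' candidate's variational free energy `F`, expected free energy `G`,
#' posterior probability `pi`, and the epoch's precision `gamma`.
#'
#' @param x A [run_trial()] object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.forage_trial <- function(x, ...) {
  n_epochs <- ncol(x$pi)
  purrr::map_dfr(seq_len(n_epochs), function(t) {
    tibble::tibble(
      epoch = t,
      candidate = LOCATIONS,
      F = x$F[, t], G = x$G[, t], pi = x$pi[, t],
      gamma = x$gamma[t],
      action = LOCATIONS[if (t <= length(x$actions)) x$actions[t] else NA_integer_],
      observed = CUES[x$observations[[t]]$what]
    )
  })
}

#' @rdname tidy.forage_trial
#' @export
tidy.forage_sweep <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.forage_sweep <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_trials = sum(x$n),
    best_accuracy = max(x$accuracy),
    best_c = x$c[which.max(x$accuracy)],
    best_beta = x$beta[which.max(x$accuracy)]
  )
}

#' Plot a firing-rate raster
#'
#' Image view of the belief-encoding units of one hidden-state factor:
#' rows are (represented epoch x state) units, columns are belief-update
#' bins; dark cells are high firing rates (probabilities).
#'
#' @param object A [run_trial()] object (with `trace = TRUE`).
#' @param factor Hidden-state factor to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.forage_trial <- function(object, factor = "context", ...) {
  r <- firing_raster(object, factor)
  df <- tidyr::expand_grid(unit = seq_len(nrow(r)), bin = seq_len(ncol(r)))
  df$rate <- as.vector(r)  # column-major: unit varies fastest
  df$time <- attr(r, "time")[df$bin]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$unit,
                                   fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(r)),
                             labels = rownames(r)) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "rate",
                  title = paste("units encoding", factor)) +
    ggplot2::theme_minimal()
}

#' Heatmaps of the preference-by-precision sweep
#'
#' @param object A [run_sweep()] result.
#' @param metric One of `"accuracy"`, `"decision_time"`, `"reaction_time"`.
#' @param ... Unused.
#' @return A ggplot; precision increases to the right (prior temperature
#'   `beta` decreases), preference strength increases upward.
#' @export
autoplot.forage_sweep <- function(object, metric = "accuracy", ...) {
  metric <- match.arg(metric, c("accuracy", "decision_time", "reaction_time"))
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = -log2(.data$beta), y = .data$c,
                                   fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "prior precision (-log2 beta)",
                  y = "preference strength c", fill = metric) +
    ggplot2::theme_minimal()
}

#' Line plots of simulated physiological traces
#'
#' `plot_dopamine()` shows the simulated dopamine signal (precision and its
#' rate of change) across the trial; `plot_lfp()` shows the unit-average
#' local field potential before and after 4 Hz band-pass filtering.
#'
#' @param trial A [run_trial()] object (with `trace = TRUE` for
#'   `plot_lfp()`).
#' @param mix Passed to [dopamine_signal()].
#' @return A ggplot.
#' @export
plot_dopamine <- function(trial, mix = 4) {
  da <- dopamine_signal(trial$gamma_bins, mix = mix)
  df <- tibble::tibble(
    time = (seq_along(da) - 0.5) * BIN_SECONDS,
    dopamine = da
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$dopamine)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = 1 / trial$params$beta_prior,
                        linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "simulated dopamine (a.u.)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_dopamine
#' @param factor Factor whose units enter the LFP average.
#' @export
plot_lfp <- function(trial, factor = "context") {
  l <- simulated_lfp(firing_raster(trial, factor))
  df <- tibble::tibble(
    time = rep(l$time, 2),
    lfp = c(l$lfp_avg, l$lfp_avg_filtered),
    trace = rep(c("raw", "4 Hz band-pass"), each = length(l$time))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$lfp,
                                   linetype = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "average LFP (a.u.)") +
    ggplot2::theme_minimal()
}
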