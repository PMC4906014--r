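# The action-perception loop. At every epoch the agent (i) updates its
# trajectory posterior under each of the 8 one-step policy extensions,
# (ii) evaluates their expected free energies and updates the precision of
# its policy beliefs, (iii) forms a Bayesian model average of the next
# outcome, and (iv) acts to minimize the KL divergence between that
# prediction and the outcome implied by each candidate action.

kron_cols <- function(s_cols) {
  s_cols$flip_ud %x% s_cols$flip_lr %x% s_cols$location %x% s_cols$context
}

#' Bayesian model average of the next outcome
#'
#' Mixes each policy's predicted outcome distribution at epoch `t + 1` in
#' proportion to the policy posterior.
#'
#' @param pi Policy posterior (normalized, one weight per policy).
#' @param expectations_list One per-factor expectation set per policy.
#' @param model A [build_scene_model()] object.
#' @param t Current epoch; predictions are taken at `t + 1`.
#' @return Per-modality predictive outcome distributions (list `what`,
#'   `where`).
#' @export
bma_next_outcome <- function(pi, expectations_list, model, t) {
  stopifnot(abs(sum(pi) - 1) < 1e-6, t + 1L <= model$T,
            length(pi) == length(expectations_list))
  pred <- list(what = numeric(6), where = numeric(8))
  for (k in seq_along(pi)) {
    if (pi[k] == 0) next
    q <- kron_cols(purrr::map(expectations_list[[k]], ~ .x[, t + 1L]))
    for (m in names(pred)) {
      pred[[m]] <- pred[[m]] + pi[k] * drop(model$A[[m]] %*% q)
    }
  }
  pred
}

#' Select the action that realizes the predicted outcome
#'
#' For each candidate saccade `a`, applies the transition `B(a)` to the
#' Bayesian-model-averaged beliefs about the current state, maps the result
#' through the likelihood, and returns the action minimizing the KL
#' divergence from the predicted (Bayesian model average) outcome to the
#' implied one. Ties are broken deterministically toward the lowest action
#' index.
#'
#' @param predicted Per-modality predicted outcome distributions, as from
#'   [bma_next_outcome()].
#' @param model A [build_scene_model()] object.
#' @param current Per-factor belief vectors about the current state (the
#'   Bayesian model average at epoch `t`).
#' @return The selected action index (1..8).
#' @export
select_action <- function(predicted, model, current) {
  which.min(action_kl(predicted, model, current))  # ties: lowest index
}

#' @rdname select_action
#' @return `action_kl()` returns the per-action KL divergences themselves
#'   (summed over modalities).
#' @export
action_kl <- function(predicted, model, current) {
  stopifnot(all(vapply(predicted, function(p) abs(sum(p) - 1) < 1e-6,
                       logical(1))))
  vapply(seq_len(model$n_actions), function(a) {
    nxt <- current
    nxt$location <- as.numeric(seq_len(8) == a)
    q <- kron_cols(nxt)
    total <- 0
    for (m in names(predicted)) {
      implied <- drop(model$A[[m]] %*% q)
      p <- predicted[[m]]
      total <- total + sum(p * (ln_safe(p) - ln_safe(implied)))
    }
    total
  }, numeric(1))
}

#' Simulate one foraging trial
#'
#' Runs the closed action-perception loop on a scene: starting from central
#' fixation, the agent alternately updates its beliefs under the 8 one-step
#' policy extensions, evaluates expected free energy, updates precision,
#' and saccades; the environment returns the cue (or feedback) at each
#' sampled location. The trial's decision is the first saccade to a choice
#' location; with `stop_at_choice = FALSE` the simulation continues to `T`
#' with the eye held at the choice location (feedback repeats), which keeps
#' the belief and precision traces complete for response simulation.
#'
#' Precision is updated when each new outcome arrives, over the previous
#' epoch's candidate policies: the observed location collapses the policy
#' posterior onto the executed policy, while the prior `pi0` spreads over
#' the candidates according to their planning-time expected free energies,
#' so `beta_post = beta_prior + (pi - pi0) . G` measures how much better
#' (or worse) the executed policy was than expected without observations.
#'
#' @param model A [build_scene_model()] object.
#' @param scene A [scene_layout()] object (the ground truth).
#' @param seed Optional RNG seed (only consumed in `"sampled"` mode).
#' @param max_saccades Maximum number of saccades (`<= T - 1`).
#' @param action_mode `"argmin"` (deterministic KL minimization, index
#'   tie-break) or `"sampled"` (action drawn from `softmax(-alpha * KL)`,
#'   the stochastic counterpart of the same rule).
#' @param action_precision The inverse temperature `alpha` of sampled
#'   action selection; `"argmin"` is its infinite limit.
#' @param g_horizon Passed to [expected_free_energy()].
#' @param trace Keep per-iteration belief snapshots (needed for
#'   [firing_raster()]); disable for large sweeps.
#' @param stop_at_choice Stop simulating once feedback has been observed.
#' @return An object of class `forage_trial`; see [glance.forage_trial()]
#'   and [tidy.forage_trial()] for tabular views.
#' @export
run_trial <- function(model, scene, seed = NULL,
                      max_saccades = model$T - 1L,
                      action_mode = c("argmin", "sampled"),
                      action_precision = 1,
                      g_horizon = c("remaining", "next"),
                      trace = TRUE, stop_at_choice = FALSE) {
  action_mode <- match.arg(action_mode)
  g_horizon <- match.arg(g_horizon)
  stopifnot(inherits(model, "forage_model"), inherits(scene, "scene_config"),
            max_saccades + 1L <= model$T, max_saccades >= 0)
  if (!is.null(seed)) set.seed(seed)
  T <- model$T
  n_pol <- model$n_actions
  n_bins <- 16L

  obs <- list(list(what = 1L, where = 1L))  # initial central fixation
  executed <- integer(0)
  gamma <- numeric(0)
  gamma_bins <- numeric(0)
  pi_hist <- F_hist <- G_hist <- matrix(NA_real_, n_pol, 0)
  conv_flags <- logical(0)
  iter_per_epoch <- integer(0)
  prev <- NULL
  choice_made <- FALSE
  xn <- if (trace) {
    purrr::map(N_STATES, function(d) array(NA_real_, c(d, T, n_bins, 0)))
  } else NULL

  for (t in seq_len(T)) {
    # -- precision: response to the outcome that just arrived -------------
    if (t == 1L) {
      g_t <- 1 / model$beta_prior
      gamma_bins <- c(gamma_bins, rep(g_t, n_bins))
    } else {
      pi_forced <- as.numeric(seq_len(n_pol) == executed[t - 1L])
      up <- update_precision(pi = pi_forced, G = prev$G,
                             beta_prior = model$beta_prior)
      g_t <- up$gamma
      gtr <- up$gamma_trace
      gamma_bins <- c(gamma_bins,
                      c(gtr, rep(gtr[length(gtr)], n_bins - length(gtr))))
    }
    gamma <- c(gamma, g_t)

    # -- planning: one-step policy extensions -----------------------------
    states <- vector("list", n_pol)
    Fv <- Gv <- numeric(n_pol)
    comps <- vector("list", n_pol)
    iters <- 0L
    straces <- if (trace) vector("list", n_pol) else NULL
    for (k in seq_len(n_pol)) {
      pol <- c(executed, rep(k, T - t))
      init <- if (is.null(prev)) NULL else prev$states[[executed[t - 1L]]]
      us <- update_states(model, obs, pol, init = init, trace = trace)
      states[[k]] <- us$expectations
      Fv[k] <- us$F
      iters <- iters + us$n_iter
      conv_flags <- c(conv_flags, us$converged)
      if (trace) straces[[k]] <- us$s_trace
      if (t < T) {
        ef <- expected_free_energy(model, us$expectations, t,
                                   horizon = g_horizon)
        Gv[k] <- ef$G
        comps[[k]] <- ef$components
      }  # at t = T there are no future outcomes to score; G = 0
    }
    pp <- policy_posterior(Fv, Gv, g_t)
    pi_t <- pp$pi
    pi_hist <- cbind(pi_hist, pi_t)
    F_hist <- cbind(F_hist, Fv)
    G_hist <- cbind(G_hist, Gv)
    iter_per_epoch <- c(iter_per_epoch, iters)

    if (trace) {
      for (f in FACTORS) {
        blk <- array(0, c(N_STATES[[f]], T, n_bins))
        for (k in seq_len(n_pol)) {
          tr <- straces[[k]]
          for (b in seq_len(n_bins)) {
            snap <- tr[[min(b, length(tr))]][[f]]
            blk[, , b] <- blk[, , b] + pi_t[k] * snap
          }
        }
        xn[[f]] <- array(c(xn[[f]], blk), c(N_STATES[[f]], T, n_bins, t))
      }
    }

    # -- action -----------------------------------------------------------
    if (t > max_saccades || t == T) break
    if (choice_made) {
      a <- executed[length(executed)]  # hold the eye at the choice location
    } else {
      pred <- bma_next_outcome(pi_t, states, model, t)
      cur <- purrr::map(FACTORS, function(f) {
        v <- numeric(N_STATES[[f]])
        for (k in seq_len(n_pol)) v <- v + pi_t[k] * states[[k]][[f]][, t]
        v
      })
      names(cur) <- FACTORS
      if (action_mode == "sampled") {
        kl <- action_kl(pred, model, cur)
        a <- sample.int(n_pol, 1L, prob = softmax(-action_precision * kl))
      } else {
        a <- select_action(pred, model, cur)
      }
    }
    executed <- c(executed, a)
    obs[[t + 1L]] <- env_step(scene, a)
    if (a >= 6L) choice_made <- TRUE
    prev <- list(G = Gv, states = states)
    if (choice_made && stop_at_choice) {
      # account for the arrival of the feedback outcome
      pi_forced <- as.numeric(seq_len(n_pol) == a)
      up <- update_precision(pi = pi_forced, G = Gv,
                             beta_prior = model$beta_prior)
      gamma <- c(gamma, up$gamma)
      gtr <- up$gamma_trace
      gamma_bins <- c(gamma_bins,
                      c(gtr, rep(gtr[length(gtr)], n_bins - length(gtr))))
      break
    }
  }

  choice_idx <- which(executed >= 6L)
  choice <- if (length(choice_idx)) executed[choice_idx[1L]] else NA_integer_
  # scoring freezes at the first feedback outcome
  feedback <- if (length(choice_idx)) {
    c("right", "wrong")[obs[[choice_idx[1L] + 1L]]$what - 4L]
  } else "none"

  structure(
    list(scene = scene, actions = executed, observations = obs,
         choice = choice,
         choice_label = if (is.na(choice)) NA_character_ else LOCATIONS[choice],
         decision_saccade = if (length(choice_idx)) choice_idx[1L] else NA_integer_,
         feedback = feedback,
         gamma = gamma, gamma_bins = gamma_bins,
         pi = pi_hist, F = F_hist, G = G_hist,
         converged = conv_flags,
         iterations_total = sum(iter_per_epoch),
         iterations_per_epoch = iter_per_epoch,
         trace = xn,
         n_epochs = length(iter_per_epoch),
         max_saccades = max_saccades,
         params = list(c = model$c, beta_prior = model$beta_prior, T = T,
                       action_mode = action_mode,
                       action_precision = action_precision,
                       g_horizon = g_horizon, seed = seed)),
    class = "forage_trial"
  )
}

#' @export
print.forage_trial <- function(x, ...) {
  acts <- paste(LOCATIONS[x$actions], collapse = " -> ")
  cat(sprintf("<forage_trial> scene: %s (lr=%d, ud=%d)\n",
              x$scene$context, x$scene$flip_lr, x$scene$flip_ud))
  cat(sprintf("  saccades: %s\n", if (nzchar(acts)) acts else "(none)"))
  cat(sprintf("  choice: %s, feedback: %s, %d variational iterations\n",
              ifelse(is.na(x$choice), "none", x$choice_label), x$feedback,
              x$iterations_total))
  invisible(x)
}
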