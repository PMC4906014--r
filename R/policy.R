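# Expected free energy, policy posterior, and precision (inverse
# temperature) dynamics. Expected free energy decomposes as risk (the
# divergence of predicted from preferred outcomes) plus ambiguity (expected
# outcome entropy given states), or equivalently as negative epistemic value
# (state-outcome mutual information) minus extrinsic value (expected log
# preference), up to the preference normalization constant.

# Normalized log preferences: C enters the risk term as log softmax(C), so
# the additive constant of the (unnormalized log-probability) preferences is
# absorbed.
ln_pref <- function(C) C - log(sum(exp(C)))

#' Expected free energy of a policy's predictive beliefs
#'
#' For each future epoch `tau > current_epoch` and each outcome modality,
#' forms the predictive outcome distribution `o = A . q` (with `q` the
#' factorized predictive joint), and accumulates `risk = sum o (ln o - ln
#' softmax(C))` plus `ambiguity = E_q[H(outcome | state)]`. For this task's
#' one-hot likelihoods the ambiguity is identically zero, so `G` equals
#' accumulated risk. Epistemic (mutual information) and extrinsic
#' (`E[C]`) components are returned for diagnostics.
#'
#' @param model A [build_scene_model()] object.
#' @param expectations Per-factor expectation matrices (`states x T`) whose
#'   columns beyond `current_epoch` are policy-conditioned predictions.
#' @param current_epoch Epoch `t`; epochs `t+1 .. T` are scored.
#' @param horizon `"remaining"` accumulates over every remaining epoch;
#'   `"next"` scores only epoch `t + 1`.
#' @return A list with scalar `G` and a tibble `components` (per epoch and
#'   modality: risk, ambiguity, epistemic, extrinsic).
#' @export
expected_free_energy <- function(model, expectations, current_epoch,
                                 horizon = c("remaining", "next")) {
  horizon <- match.arg(horizon)
  T <- model$T
  stopifnot(current_epoch >= 0, current_epoch < T)
  taus <- if (horizon == "remaining") (current_epoch + 1):T else current_epoch + 1

  lnC <- purrr::map(model$C, ln_pref)
  # outcome entropy per joint state (zero for one-hot columns)
  H <- purrr::map(model$A, function(A) -colSums(A * log(A + (A == 0))))

  G <- 0
  rows <- vector("list", length(taus) * 2L)
  r <- 0L
  for (tau in taus) {
    q <- expectations$flip_ud[, tau] %x% expectations$flip_lr[, tau] %x%
      expectations$location[, tau] %x% expectations$context[, tau]
    for (m in names(model$A)) {
      o <- drop(model$A[[m]] %*% q)
      risk <- sum(o * (ln_safe(o) - lnC[[m]]))
      ambiguity <- sum(q * H[[m]])
      epistemic <- -sum(o * ln_safe(o)) - ambiguity
      extrinsic <- sum(o * model$C[[m]])
      G <- G + risk + ambiguity
      r <- r + 1L
      rows[[r]] <- tibble::tibble(epoch = tau, modality = m, risk = risk,
                                  ambiguity = ambiguity, epistemic = epistemic,
                                  extrinsic = extrinsic)
    }
  }
  list(G = G, components = dplyr::bind_rows(rows))
}

#' Posterior and prior beliefs about policies
#'
#' `pi = softmax(-F - gamma G)` combines the evidence each policy has
#' accumulated (its variational free energy `F`) with its expected free
#' energy `G`, weighted by the precision `gamma`. `pi0 = softmax(-gamma G)`
#' is the corresponding prior (no-observation) belief used by the precision
#' update.
#'
#' @param F,G Per-policy free energies (numeric vectors, equal length).
#' @param gamma Precision (inverse temperature), `> 0`.
#' @return A list with normalized `pi` and `pi0`.
#' @export
policy_posterior <- function(F, G, gamma) {
  stopifnot(length(F) == length(G), is.finite(F), is.finite(G), gamma > 0)
  list(pi = softmax(-F - gamma * G), pi0 = softmax(-gamma * G))
}

#' Update the precision of beliefs about policies
#'
#' Fixed-point iteration of `beta <- beta_prior + (pi - pi0) . G`, jointly
#' with re-evaluation of the policy beliefs, until `|delta beta| < tol`
#' (at most `max_iter` inner iterations). The expected precision is driven
#' by the difference in expected free energy under the policy beliefs with
#' and without observations: when observations favor policies with low
#' expected free energy, `(pi - pi0) . G < 0` and the precision `gamma =
#' 1/beta` rises (a simulated dopamine burst); when they favor policies
#' with high expected free energy, `gamma` falls (phasic suppression).
#'
#' Three calling modes: supply `F` to recompute both `pi` and `pi0` from
#' [policy_posterior()] at each inner iteration; supply a forced `pi`
#' (e.g. the delta posterior implied by an observed outcome) to recompute
#' only `pi0 = softmax(-gamma G)`; or supply both `pi` and `pi0` fixed, in
#' which case the update is a single assignment.
#'
#' @param pi Optional forced policy posterior.
#' @param pi0 Optional fixed policy prior.
#' @param G Per-policy expected free energies.
#' @param beta_prior Prior expectation of the temperature, `> 0`.
#' @param F Optional per-policy variational free energies.
#' @param tol Convergence tolerance on `beta`.
#' @param max_iter Maximum inner iterations.
#' @return A list with `beta` (posterior temperature, floored at 1/64),
#'   `gamma = 1/beta`, the final `pi` and `pi0`, and `gamma_trace` (one
#'   value per inner iteration, for dopamine simulation).
#' @export
update_precision <- function(pi = NULL, pi0 = NULL, G, beta_prior,
                             F = NULL, tol = 1e-4, max_iter = 8L) {
  stopifnot(beta_prior > 0)
  if (is.null(pi) && is.null(F)) stop("supply either `pi` or `F`", call. = FALSE)
  fixed_pi <- !is.null(pi)
  fixed_pi0 <- !is.null(pi0)
  beta <- beta_prior
  gamma <- 1 / beta
  gamma_trace <- numeric(0)
  for (i in seq_len(max_iter)) {
    if (!fixed_pi) pi <- softmax(-F - gamma * G)
    if (!fixed_pi0) pi0 <- softmax(-gamma * G)
    target <- max(beta_prior + sum((pi - pi0) * G), 1 / 64)
    # half-step relaxation: the plain fixed-point map can 2-cycle when the
    # spread of G is large; with both beliefs held fixed the target is
    # constant and the assignment is exact
    beta_new <- if (fixed_pi && fixed_pi0) target else (beta + target) / 2
    beta_new <- max(beta_new, 1 / 64)
    gamma <- 1 / beta_new
    gamma_trace <- c(gamma_trace, gamma)
    done <- abs(beta_new - beta) < tol
    beta <- beta_new
    if (done) break
  }
  list(beta = beta, gamma = gamma, pi = pi, pi0 = pi0,
       gamma_trace = gamma_trace)
}
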