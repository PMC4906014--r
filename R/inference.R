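# Mean-field variational state estimation. Posterior beliefs factorize over
# hidden-state factors and epochs; each factor/epoch marginal is updated by
# a gradient step in log space followed by softmax renormalization. Updates
# run for at most 16 iterations per epoch and stop early once the free
# energy decrease falls below 1/128 -- the same scheduling that defines the
# simulated "reaction time" of the agent.

softmax <- function(x) {
  y <- exp(x - max(x))
  y / sum(y)
}

# Contract a 4-d array (joint over factors) with the marginal vectors of
# every factor except `n`; returns a vector over factor n's states.
contract_but <- function(arr, s_cols, n) {
  d <- dim(arr)
  others <- setdiff(seq_along(d), n)
  m <- aperm(arr, c(n, others))
  dim(m) <- c(d[n], prod(d[others]))
  v <- s_cols[[others[3]]] %x% s_cols[[others[2]]] %x% s_cols[[others[1]]]
  drop(m %*% v)
}

# Full contraction with all factor marginals (expected value under the
# factorized joint).
contract_all <- function(arr, s_cols) {
  sum(contract_but(arr, s_cols, 1L) * s_cols[[1L]])
}

# Forward propagation of priors under a policy: the initialization used for
# a fresh (un-extended) policy.
prior_expectations <- function(model, policy) {
  T <- model$T
  purrr::imap(model$D, function(d, f) {
    s <- matrix(d, length(d), T)
    if (f == "location") {
      for (tau in 2:T) s[, tau] <- as.numeric(seq_len(8) == policy[tau - 1L])
    }
    s
  })
}

# Floored-log likelihood array for one observation, joint over factors.
obs_loglik <- function(model, obs) {
  arr <- model$lnA$what[obs$what, ] + model$lnA$where[obs$where, ]
  dim(arr) <- model$dims
  arr
}

#' Variational free energy of factorized beliefs
#'
#' Evaluates `F = complexity - accuracy` under the mean-field
#' factorization: complexity is the divergence of each factor/epoch
#' marginal from its forward (prior) message under the policy, and accuracy
#' is the expected log-likelihood of the observed outcomes. `F` is additive
#' over epochs and factors and upper-bounds the negative log evidence.
#'
#' @param model A [build_scene_model()] object.
#' @param expectations Per-factor expectation matrices (`states x T`).
#' @param observations List of observations (fields `what`, `where`) for
#'   epochs `1..t`.
#' @param policy Integer vector of actions (length `T - 1`).
#' @return Scalar free energy (nats).
#' @export
free_energy <- function(model, expectations, observations, policy) {
  T <- model$T
  stopifnot(length(policy) == T - 1L)
  ok <- vapply(expectations,
               function(s) all(abs(colSums(s) - 1) < 1e-6) && all(s >= 0),
               logical(1))
  if (!all(ok)) stop("expectations must be normalized probability columns",
                     call. = FALSE)
  Fv <- 0
  for (tau in seq_len(T)) {
    for (f in FACTORS) {
      s <- expectations[[f]][, tau]
      fwd <- if (tau == 1L) {
        model$D[[f]]
      } else if (f == "location") {
        as.numeric(seq_len(8) == policy[tau - 1L])
      } else {
        expectations[[f]][, tau - 1L]
      }
      Fv <- Fv + sum(s * (ln_safe(s) - ln_safe(fwd)))
    }
  }
  for (tau in seq_along(observations)) {
    s_cols <- purrr::map(expectations, ~ .x[, tau])
    Fv <- Fv - contract_all(obs_loglik(model, observations[[tau]]), s_cols)
  }
  Fv
}

#' Mean-field belief update for one policy
#'
#' Runs the variational gradient updates for the trajectory posterior under
#' one policy. Each iteration sweeps every factor and observed epoch,
#' forming the message `v` = forward transition message + backward
#' transition message (from the next *observed* epoch) + log of the
#' observation likelihood contracted over the other factors' beliefs, and
#' then relaxes the marginal in log space: `s <- softmax(ln s + kappa (v -
#' ln s))`. Past epochs are revisited on every call, so beliefs about the
#' past are postdictive. Epochs beyond the last observation are pure
#' predictions under the policy and have a closed form here (identity
#' transitions carry the current static marginals forward; the controllable
#' location factor follows the policy exactly), so they are propagated
#' rather than iterated. Iteration stops after `max_iter` sweeps or as soon
#' as the free-energy decrease falls below `tol`.
#'
#' @param model A [build_scene_model()] object.
#' @param observations Observations for epochs `1..t` (list of `what`/
#'   `where` pairs); `t` may be less than `T`.
#' @param policy Integer action vector of length `T - 1` (executed prefix
#'   plus candidate continuation).
#' @param init Optional initial expectations (e.g. the parent policy's),
#'   defaulting to forward-propagated priors.
#' @param kappa Step size of the log-space relaxation.
#' @param max_iter Maximum number of update sweeps.
#' @param tol Early-stopping threshold on the free-energy decrease; `0`
#'   disables early stopping (always run `max_iter` sweeps).
#' @param trace If `TRUE`, store a per-iteration snapshot of the
#'   expectations (used for simulated firing-rate rasters).
#' @return A list with `expectations`, final free energy `F`, iteration
#'   count `n_iter`, `converged` flag, per-iteration `F_trace`, and
#'   (optionally) `s_trace`.
#' @export
update_states <- function(model, observations, policy, init = NULL,
                          kappa = 0.25, max_iter = 16L, tol = 1 / 128,
                          trace = FALSE, log_first = FALSE) {
  T <- model$T
  t <- length(observations)
  stopifnot(length(policy) == T - 1L, t <= T)
  s <- if (is.null(init)) prior_expectations(model, policy) else init
  ok <- vapply(s, function(x) all(abs(colSums(x) - 1) < 1e-6) && all(x >= -1e-12),
               logical(1))
  if (!all(ok)) stop("initial expectations must be normalized", call. = FALSE)
  # Location transitions are deterministic and controllable, so predictive
  # location marginals are exact one-hot vectors under the policy; set them
  # directly (an init inherited from a parent policy carries the parent's
  # saccade plan, and relaxing away from a one-hot through the log floor
  # would take many iterations while leaving F on a flat plateau).
  if (t < T) {
    for (tau in (t + 1L):T) {
      s$location[, tau] <- as.numeric(seq_len(8) == policy[tau - 1L])
    }
  }

  # Per-observation likelihood arrays, pre-permuted once per factor so each
  # message is a single small matrix-vector product. The message to factor n
  # is ln(E_{q(others)}[P(o | s)]): the likelihood is contracted over the
  # other factors' beliefs *before* the log is taken, so a state is driven
  # to the log floor only when it is inconsistent with the observation under
  # every configuration of the other factors. (Taking logs first instead
  # lets the floor term dominate whenever any other factor is uncertain,
  # which destabilizes the temporal mean field; see the methods vignette.)
  dims <- model$dims
  perm_mats <- function(arr) {
    purrr::map(seq_along(dims), function(n) {
      others <- setdiff(seq_along(dims), n)
      m <- aperm(arr, c(n, others))
      dim(m) <- c(dims[n], prod(dims[others]))
      m
    })
  }
  L_mats <- purrr::map(observations, function(o) {
    arr <- model$A$what[o$what, ] * model$A$where[o$where, ]
    dim(arr) <- dims
    perm_mats(arr)
  })
  lnL_mats <- purrr::map(observations, ~ perm_mats(obs_loglik(model, .x)))
  lnD <- purrr::map(model$D, ln_safe)
  loc_onehot <- purrr::map(seq_len(8), function(a) {
    ln_safe(as.numeric(seq_len(8) == a))
  })

  # fast free energy: complexity against forward messages minus accuracy
  fast_F <- function(s) {
    Fv <- 0
    for (nf in seq_along(FACTORS)) {
      f <- FACTORS[nf]
      sm <- s[[f]]
      lnsm <- ln_safe(sm)
      fwd <- cbind(lnD[[f]],
                   if (f == "location") {
                     vapply(policy, function(a) loc_onehot[[a]], numeric(8))
                   } else lnsm[, -T, drop = FALSE])
      Fv <- Fv + sum(sm * (lnsm - fwd))
    }
    for (tau in seq_len(t)) {
      oth <- s$flip_ud[, tau] %x% s$flip_lr[, tau] %x% s$location[, tau]
      Fv <- Fv - sum(s$context[, tau] * (lnL_mats[[tau]][[1L]] %*% oth))
    }
    Fv
  }

  F_trace <- fast_F(s)
  s_trace <- if (trace) list() else NULL
  # Unobserved epochs are pure predictions under the policy: statics are
  # the current-epoch marginals carried forward by the identity
  # transitions, locations the policy's one-hot targets. At that propagated
  # point the exact backward gradient through a prediction epoch is
  # constant, so prediction epochs neither receive updates nor send
  # backward messages; iterating them with the ln-s message instead pulls
  # the tail of the trajectory toward uniform and leaves spurious
  # complexity in F.
  propagate <- function(s) {
    if (t < T) {
      for (f in FACTORS[-2L]) s[[f]][, (t + 1L):T] <- s[[f]][, t]
    }
    s
  }
  s <- propagate(s)

  converged <- FALSE
  n_iter <- 0L
  for (i in seq_len(max_iter)) {
    for (tau in seq_len(t)) {
      cols <- list(s$context[, tau], s$location[, tau],
                   s$flip_lr[, tau], s$flip_ud[, tau])
      for (nf in seq_along(FACTORS)) {
        f <- FACTORS[nf]
        v <- if (tau == 1L) {
          lnD[[f]]
        } else if (nf == 2L) {
          loc_onehot[[policy[tau - 1L]]]
        } else {
          ln_safe(s[[f]][, tau - 1L])
        }
        if (tau < t && nf != 2L) {
          # backward message under identity transitions; for the location
          # factor B(a)^T s is constant and drops out of the softmax
          v <- v + ln_safe(s[[f]][, tau + 1L])
        }
        others <- setdiff(1:4, nf)
        kv <- cols[[others[3]]] %x% cols[[others[2]]] %x% cols[[others[1]]]
        v <- v + if (log_first) {
          drop(lnL_mats[[tau]][[nf]] %*% kv)
        } else {
          ln_safe(drop(L_mats[[tau]][[nf]] %*% kv))
        }
        lns <- ln_safe(s[[f]][, tau])
        newcol <- softmax(lns + kappa * (v - lns))
        s[[f]][, tau] <- newcol
        cols[[nf]] <- newcol
      }
    }
    s <- propagate(s)
    n_iter <- i
    Fi <- fast_F(s)
    F_trace <- c(F_trace, Fi)
    if (trace) s_trace[[i]] <- s
    if (tol > 0 && F_trace[i] - Fi < tol) {
      converged <- TRUE
      break
    }
  }
  list(expectations = s, F = F_trace[length(F_trace)], n_iter = n_iter,
       converged = converged, F_trace = F_trace, s_trace = s_trace)
}
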