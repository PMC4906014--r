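# Ground-truth references: exact joint Bayesian inference by enumeration,
# brute-force policy counting, and exhaustive decision-tree search over the
# 12-configuration task. These are deliberately written without the
# factorized shortcuts used by the variational engine, so they can serve as
# independent oracles in tests.

#' Exact joint posterior by enumeration
#'
#' Enumerates all 96 joint hidden-state configurations (3 contexts x 8
#' locations x 2 x 2 reflections), applies the deterministic likelihood of
#' every observation in the history, and renormalizes. Because the location
#' trajectory is fully determined by the executed actions, the posterior is
#' supported on the 12 static (context, reflections) configurations at the
#' current location.
#'
#' @param model A [build_scene_model()] object.
#' @param actions Integer vector of executed saccade targets (may be empty).
#' @param observations List of observations as returned by [env_step()]
#'   (fields `what`, `where`), one per epoch; `length(observations)` must be
#'   `length(actions) + 1` (the initial fixation outcome counts).
#' @return A list with `joint` (length-96 posterior over joint states at
#'   the current epoch), `marginals` (per-factor marginals), and `configs`
#'   (tibble of the 12 static configurations with their posterior mass).
#' @export
exact_posterior <- function(model, actions = integer(0), observations = list()) {
  stopifnot(inherits(model, "forage_model"))
  actions <- as.integer(actions)
  if (length(observations) != length(actions) + 1L && length(observations) > 0L) {
    stop("need length(observations) == length(actions) + 1", call. = FALSE)
  }
  # location at epoch tau: fixation at tau = 1, then the saccade targets
  locs <- c(1L, actions)
  grid <- tidyr::expand_grid(flip_ud = 0:1, flip_lr = 0:1, ctx = 1:3)
  w <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    p <- model$D$context[grid$ctx[r]] *
      model$D$flip_lr[grid$flip_lr[r] + 1L] *
      model$D$flip_ud[grid$flip_ud[r] + 1L]
    for (tau in seq_along(observations)) {
      o <- observations[[tau]]
      j <- joint_index(grid$ctx[r], locs[tau], grid$flip_lr[r], grid$flip_ud[r])
      p <- p * model$A$what[o$what, j] * model$A$where[o$where, j]
    }
    w[r] <- p
  }
  if (sum(w) <= 0) stop("observation history has zero probability", call. = FALSE)
  w <- w / sum(w)

  cur_loc <- locs[max(1L, length(locs))]
  joint <- numeric(prod(model$dims))
  for (r in seq_len(nrow(grid))) {
    joint[joint_index(grid$ctx[r], cur_loc, grid$flip_lr[r], grid$flip_ud[r])] <-
      w[r]
  }
  marginals <- list(
    context  = vapply(1:3, function(i) sum(w[grid$ctx == i]), 0),
    location = as.numeric(seq_len(8) == cur_loc),
    flip_lr  = vapply(0:1, function(i) sum(w[grid$flip_lr == i]), 0),
    flip_ud  = vapply(0:1, function(i) sum(w[grid$flip_ud == i]), 0)
  )
  names(marginals$context) <- CONTEXTS
  configs <- tibble::tibble(
    context = CONTEXTS[grid$ctx], flip_lr = grid$flip_lr,
    flip_ud = grid$flip_ud, posterior = w
  )
  list(joint = joint, marginals = marginals, configs = configs)
}

#' Count (and enumerate) policies
#'
#' @param depth Policy depth (number of consecutive actions).
#' @param n_actions Number of available actions per step.
#' @param list_policies If `TRUE` and `depth <= 5`, also return the explicit
#'   matrix of action sequences (one row per policy).
#' @return The policy count `n_actions^depth`; with `list_policies = TRUE`,
#'   a list with `count` and `policies`.
#' @export
enumerate_policies <- function(depth, n_actions = 8L, list_policies = FALSE) {
  stopifnot(depth >= 1, n_actions >= 1)
  count <- n_actions^depth
  if (!list_policies) return(count)
  if (depth > 5) stop("explicit enumeration supported for depth <= 5", call. = FALSE)
  policies <- as.matrix(expand.grid(rep(list(seq_len(n_actions)), depth)))
  dimnames(policies) <- NULL
  list(count = count, policies = policies)
}

#' Minimal worst-case number of moves guaranteeing correct categorization
#'
#' Exhaustive search for the smallest number of moves (quadrant samples
#' plus the final choice, which counts as a move) after which the scene
#' category is certain for *every* configuration of the task.
#'
#' The default (`adaptive = FALSE`) searches over open-loop sampling
#' sequences -- fixed sets of quadrants sampled regardless of what is seen,
#' with only the final choice conditioned on the observations. This is the
#' notion that matches policies defined as fixed action sequences (and
#' hence the `8^depth` policy enumeration): on the full 12-configuration
#' task, four quadrant samples are required, so five moves guarantee a
#' correct categorization.
#'
#' With `adaptive = TRUE` the search is over closed-loop decision trees
#' whose internal nodes sample a quadrant and branch on the cue observed
#' there, memoized over information sets (subsets of still-consistent
#' configurations). Adaptivity is strictly stronger here: on the full task
#' a decision tree guarantees the category in four moves (sample a
#' quadrant; if it is empty, sample the diagonally opposite quadrant --
#' if that is also empty the scene can only be "wait").
#'
#' @param scenes A list of `scene_config` objects defining the task
#'   (defaults to all 12 configurations).
#' @param adaptive If `TRUE`, search closed-loop decision trees; otherwise
#'   open-loop sequences.
#' @return The minimal worst-case number of moves (integer).
#' @export
minimal_guaranteeing_depth <- function(scenes = all_scenes()$scene,
                                       adaptive = FALSE) {
  cues <- t(vapply(scenes, function(s) s$layout[QUADRANTS], character(4)))
  ctxs <- vapply(scenes, function(s) s$context, character(1))
  n <- length(scenes)

  if (!adaptive) {
    # smallest quadrant subset separating every context-discordant pair
    pairs <- which(outer(ctxs, ctxs, "!=") & upper.tri(diag(n)), arr.ind = TRUE)
    for (k in 0:4) {
      subsets <- if (k == 0) list(integer(0)) else utils::combn(4, k, simplify = FALSE)
      for (qs in subsets) {
        sep <- nrow(pairs) == 0L ||
          all(vapply(seq_len(nrow(pairs)), function(r) {
            length(qs) > 0 &&
              any(cues[pairs[r, 1], qs] != cues[pairs[r, 2], qs])
          }, logical(1)))
        if (sep) return(k + 1L)
      }
    }
    stop("task is not solvable by quadrant sampling", call. = FALSE)
  }

  memo <- new.env(parent = emptyenv())

  solve <- function(idx) {
    key <- paste(idx, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (length(unique(ctxs[idx])) == 1L) {
      memo[[key]] <- 1L  # choose now; correct for every consistent config
      return(1L)
    }
    best <- Inf
    for (q in 1:4) {
      branches <- split(idx, cues[idx, q])
      if (length(branches) == 1L) next  # uninformative sample
      worst <- 1L + max(vapply(branches, solve, numeric(1)))
      if (worst < best) best <- worst
    }
    memo[[key]] <- best
    best
  }
  as.integer(solve(seq_len(n)))
}

#' Brute-force expected free energy
#'
#' Evaluates the expected free energy of the predictive beliefs of a policy
#' by explicit summation over every joint hidden state and every outcome,
#' with no factorized shortcuts: the predictive joint over states is formed
#' element by element from the factor marginals, predictive outcome
#' distributions by direct summation, and risk/ambiguity/epistemic terms by
#' scalar loops. Used to validate the engine's [expected_free_energy()].
#'
#' @param model A [build_scene_model()] object.
#' @param expectations Per-factor expectation matrices (`states x T`), as in
#'   the engine's belief states.
#' @param current_epoch Epoch `t`; epochs `t+1 .. T` are scored.
#' @return A list with scalar `G` and per-epoch component tibble.
#' @export
brute_force_G <- function(model, expectations, current_epoch) {
  T <- model$T
  stopifnot(current_epoch >= 0, current_epoch < T)
  dims <- model$dims
  n_joint <- prod(dims)
  states <- as.matrix(expand.grid(ctx = 1:3, loc = 1:8, fl = 1:2, fu = 1:2))
  lnC <- purrr::map(model$C, function(cv) cv - log(sum(exp(cv))))

  G <- 0
  rows <- list()
  for (tau in (current_epoch + 1):T) {
    q <- numeric(n_joint)
    for (j in seq_len(n_joint)) {
      q[j] <- expectations$context[states[j, "ctx"], tau] *
        expectations$location[states[j, "loc"], tau] *
        expectations$flip_lr[states[j, "fl"], tau] *
        expectations$flip_ud[states[j, "fu"], tau]
    }
    for (m in names(model$A)) {
      A <- model$A[[m]]
      n_out <- nrow(A)
      o <- numeric(n_out)
      for (i in seq_len(n_out)) {
        for (j in seq_len(n_joint)) o[i] <- o[i] + A[i, j] * q[j]
      }
      risk <- 0
      for (i in seq_len(n_out)) {
        if (o[i] > 0) risk <- risk + o[i] * (log(o[i]) - lnC[[m]][i])
      }
      ambiguity <- 0
      for (j in seq_len(n_joint)) {
        h <- 0
        for (i in seq_len(n_out)) {
          if (A[i, j] > 0) h <- h - A[i, j] * log(A[i, j])
        }
        ambiguity <- ambiguity + q[j] * h
      }
      h_o <- 0
      for (i in seq_len(n_out)) if (o[i] > 0) h_o <- h_o - o[i] * log(o[i])
      epistemic <- h_o - ambiguity
      extrinsic <- sum(o * model$C[[m]])
      G <- G + risk + ambiguity
      rows[[length(rows) + 1L]] <- tibble::tibble(
        epoch = tau, modality = m, risk = risk, ambiguity = ambiguity,
        epistemic = epistemic, extrinsic = extrinsic
      )
    }
  }
  list(G = G, components = dplyr::bind_rows(rows))
}
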