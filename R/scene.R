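# Task structure: a 2x2 scene containing a bird together with either a seed
# or a cat. The scene category is defined purely by the spatial relation
# between the two cues: seed next to the bird -> "feed", cat next to the
# bird -> "flee", seed diagonally opposite the bird -> "wait". Absolute cue
# positions are nuisance variables, generated by reflecting a base scene
# about the vertical and/or horizontal axis.

#' @importFrom rlang .data
NULL

# Fixed index orders. Serialized traces are only comparable across runs
# because these never change.
CONTEXTS  <- c("flee", "feed", "wait")
LOCATIONS <- c("fixation", "UL", "LL", "UR", "LR",
               "choose-flee", "choose-feed", "choose-wait")
CUES      <- c("null", "seed", "bird", "cat", "right", "wrong")
QUADRANTS <- c("UL", "UR", "LL", "LR")
FACTORS   <- c("context", "location", "flip_lr", "flip_ud")
N_STATES  <- c(context = 3L, location = 8L, flip_lr = 2L, flip_ud = 2L)

# Base scenes: bird at the upper right in all three; its companion at the
# horizontally adjacent quadrant (UL) for flee/feed and at the diagonally
# opposite quadrant (LL) for wait.
BASE_LAYOUTS <- list(
  flee = c(UL = "cat",  UR = "bird", LL = "null", LR = "null"),
  feed = c(UL = "seed", UR = "bird", LL = "null", LR = "null"),
  wait = c(UL = "null", UR = "bird", LL = "seed", LR = "null")
)

# Quadrant permutations under the two reflections.
FLIP_LR_MAP <- c(UL = "UR", UR = "UL", LL = "LR", LR = "LL")
FLIP_UD_MAP <- c(UL = "LL", UR = "LR", LL = "UL", LR = "UR")

#' Construct a scene configuration
#'
#' Builds the ground-truth hidden cause of a trial: a scene category
#' (`flee`, `feed`, or `wait`) together with two binary reflections, and the
#' 2x2 cue layout they induce. `flip_lr` reflects about the vertical axis
#' (swaps the left and right columns); `flip_ud` reflects about the
#' horizontal axis (swaps the top and bottom rows).
#'
#' @param context Scene category, one of `"flee"`, `"feed"`, `"wait"`.
#' @param flip_lr,flip_ud Binary (0/1 or logical) reflection flags.
#' @return An object of class `scene_config`: a list with elements
#'   `context`, `flip_lr`, `flip_ud`, and `layout` (a named character vector
#'   over quadrants `UL`, `UR`, `LL`, `LR`).
#' @examples
#' scene_layout("flee", 0, 0)$layout  # bird at UR, cat at UL
#' @export
scene_layout <- function(context, flip_lr = 0, flip_ud = 0) {
  context <- as.character(context)
  if (length(context) != 1L || !context %in% CONTEXTS) {
    stop("`context` must be one of: ", paste(CONTEXTS, collapse = ", "),
         call. = FALSE)
  }
  flip_lr <- as.integer(flip_lr)
  flip_ud <- as.integer(flip_ud)
  stopifnot(flip_lr %in% 0:1, flip_ud %in% 0:1)

  layout <- BASE_LAYOUTS[[context]]
  if (flip_lr == 1L) names(layout) <- FLIP_LR_MAP[names(layout)]
  if (flip_ud == 1L) names(layout) <- FLIP_UD_MAP[names(layout)]
  layout <- layout[QUADRANTS]

  structure(
    list(context = context, flip_lr = flip_lr, flip_ud = flip_ud,
         layout = layout),
    class = "scene_config"
  )
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("<scene_config> context=%s flip_lr=%d flip_ud=%d\n",
              x$context, x$flip_lr, x$flip_ud))
  grid <- matrix(x$layout[c("UL", "UR", "LL", "LR")], 2, 2, byrow = TRUE,
                 dimnames = list(c("top", "bottom"), c("left", "right")))
  print(grid, quote = FALSE)
  invisible(x)
}

#' All 12 scene configurations
#'
#' @return A tibble with one row per (context, flip_lr, flip_ud)
#'   combination and a list-column `scene` of [scene_layout()] objects.
#' @export
all_scenes <- function() {
  grid <- tidyr::expand_grid(context = CONTEXTS, flip_lr = 0:1, flip_ud = 0:1)
  grid$scene <- purrr::pmap(grid, scene_layout)
  grid
}

#' Sample random scene configurations
#'
#' Contexts and reflections are drawn uniformly and independently, using
#' the current RNG state (seed it with [set.seed()] for reproducibility).
#'
#' @param n Number of scenes.
#' @return A list of `scene_config` objects.
#' @export
sample_scenes <- function(n) {
  stopifnot(n >= 1)
  ctx <- sample(CONTEXTS, n, replace = TRUE)
  fl  <- sample(0:1, n, replace = TRUE)
  fu  <- sample(0:1, n, replace = TRUE)
  purrr::pmap(list(ctx, fl, fu), scene_layout)
}

# Column-major joint state index over factors (context, location, flip_lr,
# flip_ud); the joint space has 3*8*2*2 = 96 configurations.
joint_index <- function(ctx, loc, fl, fu) {
  ctx + 3L * (loc - 1L) + 24L * fl + 48L * fu
}

# Floor used before taking logs of one-hot probabilities.
LOG_FLOOR <- 1e-16
ln_safe <- function(x) log(pmax(x, LOG_FLOOR))

#' Build the scene-construction generative model
#'
#' Assembles the likelihood, transition, preference, and prior arrays of the
#' foraging task. Two outcome modalities report *what* is seen (one of six
#' cues: null, seed, bird, cat, and right/wrong feedback) and *where* it is
#' seen (fixation, four quadrants, three choice locations). Hidden states
#' factorize into scene context, sampled location, and two reflection flags
#' (3 x 8 x 2 x 2 = 96 joint configurations). All likelihoods are
#' deterministic (one-hot columns): the cue seen at a quadrant is the
#' layout cue there, fixation shows the null cue, and the choice location
#' matching the true context returns `right` feedback while the other two
#' return `wrong`.
#'
#' Preferences over the *what* modality are `C1 = [0, 0, 0, 0, c, -2c]`:
#' the agent expects correct feedback `exp(c)` times more than any visual
#' cue and expects incorrect feedback very rarely. There is no preference
#' over sampled locations. Only the location factor is controllable: saccade
#' action `k` moves the eye to location `k` from anywhere; the other factors
#' are static (identity transitions).
#'
#' @param c Preference strength (utility of correct feedback), `c >= 0`.
#' @param beta_prior Prior expectation of the inverse precision (temperature)
#'   of policy selection, `> 0`. Precision is `gamma = 1/beta`.
#' @param T Number of outcome epochs per trial (including the initial
#'   fixation), `>= 2`; `T` epochs allow `T - 1` saccades.
#' @return An object of class `forage_model`: a list with likelihood
#'   matrices `A` (`what`: 6 x 96, `where`: 8 x 96) and their floored logs
#'   `lnA`, transition arrays `B` (per factor, state x state x action),
#'   preference vectors `C`, priors `D`, `beta_prior`, `T`, and label
#'   metadata.
#' @examples
#' m <- build_scene_model(c = 2, beta_prior = 1, T = 6)
#' m$C$what  # 0 0 0 0 2 -4
#' @export
build_scene_model <- function(c = 2, beta_prior = 1, T = 6) {
  stopifnot(is.numeric(c), length(c) == 1L, c >= 0,
            is.numeric(beta_prior), length(beta_prior) == 1L, beta_prior > 0,
            T == as.integer(T), T >= 2)
  T <- as.integer(T)

  n_joint <- prod(N_STATES)
  A_what  <- matrix(0, 6, n_joint)
  A_where <- matrix(0, 8, n_joint)

  loc_quadrant <- c(NA, "UL", "LL", "UR", "LR", NA, NA, NA)
  for (fu in 0:1) for (fl in 0:1) for (ctx in 1:3) {
    layout <- scene_layout(CONTEXTS[ctx], fl, fu)$layout
    for (loc in 1:8) {
      j <- joint_index(ctx, loc, fl, fu)
      what <- if (loc == 1L) {
        "null"
      } else if (loc <= 5L) {
        layout[[loc_quadrant[loc]]]
      } else if (loc - 5L == ctx) "right" else "wrong"
      A_what[match(what, CUES), j] <- 1
      A_where[loc, j] <- 1
    }
  }

  B <- list(
    context  = array(diag(3), c(3, 3, 8)),
    location = array(0, c(8, 8, 8)),
    flip_lr  = array(diag(2), c(2, 2, 8)),
    flip_ud  = array(diag(2), c(2, 2, 8))
  )
  for (k in 1:8) B$location[k, , k] <- 1  # move to location k from anywhere

  model <- structure(
    list(
      A  = list(what = A_what, where = A_where),
      lnA = list(what = ln_safe(A_what), where = ln_safe(A_where)),
      B  = B,
      C  = list(what = c(0, 0, 0, 0, c, -2 * c), where = rep(0, 8)),
      D  = list(context = rep(1 / 3, 3), location = c(1, rep(0, 7)),
                flip_lr = rep(1 / 2, 2), flip_ud = rep(1 / 2, 2)),
      beta_prior = beta_prior,
      T = T,
      c = c,
      n_actions = 8L,
      dims = N_STATES,
      labels = list(contexts = CONTEXTS, locations = LOCATIONS, cues = CUES)
    ),
    class = "forage_model"
  )
  model
}

#' @export
print.forage_model <- function(x, ...) {
  cat(sprintf(
    "<forage_model> %d joint hidden states (%s), %d actions, T = %d\n",
    prod(x$dims), paste(x$dims, collapse = " x "), x$n_actions, x$T))
  cat(sprintf("  c = %g, beta_prior = %g\n", x$c, x$beta_prior))
  invisible(x)
}

#' Query the environment with a saccade
#'
#' The ground-truth environment: given the true scene and a saccade target,
#' returns the (deterministic) observation in both modalities.
#'
#' @param scene A [scene_layout()] object.
#' @param action Saccade target: an index in 1..8 or a location name.
#' @return A list with integer indices `what`, `where` and their labels
#'   `what_label`, `where_label`.
#' @export
env_step <- function(scene, action) {
  stopifnot(inherits(scene, "scene_config"))
  if (is.character(action)) action <- match(action, LOCATIONS)
  if (is.na(action) || !action %in% 1:8) {
    stop("`action` must be a location index 1..8 or one of: ",
         paste(LOCATIONS, collapse = ", "), call. = FALSE)
  }
  action <- as.integer(action)
  ctx <- match(scene$context, CONTEXTS)
  what <- if (action == 1L) {
    1L
  } else if (action <= 5L) {
    match(scene$layout[[c(NA, "UL", "LL", "UR", "LR")[action]]], CUES)
  } else if (action - 5L == ctx) 5L else 6L
  list(what = what, where = action,
       what_label = CUES[what], where_label = LOCATIONS[action])
}

# Joint state index of a scene at a given location.
scene_state <- function(scene, location = 1L) {
  joint_index(match(scene$context, CONTEXTS), as.integer(location),
              scene$flip_lr, scene$flip_ud)
}

#' Export / import a generative model as JSON
#'
#' Serializes the dense A/B/C/D arrays (row-major), factor names and
#' cardinalities, and scalar parameters, for oracle cross-checking and
#' regression tests. `forage_model_from_json()` reconstructs an identical
#' model object.
#'
#' @param model A [build_scene_model()] object.
#' @param path File path for the JSON document.
#' @return `forage_model_to_json()` returns `path` invisibly;
#'   `forage_model_from_json()` returns a `forage_model`.
#' @export
forage_model_to_json <- function(model, path) {
  stopifnot(inherits(model, "forage_model"))
  doc <- list(
    factors = as.list(model$dims),
    modalities = list(what = 6L, where = 8L),
    # row-major dumps: t() so that each row of the R matrix is contiguous
    A = purrr::map(model$A, ~ as.vector(t(.x))),
    B = purrr::map(model$B, ~ as.vector(aperm(.x, c(3, 1, 2)))),
    C = model$C,
    D = model$D,
    beta_prior = model$beta_prior,
    T = model$T,
    c = model$c,
    labels = model$labels
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname forage_model_to_json
#' @export
forage_model_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- unlist(doc$factors)
  n_joint <- prod(dims)
  A <- list(
    what  = matrix(doc$A$what,  6, n_joint, byrow = TRUE),
    where = matrix(doc$A$where, 8, n_joint, byrow = TRUE)
  )
  B <- purrr::imap(doc$B, function(v, nm) {
    d <- dims[[nm]]
    aperm(array(v, c(8, d, d)), c(2, 3, 1))
  })
  structure(
    list(A = A, lnA = purrr::map(A, ln_safe), B = B,
         C = doc$C, D = doc$D,
         beta_prior = doc$beta_prior, T = as.integer(doc$T), c = doc$c,
         n_actions = 8L, dims = dims, labels = doc$labels),
    class = "forage_model"
  )
}
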