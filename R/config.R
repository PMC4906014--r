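# Run configuration, serialization, and the programmatic surface behind the
# command-line entry point (inst/cli/forage.R).

#' Build and validate a run configuration
#'
#' A validated bundle of every tunable the simulator exposes. Configs
#' round-trip through YAML/JSON unchanged, and every run can be replayed
#' exactly from its config and seed.
#'
#' @param c Preference strength (>= 0).
#' @param beta_prior Prior temperature of policy beliefs (> 0).
#' @param T Epochs per trial (>= 2).
#' @param max_saccades Saccades per trial (`<= T - 1`).
#' @param seed Integer seed.
#' @param action_mode `"argmin"` or `"sampled"`.
#' @param g_horizon `"remaining"` or `"next"` (how far expected free energy
#'   accumulates).
#' @param scene Optional fixed scene as `list(context, flip_lr, flip_ud)`;
#'   `NULL` draws a random scene from the seed.
#' @param sweep List with `n_trials`, `c_levels`, `precision_levels` for
#'   [run_sweep()].
#' @return A validated list of class `forage_config`.
#' @export
forage_config <- function(c = 2, beta_prior = 1, T = 6L,
                          max_saccades = T - 1L, seed = 1L,
                          action_mode = c("argmin", "sampled"),
                          g_horizon = c("remaining", "next"),
                          scene = NULL,
                          sweep = list(n_trials = 32L,
                                       c_levels = seq(0, 4, length.out = 8),
                                       precision_levels =
                                         2^seq(6, -4, length.out = 8))) {
  action_mode <- match.arg(action_mode)
  g_horizon <- match.arg(g_horizon)
  if (!is.numeric(c) || length(c) != 1L || c < 0) {
    stop("config error: `c` must be a single nonnegative number", call. = FALSE)
  }
  if (!is.numeric(beta_prior) || length(beta_prior) != 1L || beta_prior <= 0) {
    stop("config error: `beta_prior` must be a single positive number",
         call. = FALSE)
  }
  T <- as.integer(T)
  max_saccades <- as.integer(max_saccades)
  seed <- as.integer(seed)
  if (is.na(T) || T < 2L) stop("config error: T must be >= 2", call. = FALSE)
  if (is.na(max_saccades) || max_saccades < 0L || max_saccades > T - 1L) {
    stop("config error: max_saccades must be in 0..T-1", call. = FALSE)
  }
  if (is.na(seed)) stop("config error: seed must be an integer", call. = FALSE)
  if (!is.null(scene)) {
    scene <- list(context = as.character(scene$context),
                  flip_lr = as.integer(scene$flip_lr),
                  flip_ud = as.integer(scene$flip_ud))
    if (!scene$context %in% CONTEXTS) {
      stop("config error: unknown scene context", call. = FALSE)
    }
  }
  stopifnot(is.list(sweep), sweep$n_trials >= 1,
            length(sweep$c_levels) >= 1, length(sweep$precision_levels) >= 1)
  structure(
    list(c = c, beta_prior = beta_prior, T = T, max_saccades = max_saccades,
         seed = seed, action_mode = action_mode, g_horizon = g_horizon,
         scene = scene,
         sweep = list(n_trials = as.integer(sweep$n_trials),
                      c_levels = as.numeric(sweep$c_levels),
                      precision_levels = as.numeric(sweep$precision_levels))),
    class = "forage_config"
  )
}

#' Read / write a configuration file
#'
#' Configs are stored as YAML (`.yml`/`.yaml`) or JSON (anything else) and
#' revalidated on read, so a malformed file fails with a named error.
#'
#' @param config A [forage_config()] object.
#' @param path Destination / source file.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "forage_config"))
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(forage_config, x[!vapply(x, is.null, logical(1))])
}

# Reproducibility stamp attached to every CLI output.
run_metadata <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  git_rev <- tryCatch(
    system2("git", c("rev-parse", "HEAD"), stdout = TRUE, stderr = NULL)[1],
    error = function(e) NA_character_, warning = function(w) NA_character_
  )
  list(
    config_md5 = unname(tools::md5sum(tf)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("epiforage")),
    r_version = R.version.string,
    git_revision = if (is.na(git_rev)) NULL else git_rev,
    timestamp = format(Sys.time(), tz = "UTC")
  )
}

#' Run one trial from a configuration
#'
#' Builds the model, draws (or fixes) the scene, runs the trial, and
#' returns a JSON-ready list: trial summary, per-epoch diagnostics, belief
#' trace, precision/dopamine traces, and a reproducibility stamp (config
#' hash, seed, versions). Deterministic given the config.
#'
#' @param config A [forage_config()] object.
#' @param json_path Optional path; when given, the result is written as
#'   JSON.
#' @return The result list, invisibly when written to file.
#' @export
cli_run_trial <- function(config, json_path = NULL) {
  stopifnot(inherits(config, "forage_config"))
  model <- build_scene_model(c = config$c, beta_prior = config$beta_prior,
                             T = config$T)
  set.seed(config$seed)
  scene <- if (is.null(config$scene)) {
    sample_scenes(1)[[1]]
  } else {
    scene_layout(config$scene$context, config$scene$flip_lr,
                 config$scene$flip_ud)
  }
  trial <- run_trial(model, scene, seed = config$seed,
                     max_saccades = config$max_saccades,
                     action_mode = config$action_mode,
                     g_horizon = config$g_horizon, trace = TRUE)
  out <- list(
    metadata = run_metadata(config),
    scene = list(context = scene$context, flip_lr = scene$flip_lr,
                 flip_ud = scene$flip_ud, layout = as.list(scene$layout)),
    summary = as.list(glance.forage_trial(trial)),
    actions = LOCATIONS[trial$actions],
    observations = purrr::map(trial$observations, function(o) {
      list(what = CUES[o$what], where = LOCATIONS[o$where])
    }),
    per_epoch = list(F = trial$F, G = trial$G, pi = trial$pi,
                     gamma = trial$gamma,
                     iterations = trial$iterations_per_epoch,
                     converged = trial$converged),
    gamma_bins = trial$gamma_bins,
    dopamine = dopamine_signal(trial$gamma_bins),
    beliefs = purrr::map(trial$trace, function(a) {
      list(dim = dim(a), values = as.vector(a))
    })
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         matrix = "columnmajor")
    return(invisible(out))
  }
  out
}

#' Run a preference-by-precision sweep from a configuration
#'
#' @param config A [forage_config()] object (the `sweep` block supplies the
#'   grid).
#' @param csv_path Optional path for the per-cell CSV (one row per grid
#'   cell); bytes are identical across reruns with the same config.
#' @return The [run_sweep()] tibble, invisibly when written to file.
#' @export
cli_sweep <- function(config, csv_path = NULL) {
  stopifnot(inherits(config, "forage_config"))
  sw <- run_sweep(config$sweep$n_trials,
                  c_levels = config$sweep$c_levels,
                  precision_levels = config$sweep$precision_levels,
                  seed = config$seed, T = config$T,
                  action_mode = if (config$action_mode == "argmin")
                    "argmin" else "sampled")
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(sw), csv_path, row.names = FALSE)
    return(invisible(sw))
  }
  sw
}

#' Cross-check the engine against the exact oracles
#'
#' Recomputes the oracle quantities (joint state count, policy counts,
#' minimal guaranteeing depth, expected-free-energy agreement on random
#' belief states, and the mean-field overconfidence demonstration) and
#' returns them as a list.
#'
#' @param seed Seed for the random belief states.
#' @param n_belief_states How many random belief states to compare.
#' @return A list of oracle results.
#' @export
oracle_check <- function(seed = 1L, n_belief_states = 20L) {
  set.seed(seed)
  model <- build_scene_model()
  dev <- numeric(n_belief_states)
  for (i in seq_len(n_belief_states)) {
    expectations <- random_beliefs(model)
    t0 <- sample(0:(model$T - 1L), 1)
    dev[i] <- abs(expected_free_energy(model, expectations, t0)$G -
                    brute_force_G(model, expectations, t0)$G)
  }
  obs <- list(list(what = 1L, where = 1L), list(what = 1L, where = 5L))
  mf <- update_states(model, obs, c(5L, rep(5L, model$T - 2L)))
  ex <- exact_posterior(model, 5L, obs)
  list(
    joint_states = prod(model$dims),
    policies_depth5 = enumerate_policies(5, 8),
    minimal_moves = minimal_guaranteeing_depth(),
    minimal_moves_adaptive = minimal_guaranteeing_depth(adaptive = TRUE),
    max_G_deviation = max(dev),
    exact_p_wait = unname(ex$marginals$context["wait"]),
    meanfield_p_wait = mf$expectations$context[3, 2]
  )
}

# Random normalized belief states over all factors and epochs (test helper
# for oracle comparisons).
random_beliefs <- function(model) {
  purrr::map(model$D, function(d) {
    s <- matrix(stats::rgamma(length(d) * model$T, shape = 1),
                length(d), model$T)
    sweep(s, 2, colSums(s), "/")
  })
}
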