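# Shared fixtures: small models and canonical observation histories built
# in code at test time.

model_default <- function(c = 2, beta_prior = 1, T = 6) {
  build_scene_model(c = c, beta_prior = beta_prior, T = T)
}

obs_fixation <- function() list(what = 1L, where = 1L)

# observation history: initial fixation followed by saccades to `targets`
obs_history <- function(scene, targets) {
  c(list(obs_fixation()), lapply(targets, function(a) env_step(scene, a)))
}

# a stay-at-last-target policy vector of length T - 1
stay_policy <- function(targets, T) {
  c(targets, rep(targets[length(targets)], T - 1L - length(targets)))
}

expect_normalized <- function(x, tol = 1e-8) {
  expect_true(all(x >= -tol))
  expect_equal(sum(x), 1, tolerance = tol)
}
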