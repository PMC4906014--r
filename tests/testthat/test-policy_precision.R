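test_that("expected free energy matches the brute-force oracle", {
  m <- model_default()
  set.seed(42)
  for (i in 1:100) {
    s <- epiforage:::random_beliefs(m)
    t0 <- sample(0:(m$T - 1L), 1)
    fast <- expected_free_energy(m, s, t0)
    slow <- brute_force_G(m, s, t0)
    expect_lt(abs(fast$G - slow$G), 1e-8)
  }
})

test_that("expected free energy components behave as the theory demands", {
  m <- model_default()
  set.seed(7)
  for (i in 1:20) {
    s <- epiforage:::random_beliefs(m)
    ef <- expected_free_energy(m, s, 1)
    # mutual information is nonnegative; one-hot likelihoods are unambiguous
    expect_true(all(ef$components$epistemic >= -1e-9))
    expect_true(all(abs(ef$components$ambiguity) < 1e-12))
    # decomposition: risk + ambiguity = -epistemic - extrinsic + ln Z(C)
    const <- sum(vapply(m$C, function(cv) log(sum(exp(cv))), 0))
    by_epoch <- dplyr::summarise(
      dplyr::group_by(ef$components, .data$epoch),
      lhs = sum(.data$risk + .data$ambiguity),
      rhs = sum(-.data$epistemic - .data$extrinsic) + const
    )
    expect_equal(by_epoch$lhs, by_epoch$rhs, tolerance = 1e-6)
  }
})

test_that("delta state expectations abolish epistemic value", {
  m <- model_default()
  s <- epiforage:::prior_expectations(m, rep(2L, 5))
  s$context[, ] <- rep(c(0, 1, 0), m$T)
  s$flip_lr[, ] <- rep(c(1, 0), m$T)
  s$flip_ud[, ] <- rep(c(0, 1), m$T)
  ef <- expected_free_energy(m, s, 0)
  expect_true(all(abs(ef$components$epistemic) < 1e-9))
})

test_that("with flat preferences, G ranks policies by epistemic value alone", {
  m <- build_scene_model(c = 0)
  # context uniform, reflections and location known: the unvisited quadrant
  # is informative, the known-null quadrant is not
  obs <- obs_history(scene_layout("wait", 0, 0), 5L)  # null at LR
  base <- epiforage:::prior_expectations(m, stay_policy(5L, m$T))
  base$flip_lr[, ] <- rep(c(1, 0), m$T)
  base$flip_ud[, ] <- rep(c(1, 0), m$T)
  G <- vapply(c(2L, 5L), function(a) {
    s <- base
    s$location[, 3:m$T] <- as.numeric(1:8 == a)
    ef <- expected_free_energy(m, s, 2)
    ef$G
  }, numeric(1))
  epi <- vapply(c(2L, 5L), function(a) {
    s <- base
    s$location[, 3:m$T] <- as.numeric(1:8 == a)
    sum(expected_free_energy(m, s, 2)$components$epistemic)
  }, numeric(1))
  expect_lt(G[1], G[2])        # unvisited UL beats revisiting known-null LR
  expect_gt(epi[1], epi[2])    # and precisely because it is informative
  # G ordering equals (negative) epistemic ordering under c = 0
  expect_equal(order(G), order(-epi))
})

test_that("policy posterior combines evidence and expected free energy", {
  pp <- policy_posterior(c(0, 0), c(1, 1), gamma = 1)
  expect_equal(pp$pi, c(0.5, 0.5))
  expect_equal(pp$pi0, c(0.5, 0.5))

  pp2 <- policy_posterior(c(0, 0), c(-log(3), 0), gamma = 1)
  expect_equal(pp2$pi, c(0.75, 0.25))

  # gamma -> 0: selection driven purely by accumulated evidence
  pp3 <- policy_posterior(c(0, 2), c(-5, 5), gamma = 1e-9)
  expect_equal(pp3$pi, epiforage:::softmax(-c(0, 2)), tolerance = 1e-6)
  expect_error(policy_posterior(c(0, NA), c(0, 0), 1))
})

test_that("precision update: fixed points, forced posteriors, direction", {
  # pi == pi0 is a fixed point at the prior
  up <- update_precision(pi = c(0.5, 0.5), pi0 = c(0.5, 0.5), G = c(1, 2),
                         beta_prior = 1.7)
  expect_equal(up$beta, 1.7)
  expect_equal(up$gamma, 1 / 1.7)

  # hand-computed single step with forced posteriors
  pi0 <- epiforage:::softmax(-c(0, 1))
  up2 <- update_precision(pi = c(0.9, 0.1), pi0 = pi0, G = c(0, 1),
                          beta_prior = 1)
  expect_equal(up2$beta, 1 + (0.1 - pi0[2]) * 1, tolerance = 1e-12)
  expect_equal(up2$gamma, 1 / up2$beta)
  expect_gt(up2$gamma, 1)  # observations favored the low-G policy: burst

  # observations favoring the high-G policy suppress precision
  up3 <- update_precision(pi = c(0.1, 0.9), pi0 = pi0, G = c(0, 1),
                          beta_prior = 1)
  expect_lt(up3$gamma, 1)

  # joint iteration from F converges and respects the beta floor
  up4 <- update_precision(G = c(0, 5, 10), F = c(0, 0, 0), beta_prior = 1)
  expect_gt(up4$beta, 1 / 64)
  expect_normalized(up4$pi)
  expect_normalized(up4$pi0)
  up5 <- update_precision(pi = c(1, 0), pi0 = c(0, 1), G = c(-80, 80),
                          beta_prior = 0.5)
  expect_equal(up5$beta, 1 / 64)  # clipped
})
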