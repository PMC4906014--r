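test_that("Bayesian model averaging mixes per-policy outcome predictions", {
  m <- model_default()
  # two policies predicting different locations at t + 1
  s_ur <- epiforage:::prior_expectations(m, rep(4L, 5))
  s_ul <- epiforage:::prior_expectations(m, rep(2L, 5))
  sts <- list(s_ur, s_ul)

  # delta posterior: the prediction is that policy's prediction
  p1 <- bma_next_outcome(c(1, 0), sts, m, t = 1)
  expect_equal(p1$where, as.numeric(1:8 == 4))

  # uniform posterior over disjoint one-hot locations: a 50/50 mixture
  p2 <- bma_next_outcome(c(0.5, 0.5), sts, m, t = 1)
  expect_equal(p2$where[c(4, 2)], c(0.5, 0.5))

  p3 <- bma_next_outcome(c(0.75, 0.25), sts, m, t = 1)
  expect_equal(p3$where[c(4, 2)], c(0.75, 0.25))
  expect_normalized(p3$what)
})

test_that("action selection realizes the predicted outcome", {
  m <- model_default()
  cur <- purrr::map(as.list(epiforage:::N_STATES), ~ rep(1 / .x, .x))
  names(cur) <- epiforage:::FACTORS

  # one-hot where-prediction: saccade straight there (KL = 0 in 'where')
  pred <- list(what = rep(1 / 6, 6), where = as.numeric(1:8 == 4))
  expect_equal(select_action(pred, m, cur), 4L)

  # 75/25 prediction: the more probable location wins
  pred2 <- list(what = rep(1 / 6, 6),
                where = c(0, 0.25, 0, 0.75, 0, 0, 0, 0))
  expect_equal(select_action(pred2, m, cur), 4L)
  kl <- action_kl(pred2, m, cur)
  expect_lt(kl[4], kl[2])

  # exact ties resolve to the lowest action index
  pred3 <- list(what = rep(1 / 6, 6), where = rep(1 / 8, 8))
  kl3 <- action_kl(pred3, m, cur)
  expect_equal(select_action(pred3, m, cur), which.min(kl3))
  expect_equal(which.min(kl3), match(min(kl3), kl3))
})

test_that("a flee scene at defaults is categorized correctly within 5 saccades", {
  m <- model_default()  # c = 2, beta = 1, T = 6
  tr <- run_trial(m, scene_layout("flee", 0, 0))
  expect_equal(tr$choice_label, "choose-flee")
  expect_equal(tr$feedback, "right")
  expect_lte(tr$decision_saccade, 5L)
  # trial record invariants
  expect_equal(length(tr$observations), length(tr$actions) + 1L)
  expect_true(all(tr$gamma > 0))
  expect_true(all(is.finite(tr$gamma_bins)))
})

test_that("executed actions always carry posterior mass", {
  m <- model_default()
  set.seed(5)
  for (sc in sample_scenes(3)) {
    tr <- run_trial(m, sc, seed = 9, action_mode = "sampled", trace = FALSE)
    for (t in seq_along(tr$actions)) {
      expect_gt(tr$pi[tr$actions[t], t], 0)
    }
  }
})

test_that("exploration hands over to exploitation at the choice", {
  m <- model_default()
  tr <- run_trial(m, scene_layout("feed", 1, 0), trace = FALSE)
  if (!is.na(tr$decision_saccade)) {
    t_choice <- tr$decision_saccade
    # before the choice the agent explores quadrants
    expect_true(all(tr$actions[seq_len(t_choice - 1)] <= 5))
    # at the choice epoch the chosen policy's extrinsic value dominates its
    # epistemic value: recompute the components for the executed choice
    obs <- tr$observations[seq_len(t_choice)]
    pol <- c(tr$actions[seq_len(t_choice - 1)], rep(tr$choice, m$T - t_choice))
    us <- update_states(m, obs, pol)
    ef <- expected_free_energy(m, us$expectations, t_choice)
    what <- ef$components[ef$components$modality == "what", ]
    expect_gt(sum(what$extrinsic), sum(what$epistemic))
  } else {
    fail("no choice was made in the deterministic feed trial")
  }
})

test_that("with no preferences the agent keeps exploring instead of reporting", {
  m0 <- build_scene_model(c = 0, T = 6)
  n_choice <- 0L
  set.seed(2)
  scenes <- sample_scenes(6)
  for (k in seq_along(scenes)) {
    tr <- run_trial(m0, scenes[[k]], seed = 20 + k, action_mode = "sampled",
                    trace = FALSE, stop_at_choice = TRUE)
    n_choice <- n_choice + !is.na(tr$choice)
  }
  expect_lte(n_choice, 2L)  # choices are rare without incentive
})

test_that("at default preference and precision most of 32 trials are correct", {
  m <- build_scene_model(c = 2, beta_prior = 1, T = 7)
  set.seed(11)
  scenes <- sample_scenes(32)
  correct <- logical(32)
  for (k in seq_along(scenes)) {
    tr <- run_trial(m, scenes[[k]], seed = 100 + k, max_saccades = 6,
                    action_mode = "sampled", trace = FALSE,
                    stop_at_choice = TRUE)
    correct[k] <- score_trial(tr)$correct
  }
  expect_gte(sum(correct), 29L)
})
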