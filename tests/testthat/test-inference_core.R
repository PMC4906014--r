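test_that("one uncertain factor: mean field equals exact Bayes", {
  # clamp the reflections via the priors so only the context is uncertain
  m <- model_default()
  m$D$flip_lr <- c(1, 0)
  m$D$flip_ud <- c(1, 0)

  # a bird at UR is consistent with every context: posterior stays uniform
  # and F attains the negative log evidence (= 0, evidence 1)
  sc <- scene_layout("flee", 0, 0)
  us <- update_states(m, obs_history(sc, 4L), stay_policy(4L, m$T))
  expect_equal(us$expectations$context[, 2], rep(1 / 3, 3), tolerance = 1e-6)
  expect_lt(abs(us$F), 0.02)
  expect_true(us$converged)

  # a cat at UL identifies flee; exact posterior is a delta
  us2 <- update_states(m, obs_history(sc, 2L), stay_policy(2L, m$T))
  ex <- exact_posterior(m, 2L, obs_history(sc, 2L))
  expect_equal(us2$expectations$context[, 2],
               unname(ex$marginals$context), tolerance = 1e-4)
  # F -> -ln P(o) = -ln(1/3), up to the early-stopping residue and the
  # log-floor slack on the vanishing-probability states
  expect_equal(us2$F, -log(1 / 3), tolerance = 0.05)
})

test_that("free energy upper-bounds the negative log evidence (one factor)", {
  m <- model_default()
  m$D$flip_lr <- c(1, 0)
  m$D$flip_ud <- c(1, 0)
  sc <- scene_layout("feed", 0, 0)
  obs <- obs_history(sc, 2L)  # seed at UL: only feed consistent
  pol <- stay_policy(2L, m$T)
  neg_log_ev <- -log(1 / 3)
  us <- update_states(m, obs, pol)
  # slack: the log floor caps the penalty on vanishing-probability states
  expect_gte(us$F, neg_log_ev - 0.05)
  # arbitrary (wrong) expectations can only increase F
  set.seed(1)
  for (i in 1:10) {
    s <- us$expectations
    w <- stats::runif(3)
    s$context[, 2] <- w / sum(w)
    expect_gte(free_energy(m, s, obs, pol), neg_log_ev - 1e-6)
  }
})

test_that("after seeing all four quadrants the true context dominates", {
  # the mean-field fixed point (no early stopping) against the exact delta
  m <- model_default()
  for (s in all_scenes()$scene) {
    us <- update_states(m, obs_history(s, 2:5), stay_policy(2:5, m$T),
                        max_iter = 200L, tol = 0)
    ctx <- us$expectations$context[, 5]
    expect_gte(ctx[match(s$context, c("flee", "feed", "wait"))], 0.95)
  }
})

test_that("free energy does not increase across an update epoch", {
  m <- model_default()
  set.seed(3)
  for (i in 1:6) {
    sc <- sample_scenes(1)[[1]]
    targets <- sample(2:5, sample(1:4, 1))
    us <- update_states(m, obs_history(sc, targets),
                        stay_policy(targets, m$T))
    expect_lte(us$F, us$F_trace[1] + 1e-9)
  }
})

test_that("early stopping fires exactly when the F decrease falls below 1/128", {
  m <- model_default()
  sc <- scene_layout("flee", 0, 0)
  us <- update_states(m, obs_history(sc, 2L), stay_policy(2L, m$T))
  dec <- -diff(us$F_trace)
  if (us$converged) {
    expect_lt(dec[length(dec)], 1 / 128)
    if (length(dec) > 1) expect_true(all(dec[-length(dec)] >= 1 / 128))
  } else {
    expect_equal(us$n_iter, 16L)
  }
})

test_that("expectations stay normalized and positive throughout", {
  m <- model_default()
  sc <- scene_layout("wait", 1, 0)
  us <- update_states(m, obs_history(sc, c(3L, 4L)),
                      stay_policy(c(3L, 4L), m$T), trace = TRUE)
  for (snap in us$s_trace) {
    for (f in names(snap)) {
      expect_true(all(abs(colSums(snap[[f]]) - 1) < 1e-8))
      expect_true(all(snap[[f]] >= 0))
    }
  }
})

test_that("mean-field overconfidence: wait is suppressed below the exact 1/3", {
  m <- model_default()
  sc <- scene_layout("wait", 0, 0)
  obs <- obs_history(sc, 5L)  # single null observation at LR
  ex <- exact_posterior(m, 5L, obs)
  expect_equal(unname(ex$marginals$context["wait"]), 1 / 3, tolerance = 1e-12)
  us <- update_states(m, obs, stay_policy(5L, m$T))
  p_wait_mf <- us$expectations$context[3, 2]
  expect_lt(p_wait_mf, 1 / 3)
  # KL(exact joint || product of mean-field marginals) > 0 in this scenario
  q <- us$expectations$context[, 2] %o% us$expectations$flip_lr[, 2]
  q <- as.vector(q %o% us$expectations$flip_ud[, 2])
  p <- with(ex$configs, {
    arr <- array(0, c(3, 2, 2))
    for (r in seq_along(posterior)) {
      arr[match(context[r], c("flee", "feed", "wait")),
          flip_lr[r] + 1, flip_ud[r] + 1] <- posterior[r]
    }
    as.vector(arr)
  })
  kl <- sum(p[p > 0] * (log(p[p > 0]) - log(pmax(q[p > 0], 1e-16))))
  expect_gt(kl, 0.1)
})

test_that("rejects non-normalized inputs", {
  m <- model_default()
  s <- epiforage:::prior_expectations(m, rep(2L, 5))
  s$context[1, 1] <- 2
  expect_error(update_states(m, list(obs_fixation()), rep(2L, 5), init = s),
               "normalized")
  expect_error(free_energy(m, s, list(obs_fixation()), rep(2L, 5)),
               "normalized")
})
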