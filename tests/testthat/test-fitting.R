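test_that("a pure-noise model scores n * log(2) on any log", {
  p0 <- model_params("q_learning", alpha = 0.5, beta = 0)
  expect_equal(neg_log_likelihood("q_learning", p0, random_log(20, 1)),
               20 * log(2), tolerance = 1e-12)
  log160 <- simulate_agent("q_learning",
                           model_params("q_learning", alpha = 0.3, beta = 4),
                           seed = 2)
  expect_equal(neg_log_likelihood("q_learning", p0, log160), 160 * log(2),
               tolerance = 1e-12)
})

test_that("likelihood replay matches the independent oracle on random logs, all model kinds", {
  for (kind in model_kinds()) {
    for (seed in 1:5) {
      log <- random_log(20, seed = seed * 7)
      params <- random_params(kind, seed = seed * 13, phi_too = TRUE)
      expect_equal(neg_log_likelihood(kind, params, log),
                   oracle_nll(kind, params, log),
                   tolerance = 1e-10)
      # and in the mode where no-feedback outcomes do not teach
      expect_equal(
        neg_log_likelihood(kind, params, log, update_on_no_feedback = FALSE),
        oracle_nll(kind, params, log, update_on_no_feedback = FALSE),
        tolerance = 1e-10
      )
    }
  }
})

test_that("a near-certain model drives its trial likelihood toward zero", {
  # strong perseveration: the repeat trial is predicted almost surely
  log <- random_log(1, 3)
  log2 <- rbind(log, log)
  log2$trial <- 1:2
  p <- model_params("q_learning", alpha = 0, beta = 0, phi = 5)
  nll <- neg_log_likelihood("q_learning", p, log2)
  expect_equal(nll, log(2) - log(stats::plogis(5)), tolerance = 1e-10)
})

test_that("top-up trials never influence the likelihood", {
  log <- run_session(agent_antioptimal(), seed = 17)
  expect_gt(sum(log$topup), 0)
  main <- log[!log$topup, ]
  for (kind in c("q_learning", "actor_critic_free_beta")) {
    params <- random_params(kind, seed = 5)
    expect_identical(neg_log_likelihood(kind, params, log),
                     neg_log_likelihood(kind, params, main))
  }
})

test_that("fitting beats the generating parameters, chance, and a grid search", {
  truth <- model_params("q_learning", alpha = 0.3, beta = 3)
  log <- simulate_agent("q_learning", truth, seed = 31)
  fit <- fit_subject("q_learning", log, n_restarts = 8, seed = 41)
  expect_lte(fit$negLLE, neg_log_likelihood("q_learning", truth, log))
  expect_lte(fit$negLLE, 160 * log(2) + 0.01)
  grid <- expand.grid(alpha = seq(0.02, 0.98, length.out = 15),
                      beta = seq(0.1, 12, length.out = 15))
  grid_best <- min(mapply(function(a, b) {
    neg_log_likelihood("q_learning",
                       model_params("q_learning", alpha = a, beta = b), log)
  }, grid$alpha, grid$beta))
  expect_lte(fit$negLLE, grid_best)
})

test_that("best-of-n restarts is nonincreasing in n for a fixed seed stream", {
  log <- simulate_agent("actor_only",
                        model_params("actor_only", alpha_a_plus = 0.4,
                                     alpha_a_minus = 0.2, beta = 4),
                        seed = 51)
  vals <- sapply(1:5, function(n) {
    fit_subject("actor_only", log, n_restarts = n, seed = 99,
                polish = FALSE)$negLLE
  })
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("the free-beta actor-critic fit nests the fixed-beta fit", {
  log <- simulate_agent("actor_critic_free_beta",
                        random_params("actor_critic_free_beta", 61),
                        seed = 62)
  fit_fixed <- fit_subject("actor_critic_no_beta", log, n_restarts = 4,
                           seed = 63)
  start <- c(fit_fixed$alpha_c_plus, fit_fixed$alpha_c_minus,
             fit_fixed$alpha_a_plus, fit_fixed$alpha_a_minus, 1)
  fit_free <- fit_subject("actor_critic_free_beta", log, n_restarts = 4,
                          seed = 64, extra_starts = matrix(start, nrow = 1))
  expect_lte(fit_free$negLLE, fit_fixed$negLLE + 1e-6)
})

test_that("cohort fitting maps subjects, tolerates failures, and is reproducible", {
  logs <- lapply(1:3, function(i) {
    simulate_agent("q_learning",
                   model_params("q_learning", alpha = 0.3, beta = 4),
                   seed = i, subject_id = paste0("s", i))
  })
  fits <- fit_cohort("q_learning", logs, n_restarts = 3, seed = 5)
  expect_equal(nrow(fits), 3)
  expect_equal(fits$subject_id, c("s1", "s2", "s3"))
  fits2 <- fit_cohort("q_learning", logs, n_restarts = 3, seed = 5)
  expect_equal(fits$negLLE, fits2$negLLE)
  expect_equal(nrow(fit_cohort("q_learning", list(), seed = 1)), 0)
  # a corrupt log becomes a flagged row, not an abort
  bad <- logs[[2]]
  bad$response <- "Z"
  fits3 <- fit_cohort("q_learning", list(logs[[1]], bad), n_restarts = 2,
                      seed = 6)
  expect_equal(nrow(fits3), 2)
  expect_false(fits3$converged[2])
  expect_true(is.na(fits3$negLLE[2]))
})

test_that("an empty recovery study returns empty frames", {
  rec <- recover_parameters("q_learning", function(n) {
    data.frame(alpha = runif(n), beta = runif(n, 1, 5))
  }, n_agents = 0)
  expect_equal(nrow(rec$summary), 0)
  expect_equal(nrow(rec$agents), 0)
})
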