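test_that("free-parameter counts match the model family", {
  expect_equal(model_info("q_learning")$k, 2)
  expect_equal(model_info("actor_only")$k, 3)
  expect_equal(model_info("actor_critic_no_beta")$k, 4)
  expect_equal(model_info("actor_critic_free_beta")$k, 5)
  expect_equal(model_info("q_learning", kernel = TRUE)$k, 3)
  expect_equal(model_params("actor_critic_no_beta")$beta, 1)
  expect_error(model_params("actor_critic_no_beta", beta = 3), "fixed")
  expect_error(model_params("q_learning", alpha = 1.2), "\\[0, 1\\]")
  expect_error(model_params("q_learning", beta = -1), "nonnegative")
})

test_that("prediction errors and value updates follow the defining equations", {
  st <- init_state()
  expect_equal(prediction_error_q(st, "S1", "A", 1), 1)
  st$Q["S2", "B"] <- 0.4
  expect_equal(prediction_error_q(st, "S2", "B", 0.4), 0)
  expect_equal(prediction_error_q(st, "S2", "B", -1), -1.4)

  p <- model_params("actor_only", alpha_a_plus = 0.5, alpha_a_minus = 0.2)
  st <- init_state()
  st <- q_update(st, "S1", "A", 1, p)
  expect_equal(st$Q["S1", "A"], 0.5)
  expect_equal(sum(st$Q != 0), 1)  # nothing else moved
  st$Q["S3", "B"] <- 0.5
  st <- q_update(st, "S3", "B", -1.5, p)
  expect_equal(st$Q["S3", "B"], 0.5 + 0.2 * -1.5)  # 0.2
  p0 <- model_params("q_learning", alpha = 0)
  expect_equal(q_update(init_state(), "S1", "A", 5, p0), init_state())
})

test_that("critic and actor updates share the critic's prediction error", {
  p <- model_params("actor_critic_free_beta", alpha_c_plus = 0.3,
                    alpha_c_minus = 0.1, alpha_a_plus = 0.4,
                    alpha_a_minus = 0.25)
  st <- init_state()
  cu <- critic_update(st, "S1", 1, p)
  expect_equal(cu$delta, 1)
  expect_equal(cu$state$V[["S1"]], 0.3)
  st2 <- cu$state
  cu2 <- critic_update(st2, "S1", st2$V[["S1"]], p)  # outcome equals value
  expect_equal(cu2$delta, 0)
  expect_equal(cu2$state$V, st2$V)
  st3 <- init_state(); st3$V["S2"] <- 0.3
  cu3 <- critic_update(st3, "S2", -1, p)
  expect_equal(cu3$delta, -1.3)
  expect_equal(cu3$state$V[["S2"]], 0.3 + 0.1 * -1.3)  # 0.17

  st4 <- actor_update(init_state(), "S1", "A", 1, p)
  expect_equal(st4$P["S1", "A"], 0.4)
  st5 <- init_state(); st5$P["S1", "A"] <- 0.4
  st5 <- actor_update(st5, "S1", "A", -2, p)
  expect_equal(st5$P["S1", "A"], 0.4 + 0.25 * -2)  # -0.1
  expect_error(critic_update(init_state(), "S1", 1,
                             model_params("q_learning")),
               "actor-critic")
})

test_that("softmax choice rule: symmetry, noise limit, closed form", {
  st <- init_state()
  expect_equal(choice_prob(st, "S1", model_params("q_learning", beta = 5)),
               c(A = 0.5, B = 0.5))
  st$Q["S1", "A"] <- 0.9; st$Q["S1", "B"] <- -0.7
  expect_equal(choice_prob(st, "S1", model_params("q_learning", beta = 0)),
               c(A = 0.5, B = 0.5))
  st2 <- init_state(); st2$Q["S1", "A"] <- 1
  p <- choice_prob(st2, "S1", model_params("q_learning", beta = 1))
  expect_equal(p[["A"]], 1 / (1 + exp(-1)), tolerance = 1e-12)
  # actor-critic kinds read P, not Q
  st3 <- init_state(); st3$Q["S1", "A"] <- 5; st3$P["S1", "B"] <- 1
  pac <- choice_prob(st3, "S1", model_params("actor_critic_free_beta",
                                             beta = 1))
  expect_lt(pac[["A"]], 0.5)
})

test_that("choice probabilities conserve mass on random states", {
  set.seed(42)
  for (i in 1:50) {
    st <- init_state()
    st$Q[] <- runif(8, -1, 1); st$P[] <- runif(8, -1, 1)
    st$V[] <- runif(4, -1, 1)
    s <- sample(c("S1", "S2", "S3", "S4"), 1)
    st$C[s, sample(1:2, 1)] <- 1
    kind <- sample(model_kinds(), 1)
    pr <- choice_prob(st, s, random_params(kind, seed = i), kind)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr > 0 & pr < 1))
  }
})

test_that("a step with zero prediction error only moves the choice indicator", {
  p <- model_params("q_learning", alpha = 0.7)
  st <- step_model("q_learning", init_state(), "S1", "A", 0, p)
  expect_equal(st$Q, init_state()$Q)
  expect_equal(st$C["S1", ], c(A = 1, B = 0))
  st2 <- step_model("q_learning", st, "S1", "B", 0, p)
  expect_equal(st2$C["S1", ], c(A = 0, B = 1))
})

test_that("an actor-critic step updates V and P from the same prediction error", {
  p <- model_params("actor_critic_free_beta", alpha_c_plus = 0.3,
                    alpha_a_plus = 0.4)
  st <- step_model("actor_critic_free_beta", init_state(), "S3", "B", 1, p)
  expect_equal(st$V[["S3"]], 0.3)        # alpha_c+ * delta, delta = 1
  expect_equal(st$P["S3", "B"], 0.4)     # alpha_a+ * the same delta
  expect_equal(st$C["S3", "B"], 1)
})

test_that("Q and V stay in [-1, 1] along random trajectories (convex-combination bound)", {
  set.seed(7)
  for (rep in 1:20) {
    kind <- sample(model_kinds(), 1)
    params <- random_params(kind, seed = rep * 101)
    st <- init_state()
    for (t in 1:120) {
      s <- sample(c("S1", "S2", "S3", "S4"), 1)
      a <- sample(c("A", "B"), 1)
      o <- sample(c(-1, 0, 1), 1)
      st <- step_model(kind, st, s, a, o, params)
    }
    expect_true(all(st$Q >= -1 & st$Q <= 1))
    expect_true(all(st$V >= -1 & st$V <= 1))
  }
})

test_that("valence-split update with equal rates matches the single-rate model", {
  for (seed in 1:5) {
    log <- random_log(60, seed = seed)
    a <- runif(1)
    beta <- runif(1, 0, 6)
    nll_split <- neg_log_likelihood(
      "actor_only",
      model_params("actor_only", alpha_a_plus = a, alpha_a_minus = a,
                   beta = beta), log)
    nll_single <- neg_log_likelihood(
      "q_learning", model_params("q_learning", alpha = a, beta = beta), log)
    expect_equal(nll_split, nll_single, tolerance = 1e-12)
  }
})

test_that("fixing beta to 1 nests the free-beta actor-critic", {
  for (seed in 1:5) {
    log <- random_log(60, seed = seed + 50)
    p <- random_params("actor_critic_no_beta", seed = seed)
    p_free <- model_params("actor_critic_free_beta",
                           alpha_c_plus = p$alpha_c_plus,
                           alpha_c_minus = p$alpha_c_minus,
                           alpha_a_plus = p$alpha_a_plus,
                           alpha_a_minus = p$alpha_a_minus, beta = 1)
    expect_equal(neg_log_likelihood("actor_critic_no_beta", p, log),
                 neg_log_likelihood("actor_critic_free_beta", p_free, log),
                 tolerance = 1e-12)
  }
})

test_that("positive perseveration favors repeating the previous choice even with beta = 0", {
  p <- model_params("q_learning", alpha = 0.5, beta = 0, phi = 1.5)
  st <- step_model("q_learning", init_state(), "S1", "A", 1, p)
  pr <- choice_prob(st, "S1", p)
  expect_gt(pr[["A"]], 0.5)
  st2 <- step_model("q_learning", st, "S1", "B", -1, p)
  pr2 <- choice_prob(st2, "S1", p)
  expect_gt(pr2[["B"]], 0.5)
})

test_that("simulated agents are reproducible and respect the noise limit", {
  p <- model_params("q_learning", alpha = 0.4, beta = 3)
  expect_identical(simulate_agent("q_learning", p, seed = 8),
                   simulate_agent("q_learning", p, seed = 8))
  p0 <- model_params("q_learning", alpha = 0.4, beta = 0)
  log <- simulate_agent("q_learning", p0, seed = 9)
  # chance responding: A-rate within binomial error over 160 trials
  expect_lt(abs(mean(log$response == "A") - 0.5), 4 * sqrt(0.25 / 160))
})

test_that("a deterministic enough learner improves across blocks", {
  p <- model_params("actor_only", alpha_a_plus = 0.5, alpha_a_minus = 0.5,
                    beta = 8)
  rates <- sapply(1:60, function(s) {
    log <- simulate_agent("actor_only", p, seed = s)
    c(first = mean(log$optimal[log$block == 1]),
      last = mean(log$optimal[log$block == 4]))
  })
  expect_gt(mean(rates["last", ]) - mean(rates["first", ]), 0.1)
})
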