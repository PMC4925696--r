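# Independent likelihood oracle: a plain, slow, trial-by-trial replay using
# named-list bookkeeping and the defining equations written out directly.
# Shares no code with the package internals.
oracle_nll <- function(kind, params, log, update_on_no_feedback = TRUE) {
  actor_critic <- kind %in% c("actor_critic_no_beta", "actor_critic_free_beta")
  vals <- list()
  for (s in c("S1", "S2", "S3", "S4"))
    vals[[s]] <- list(Q = c(A = 0, B = 0), V = 0, P = c(A = 0, B = 0),
                      last = NA_character_)
  total <- 0
  rows <- log[!log$topup, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    s <- rows$stimulus[i]
    ch <- rows$response[i]
    o <- sign(rows$feedback_points[i])
    v <- vals[[s]]
    x <- if (actor_critic) v$P else v$Q
    kA <- if (identical(v$last, "A")) 1 else 0
    kB <- if (identical(v$last, "B")) 1 else 0
    pA <- 1 / (1 + exp(-(params$beta * (x[["A"]] - x[["B"]]) +
                           params$phi * (kA - kB))))
    total <- total - log(if (ch == "A") pA else 1 - pA)
    if (update_on_no_feedback || o != 0) {
      if (kind == "q_learning") {
        d <- o - v$Q[[ch]]
        v$Q[[ch]] <- v$Q[[ch]] + params$alpha * d
      } else if (kind == "actor_only") {
        d <- o - v$Q[[ch]]
        rate <- if (d > 0) params$alpha_a_plus else params$alpha_a_minus
        v$Q[[ch]] <- v$Q[[ch]] + rate * d
      } else {
        d <- o - v$V
        crate <- if (d > 0) params$alpha_c_plus else params$alpha_c_minus
        arate <- if (d > 0) params$alpha_a_plus else params$alpha_a_minus
        v$V <- v$V + crate * d
        v$P[[ch]] <- v$P[[ch]] + arate * d
      }
    }
    v$last <- ch
    vals[[s]] <- v
  }
  total
}

# Hand-rolled random log: random stimuli/categories/responses with feedback
# following the task's matrix, built without the package's session machinery.
random_log <- function(n_trials, seed, subject_id = "rnd") {
  set.seed(seed)
  stims <- c("S1", "S2", "S3", "S4")
  valence <- c(S1 = "positive", S2 = "positive",
               S3 = "negative", S4 = "negative")
  common <- c(S1 = "A", S2 = "B", S3 = "A", S4 = "B")
  s <- sample(stims, n_trials, replace = TRUE)
  cc <- ifelse(runif(n_trials) < 0.8, common[s],
               ifelse(common[s] == "A", "B", "A"))
  r <- sample(c("A", "B"), n_trials, replace = TRUE)
  fb <- ifelse(valence[s] == "positive" & r == cc, 25,
               ifelse(valence[s] == "negative" & r != cc, -25, 0))
  data.frame(
    subject_id = subject_id, group = "HC",
    block = rep(1L, n_trials), trial = seq_len(n_trials),
    stimulus = s, valence = unname(valence[s]), correct_category = cc,
    response = r, feedback_points = fb,
    optimal = r == unname(common[s]), topup = FALSE
  )
}

# Random in-bounds parameter set for a model kind.
random_params <- function(kind, seed, phi_too = FALSE) {
  set.seed(seed)
  model_params(
    kind,
    alpha = runif(1), alpha_a_plus = runif(1), alpha_a_minus = runif(1),
    alpha_c_plus = runif(1), alpha_c_minus = runif(1),
    beta = if (kind == "actor_critic_no_beta") 1 else runif(1, 0, 8),
    phi = if (phi_too) runif(1, -2, 2) else 0
  )
}
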