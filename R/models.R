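# Trial-by-trial learning models: Q-learning (one learning rate), a
# valence-split actor-only learner, and actor-critic variants in which a
# critic learns stimulus values V and broadcasts its prediction error to an
# actor learning action preferences P. All models share a two-option softmax
# choice rule with noise parameter beta and perseveration (choice-kernel)
# parameter phi. Outcomes are coded o = sign(feedback points) in {-1, 0, +1};
# beta absorbs the point scale.

.stimuli <- c("S1", "S2", "S3", "S4")
.actions <- c("A", "B")

#' The model family
#'
#' Four model kinds are supported:
#' \describe{
#'   \item{`q_learning`}{one learning rate `alpha` applied to both prediction
#'     error signs, on stimulus-action values; 2 free parameters
#'     (`alpha`, `beta`).}
#'   \item{`actor_only`}{valence-split learning directly on stimulus-action
#'     values (no critic); 3 free parameters (`alpha_a_plus`,
#'     `alpha_a_minus`, `beta`).}
#'   \item{`actor_critic_no_beta`}{actor-critic with the softmax noise fixed
#'     at `beta = 1`; 4 free parameters (`alpha_c_plus`, `alpha_c_minus`,
#'     `alpha_a_plus`, `alpha_a_minus`).}
#'   \item{`actor_critic_free_beta`}{the full actor-critic; 5 free parameters
#'     (the four learning rates plus `beta`).}
#' }
#' The perseveration weight `phi` defaults to 0 and is not free; passing
#' `kernel = TRUE` to [model_info()] adds it to the free set as a
#' choice-kernel variant of any model.
#'
#' @return `model_kinds()` returns the four kind names.
#' @export
model_kinds <- function() {
  c("q_learning", "actor_only", "actor_critic_no_beta",
    "actor_critic_free_beta")
}

#' @rdname model_kinds
#' @param kind One of [model_kinds()].
#' @param kernel Free the perseveration weight `phi` as an extra parameter?
#' @return `model_info()` returns a list with elements `kind`, `free`
#'   (ordered free-parameter names), `k` (their count) and `actor_critic`
#'   (does the choice rule read actor preferences P rather than Q?).
#' @export
model_info <- function(kind = model_kinds(), kernel = FALSE) {
  kind <- match.arg(kind)
  free <- switch(kind,
    q_learning             = c("alpha", "beta"),
    actor_only             = c("alpha_a_plus", "alpha_a_minus", "beta"),
    actor_critic_no_beta   = c("alpha_c_plus", "alpha_c_minus",
                               "alpha_a_plus", "alpha_a_minus"),
    actor_critic_free_beta = c("alpha_c_plus", "alpha_c_minus",
                               "alpha_a_plus", "alpha_a_minus", "beta")
  )
  if (kernel) free <- c(free, "phi")
  list(kind = kind, free = free, k = length(free),
       actor_critic = kind %in% c("actor_critic_no_beta",
                                  "actor_critic_free_beta"))
}

#' Model parameters
#'
#' Builds a complete, validated parameter set for any model kind. Learning
#' rates live in \[0, 1\]; `beta >= 0` (fixed at 1 for
#' `actor_critic_no_beta`); `phi` is any real, defaulting to 0 (no
#' perseveration).
#'
#' @param kind One of [model_kinds()].
#' @param ... Named parameter values among `alpha`, `alpha_a_plus`,
#'   `alpha_a_minus`, `alpha_c_plus`, `alpha_c_minus`, `beta`, `phi`.
#' @return A named list of class `"model_params"` containing every parameter
#'   (with the model's fixed or default values filled in).
#' @export
#' @examples
#' model_params("q_learning", alpha = 0.3, beta = 3)
model_params <- function(kind = model_kinds(), ...) {
  kind <- match.arg(kind)
  defaults <- list(alpha = 0.1, alpha_a_plus = 0.1, alpha_a_minus = 0.1,
                   alpha_c_plus = 0.1, alpha_c_minus = 0.1, beta = 1,
                   phi = 0)
  supplied <- list(...)
  unknown <- setdiff(names(supplied), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p <- utils::modifyList(defaults, supplied)
  if (kind == "actor_critic_no_beta") {
    if (!is.null(supplied$beta) && supplied$beta != 1)
      stop("`beta` is fixed at 1 for actor_critic_no_beta", call. = FALSE)
    p$beta <- 1
  }
  rates <- c("alpha", "alpha_a_plus", "alpha_a_minus",
             "alpha_c_plus", "alpha_c_minus")
  for (r in rates)
    if (p[[r]] < 0 || p[[r]] > 1)
      stop("learning rate `", r, "` must lie in [0, 1]", call. = FALSE)
  if (p$beta < 0) stop("`beta` must be nonnegative", call. = FALSE)
  p$kind <- kind
  class(p) <- "model_params"
  p
}

# Full parameter list from a vector of free-parameter values.
params_from_free <- function(kind, x, kernel = FALSE) {
  info <- model_info(kind, kernel = kernel)
  stopifnot(length(x) == info$k)
  do.call(model_params, c(list(kind = kind),
                          stats::setNames(as.list(x), info$free)))
}

#' Fresh model state
#'
#' Q (stimulus-action values), V (critic stimulus values), P (actor
#' preferences) all start at zero; C (the last-choice indicator feeding the
#' perseveration term) starts all-zero and after a stimulus's first
#' presentation carries a single 1 marking the previous response to it.
#'
#' @return A list with matrices `Q`, `P`, `C` (4 stimuli by 2 actions) and
#'   vector `V` (length 4).
#' @export
init_state <- function() {
  m <- matrix(0, 4, 2, dimnames = list(.stimuli, .actions))
  list(Q = m, V = stats::setNames(numeric(4), .stimuli), P = m, C = m)
}

as_outcome <- function(feedback_points) sign(feedback_points)

stim_index <- function(stimulus) {
  i <- match(stimulus, .stimuli)
  if (anyNA(i)) stop("unknown stimulus id", call. = FALSE)
  i
}

action_index <- function(action) {
  i <- match(action, .actions)
  if (anyNA(i)) stop("action must be \"A\" or \"B\"", call. = FALSE)
  i
}

#' Prediction error on stimulus-action values
#'
#' For Q-learning and the actor-only model the prediction error is the
#' discrepancy between the coded outcome and the value of the presented
#' stimulus paired with the chosen action:
#' `delta = o - Q(s, chosen action)`.
#'
#' @param state A model state from [init_state()].
#' @param stimulus Stimulus id.
#' @param action The chosen action, `"A"` or `"B"`.
#' @param outcome Coded outcome in `{-1, 0, +1}`.
#' @return The scalar prediction error.
#' @export
prediction_error_q <- function(state, stimulus, action, outcome) {
  outcome - state$Q[stim_index(stimulus), action_index(action)]
}

#' Valence-split update of stimulus-action values
#'
#' Increments the chosen action's Q by `alpha_plus * delta` when `delta > 0`
#' and `alpha_minus * delta` when `delta < 0`; for `q_learning` a single
#' `alpha` plays both roles. Other actions and stimuli are untouched, and a
#' zero prediction error leaves the state unchanged.
#'
#' @inheritParams prediction_error_q
#' @param delta Prediction error for the chosen action.
#' @param params A [model_params()] object.
#' @param kind The model kind (determines whether the single-rate or
#'   valence-split rule applies).
#' @return The updated state.
#' @export
q_update <- function(state, stimulus, action, delta, params,
                     kind = params$kind) {
  s <- stim_index(stimulus); a <- action_index(action)
  rate <- if (kind == "q_learning") params$alpha
          else if (delta > 0) params$alpha_a_plus else params$alpha_a_minus
  state$Q[s, a] <- state$Q[s, a] + rate * delta
  state
}

#' Critic update (actor-critic models)
#'
#' The critic's prediction error is `delta = o - V(s)`, i.e. relative to the
#' stimulus value independent of the chosen action; V is then incremented by
#' `alpha_c_plus * delta` if `delta > 0`, `alpha_c_minus * delta` if
#' `delta < 0`. The same `delta` is returned for the actor.
#'
#' @inheritParams q_update
#' @param outcome Coded outcome in `{-1, 0, +1}`.
#' @return A list with the updated `state` and the critic's `delta`.
#' @export
critic_update <- function(state, stimulus, outcome, params) {
  if (!params$kind %in% c("actor_critic_no_beta", "actor_critic_free_beta"))
    stop("critic_update() applies to actor-critic models only", call. = FALSE)
  s <- stim_index(stimulus)
  delta <- outcome - state$V[[s]]
  rate <- if (delta > 0) params$alpha_c_plus else params$alpha_c_minus
  state$V[s] <- state$V[s] + rate * delta
  list(state = state, delta = delta)
}

#' Actor update (actor-critic models)
#'
#' The critic's prediction error is conveyed to the actor, which increments
#' its preference for the selected choice by `alpha_a_plus * delta`
#' (`delta > 0`) or `alpha_a_minus * delta` (`delta < 0`).
#'
#' @inheritParams q_update
#' @param choice The chosen action.
#' @return The updated state.
#' @export
actor_update <- function(state, stimulus, choice, delta, params) {
  s <- stim_index(stimulus); a <- action_index(choice)
  rate <- if (delta > 0) params$alpha_a_plus else params$alpha_a_minus
  state$P[s, a] <- state$P[s, a] + rate * delta
  state
}

#' Softmax choice probabilities with perseveration
#'
#' `pA = 1 / (1 + exp(-beta * (xA - xB) - phi * (C(s,A) - C(s,B))))` where
#' `x` is the stimulus-action value Q for `q_learning` and `actor_only`, and
#' the actor preference P for the actor-critic kinds. `beta = 0` with
#' `phi = 0` gives chance responding; `phi > 0` biases toward repeating the
#' previous response to the same stimulus, `phi < 0` toward switching.
#'
#' @inheritParams q_update
#' @return Named numeric vector `c(A = pA, B = pB)`, strictly inside (0, 1)
#'   and summing to 1.
#' @export
#' @examples
#' st <- init_state(); st$Q["S1", "A"] <- 1
#' choice_prob(st, "S1", model_params("q_learning", beta = 1))
choice_prob <- function(state, stimulus, params, kind = params$kind) {
  s <- stim_index(stimulus)
  x <- if (model_info(kind)$actor_critic) state$P[s, ] else state$Q[s, ]
  z <- params$beta * (x[[1]] - x[[2]]) +
    params$phi * (state$C[s, 1] - state$C[s, 2])
  pA <- stats::plogis(z)
  c(A = pA, B = 1 - pA)
}

#' One learning step
#'
#' Applies the model-appropriate update chain for an observed
#' (stimulus, action, outcome) triple — critic then actor for the
#' actor-critic kinds, the single-rate Q rule for `q_learning`, the
#' valence-split Q rule for `actor_only` — then records the choice in the
#' last-choice indicator C.
#'
#' @inheritParams q_update
#' @param outcome Coded outcome in `{-1, 0, +1}`; use
#'   `sign(feedback_points)`.
#' @param update_values If `FALSE`, value updates are skipped (the
#'   `update_on_no_feedback = FALSE` replay mode uses this for o = 0 trials);
#'   the choice indicator is always updated.
#' @return The updated state.
#' @export
step_model <- function(kind, state, stimulus, action, outcome, params,
                       update_values = TRUE) {
  kind <- match.arg(kind, model_kinds())
  s <- stim_index(stimulus); a <- action_index(action)
  if (update_values) {
    if (model_info(kind)$actor_critic) {
      cu <- critic_update(state, stimulus, outcome, params)
      state <- actor_update(cu$state, stimulus, action, cu$delta, params)
    } else {
      delta <- prediction_error_q(state, stimulus, action, outcome)
      state <- q_update(state, stimulus, action, delta, params, kind)
    }
  }
  state$C[s, ] <- 0
  state$C[s, a] <- 1
  state
}

#' Simulate a model agent over a trial schedule
#'
#' At each trial the response is sampled from [choice_prob()], feedback is
#' delivered by [feedback_for()], and the state is updated by [step_model()].
#' Deterministic given `seed`.
#'
#' @param kind One of [model_kinds()].
#' @param params A [model_params()] object.
#' @param schedule A schedule from [generate_session_schedule()]; generated
#'   fresh (from the same seed stream) when `NULL`.
#' @param seed Optional integer seed.
#' @param config A [session_config()].
#' @param update_on_no_feedback Should no-feedback outcomes (o = 0) drive
#'   value updates? Default `TRUE`: the ambiguous outcome is treated as a
#'   zero-valued one, so `delta = 0 - value`.
#' @param subject_id,group Metadata for the emitted log.
#' @return A `"session_log"` data frame (no top-up trials; see [run_session()]
#'   with [rl_agent()] for full sessions including the top-up rule).
#' @export
simulate_agent <- function(kind, params, schedule = NULL, seed = NULL,
                           config = session_config(),
                           update_on_no_feedback = TRUE,
                           subject_id = "sim", group = "HC") {
  kind <- match.arg(kind, model_kinds())
  with_seed(seed, {
    if (is.null(schedule)) schedule <- generate_session_schedule(config)
    stims <- stimulus_set()
    state <- init_state()
    n <- nrow(schedule)
    response <- character(n)
    feedback <- numeric(n)
    for (t in seq_len(n)) {
      st <- schedule$stimulus[t]
      p <- choice_prob(state, st, params, kind)
      r <- if (stats::runif(1) < p[["A"]]) "A" else "B"
      fb <- feedback_for(st, r, schedule$correct_category[t], config)
      state <- step_model(kind, state, st, r, as_outcome(fb), params,
                          update_values = update_on_no_feedback || fb != 0)
      response[t] <- r
      feedback[t] <- fb
    }
    log <- data.frame(
      subject_id = subject_id, group = group,
      block = schedule$block, trial = schedule$trial,
      stimulus = schedule$stimulus,
      valence = stims$valence[match(schedule$stimulus, stims$stimulus)],
      correct_category = schedule$correct_category,
      response = response, feedback_points = feedback,
      optimal = response ==
        stims$common_category[match(schedule$stimulus, stims$stimulus)],
      topup = FALSE
    )
    structure(log, final_points = config$start_points + sum(feedback),
              class = c("session_log", "data.frame"))
  })
}

#' A learning agent for [run_session()]
#'
#' Wraps a model kind and parameter set as a stateful agent: `choose()`
#' samples from the softmax, `learn()` applies [step_model()] with the coded
#' outcome. Top-up trials do not reach `learn()` (they are post-task filler
#' with forced outcomes).
#'
#' @inheritParams simulate_agent
#' @return An agent list with `choose` and `learn` functions.
#' @export
rl_agent <- function(kind, params, update_on_no_feedback = TRUE) {
  kind <- match.arg(kind, model_kinds())
  state <- init_state()
  list(
    choose = function(stimulus) {
      p <- choice_prob(state, stimulus, params, kind)
      if (stats::runif(1) < p[["A"]]) "A" else "B"
    },
    learn = function(stimulus, response, feedback_points) {
      o <- as_outcome(feedback_points)
      state <<- step_model(kind, state, stimulus, response, o, params,
                           update_values = update_on_no_feedback ||
                             feedback_points != 0)
    }
  )
}
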