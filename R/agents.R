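# Simple reference agents for run_session(). Each agent is a list with a
# choose(stimulus) function and an optional learn(stimulus, response,
# feedback_points) function; rl_agent() in models.R provides the learning
# agents.

#' Reference agents for task simulation
#'
#' `agent_optimal()` always picks the stimulus's common category;
#' `agent_antioptimal()` always picks the rare one (the pessimal policy, useful
#' for exercising the top-up rule); `agent_random()` picks uniformly at random
#' from R's RNG; `agent_constant()` always presses the same key.
#'
#' @param response For `agent_constant()`, the fixed response, `"A"` or `"B"`.
#' @return An agent list usable with [run_session()].
#' @export
agent_optimal <- function() {
  common <- stats::setNames(stimulus_set()$common_category,
                            stimulus_set()$stimulus)
  list(choose = function(stimulus) unname(common[[stimulus]]))
}

#' @rdname agent_optimal
#' @export
agent_antioptimal <- function() {
  common <- stats::setNames(stimulus_set()$common_category,
                            stimulus_set()$stimulus)
  list(choose = function(stimulus) {
    if (common[[stimulus]] == "A") "B" else "A"
  })
}

#' @rdname agent_optimal
#' @export
agent_random <- function() {
  list(choose = function(stimulus) sample(c("A", "B"), 1L))
}

#' @rdname agent_optimal
#' @export
agent_constant <- function(response = "A") {
  stopifnot(response %in% c("A", "B"))
  list(choose = function(stimulus) response)
}
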