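# Task design: the probabilistic classification task with valence-split
# feedback. Four stimuli; two (S1, S2) trained with reward (+25 for correct,
# nothing otherwise), two (S3, S4) with punishment (-25 for incorrect,
# nothing otherwise). Category contingencies are 80/20.

#' The four-stimulus set of the valence-split classification task
#'
#' S1 and S2 belong to the positive-feedback (reward) task, S3 and S4 to the
#' negative-feedback (punishment) task. S1 and S3 belong to category A with
#' probability 0.8, S2 and S4 to category B with probability 0.8.
#'
#' @return A data frame with one row per stimulus and columns `stimulus`,
#'   `valence` (`"positive"` or `"negative"`), `common_category` (`"A"` or
#'   `"B"`) and `p_common` (0.8).
#' @export
#' @examples
#' stimulus_set()
stimulus_set <- function() {
  data.frame(
    stimulus        = c("S1", "S2", "S3", "S4"),
    valence         = c("positive", "positive", "negative", "negative"),
    common_category = c("A", "B", "A", "B"),
    p_common        = 0.8
  )
}

#' Session configuration for the classification task
#'
#' Defaults reproduce the administered task: 4 blocks in which each of the 4
#' stimuli appears 10 times (8 with its common category, 2 with the rare one),
#' i.e. 160 main trials; feedback of +25/-25 points; a starting tally of 500
#' points; and a post-task top-up rule that appends forced-correct trials when
#' the final tally is below 500 until it reaches at least 525.
#'
#' @param n_blocks Number of blocks.
#' @param reps_per_stimulus Presentations of each stimulus per block.
#' @param common_reps How many of those presentations carry the stimulus's
#'   common category. Must not exceed `reps_per_stimulus`.
#' @param reward_points Points won on a correct response to a positive-valence
#'   stimulus.
#' @param punishment_points Points lost (negative number) on an incorrect
#'   response to a negative-valence stimulus.
#' @param start_points Tally at the start of the session.
#' @param topup_floor Tally below which top-up trials are triggered after the
#'   main trials.
#' @param topup_target Tally that top-up trials must reach before stopping.
#' @return A list of class `"session_config"`.
#' @export
session_config <- function(n_blocks = 4L, reps_per_stimulus = 10L,
                           common_reps = 8L, reward_points = 25,
                           punishment_points = -25, start_points = 500,
                           topup_floor = 500, topup_target = 525) {
  n_blocks <- as.integer(n_blocks)
  reps_per_stimulus <- as.integer(reps_per_stimulus)
  common_reps <- as.integer(common_reps)
  if (n_blocks < 1L || reps_per_stimulus < 1L || common_reps < 0L)
    stop("block and repetition counts must be positive", call. = FALSE)
  if (common_reps > reps_per_stimulus)
    stop("`common_reps` cannot exceed `reps_per_stimulus`", call. = FALSE)
  if (reward_points <= 0 || punishment_points >= 0)
    stop("`reward_points` must be positive and `punishment_points` negative",
         call. = FALSE)
  structure(
    list(n_blocks = n_blocks, reps_per_stimulus = reps_per_stimulus,
         common_reps = common_reps, reward_points = reward_points,
         punishment_points = punishment_points, start_points = start_points,
         topup_floor = topup_floor, topup_target = topup_target),
    class = "session_config"
  )
}

#' Generate the trial composition of one block
#'
#' Each stimulus appears `reps_per_stimulus` times; exactly `common_reps` of
#' those presentations carry the stimulus's common category and the remainder
#' the rare one. Composition is exact (deterministic counts, not i.i.d.
#' sampling); trial order is a uniform shuffle drawn from the current RNG
#' state, so wrap calls in [set.seed()] for reproducibility.
#'
#' @param config A [session_config()].
#' @return A data frame with columns `stimulus` and `correct_category`, one
#'   row per trial (40 rows under defaults).
#' @export
generate_block <- function(config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  stims <- stimulus_set()
  rare <- ifelse(stims$common_category == "A", "B", "A")
  n_rare <- config$reps_per_stimulus - config$common_reps
  stimulus <- rep(stims$stimulus, each = config$reps_per_stimulus)
  correct <- unlist(Map(
    function(common, rar) c(rep(common, config$common_reps), rep(rar, n_rare)),
    stims$common_category, rare
  ), use.names = FALSE)
  ord <- sample.int(length(stimulus))
  data.frame(stimulus = stimulus[ord], correct_category = correct[ord])
}

#' Generate a full session schedule (all blocks, no responses yet)
#'
#' @param config A [session_config()].
#' @param seed Optional integer seed; when supplied the schedule is a pure
#'   function of it (the caller's RNG state is left untouched).
#' @return A data frame with columns `block`, `trial` (1-based within the
#'   session), `stimulus`, `correct_category`.
#' @export
generate_session_schedule <- function(config = session_config(), seed = NULL) {
  run <- function() {
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      cbind(block = b, generate_block(config))
    })
    out <- do.call(rbind, blocks)
    out$trial <- seq_len(nrow(out))
    out[, c("block", "trial", "stimulus", "correct_category")]
  }
  with_seed(seed, run())
}

#' Feedback points for one trial
#'
#' Implements the task's feedback matrix: a correct response to a
#' positive-valence stimulus wins `reward_points`; an incorrect response to a
#' negative-valence stimulus loses points; every other outcome gives no
#' feedback (0 points), and the no-feedback outcome is observationally
#' identical across valences.
#'
#' @param stimulus Stimulus id(s), `"S1"`..`"S4"`.
#' @param response Response(s), `"A"` or `"B"`.
#' @param correct_category The category sampled for the trial, `"A"` or `"B"`.
#' @param config A [session_config()] supplying the point values.
#' @return Numeric vector of feedback points in
#'   `{reward_points, 0, punishment_points}`.
#' @export
#' @examples
#' feedback_for("S1", "A", "A")  # correct, positive valence: +25
#' feedback_for("S3", "A", "A")  # correct, negative valence: no feedback
#' feedback_for("S4", "A", "B")  # incorrect, negative valence: -25
feedback_for <- function(stimulus, response, correct_category,
                         config = session_config()) {
  stims <- stimulus_set()
  idx <- match(stimulus, stims$stimulus)
  if (anyNA(idx)) stop("unknown stimulus id", call. = FALSE)
  if (!all(response %in% c("A", "B")) ||
      !all(correct_category %in% c("A", "B")))
    stop("responses and categories must be \"A\" or \"B\"", call. = FALSE)
  valence <- stims$valence[idx]
  correct <- response == correct_category
  ifelse(valence == "positive" & correct, config$reward_points,
         ifelse(valence == "negative" & !correct, config$punishment_points, 0))
}

#' Play one session of the task against an agent
#'
#' Generates the block schedule, queries the agent for a response on every
#' trial, delivers feedback, and accumulates the point tally from
#' `start_points`. If the tally after the main trials is below `topup_floor`,
#' top-up trials are appended: the agent is still shown a stimulus but its
#' response is taken as correct and +25 points are awarded, until the tally
#' reaches `topup_target`. Top-up trials are flagged `topup = TRUE` and are
#' excluded from all model fitting and behavioral metrics. The `optimal` flag
#' records whether the response matched the stimulus's common category,
#' regardless of the sampled outcome.
#'
#' @param agent An agent as returned by [agent_optimal()], [rl_agent()], etc.:
#'   a list with a `choose(stimulus)` function returning `"A"` or `"B"` and an
#'   optional `learn(stimulus, response, feedback_points)` function called
#'   after each main trial.
#' @param config A [session_config()].
#' @param seed Optional integer seed making the whole session (schedule and
#'   any agent sampling that uses R's RNG) reproducible.
#' @param subject_id,group Metadata stamped on every trial row.
#' @return A data frame of class `"session_log"` with one row per trial and
#'   columns `subject_id`, `group`, `block`, `trial`, `stimulus`, `valence`,
#'   `correct_category`, `response`, `feedback_points`, `optimal`, `topup`.
#'   The final tally is attached as attribute `"final_points"` (see
#'   [final_points()]).
#' @export
run_session <- function(agent, config = session_config(), seed = NULL,
                        subject_id = "s1", group = "HC") {
  stopifnot(is.list(agent), is.function(agent$choose))
  with_seed(seed, {
    sched <- local({
      blocks <- lapply(seq_len(config$n_blocks), function(b) {
        cbind(block = b, generate_block(config))
      })
      out <- do.call(rbind, blocks)
      out$trial <- seq_len(nrow(out))
      out
    })
    stims <- stimulus_set()
    n <- nrow(sched)
    response <- character(n)
    feedback <- numeric(n)
    for (t in seq_len(n)) {
      st <- sched$stimulus[t]
      r <- agent$choose(st)
      if (!is.character(r) || length(r) != 1L || !r %in% c("A", "B"))
        stop("agent returned an invalid response: must be \"A\" or \"B\"",
             call. = FALSE)
      fb <- feedback_for(st, r, sched$correct_category[t], config)
      if (is.function(agent$learn)) agent$learn(st, r, fb)
      response[t] <- r
      feedback[t] <- fb
    }
    tally <- config$start_points + sum(feedback)
    log <- data.frame(
      subject_id = subject_id, group = group,
      block = sched$block, trial = sched$trial, stimulus = sched$stimulus,
      valence = stims$valence[match(sched$stimulus, stims$stimulus)],
      correct_category = sched$correct_category,
      response = response, feedback_points = feedback,
      optimal = response ==
        stims$common_category[match(sched$stimulus, stims$stimulus)],
      topup = FALSE
    )
    if (tally < config$topup_floor) {
      extra <- list()
      t <- n
      while (tally < config$topup_target) {
        t <- t + 1L
        st <- sample(stims$stimulus, 1L)
        # response taken as correct; reward awarded so the tally can rise
        agent$choose(st)
        i <- match(st, stims$stimulus)
        tally <- tally + config$reward_points
        extra[[length(extra) + 1L]] <- data.frame(
          subject_id = subject_id, group = group,
          block = config$n_blocks, trial = t, stimulus = st,
          valence = stims$valence[i],
          correct_category = stims$common_category[i],
          response = stims$common_category[i],
          feedback_points = config$reward_points,
          optimal = TRUE, topup = TRUE
        )
      }
      log <- rbind(log, do.call(rbind, extra))
    }
    structure(log, final_points = tally,
              class = c("session_log", "data.frame"))
  })
}

#' Final point tally of a session
#'
#' @param log A session log from [run_session()] or [simulate_agent()].
#' @return The tally after all trials, including any top-up trials.
#' @export
final_points <- function(log) {
  fp <- attr(log, "final_points")
  if (is.null(fp)) stop("not a session log with a recorded tally",
                        call. = FALSE)
  fp
}

#' Write / read a session log as CSV
#'
#' One row per trial with the standard columns; the final tally is
#' reconstructed on read from the start points plus accumulated feedback.
#'
#' @param log A session log.
#' @param path File path.
#' @param config A [session_config()] used to reconstruct the tally on read.
#' @return `read_session_log()` returns a `"session_log"` data frame;
#'   `write_session_log()` returns `path` invisibly.
#' @export
write_session_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path, config = session_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "block", "trial", "stimulus", "valence",
              "correct_category", "response", "feedback_points", "optimal",
              "topup")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("session log is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$optimal <- as.logical(df$optimal)
  df$topup <- as.logical(df$topup)
  structure(df,
            final_points = config$start_points + sum(df$feedback_points),
            class = c("session_log", "data.frame"))
}

# Evaluate `expr` under a temporary RNG state when `seed` is given, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
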