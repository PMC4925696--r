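# Per-subject maximum-likelihood fitting. The likelihood replays a session
# log under teacher forcing: the model state is advanced with the subject's
# actual responses and observed feedback, and negLLE accumulates -log of the
# probability assigned to each observed response. Optimization is bounded
# multi-restart L-BFGS-B with a Nelder-Mead polish of the best restart.

# Integer codes for the replay loop's dispatch.
kind_code <- function(kind) {
  match(kind, c("q_learning", "actor_only",
                "actor_critic_no_beta", "actor_critic_free_beta"))
}

# Compact representation of a log for repeated likelihood evaluation.
encode_log <- function(log) {
  if (!all(c("stimulus", "response", "feedback_points", "topup") %in%
           names(log)))
    stop("not a session log", call. = FALSE)
  keep <- !log$topup
  stim <- match(log$stimulus[keep], .stimuli)
  act <- match(log$response[keep], .actions)
  if (anyNA(stim) || anyNA(act))
    stop("log contains invalid stimulus or response codes", call. = FALSE)
  list(stim = stim, act = act, out = sign(log$feedback_points[keep]))
}

# Scalar-state replay, kept free of per-trial allocation for speed.
nll_replay <- function(code, stim, act, out, alpha, aap, aam, acp, acm,
                       beta, phi, upd_no_fb) {
  Q <- matrix(0, 4, 2)
  V <- numeric(4)
  P <- matrix(0, 4, 2)
  K <- matrix(0, 4, 2)
  nll <- 0
  for (t in seq_along(stim)) {
    s <- stim[t]; a <- act[t]; o <- out[t]
    if (code <= 2L) {
      dx <- Q[s, 1L] - Q[s, 2L]
    } else {
      dx <- P[s, 1L] - P[s, 2L]
    }
    z <- beta * dx + phi * (K[s, 1L] - K[s, 2L])
    if (a == 2L) z <- -z
    nll <- nll + log1p(exp(-abs(z))) + max(-z, 0)  # -log(plogis(z)), stable
    if (upd_no_fb || o != 0) {
      if (code == 1L) {
        d <- o - Q[s, a]
        Q[s, a] <- Q[s, a] + alpha * d
      } else if (code == 2L) {
        d <- o - Q[s, a]
        Q[s, a] <- Q[s, a] + (if (d > 0) aap else aam) * d
      } else {
        d <- o - V[s]
        V[s] <- V[s] + (if (d > 0) acp else acm) * d
        P[s, a] <- P[s, a] + (if (d > 0) aap else aam) * d
      }
    }
    K[s, 1L] <- 0; K[s, 2L] <- 0; K[s, a] <- 1
  }
  nll
}

#' Negative log-likelihood of a session log under a model
#'
#' Replays the log trial by trial under teacher forcing and accumulates
#' `-log Pr(response)` over all non-top-up trials. A model with `beta = 0`
#' and `phi = 0` assigns probability 1/2 throughout, so its negLLE is
#' `n_trials * log(2)` (about 110.90 for 160 trials) — the chance ceiling any
#' fit should beat.
#'
#' @param kind One of [model_kinds()].
#' @param params A [model_params()] object (or anything coercible via
#'   [model_params()] arguments).
#' @param log A session log; top-up trials are skipped.
#' @param update_on_no_feedback Should o = 0 trials drive value updates
#'   (default `TRUE`)?
#' @return The scalar negLLE (nonnegative).
#' @export
neg_log_likelihood <- function(kind, params, log,
                               update_on_no_feedback = TRUE) {
  kind <- match.arg(kind, model_kinds())
  enc <- encode_log(log)
  if (length(enc$stim) < 1L)
    stop("log has no analyzable (non-top-up) trials", call. = FALSE)
  nll_replay(kind_code(kind), enc$stim, enc$act, enc$out,
             params$alpha, params$alpha_a_plus, params$alpha_a_minus,
             params$alpha_c_plus, params$alpha_c_minus,
             params$beta, params$phi, update_on_no_feedback)
}

#' Default box constraints for free parameters
#'
#' Learning rates are bounded to \[0, 1\]; the softmax noise `beta` to
#' \[0, `beta_max`\]; the perseveration weight `phi` to
#' \[-`phi_max`, `phi_max`\]. With outcomes coded in `{-1, 0, +1}`,
#' `beta_max = 20` saturates the softmax, so the defaults are effectively
#' unrestrictive.
#'
#' @param kind One of [model_kinds()].
#' @param kernel Include a free `phi`?
#' @param beta_max,phi_max Bound magnitudes.
#' @return A 2-row matrix (`lower`, `upper`) with one column per free
#'   parameter.
#' @export
default_bounds <- function(kind, kernel = FALSE, beta_max = 20,
                           phi_max = 5) {
  info <- model_info(kind, kernel = kernel)
  lower <- upper <- stats::setNames(numeric(info$k), info$free)
  for (p in info$free) {
    if (p == "beta") {
      lower[p] <- 0; upper[p] <- beta_max
    } else if (p == "phi") {
      lower[p] <- -phi_max; upper[p] <- phi_max
    } else {
      lower[p] <- 0; upper[p] <- 1
    }
  }
  rbind(lower = lower, upper = upper)
}

#' Fit one subject's session log by maximum likelihood
#'
#' Minimizes [neg_log_likelihood()] over the model's free parameters with
#' bounded L-BFGS-B from `n_restarts` random interior starting points (plus
#' any `extra_starts`), falling back to a box-clamped Nelder-Mead search for
#' any restart where the gradient-based run fails, and finishing with a
#' derivative-free Nelder-Mead polish of the best solution. Deterministic
#' given `seed`.
#'
#' @param kind One of [model_kinds()].
#' @param log A session log.
#' @param n_restarts Number of random restarts.
#' @param seed Optional integer seed for the restart draws.
#' @param bounds A bounds matrix as from [default_bounds()].
#' @param extra_starts Optional matrix of additional starting points (one row
#'   per start, columns in free-parameter order).
#' @param kernel Free the perseveration weight `phi`?
#' @param update_on_no_feedback Passed to [neg_log_likelihood()].
#' @param polish Run the Nelder-Mead polish of the best restart?
#' @return A one-row data frame: `subject_id`, `model`, `kernel`, every model
#'   parameter (NA when not free in this model), `negLLE`, `n_restarts`,
#'   `best_restart`, `converged`.
#' @export
fit_subject <- function(kind, log, n_restarts = 10L, seed = NULL,
                        bounds = default_bounds(kind, kernel),
                        extra_starts = NULL, kernel = FALSE,
                        update_on_no_feedback = TRUE, polish = TRUE) {
  kind <- match.arg(kind, model_kinds())
  info <- model_info(kind, kernel = kernel)
  if (!identical(colnames(bounds), info$free))
    stop("bounds columns must match the model's free parameters",
         call. = FALSE)
  enc <- encode_log(log)
  if (length(enc$stim) < 1L)
    stop("log has no analyzable (non-top-up) trials", call. = FALSE)
  code <- kind_code(kind)
  lower <- bounds["lower", ]; upper <- bounds["upper", ]

  full <- function(x) {
    p <- as.list(x)
    names(p) <- info$free
    defaults <- list(alpha = 0, alpha_a_plus = 0, alpha_a_minus = 0,
                     alpha_c_plus = 0, alpha_c_minus = 0,
                     beta = if (kind == "actor_critic_no_beta") 1 else 0,
                     phi = 0)
    utils::modifyList(defaults, p)
  }
  objective <- function(x) {
    p <- full(x)
    nll_replay(code, enc$stim, enc$act, enc$out,
               p$alpha, p$alpha_a_plus, p$alpha_a_minus,
               p$alpha_c_plus, p$alpha_c_minus, p$beta, p$phi,
               update_on_no_feedback)
  }
  clamped <- function(x) objective(pmin(pmax(x, lower), upper))

  # Row-wise draws so the first n rows form a common prefix across calls
  # with the same seed: best-of-n negLLE is then nonincreasing in n.
  starts <- with_seed(seed, {
    m <- matrix(stats::runif(n_restarts * info$k), n_restarts, info$k,
                byrow = TRUE)
    sweep(sweep(m, 2, upper - lower, `*`), 2, lower, `+`)
  })
  if (!is.null(extra_starts)) {
    extra_starts <- matrix(as.numeric(extra_starts), ncol = info$k)
    starts <- rbind(starts, extra_starts)
  }
  colnames(starts) <- info$free

  best <- NULL
  best_i <- NA_integer_
  any_converged <- FALSE
  failures <- character(0)
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      res <- tryCatch(
        stats::optim(starts[i, ], clamped, method = "Nelder-Mead"),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures <- c(failures, conditionMessage(res))
        next
      }
      res$par <- pmin(pmax(res$par, lower), upper)
    }
    if (is.null(best) || res$value < best$value) {
      best <- res
      best_i <- i
    }
    if (res$convergence == 0) any_converged <- TRUE
  }
  if (is.null(best))
    stop("all restarts failed: ", paste(unique(failures), collapse = "; "),
         call. = FALSE)
  if (polish && info$k >= 2L) {
    pol <- tryCatch(
      stats::optim(best$par, clamped, method = "Nelder-Mead",
                   control = list(reltol = 1e-10)),
      error = function(e) NULL
    )
    if (!is.null(pol) && pol$value < best$value) {
      pol$par <- pmin(pmax(pol$par, lower), upper)
      best <- pol
    }
  }
  p <- full(best$par)
  all_names <- c("alpha", "alpha_a_plus", "alpha_a_minus",
                 "alpha_c_plus", "alpha_c_minus", "beta", "phi")
  row <- stats::setNames(as.list(rep(NA_real_, length(all_names))), all_names)
  for (nm in info$free) row[[nm]] <- p[[nm]]
  cbind(
    data.frame(subject_id = as.character(log$subject_id[1]), model = kind,
               kernel = kernel),
    as.data.frame(row),
    data.frame(negLLE = best$value, n_restarts = nrow(starts),
               best_restart = best_i, converged = any_converged,
               error = NA_character_)
  )
}

#' Fit every subject in a cohort
#'
#' Maps [fit_subject()] over a list of session logs; per-subject failures are
#' kept as flagged rows (`converged = FALSE`, `negLLE = NA`, the message in
#' `error`) and never abort the cohort.
#'
#' @inheritParams fit_subject
#' @param logs A list of session logs.
#' @return A data frame with one row per subject in the `fit_subject` schema.
#' @export
fit_cohort <- function(kind, logs, n_restarts = 10L, seed = NULL,
                       kernel = FALSE, update_on_no_feedback = TRUE) {
  kind <- match.arg(kind, model_kinds())
  template <- fit_schema(kind, kernel)
  if (length(logs) == 0L) return(template)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(logs)))
  rows <- lapply(seq_along(logs), function(i) {
    tryCatch(
      fit_subject(kind, logs[[i]], n_restarts = n_restarts,
                  seed = sub_seeds[i], kernel = kernel,
                  update_on_no_feedback = update_on_no_feedback),
      error = function(e) {
        data.frame(subject_id = as.character(logs[[i]]$subject_id[1]),
                   model = kind, kernel = kernel, alpha = NA_real_,
                   alpha_a_plus = NA_real_, alpha_a_minus = NA_real_,
                   alpha_c_plus = NA_real_, alpha_c_minus = NA_real_,
                   beta = NA_real_, phi = NA_real_, negLLE = NA_real_,
                   n_restarts = NA_integer_, best_restart = NA_integer_,
                   converged = FALSE, error = conditionMessage(e))
      }
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fit_schema <- function(kind, kernel) {
  data.frame(subject_id = character(0), model = character(0),
             kernel = logical(0), alpha = numeric(0),
             alpha_a_plus = numeric(0), alpha_a_minus = numeric(0),
             alpha_c_plus = numeric(0), alpha_c_minus = numeric(0),
             beta = numeric(0), phi = numeric(0), negLLE = numeric(0),
             n_restarts = integer(0), best_restart = integer(0),
             converged = logical(0), error = character(0))
}

#' Parameter-recovery study
#'
#' Standard validation of the fitting pipeline: draw true parameters from
#' `sampler`, simulate one session per agent, refit with the same model, and
#' summarize per-parameter bias, RMSE and true-vs-recovered Pearson
#' correlation.
#'
#' @param kind One of [model_kinds()].
#' @param sampler A function `n -> data.frame` with one column per free
#'   parameter (in [model_info()] order) and `n` rows, drawing true values
#'   within the fitting bounds.
#' @param n_agents Number of simulated agents.
#' @param seed Integer seed controlling draws, simulation and fitting.
#' @param config Task [session_config()].
#' @param n_restarts Restarts per fit.
#' @param kernel Free `phi`?
#' @return A list with `summary` (parameter, bias, rmse, correlation) and
#'   `agents` (true and fitted values side by side). Empty frames when
#'   `n_agents = 0`.
#' @export
recover_parameters <- function(kind, sampler, n_agents, seed = NULL,
                               config = session_config(), n_restarts = 5L,
                               kernel = FALSE) {
  kind <- match.arg(kind, model_kinds())
  info <- model_info(kind, kernel = kernel)
  if (n_agents == 0L) {
    return(list(
      summary = data.frame(parameter = character(0), bias = numeric(0),
                           rmse = numeric(0), correlation = numeric(0)),
      agents = data.frame()
    ))
  }
  with_seed(seed, {
    truth <- as.data.frame(sampler(n_agents))
    if (!identical(names(truth), info$free))
      stop("sampler must return columns ",
           paste(info$free, collapse = ", "), call. = FALSE)
    fits <- vector("list", n_agents)
    for (i in seq_len(n_agents)) {
      params <- params_from_free(kind, as.numeric(truth[i, ]),
                                 kernel = kernel)
      log <- simulate_agent(kind, params, config = config,
                            subject_id = paste0("agent", i))
      fits[[i]] <- fit_subject(kind, log, n_restarts = n_restarts,
                               seed = sample.int(.Machine$integer.max, 1L),
                               kernel = kernel)
    }
    fitted <- do.call(rbind, fits)
    agents <- cbind(
      stats::setNames(truth, paste0("true_", names(truth))),
      stats::setNames(fitted[info$free], paste0("fit_", info$free)),
      negLLE = fitted$negLLE
    )
    summary <- do.call(rbind, lapply(info$free, function(p) {
      err <- agents[[paste0("fit_", p)]] - agents[[paste0("true_", p)]]
      data.frame(
        parameter = p,
        bias = mean(err),
        rmse = sqrt(mean(err^2)),
        correlation = if (n_agents > 1)
          stats::cor(agents[[paste0("true_", p)]],
                     agents[[paste0("fit_", p)]])
        else NA_real_
      )
    }))
    list(summary = summary, agents = agents)
  })
}
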