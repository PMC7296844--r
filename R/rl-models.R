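#' The five reinforcement-learning models of the task
#'
#' Constructs the structure of one of the five Rescorla-Wagner models.
#' All models value the two stimuli with a delta rule,
#' `q[a] <- q[a] + alpha * (rho * outcome - q[a])`, and choose on free-choice
#' trials through a softmax over the two rho-scaled values with unit
#' temperature (rho doubles as the effective inverse temperature, the
#' identifiable parameterisation when outcomes are binary). They differ in
#' whether forced ("no choice") outcomes update values and whether the
#' learning rate alpha and the reward sensitivity rho are condition specific:
#' \describe{
#'   \item{1}{choice outcomes only; single alpha, single rho (2 params)}
#'   \item{2}{learns from both conditions; single alpha, single rho (2)}
#'   \item{3}{separate alpha for choice / no-choice; single rho (3)}
#'   \item{4}{single alpha; separate rho by condition (3)}
#'   \item{5}{separate alpha and separate rho (4)}
#' }
#'
#' @param modelId integer in 1..5.
#' @return an [RLModel-class] object.
#' @examples
#' rlModel(3)
#' @export
rlModel <- function(modelId) {
  modelId <- as.integer(modelId)
  stopifnot(length(modelId) == 1L, modelId %in% 1:5)
  defs <- list(
    list(FALSE, FALSE, FALSE, c("logit_alpha", "log_rho")),
    list(TRUE,  FALSE, FALSE, c("logit_alpha", "log_rho")),
    list(TRUE,  TRUE,  FALSE, c("logit_alpha_choice", "logit_alpha_nochoice", "log_rho")),
    list(TRUE,  FALSE, TRUE,  c("logit_alpha", "log_rho_choice", "log_rho_nochoice")),
    list(TRUE,  TRUE,  TRUE,  c("logit_alpha_choice", "logit_alpha_nochoice",
                                "log_rho_choice", "log_rho_nochoice"))
  )[[modelId]]
  new("RLModel", modelId = modelId, learnsFromNoChoice = defs[[1]],
      splitLearningRate = defs[[2]], splitSensitivity = defs[[3]],
      nParams = length(defs[[4]]), paramNames = defs[[4]])
}

logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))

#' Convert between native and unconstrained RL parameters
#'
#' Learning rates live in (0,1) and are logit-transformed; reward
#' sensitivities are positive and log-transformed. All fitting happens in the
#' unconstrained (theta) space.
#'
#' @param model an [RLModel-class].
#' @param alpha_choice,alpha_nochoice learning rates in (0,1).
#' @param rho_choice,rho_nochoice reward sensitivities > 0. Parameters shared
#'   by the model may be omitted (aliased from the choice value).
#' @return `rlParamsToTheta`: unconstrained numeric vector of length
#'   `nParams(model)`; `thetaToRlParams`: named list with all four native
#'   parameters (shared ones aliased).
#' @examples
#' th <- rlParamsToTheta(rlModel(3), alpha_choice = 0.4,
#'                       alpha_nochoice = 0.2, rho_choice = 1)
#' thetaToRlParams(rlModel(3), th)
#' @export
rlParamsToTheta <- function(model, alpha_choice, alpha_nochoice = alpha_choice,
                            rho_choice, rho_nochoice = rho_choice) {
  stopifnot(alpha_choice > 0, alpha_choice < 1, rho_choice > 0,
            alpha_nochoice > 0, alpha_nochoice < 1, rho_nochoice > 0)
  switch(model@modelId,
    c(logit(alpha_choice), log(rho_choice)),
    c(logit(alpha_choice), log(rho_choice)),
    c(logit(alpha_choice), logit(alpha_nochoice), log(rho_choice)),
    c(logit(alpha_choice), log(rho_choice), log(rho_nochoice)),
    c(logit(alpha_choice), logit(alpha_nochoice),
      log(rho_choice), log(rho_nochoice)))
}

#' @rdname rlParamsToTheta
#' @param theta unconstrained parameter vector.
#' @export
thetaToRlParams <- function(model, theta) {
  stopifnot(length(theta) == model@nParams)
  out <- switch(model@modelId,
    list(invlogit(theta[1]), 0,                 exp(theta[2]), exp(theta[2])),
    list(invlogit(theta[1]), invlogit(theta[1]), exp(theta[2]), exp(theta[2])),
    list(invlogit(theta[1]), invlogit(theta[2]), exp(theta[3]), exp(theta[3])),
    list(invlogit(theta[1]), invlogit(theta[1]), exp(theta[2]), exp(theta[3])),
    list(invlogit(theta[1]), invlogit(theta[2]), exp(theta[3]), exp(theta[4])))
  names(out) <- c("alpha_choice", "alpha_nochoice", "rho_choice", "rho_nochoice")
  out
}

# trials data.frame -> integer vectors for the C++ replay core
.trialsToInt <- function(trials) {
  stopifnot(!is.unsorted(trials$index))
  act <- as.integer(!is.na(trials$action) & trials$action == "high")
  list(condition = as.integer(trials$condition == "choice"),
       action = act,
       outcome = ifelse(is.na(trials$outcome), 0L, as.integer(trials$outcome)),
       missed = as.integer(trials$missed))
}

#' Single Rescorla-Wagner value update
#'
#' Applies one delta-rule update and returns the new values and the reward
#' prediction error `rpe = rho * outcome - q[action]`. The unchosen stimulus
#' is untouched. Under model 1 on a forced trial the values are left unchanged
#' but the prediction error is still returned (it is used as an fMRI
#' regressor; set `rpeOnNoChoice = FALSE` in [rpeSeries()] to zero it
#' instead).
#'
#' @param q numeric(2): current values of (low, high) stimulus.
#' @param action "high" or "low".
#' @param outcome 0 or 1.
#' @param condition "choice" or "no_choice".
#' @param theta unconstrained parameters.
#' @param model an [RLModel-class].
#' @return list with `q` (updated values) and `rpe`.
#' @examples
#' m <- rlModel(2)
#' updateQ(c(low = 0, high = 0), "high", 1, "choice",
#'         rlParamsToTheta(m, alpha_choice = 0.5, rho_choice = 1), m)
#' @export
updateQ <- function(q, action, outcome, condition, theta, model) {
  stopifnot(outcome %in% c(0, 1), length(q) == 2L)
  p <- thetaToRlParams(model, theta)
  isChoice <- condition == "choice"
  alpha <- if (isChoice) p$alpha_choice else p$alpha_nochoice
  rho <- if (isChoice) p$rho_choice else p$rho_nochoice
  a <- if (action == "high") 2L else 1L
  rpe <- rho * outcome - q[[a]]
  learns <- isChoice || model@learnsFromNoChoice
  if (learns) q[[a]] <- q[[a]] + alpha * rpe
  list(q = q, rpe = rpe)
}

#' Softmax choice probability of the high-probability stimulus
#'
#' Unit-temperature softmax over the two rho-scaled stimulus values, so the
#' probability of choosing the high arm is `1 / (1 + exp(-(q_high - q_low)))`.
#'
#' @param q numeric(2): values of (low, high) stimulus (already rho-scaled).
#' @return probability of choosing the high arm, in (0, 1).
#' @examples
#' choiceProb(c(0, log(3)))  # 0.75
#' @export
choiceProb <- function(q) {
  stopifnot(length(q) == 2L, all(is.finite(q)))
  1 / (1 + exp(-(q[[2]] - q[[1]])))
}

#' Negative log-likelihood of a subject's choices
#'
#' Sum of `-log P(action)` over non-missed free-choice trials only; forced
#' actions are imposed by the task and carry no likelihood, but their outcomes
#' still propagate through the values for models that learn from them. Missed
#' trials are skipped entirely.
#'
#' @param subject a [SubjectRecord-class] or its `trials` data.frame.
#' @param model an [RLModel-class].
#' @param theta unconstrained parameters.
#' @param gradient return the analytic gradient as attribute `"gradient"`?
#' @return the NLL (numeric scalar), optionally with a gradient attribute.
#' @export
negLogLik <- function(subject, model, theta, gradient = FALSE) {
  tr <- if (is(subject, "SubjectRecord")) subject@trials else subject
  v <- .trialsToInt(tr)
  r <- .rl_replay_cpp(as.numeric(theta), model@modelId, v$condition, v$action,
                      v$outcome, v$missed, gradient, FALSE, FALSE)
  if (!is.finite(r$nll)) stop("non-finite likelihood at the supplied parameters")
  out <- r$nll
  if (gradient) attr(out, "gradient") <- r$grad
  out
}

#' Reward-prediction-error series for model-based fMRI
#'
#' Replays the fitted model over the session and returns one prediction error
#' per non-missed outcome event, aligned to the outcome onset.
#'
#' @inheritParams negLogLik
#' @param rpeOnNoChoice for model 1 only: report the (non-updating) prediction
#'   error on forced trials (`TRUE`, default) or zero it.
#' @return data.frame with `onset` (s), `rpe`, `condition`, `outcome`.
#' @export
rpeSeries <- function(subject, model, theta, rpeOnNoChoice = TRUE) {
  tr <- if (is(subject, "SubjectRecord")) subject@trials else subject
  v <- .trialsToInt(tr)
  r <- .rl_replay_cpp(as.numeric(theta), model@modelId, v$condition, v$action,
                      v$outcome, v$missed, FALSE, TRUE, rpeOnNoChoice)
  keep <- !tr$missed
  rpe <- r$rpe
  rpe[is.na(rpe) & keep] <- 0  # model 1 forced trials with rpeOnNoChoice=FALSE
  data.frame(onset = tr$outcome_onset[keep], rpe = rpe[keep],
             condition = tr$condition[keep], outcome = tr$outcome[keep])
}

#' Per-trial choice probabilities under a model replay
#'
#' Mostly a diagnostic/testing aid: the running probability of choosing the
#' high arm before each trial's update.
#' @inheritParams negLogLik
#' @return numeric vector, NA on missed trials.
#' @export
replayChoiceProb <- function(subject, model, theta) {
  tr <- if (is(subject, "SubjectRecord")) subject@trials else subject
  v <- .trialsToInt(tr)
  .rl_replay_cpp(as.numeric(theta), model@modelId, v$condition, v$action,
                 v$outcome, v$missed, FALSE, TRUE, TRUE)$p_high
}
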