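#' Task configuration for the probabilistic reward learning task
#'
#' Describes the session: 66 trials split into 33 free-choice and 33 forced
#' ("no choice") trials, two stimuli rewarded with probability 0.8 (high arm)
#' and 0.2 (low arm), 100 points per win, and event-related timing at a
#' repetition time of 1.56 s. Phase onsets are jittered so that cue, response
#' and outcome regressors are dissociable.
#'
#' @slot nTrials total trials per session.
#' @slot nChoiceTrials number of free-choice trials.
#' @slot pRewardHigh,pRewardLow reward probability of each arm.
#' @slot winPoints points displayed for a win.
#' @slot cueDuration,decisionDuration,outcomeDuration nominal display
#'   durations in seconds.
#' @slot jitterRange length-2 numeric; inter-phase onset-to-onset gaps are
#'   drawn uniformly from this range (seconds).
#' @slot tr repetition time in seconds.
#' @slot nScans number of volumes acquired; the session must fit inside
#'   `nScans * tr`.
#' @export
setClass("TaskConfig", representation(
  nTrials = "integer", nChoiceTrials = "integer",
  pRewardHigh = "numeric", pRewardLow = "numeric", winPoints = "numeric",
  cueDuration = "numeric", decisionDuration = "numeric",
  outcomeDuration = "numeric", jitterRange = "numeric",
  tr = "numeric", nScans = "integer"
))

setValidity("TaskConfig", function(object) {
  msg <- character()
  if (object@nChoiceTrials > object@nTrials)
    msg <- c(msg, "nChoiceTrials must not exceed nTrials")
  p <- c(object@pRewardHigh, object@pRewardLow)
  if (any(p < 0 | p > 1)) msg <- c(msg, "reward probabilities must lie in [0, 1]")
  dur <- c(object@cueDuration, object@decisionDuration, object@outcomeDuration,
           object@tr)
  if (any(dur <= 0)) msg <- c(msg, "durations and tr must be positive")
  if (length(object@jitterRange) != 2L || diff(object@jitterRange) < 0 ||
      any(object@jitterRange < 0))
    msg <- c(msg, "jitterRange must be a non-decreasing non-negative pair")
  if (object@nScans < 1L) msg <- c(msg, "nScans must be positive")
  if (length(msg)) msg else TRUE
})

#' One subject's session: trials, covariates and simulation ground truth
#'
#' @slot subjectId character identifier.
#' @slot trials data.frame with one row per trial: `index`, `condition`
#'   ("choice"/"no_choice"), `cue_onset`, `response_onset`, `outcome_onset`
#'   (seconds), `action` ("high"/"low": stimulus identity by reward
#'   probability), `forced_action` (NA on choice trials), `outcome` (0/1, NA
#'   when missed), `missed` (logical).
#' @slot qids Quick Inventory of Depressive Symptomatology score (0-27).
#' @slot hadsA HADS anxiety subscale score (0-21).
#' @slot age years; @slot sex "F"/"M"; @slot site "A"/"B".
#' @slot mde major depressive episode status: "never", "past" or "current".
#' @slot trueParams simulation ground-truth RL parameters in unconstrained
#'   space (numeric, possibly empty).
#' @slot trueDcm simulation ground-truth DCM parameter vector (numeric,
#'   possibly empty).
#' @export
setClass("SubjectRecord", representation(
  subjectId = "character", trials = "data.frame",
  qids = "numeric", hadsA = "numeric", age = "numeric",
  sex = "character", site = "character", mde = "character",
  trueParams = "numeric", trueDcm = "numeric"
))

setValidity("SubjectRecord", function(object) {
  msg <- character()
  tr <- object@trials
  need <- c("index", "condition", "cue_onset", "response_onset",
            "outcome_onset", "action", "forced_action", "outcome", "missed")
  if (!all(need %in% names(tr)))
    return(paste("trials must contain columns:", paste(need, collapse = ", ")))
  if (nrow(tr)) {
    if (any(!(tr$condition %in% c("choice", "no_choice"))))
      msg <- c(msg, "condition must be 'choice' or 'no_choice'")
    bad <- tr$cue_onset >= tr$response_onset | tr$response_onset >= tr$outcome_onset
    if (any(bad)) msg <- c(msg, "phase onsets must be strictly increasing within trials")
    nc <- tr$condition == "no_choice"
    if (any(nc & !is.na(tr$forced_action) & tr$action != tr$forced_action))
      msg <- c(msg, "no_choice actions must equal forced_action")
    if (any(tr$missed & !is.na(tr$outcome)))
      msg <- c(msg, "missed trials carry no outcome")
  }
  if (length(object@qids) && (object@qids < 0 || object@qids > 27))
    msg <- c(msg, "qids outside instrument range 0-27")
  if (length(object@hadsA) && (object@hadsA < 0 || object@hadsA > 21))
    msg <- c(msg, "hadsA outside instrument range 0-21")
  if (length(msg)) msg else TRUE
})

#' A cohort of subjects
#'
#' List of [SubjectRecord-class] objects with a shared [TaskConfig-class].
#' @slot config the task configuration the sessions were generated under.
#' @export
setClass("Cohort", contains = "list",
         representation(config = "TaskConfig"))

setValidity("Cohort", function(object) {
  if (!all(vapply(object@.Data, is, logical(1), "SubjectRecord")))
    "all elements must be SubjectRecord objects" else TRUE
})

#' Structure of one of the five reinforcement-learning models
#'
#' The five models span the hypotheses of how subjects learn on free-choice
#' versus forced trials: model 1 learns from choice outcomes only; model 2
#' learns equally from both; model 3 has separate learning rates by condition;
#' model 4 has separate reward sensitivities; model 5 has both split.
#'
#' @slot modelId integer 1-5.
#' @slot learnsFromNoChoice does the model update values after forced trials?
#' @slot splitLearningRate,splitSensitivity condition-specific alpha / rho?
#' @slot nParams number of free parameters.
#' @slot paramNames names of the unconstrained parameters (logit alpha, log rho).
#' @export
setClass("RLModel", representation(
  modelId = "integer", learnsFromNoChoice = "logical",
  splitLearningRate = "logical", splitSensitivity = "logical",
  nParams = "integer", paramNames = "character"
))

#' Empirical-Bayes Gaussian group prior over unconstrained RL parameters
#' @slot mu prior mean vector; @slot sigma2 diagonal prior variances (> 0).
#' @export
setClass("GroupPrior", representation(mu = "numeric", sigma2 = "numeric"))

setValidity("GroupPrior", function(object) {
  if (length(object@mu) != length(object@sigma2))
    return("mu and sigma2 must have equal length")
  if (any(object@sigma2 <= 0)) return("sigma2 must be positive")
  TRUE
})

#' Per-subject MAP fit with Laplace covariance
#' @slot thetaMap MAP estimate in unconstrained space.
#' @slot laplaceCov inverse-Hessian covariance at the mode (symmetric PD).
#' @slot logPosterior unnormalised log posterior at the mode.
#' @slot marginalLoglik Monte-Carlo marginal log-likelihood (NA until computed).
#' @slot nLLEvals likelihood evaluations spent.
#' @export
setClass("SubjectFit", representation(
  thetaMap = "numeric", laplaceCov = "matrix", logPosterior = "numeric",
  marginalLoglik = "numeric", nLLEvals = "integer"
))

#' Group-level model comparison by integrated BIC
#' @slot ibic named numeric, one value per model.
#' @slot winner model id attaining the minimum iBIC.
#' @slot marginalLogliks list (per model) of per-subject marginal log-likelihoods.
#' @slot priors list of fitted [GroupPrior-class] objects per model.
#' @slot fits list (per model) of lists of [SubjectFit-class].
#' @export
setClass("ModelComparison", representation(
  ibic = "numeric", winner = "integer", marginalLogliks = "list",
  priors = "list", fits = "list"
))

setValidity("ModelComparison", function(object) {
  if (length(object@ibic) &&
      object@ibic[[as.character(object@winner)]] > min(object@ibic) + 1e-9)
    "winner must attain the minimum iBIC" else TRUE
})

#' Bilinear DCM structure for the VIS - VS - mPFC reward network
#'
#' Fully connected three-region bilinear model: nine endogenous connections
#' (six directed between-region influences plus three inhibitory
#' self-connections), four outcome-type modulatory inputs acting on every
#' connection, and eight driving channels (four outcome types and two cue
#' types into visual cortex; choice / no-choice button presses into all
#' regions). Self-connections are parameterised as -0.5 * exp(a) so they stay
#' inhibitory.
#'
#' @slot regions ordered region names.
#' @slot priorMu,priorVar Gaussian shrinkage prior over the 60-element
#'   parameter vector (A offdiagonal 6, A self 3, B 36, C 12, log transit 3).
#' @slot lambdaPrior mean and variance of the Gaussian prior on the
#'   observation-noise log precision.
#' @slot tr repetition time (s); @slot microtime integration bins per TR.
#' @slot freeB,freeC logical: are B / C parameters free during inversion?
#' @export
setClass("DCMSpec", representation(
  regions = "character", priorMu = "numeric", priorVar = "numeric",
  lambdaPrior = "numeric", tr = "numeric", microtime = "integer",
  freeB = "logical", freeC = "logical"
))

setValidity("DCMSpec", function(object) {
  msg <- character()
  if (length(object@priorMu) != 60L || length(object@priorVar) != 60L)
    msg <- c(msg, "priors must cover the 60-element parameter vector")
  if (any(object@priorVar <= 0)) msg <- c(msg, "prior variances must be positive")
  if (length(object@regions) != 3L) msg <- c(msg, "exactly three regions")
  if (length(msg)) msg else TRUE
})

#' Variational-Laplace posterior of a single-subject DCM
#' @slot mu posterior mean over the full 60-element parameter vector.
#' @slot cov posterior covariance over the free parameters.
#' @slot freeIdx indices of free parameters within the full vector.
#' @slot lambda posterior noise log precision.
#' @slot freeEnergy final variational free energy.
#' @slot fSeries free energy after each accepted iteration.
#' @slot explainedVariance percent variance explained by the posterior-mean
#'   prediction.
#' @slot converged logical; @slot iterations accepted iterations run.
#' @export
setClass("DCMPosterior", representation(
  mu = "numeric", cov = "matrix", freeIdx = "integer", lambda = "numeric",
  freeEnergy = "numeric", fSeries = "numeric", explainedVariance = "numeric",
  converged = "logical", iterations = "integer"
))

#' Parametric-empirical-Bayes group posterior over DCM connectivity
#' @slot beta posterior mean of group effects, covariates x parameters.
#' @slot cov posterior covariance of vec(beta) (parameter-major stacking).
#' @slot gamma between-subject log precision (random-effects hyperparameter).
#' @slot freeEnergy model evidence bound of the group model.
#' @slot design between-subject design matrix (first column ones, covariates
#'   mean-centred).
#' @slot priorMu,priorVar Gaussian prior over vec(beta).
#' @slot covariateNames,paramNames dimension names of `beta`.
#' @export
setClass("PEBResult", representation(
  beta = "matrix", cov = "matrix", gamma = "numeric", freeEnergy = "numeric",
  design = "matrix", priorMu = "numeric", priorVar = "numeric",
  covariateNames = "character", paramNames = "character"
))

#' Bayesian-model-average of reduced PEB models
#' @slot effects averaged effect per covariate x parameter.
#' @slot pNonzero posterior probability that each effect is retained.
#' @slot modelEvidences free energies (relative) of the averaged model set.
#' @slot weights posterior model probabilities (sum to 1).
#' @export
setClass("BMAResult", representation(
  effects = "matrix", pNonzero = "matrix", modelEvidences = "numeric",
  weights = "numeric"
))

setValidity("BMAResult", function(object) {
  if (any(object@pNonzero < -1e-9 | object@pNonzero > 1 + 1e-9))
    "posterior probabilities must lie in [0, 1]" else TRUE
})
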