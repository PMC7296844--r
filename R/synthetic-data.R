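# Synthetic task schedules, agents, cohorts and BOLD. The generator emulates
# the scanner task (66 trials, 33 choice / 33 forced, 80%/20% arms, jittered
# event-related pacing at TR 1.56 s) and plants known parameter-symptom and
# connectivity-symptom effects so that recovery can be tested.

# Evaluate expr under a temporary RNG state seeded by `seed` (NULL = leave
# the global stream alone).
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a task configuration
#'
#' Defaults reproduce the study task: 66 trials, 33 of them free choice, arm
#' reward probabilities 0.8 / 0.2, 100 points per win, TR 1.56 s. Trial
#' phases (cue, response, outcome) follow each other at onset-to-onset gaps
#' drawn uniformly from `jitterRange`; the default 560 volumes cover the
#' implied session length with headroom.
#'
#' @param nTrials,nChoiceTrials trial counts.
#' @param pRewardHigh,pRewardLow arm reward probabilities.
#' @param winPoints points shown on a win.
#' @param cueDuration,decisionDuration,outcomeDuration display durations (s).
#' @param jitterRange uniform bounds for inter-phase gaps (s).
#' @param tr repetition time (s).
#' @param nScans volumes acquired.
#' @return a validated [TaskConfig-class].
#' @examples
#' taskConfigDefault()
#' @export
taskConfigDefault <- function(nTrials = 66L, nChoiceTrials = 33L,
                              pRewardHigh = 0.8, pRewardLow = 0.2,
                              winPoints = 100, cueDuration = 2,
                              decisionDuration = 3, outcomeDuration = 1.5,
                              jitterRange = c(2, 6), tr = 1.56,
                              nScans = 560L) {
  new("TaskConfig", nTrials = as.integer(nTrials),
      nChoiceTrials = as.integer(nChoiceTrials), pRewardHigh = pRewardHigh,
      pRewardLow = pRewardLow, winPoints = winPoints,
      cueDuration = cueDuration, decisionDuration = decisionDuration,
      outcomeDuration = outcomeDuration, jitterRange = jitterRange,
      tr = tr, nScans = as.integer(nScans))
}

#' Generate a randomised trial schedule
#'
#' Randomly orders the required numbers of choice and no-choice trials, draws
#' forced actions on no-choice trials with equal probability per arm, and
#' draws every inter-phase onset gap uniformly from the configured jitter
#' range. Actions and outcomes are left NA; [simulateAgent()] fills them.
#'
#' @param config a [TaskConfig-class].
#' @param seed integer seed (NULL to use the current RNG stream).
#' @param leadIn seconds of dead time before the first cue.
#' @return trials data.frame (see [SubjectRecord-class]).
#' @export
generateSchedule <- function(config, seed = NULL, leadIn = 10) {
  validObject(config)
  .withSeed(seed, {
    n <- config@nTrials
    cond <- sample(rep(c("choice", "no_choice"),
                       c(config@nChoiceTrials, n - config@nChoiceTrials)))
    gaps <- matrix(runif(3 * n, config@jitterRange[1], config@jitterRange[2]),
                   nrow = n)
    cue <- resp <- outc <- numeric(n)
    t <- leadIn
    for (i in seq_len(n)) {
      cue[i] <- t
      resp[i] <- cue[i] + gaps[i, 1]
      outc[i] <- resp[i] + gaps[i, 2]
      t <- outc[i] + gaps[i, 3]
    }
    if (outc[n] + config@outcomeDuration > config@nScans * config@tr)
      stop("schedule error: session exceeds nScans * tr")
    forced <- ifelse(cond == "no_choice",
                     sample(c("high", "low"), n, replace = TRUE), NA_character_)
    data.frame(index = seq_len(n), condition = cond, cue_onset = cue,
               response_onset = resp, outcome_onset = outc,
               action = NA_character_, forced_action = forced,
               outcome = NA_real_, missed = FALSE, stringsAsFactors = FALSE)
  })
}

#' Simulate an agent performing the task under an RL model
#'
#' On free-choice trials the action is sampled from the model's softmax
#' policy over the running stimulus values; on forced trials the prescribed
#' action is executed. Outcomes are Bernoulli with the chosen arm's reward
#' probability and values are updated after every non-missed outcome
#' according to the model.
#'
#' @param schedule trials data.frame from [generateSchedule()].
#' @param model an [RLModel-class].
#' @param theta unconstrained parameters (see [rlParamsToTheta()]).
#' @param config the [TaskConfig-class] used for the schedule.
#' @param seed integer seed.
#' @param missRate probability that a trial is missed (no response, no
#'   outcome); 0 by default.
#' @return completed trials data.frame.
#' @export
simulateAgent <- function(schedule, model, theta, config, seed = NULL,
                          missRate = 0) {
  stopifnot(length(theta) == model@nParams, missRate >= 0, missRate < 1)
  thetaToRlParams(model, theta)  # errors on invalid native ranges
  .withSeed(seed, {
    n <- nrow(schedule)
    q <- c(0, 0)
    out <- schedule
    for (i in seq_len(n)) {
      if (missRate > 0 && runif(1) < missRate) {
        out$missed[i] <- TRUE
        out$action[i] <- NA_character_
        out$outcome[i] <- NA_real_
        next
      }
      if (schedule$condition[i] == "choice") {
        a <- if (runif(1) < choiceProb(q)) "high" else "low"
      } else {
        a <- schedule$forced_action[i]
      }
      pArm <- if (a == "high") config@pRewardHigh else config@pRewardLow
      r <- rbinom(1, 1, pArm)
      upd <- updateQ(q, a, r, schedule$condition[i], theta, model)
      q <- upd$q
      out$action[i] <- a
      out$outcome[i] <- r
    }
    out
  })
}

# Draw correlated (QIDS, HADS-A) integer scores: a latent bivariate Gaussian
# (r = 0.5) mapped through a right-skewed negative binomial (mean 4.5) for
# QIDS and a discretised Gaussian for HADS-A, both truncated to instrument
# range.
.drawSymptoms <- function(n, qidsMean = 4.5, qidsSize = 2, latentCor = 0.5) {
  z1 <- rnorm(n)
  z2 <- latentCor * z1 + sqrt(1 - latentCor^2) * rnorm(n)
  qids <- pmin(qnbinom(pnorm(z1), size = qidsSize, mu = qidsMean), 27)
  hads <- pmin(pmax(round(7 + 3 * z2), 0), 21)
  list(qids = as.numeric(qids), hads = as.numeric(hads))
}

#' Generate a synthetic cohort with planted parameter-symptom effects
#'
#' QIDS scores are drawn from a truncated negative binomial (mean about 4.5,
#' matching the study population), HADS anxiety is correlated with QIDS
#' through a latent Gaussian (r about 0.5), and age, sex and site are drawn
#' independently. Unconstrained RL parameters are Gaussian around the
#' population mean plus `symptomEffect * (QIDS - mean(QIDS))`, and each
#' subject then performs a freshly randomised session. Ground-truth
#' parameters are stored on every subject.
#'
#' @param nSubjects cohort size (>= 2).
#' @param model generating [RLModel-class].
#' @param paramPopulation a [GroupPrior-class]: population mean and variance
#'   of the unconstrained parameters.
#' @param symptomEffect per-parameter slope on centred QIDS (scalar or vector
#'   of length `nParams(model)`); 0 plants no effect.
#' @param seed integer seed.
#' @param config [TaskConfig-class]; default [taskConfigDefault()].
#' @param missRate per-trial miss probability.
#' @param mdeProbs probabilities of never / past / current MDE status.
#' @return a [Cohort-class].
#' @export
generateCohort <- function(nSubjects, model, paramPopulation,
                           symptomEffect = 0, seed = NULL,
                           config = taskConfigDefault(), missRate = 0,
                           mdeProbs = c(never = 0.65, past = 0.2, current = 0.15)) {
  stopifnot(nSubjects >= 2)
  validObject(paramPopulation)
  d <- model@nParams
  stopifnot(length(paramPopulation@mu) == d)
  if (any(paramPopulation@sigma2 < 1e-12))
    stop("degenerate population prior variance")
  symptomEffect <- rep_len(symptomEffect, d)
  .withSeed(seed, {
    sym <- .drawSymptoms(nSubjects)
    qidsC <- sym$qids - mean(sym$qids)
    subjects <- vector("list", nSubjects)
    for (i in seq_len(nSubjects)) {
      theta <- paramPopulation@mu + symptomEffect * qidsC[i] +
        sqrt(paramPopulation@sigma2) * rnorm(d)
      sched <- generateSchedule(config)
      tr <- simulateAgent(sched, model, theta, config, missRate = missRate)
      subjects[[i]] <- new("SubjectRecord",
        subjectId = sprintf("sub-%03d", i), trials = tr,
        qids = sym$qids[i], hadsA = sym$hads[i],
        age = rnorm(1, 58, 9), sex = sample(c("F", "M"), 1),
        site = sample(c("A", "B"), 1),
        mde = sample(names(mdeProbs), 1, prob = mdeProbs),
        trueParams = theta, trueDcm = numeric())
    }
    new("Cohort", subjects, config = config)
  })
}

#' Ground-truth DCM parameters with the planted connectivity structure
#'
#' Builds a 60-element DCM parameter vector (see [dcmSpecDefault()]) whose
#' A-matrix has the planted group structure: no influence from visual cortex
#' to ventral striatum and none from ventral striatum to mPFC, positive
#' influences elsewhere, and an mPFC -> VS connection that decreases linearly
#' with centred QIDS.
#'
#' @param qidsCentred subject's QIDS minus the cohort mean.
#' @param qidsSlope change in the mPFC -> VS connection per QIDS point
#'   (negative plants the depression-related blunting).
#' @param baseline strength of the nonzero between-region connections (Hz).
#' @param subjectSd SD of subject-level jitter on the nonzero connections.
#' @param driveOutcome,driveCue,driveResponse driving-input weights.
#' @return numeric(60) ground-truth parameter vector.
#' @export
trueDcmParams <- function(qidsCentred = 0, qidsSlope = -0.03, baseline = 0.3,
                          subjectSd = 0.05, driveOutcome = 0.1,
                          driveCue = 0.1, driveResponse = 0.05) {
  th <- numeric(60)
  # A offdiagonal order: VIS->VS, VIS->mPFC, VS->VIS, VS->mPFC, mPFC->VIS, mPFC->VS
  nz <- c(2, 3, 5, 6)
  th[nz] <- baseline + rnorm(4, 0, subjectSd)
  th[6] <- th[6] + qidsSlope * qidsCentred
  th[1] <- 0  # VIS -> VS absent by construction
  th[4] <- 0  # VS -> mPFC absent by construction
  # keep the planted network dynamically stable (slowest mode at least
  # 0.1 Hz): rescale the between-region couplings if the excitatory loops
  # push the spectral abscissa of A above -0.1
  A <- matrix(0, 3, 3)
  A[cbind(c(2, 3, 1, 3, 1, 2), rep(1:3, each = 2))] <- th[1:6]
  diag(A) <- -0.5
  abscissa <- function(sc) {
    As <- A
    As[row(As) != col(As)] <- As[row(As) != col(As)] * sc
    max(Re(eigen(As, only.values = TRUE)$values))
  }
  if (abscissa(1) > -0.1) {
    sc <- uniroot(function(s) abscissa(s) + 0.1, c(0, 1))$root
    th[1:6] <- th[1:6] * sc
  }
  th[46:49] <- driveOutcome
  th[50:51] <- driveCue
  th[52:57] <- driveResponse
  th
}

#' Synthesize region-of-interest BOLD from the DCM generative model
#'
#' Runs the bilinear three-region forward model on the subject's event
#' schedule and adds white Gaussian observation noise. Either `noiseSd` or
#' `snr` (SD of the clean signal divided by noise SD, applied per region)
#' must be given.
#'
#' @param subject a [SubjectRecord-class] with a completed session.
#' @param spec a [DCMSpec-class]; default [dcmSpecDefault()].
#' @param theta ground-truth 60-element parameter vector, e.g. from
#'   [trueDcmParams()].
#' @param noiseSd observation noise SD (>= 0).
#' @param snr alternative to `noiseSd`: per-region signal-to-noise ratio.
#' @param seed integer seed for the noise.
#' @param config [TaskConfig-class] supplying TR and scan count.
#' @return data.frame with columns `time_s`, `vis`, `vs`, `mpfc`.
#' @export
synthesizeBold <- function(subject, spec = dcmSpecDefault(), theta,
                           noiseSd = NULL, snr = NULL, seed = NULL,
                           config = taskConfigDefault()) {
  if (is.null(noiseSd) && is.null(snr)) stop("give noiseSd or snr")
  if (!is.null(noiseSd) && noiseSd < 0) stop("noiseSd must be >= 0")
  U <- dcmInputs(trials(subject), config, spec)
  y <- integrateDCM(spec, theta, U, config@nScans, config@tr)
  .withSeed(seed, {
    if (!is.null(snr)) {
      noiseSd <- apply(y, 2, sd) / snr
    } else noiseSd <- rep(noiseSd, 3)
    for (j in 1:3) y[, j] <- y[, j] + rnorm(nrow(y), 0, noiseSd[j])
    data.frame(time_s = (seq_len(nrow(y)) - 1) * config@tr,
               vis = y[, 1], vs = y[, 2], mpfc = y[, 3])
  })
}

#' Generate a cohort with planted connectivity-symptom effects and BOLD
#'
#' Convenience wrapper used by the DCM/PEB validation pipeline: simulates
#' behaviour under the winning behavioural model, builds each subject's
#' ground-truth DCM parameters via [trueDcmParams()] (mPFC -> VS declining
#' with centred QIDS) and synthesizes noisy ROI BOLD.
#'
#' @inheritParams generateCohort
#' @param qidsSlope slope of the mPFC -> VS connection on centred QIDS.
#' @param snr per-region signal-to-noise ratio of the synthetic BOLD.
#' @param spec [DCMSpec-class] forward model.
#' @return list with `cohort` (a [Cohort-class], `trueDcm` filled in) and
#'   `bold` (list of ROI time-series data.frames).
#' @export
generateDcmCohort <- function(nSubjects, qidsSlope = -0.03, snr = 1,
                              seed = NULL, config = taskConfigDefault(),
                              spec = dcmSpecDefault(),
                              model = rlModel(3),
                              paramPopulation = groupPriorDefault(model)) {
  .withSeed(seed, {
    cohort <- generateCohort(nSubjects, model, paramPopulation,
                             config = config)
    qidsC <- qids(cohort) - mean(qids(cohort))
    bold <- vector("list", nSubjects)
    for (i in seq_len(nSubjects)) {
      th <- trueDcmParams(qidsCentred = qidsC[i], qidsSlope = qidsSlope)
      cohort[[i]]@trueDcm <- th
      bold[[i]] <- synthesizeBold(cohort[[i]], spec, th, snr = snr,
                                  config = config)
    }
    list(cohort = cohort, bold = bold)
  })
}

#' Default population prior for cohort generation
#'
#' Population means correspond to a choice-trial learning rate of 0.4, a
#' no-choice learning rate of 0.2 (most subjects learn faster from free
#' choices, as observed behaviourally) and a reward sensitivity around 3,
#' which gives an asymptotic accuracy of about 0.86 on the 80/20 arms —
#' agents that visibly learn the task, as the study's participants did.
#' Learning rates spread with variance 0.25 in logit space: at the 0.4/0.2
#' means this makes about 92\% of subjects learn faster from free choices,
#' matching the proportion reported behaviourally; log sensitivity also has
#' variance 0.25.
#'
#' @param model an [RLModel-class].
#' @return a [GroupPrior-class] of matching dimension.
#' @export
groupPriorDefault <- function(model) {
  mu <- switch(model@modelId,
    c(logit(0.4), log(3)),
    c(logit(0.3), log(3)),
    c(logit(0.4), logit(0.2), log(3)),
    c(logit(0.3), log(3.5), log(2.5)),
    c(logit(0.4), logit(0.2), log(3.5), log(2.5)))
  new("GroupPrior", mu = mu, sigma2 = rep(0.25, length(mu)))
}
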