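# Bilinear three-region DCM (visual cortex, ventral striatum, mPFC):
# specification, driving/modulatory input construction, forward integration,
# variational-Laplace inversion, explained variance and the inclusion filter.

.A_NAMES <- c("VIS->VS", "VIS->mPFC", "VS->VIS", "VS->mPFC",
              "mPFC->VIS", "mPFC->VS", "self_VIS", "self_VS", "self_mPFC")
.INPUT_NAMES <- c("outcome_reward", "outcome_noreward", "outcome_choice",
                  "outcome_nochoice", "cue_choice", "cue_nochoice",
                  "response_choice", "response_nochoice")

#' Default DCM specification for the reward network
#'
#' Fully connected bilinear model over (VIS, VS, mPFC): nine endogenous
#' connections (self-connections inhibitory via -0.5 * exp(a)), four
#' outcome-type modulatory inputs acting on all nine connections, and eight
#' driving channels (four outcome types and the two cue types into visual
#' cortex; choice and no-choice button presses into every region).
#' Shrinkage priors: between-region A ~ N(0, 1/16) Hz, self log-scaling
#' ~ N(0, 1/64), B ~ N(0, 1/16), C ~ N(0, 1), log transit-time deviation
#' ~ N(0, 1/256), observation-noise log precision ~ N(4, 1).
#'
#' @param tr repetition time (s).
#' @param microtime Euler integration bins per TR.
#' @param freeB,freeC estimate the B / C parameters (fixing them at prior
#'   mean shrinks the inversion for quick tests).
#' @return a [DCMSpec-class].
#' @export
dcmSpecDefault <- function(tr = 1.56, microtime = 16L, freeB = TRUE,
                           freeC = TRUE) {
  pv <- c(rep(1 / 16, 6), rep(1 / 64, 3), rep(1 / 16, 36), rep(1, 12),
          rep(1 / 256, 3))
  new("DCMSpec", regions = c("VIS", "VS", "mPFC"), priorMu = numeric(60),
      priorVar = pv, lambdaPrior = c(4, 1), tr = tr,
      microtime = as.integer(microtime), freeB = freeB, freeC = freeC)
}

#' Build the eight mean-centred DCM input channels from a session
#'
#' Stimulus functions at microtime resolution: the four outcome types
#' (reward, no-reward, choice-trial outcomes, no-choice-trial outcomes; each
#' outcome event therefore appears in two channels), the two cue types, and
#' the two response types. Unit-height boxcars at the event durations
#' (responses are single-bin impulses). Each channel is mean-centred so the
#' A-matrix parameterises average connectivity and the B-matrix deviations
#' from it.
#'
#' @param trials trials data.frame of a completed session.
#' @param config [TaskConfig-class] supplying TR, scan count and durations.
#' @param spec [DCMSpec-class] supplying the microtime resolution.
#' @param meanCentre centre the channels (default TRUE).
#' @return `nScans * microtime` x 8 matrix with named columns.
#' @export
dcmInputs <- function(trials, config = taskConfigDefault(),
                      spec = dcmSpecDefault(), meanCentre = TRUE) {
  dtm <- config@tr / spec@microtime
  nBins <- config@nScans * spec@microtime
  ok <- !trials$missed
  win <- ok & !is.na(trials$outcome) & trials$outcome == 1
  isC <- trials$condition == "choice"
  tr1 <- function(on, dur) .deltaTrain(on, rep(dur, length(on)),
                                       rep(1, length(on)), nBins, dtm)
  U <- cbind(
    tr1(trials$outcome_onset[win], config@outcomeDuration),
    tr1(trials$outcome_onset[ok & !win], config@outcomeDuration),
    tr1(trials$outcome_onset[ok & isC], config@outcomeDuration),
    tr1(trials$outcome_onset[ok & !isC], config@outcomeDuration),
    tr1(trials$cue_onset[isC], config@cueDuration),
    tr1(trials$cue_onset[!isC], config@cueDuration),
    tr1(trials$response_onset[ok & isC], 0),
    tr1(trials$response_onset[ok & !isC], 0))
  colnames(U) <- .INPUT_NAMES
  if (meanCentre) U <- sweep(U, 2, colMeans(U))
  U
}

#' Neural state derivative of the bilinear model
#'
#' `dx/dt = (A + sum_j u_j B_j) x + C u`. When `selfLog` is supplied the
#' diagonal of A is overwritten with the inhibitory parameterisation
#' `-0.5 * exp(selfLog)`.
#'
#' @param x neural state (3-vector).
#' @param u input values (8-vector).
#' @param A 3 x 3 endogenous connectivity.
#' @param B list of 3 x 3 modulatory matrices, one per modulated input (the
#'   first `length(B)` entries of `u`).
#' @param C 3 x 8 driving-input weights.
#' @param selfLog optional length-3 log self-connection scaling.
#' @return dx/dt (3-vector).
#' @export
neuralDerivative <- function(x, u, A, B = list(), C, selfLog = NULL) {
  if (!is.null(selfLog)) diag(A) <- -0.5 * exp(selfLog)
  J <- A
  for (j in seq_along(B)) J <- J + u[j] * B[[j]]
  drop(J %*% x + C %*% u)
}

#' One balloon-Windkessel derivative evaluation
#'
#' The haemodynamic observation model per region: vasodilatory signal `s`,
#' inflow `f`, venous volume `v` and deoxyhemoglobin `q` driven by neural
#' activity `x`:
#' `ds = x - kappa s - gamma (f - 1)`, `df = s`,
#' `tau dv = f - v^(1/alpha)`,
#' `tau dq = f E(f)/E0 - v^(1/alpha) q / v`, with
#' `E(f) = 1 - (1 - E0)^(1/f)`. The BOLD signal is
#' `y = V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))`.
#'
#' @param state named list or vector with `s`, `f`, `v`, `q` (f, v, q > 0).
#' @param x neural activity (scalar).
#' @param tau transit time (s).
#' @param kappa,gamma,alpha,E0 haemodynamic constants.
#' @return list of derivatives `ds`, `df`, `dv`, `dq`.
#' @export
hemodynamicStep <- function(state, x, tau = 2, kappa = 0.64, gamma = 0.32,
                            alpha = 0.32, E0 = 0.4) {
  s <- state[["s"]]; f <- state[["f"]]; v <- state[["v"]]; q <- state[["q"]]
  if (any(c(f, v, q) <= 0)) stop("integrator error: state positivity violated")
  Ef <- 1 - (1 - E0)^(1 / f)
  fv <- v^(1 / alpha)
  list(ds = x - kappa * s - gamma * (f - 1), df = s,
       dv = (f - fv) / tau, dq = (f * Ef / E0 - fv * q / v) / tau)
}

#' BOLD observation from balloon states
#' @param v venous volume; @param q deoxyhemoglobin content.
#' @param V0,E0 resting volume fraction (percent units) and oxygen extraction.
#' @return percent BOLD signal change.
#' @export
boldSignal <- function(v, q, V0 = 4, E0 = 0.4) {
  k1 <- 7 * E0; k2 <- 2; k3 <- 2 * E0 - 0.2
  V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

#' Integrate the DCM forward model
#'
#' Fixed-step Euler at `tr / microtime`, sampled at scan onsets.
#'
#' @param spec a [DCMSpec-class].
#' @param theta full 60-element parameter vector.
#' @param inputs microtime input matrix from [dcmInputs()].
#' @param nScans,tr scan count and repetition time.
#' @return `nScans` x 3 matrix of predicted BOLD (columns VIS, VS, mPFC).
#' @export
integrateDCM <- function(spec, theta, inputs, nScans, tr = spec@tr) {
  r <- .dcm_forward_cpp(as.numeric(theta), inputs, as.integer(nScans), tr,
                        spec@microtime)
  if (!r$ok) stop("instability error: forward model diverged")
  colnames(r$bold) <- spec@regions
  r$bold
}

.freeIdx <- function(spec) {
  idx <- 1:9
  if (spec@freeB) idx <- c(idx, 10:45)
  if (spec@freeC) idx <- c(idx, 46:57)
  c(idx, 58:60)
}

#' Invert a single-subject DCM by variational Laplace
#'
#' Gauss-Newton ascent on a Laplace free-energy bound under the Gaussian
#' shrinkage priors of the specification, with Levenberg-style damping:
#' candidate steps that do not increase the free energy are rejected and the
#' damping increased, so the accepted free-energy series is non-decreasing.
#' The observation-noise log precision has its own Gaussian prior and is
#' updated by Newton steps inside each iteration. The Jacobian of the
#' forward model is obtained by finite differences of the compiled
#' integrator.
#'
#' @param spec a [DCMSpec-class].
#' @param data `nScans` x 3 matrix (or data.frame with columns vis, vs,
#'   mpfc) of ROI time series.
#' @param inputs microtime input matrix from [dcmInputs()].
#' @param maxIter maximum accepted iterations.
#' @param tol stop when the free-energy gain falls below this.
#' @param fdStep finite-difference step for the Jacobian.
#' @return a [DCMPosterior-class] (with `converged = FALSE` and the last
#'   iterate when the tolerance was not reached).
#' @export
invertVL <- function(spec, data, inputs, maxIter = 32, tol = 0.01,
                     fdStep = 1e-4) {
  if (is.data.frame(data))
    data <- as.matrix(data[, intersect(c("vis", "vs", "mpfc"), names(data))])
  nScans <- nrow(data)
  stopifnot(nrow(inputs) >= nScans * spec@microtime)
  y <- as.numeric(data)
  N <- length(y)
  free <- .freeIdx(spec)
  p <- length(free)
  mu0 <- spec@priorMu[free]
  P0 <- diag(1 / spec@priorVar[free], p)
  ldP0 <- sum(log(1 / spec@priorVar[free]))
  lam0 <- spec@lambdaPrior[1]; vlam <- spec@lambdaPrior[2]

  th <- spec@priorMu
  lam <- lam0
  nu <- 1e-4

  freeEnergyOf <- function(ee, dtheta, ldH, lamv) {
    -0.5 * exp(lamv) * ee + 0.5 * N * lamv - 0.5 * N * log(2 * pi) -
      0.5 * sum(dtheta^2 / spec@priorVar[free]) + 0.5 * ldP0 - 0.5 * ldH -
      0.5 * (lamv - lam0)^2 / vlam
  }

  jac <- .dcm_jacobian_cpp(th, inputs, nScans, spec@tr, spec@microtime,
                           as.integer(free), fdStep)
  if (!jac$ok) stop("instability error at the prior mean")
  e <- y - jac$g0
  JtJ <- crossprod(jac$J)
  H <- exp(lam) * JtJ + P0
  Fcur <- freeEnergyOf(sum(e^2), th[free] - mu0, determinant(H)$modulus, lam)
  fSeries <- Fcur
  converged <- FALSE
  iters <- 0L

  for (it in seq_len(maxIter)) {
    Jte <- crossprod(jac$J, e)
    g <- exp(lam) * Jte - (th[free] - mu0) / spec@priorVar[free]
    accepted <- FALSE
    for (try in 1:8) {
      Hd <- H + nu * diag(diag(H), p)
      step <- tryCatch(solve(Hd, g), error = function(e2) NULL)
      if (!is.null(step)) {
        th2 <- th
        th2[free] <- th[free] + step
        fw <- .dcm_forward_cpp(th2, inputs, as.integer(nScans), spec@tr,
                               spec@microtime)
        if (fw$ok) {
          e2 <- y - as.numeric(fw$bold)
          # Newton updates of the noise log precision at the candidate
          lam2 <- lam
          S <- sum(e2^2) + sum(JtJ * solve(exp(lam) * JtJ + P0))
          for (k in 1:5) {
            g1 <- 0.5 * N - 0.5 * exp(lam2) * S - (lam2 - lam0) / vlam
            h1 <- -0.5 * exp(lam2) * S - 1 / vlam
            lam2 <- lam2 - g1 / h1
          }
          H2 <- exp(lam2) * JtJ + P0
          F2 <- freeEnergyOf(sum(e2^2), th2[free] - mu0,
                             determinant(H2)$modulus, lam2)
          if (is.finite(F2) && F2 > Fcur) {
            jac2 <- .dcm_jacobian_cpp(th2, inputs, nScans, spec@tr,
                                      spec@microtime, as.integer(free), fdStep)
            if (jac2$ok) {
              th <- th2; lam <- lam2; jac <- jac2
              e <- y - jac$g0
              JtJ <- crossprod(jac$J)
              H <- exp(lam) * JtJ + P0
              dF <- F2 - Fcur
              Fcur <- F2
              fSeries <- c(fSeries, Fcur)
              nu <- max(nu / 2, 1e-6)
              accepted <- TRUE
              iters <- iters + 1L
              if (dF < tol) converged <- TRUE
              break
            }
          }
        }
      }
      nu <- nu * 10
    }
    if (!accepted) { converged <- TRUE; break }  # no improving step exists
    if (converged) break
  }

  covF <- solve(H)
  covF <- (covF + t(covF)) / 2
  pred <- matrix(jac$g0, nScans, 3)
  ev <- 100 * (1 - sum((data - pred)^2) / sum(sweep(data, 2, colMeans(data))^2))
  rownames(covF) <- colnames(covF) <- .paramNames()[free]
  names(th) <- .paramNames()
  new("DCMPosterior", mu = th, cov = covF, freeIdx = as.integer(free),
      lambda = lam, freeEnergy = Fcur, fSeries = fSeries,
      explainedVariance = ev, converged = converged, iterations = iters)
}

.paramNames <- function() {
  c(.A_NAMES[1:6], .A_NAMES[7:9],
    paste0("B", rep(1:4, each = 9), "_", rep(1:9, 4)),
    paste0("C_", c(paste0("outc", 1:4, "_VIS"), "cueC_VIS", "cueNC_VIS",
                   paste0("respC_", c("VIS", "VS", "mPFC")),
                   paste0("respNC_", c("VIS", "VS", "mPFC")))),
    paste0("transit_", c("VIS", "VS", "mPFC")))
}

#' Percent variance explained by a model prediction
#'
#' `100 * (1 - ||data - prediction||^2 / ||data - mean||^2)`, computed over
#' all regions jointly. Accepts either a prediction matrix or a fitted
#' [DCMPosterior-class] (with `spec` and `inputs` to regenerate the
#' posterior-mean prediction).
#'
#' @param object prediction matrix or [DCMPosterior-class].
#' @param data observed ROI series (matrix or data.frame).
#' @param spec,inputs needed when `object` is a posterior.
#' @return percent (<= 100; negative when the model is worse than the mean).
#' @export
explainedVariance <- function(object, data, spec = NULL, inputs = NULL) {
  if (is.data.frame(data))
    data <- as.matrix(data[, intersect(c("vis", "vs", "mpfc"), names(data))])
  denom <- sum(sweep(data, 2, colMeans(data))^2)
  if (denom == 0) stop("zero-variance data")
  pred <- if (is(object, "DCMPosterior")) {
    stopifnot(!is.null(spec), !is.null(inputs))
    integrateDCM(spec, object@mu, inputs, nrow(data))
  } else object
  100 * (1 - sum((data - pred)^2) / denom)
}

#' Filter subjects by explained variance
#'
#' Keeps subjects whose DCM explains at least `thresholdPct` of their ROI
#' signal variance, reporting the excluded count and (when scores are given)
#' a Welch test comparing the covariate between kept and excluded groups —
#' the standard check that the filter does not bias the cohort.
#'
#' @param fits list of [DCMPosterior-class].
#' @param thresholdPct inclusion threshold (percent).
#' @param scores optional per-subject covariate (e.g. QIDS) for the Welch test.
#' @return list with `kept` (indices), `nExcluded`, `explainedVariance`, and
#'   `welch` (NULL unless both groups have >= 2 members).
#' @export
filterSubjects <- function(fits, thresholdPct = 10, scores = NULL) {
  ev <- vapply(fits, varianceExplained, numeric(1))
  kept <- which(ev >= thresholdPct)
  out <- list(kept = kept, nExcluded = length(fits) - length(kept),
              explainedVariance = ev, welch = NULL)
  if (!is.null(scores) && length(kept) >= 2 && out$nExcluded >= 2)
    out$welch <- welchT(scores[kept], scores[-kept])
  out
}

#' Extract the nine endogenous (A-matrix) parameters of a DCM posterior
#'
#' The six between-region connections plus the three log self-connection
#' scalings, with their 9 x 9 posterior covariance — the quantities carried
#' to the group level.
#'
#' @param fit a [DCMPosterior-class].
#' @return list with `mu` (named 9-vector) and `cov` (9 x 9 matrix).
#' @export
aParameters <- function(fit) {
  pos <- match(1:9, fit@freeIdx)
  list(mu = setNames(fit@mu[1:9], .A_NAMES),
       cov = fit@cov[pos, pos, drop = FALSE])
}
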