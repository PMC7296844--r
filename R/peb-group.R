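# Parametric empirical Bayes over subject DCM posteriors: hierarchical
# Gaussian group model, Bayesian model reduction, greedy pruning, Bayesian
# model averaging and split-sample replication.

#' Between-subject PEB design matrix
#'
#' A column of ones (mean connectivity across participants) followed by
#' mean-centred covariates: QIDS, HADS anxiety, age, sex, collection site and
#' current-MDE status. Sex and site are coded +/- 0.5 before centring; MDE is
#' an indicator of a current episode.
#'
#' @param covars data.frame as returned by `covariates()` on a cohort.
#' @param include character vector of covariate columns to keep (default all
#'   six study covariates; `"qids"` alone gives the minimal design). Any
#'   numeric column of `covars` may be named, so a single-symptom column can
#'   replace the QIDS sum without further changes.
#' @return design matrix with first column `mean`, all later columns centred.
#' @export
pebDesign <- function(covars,
                      include = c("qids", "hads_a", "age", "sex", "site", "mde")) {
  n <- nrow(covars)
  X <- matrix(1, n, 1, dimnames = list(NULL, "mean"))
  for (nm in include) {
    v <- covars[[nm]]
    if (is.null(v)) stop("covariate not found: ", nm)
    v <- switch(nm,
      sex = ifelse(v == "M", 0.5, -0.5),
      site = ifelse(v == "B", 0.5, -0.5),
      mde = ifelse(v == "current", 0.5, -0.5),
      as.numeric(v))
    X <- cbind(X, v - mean(v))
    colnames(X)[ncol(X)] <- nm
  }
  X
}

# Default second-level priors: the commonality row inherits the
# subject-level A-parameter prior variances; covariate effects are shrunk a
# further factor 16. Between-subject random effects share the subject-level
# variances scaled by exp(-gamma)/16, gamma ~ N(0, 1).
.pebPriors <- function(nCov) {
  pv9 <- c(rep(1 / 16, 6), rep(1 / 64, 3))
  list(betaVar = c(pv9, rep(pv9 / 16, nCov - 1)),
       reVar = pv9 / 16, gammaPrior = c(0, 1))
}

#' Fit the group-level PEB model
#'
#' Hierarchical Gaussian model: each subject's nine endogenous-connectivity
#' parameters are noisy observations (with their posterior covariances) of
#' `(x_i' \%kronecker\% I_9) beta` plus between-subject random effects with a
#' common log precision `gamma`. `beta` is marginalised analytically; `gamma`
#' is optimised on the evidence (its N(0,1) prior included), giving the model
#' free energy and the Gaussian posterior over all covariate-by-connection
#' effects.
#'
#' @param subjectPosteriors list of `list(mu, cov)` nine-parameter Gaussians,
#'   e.g. from [aParameters()].
#' @param design between-subject design matrix from [pebDesign()].
#' @return a [PEBResult-class]; `posteriorMean()` gives the covariates x
#'   parameters effect matrix.
#' @export
pebFit <- function(subjectPosteriors, design) {
  n <- length(subjectPosteriors)
  stopifnot(n >= 2, nrow(design) == n)
  q <- length(subjectPosteriors[[1]]$mu)   # 9
  k <- ncol(design)
  nz <- apply(design, 2, function(cl) any(cl != 0))
  if (qr(design[, nz, drop = FALSE])$rank < sum(nz))
    stop("rank-deficient design matrix")
  pr <- .pebPriors(k)
  P0 <- diag(1 / pr$betaVar[seq_len(q * k)], q * k)
  ld0 <- -sum(log(pr$betaVar[seq_len(q * k)]))
  pnames <- names(subjectPosteriors[[1]]$mu)

  evidence <- function(gamma) {
    G <- diag(exp(-gamma) * pr$reVar, q)
    Pp <- P0
    b <- numeric(q * k)
    quad <- 0
    ldV <- 0
    for (i in seq_len(n)) {
      Vi <- subjectPosteriors[[i]]$cov + G
      Wi <- solve(Vi)
      ldV <- ldV + determinant(Vi)$modulus
      mi <- subjectPosteriors[[i]]$mu
      quad <- quad + drop(mi %*% Wi %*% mi)
      xi <- design[i, ]
      Pp <- Pp + kronecker(xi %o% xi, Wi)
      b <- b + kronecker(xi, drop(Wi %*% mi))
    }
    mb <- solve(Pp, b)
    ldPp <- determinant(Pp)$modulus
    Fv <- -0.5 * quad + 0.5 * drop(b %*% mb) -
      0.5 * (ldV - ld0 + ldPp) - 0.5 * q * n * log(2 * pi) -
      0.5 * (gamma - pr$gammaPrior[1])^2 / pr$gammaPrior[2]
    list(F = as.numeric(Fv), beta = mb, cov = solve(Pp))
  }

  opt <- optimize(function(g) -evidence(g)$F, interval = c(-6, 6))
  fit <- evidence(opt$minimum)
  beta <- matrix(fit$beta, nrow = k, ncol = q, byrow = TRUE,
                 dimnames = list(colnames(design), pnames))
  new("PEBResult", beta = beta, cov = fit$cov, gamma = opt$minimum,
      freeEnergy = fit$F, design = design,
      priorMu = numeric(q * k), priorVar = pr$betaVar[seq_len(q * k)],
      covariateNames = colnames(design), paramNames = pnames)
}

#' Bayesian model reduction of a Gaussian posterior
#'
#' Analytic evidence change and posterior obtained when the prior of an
#' already-fitted Gaussian model is replaced by a reduced prior (typically
#' with some parameters switched off by shrinking their prior variance to
#' zero), with no refitting:
#' `Pr = P + P0r - P0`,
#' `mr = Pr^{-1} (P m + P0r m0r - P0 m0)`,
#' `dF = (log det of the four precisions)/2 + (the four quadratic forms)/2`.
#'
#' @param mu,cov full-model posterior mean and covariance.
#' @param priorMu,priorVar full-model prior (mean vector, variance vector).
#' @param reducedMu,reducedVar reduced prior.
#' @return list with `dF` (reduced minus full log evidence), `mu` and `cov`
#'   of the reduced posterior.
#' @export
bmrReduce <- function(mu, cov, priorMu, priorVar, reducedMu, reducedVar) {
  P <- solve(cov)
  P0 <- diag(1 / priorVar, length(priorVar))
  P0r <- diag(1 / reducedVar, length(reducedVar))
  Pr <- P + P0r - P0
  ldPr <- determinant(Pr)$modulus
  if (!is.finite(ldPr)) stop("singular precision combination")
  h <- drop(P %*% mu + P0r %*% reducedMu - P0 %*% priorMu)
  mr <- solve(Pr, h)
  dF <- 0.5 * (sum(log(1 / reducedVar)) - sum(log(1 / priorVar)) +
                 as.numeric(determinant(P)$modulus) - as.numeric(ldPr)) +
    0.5 * (drop(mr %*% Pr %*% mr) - drop(mu %*% P %*% mu) +
             sum(priorMu^2 / priorVar) - sum(reducedMu^2 / reducedVar))
  covR <- solve(Pr)
  list(dF = as.numeric(dF), mu = mr, cov = (covR + t(covR)) / 2)
}

# Reduced prior with the given effects (indices into vec(beta)) switched off.
.offPrior <- function(priorVar, off, offVar = 1e-8) {
  v <- priorVar
  v[off] <- offVar
  v
}

#' Greedy search over reduced PEB models
#'
#' Iteratively switches off group effects that do not contribute to the free
#' energy: candidates are scanned in order of ascending |posterior mean| / SD
#' and an effect is pruned whenever removing it (on top of the current
#' reduced model) does not decrease the evidence. Scanning repeats until a
#' full pass prunes nothing. The returned model set contains the models
#' examined at the final iteration (the pruned model and its one-effect-off
#' neighbours), each with its evidence relative to the full model, ready for
#' [bmaAverage()].
#'
#' @param peb a [PEBResult-class].
#' @param offVar prior variance representing "switched off".
#' @return list with `offSet` (pruned effect indices into vec(beta)),
#'   `models` (final-iteration model set) and `dFPruned` (evidence gain of
#'   the pruned model over the full one).
#' @export
greedySearch <- function(peb, offVar = 1e-8) {
  mu <- as.numeric(t(peb@beta))       # parameter-major stacking of vec(beta)
  S <- peb@cov
  pv <- peb@priorVar
  m0 <- peb@priorMu
  nEff <- length(mu)
  reduceTo <- function(off) {
    bmrReduce(mu, S, m0, pv, m0, .offPrior(pv, off, offVar))
  }
  off <- integer()
  Fcur <- 0
  repeat {
    sdv <- sqrt(diag(S))
    ord <- order(abs(mu) / sdv)
    ord <- setdiff(ord, off)
    pruned <- FALSE
    for (j in ord) {
      cand <- reduceTo(c(off, j))
      if (cand$dF >= Fcur) {
        off <- c(off, j)
        Fcur <- cand$dF
        pruned <- TRUE
      }
    }
    if (!pruned) break
  }
  remaining <- setdiff(seq_len(nEff), off)
  models <- list()
  base <- if (length(off)) reduceTo(off) else
    list(dF = 0, mu = mu, cov = S)
  models[[1]] <- list(off = off, dF = base$dF, mu = base$mu, cov = base$cov)
  for (j in remaining) {
    cand <- reduceTo(c(off, j))
    models[[length(models) + 1]] <-
      list(off = c(off, j), dF = cand$dF, mu = cand$mu, cov = cand$cov)
  }
  list(offSet = off, models = models, dFPruned = base$dF)
}

#' Bayesian model averaging of reduced PEB models
#'
#' Averages the posterior over a model set with weights proportional to
#' exp(evidence); the probability that an effect is nonzero is the summed
#' weight of models retaining it.
#'
#' @param models model set from [greedySearch()] (each a list with `off`,
#'   `dF`, `mu`, `cov`).
#' @param peb the [PEBResult-class] the models reduce (for dimension names).
#' @return a [BMAResult-class].
#' @export
bmaAverage <- function(models, peb) {
  stopifnot(length(models) >= 1)
  dF <- vapply(models, `[[`, numeric(1), "dF")
  w <- exp(dF - max(dF))
  w <- w / sum(w)
  nEff <- length(models[[1]]$mu)
  avg <- numeric(nEff)
  pnz <- numeric(nEff)
  for (k in seq_along(models)) {
    avg <- avg + w[k] * models[[k]]$mu
    keep <- setdiff(seq_len(nEff), models[[k]]$off)
    pnz[keep] <- pnz[keep] + w[k]
  }
  kk <- length(peb@covariateNames)
  eff <- matrix(avg, nrow = kk, byrow = TRUE,
                dimnames = list(peb@covariateNames, peb@paramNames))
  pm <- matrix(pnz, nrow = kk, byrow = TRUE,
               dimnames = dimnames(eff))
  new("BMAResult", effects = eff, pNonzero = pm, modelEvidences = dF,
      weights = w)
}

#' Split-sample replication of a group effect
#'
#' Repeatedly splits the cohort into two disjoint halves (the first half is
#' larger by one when the cohort size is odd), fits the full PEB model to
#' each half (no model reduction), and records the sign of a chosen
#' covariate-by-connection effect — by default the QIDS effect on the
#' mPFC -> VS connection. 100 splits therefore produce 200 second-level
#' model fits.
#'
#' @param subjectPosteriors list of nine-parameter Gaussians (see [pebFit()]).
#' @param covars covariate data.frame aligned to the subjects.
#' @param nSplits number of random halvings.
#' @param seed integer seed.
#' @param covariate,connection effect to track.
#' @param include covariates for [pebDesign()] (recentred within each half).
#' @return list with `proportionNegative` (over all `2 * nSplits` halves),
#'   `values` (per-half posterior means) and `nFits`.
#' @export
splitSampleReplication <- function(subjectPosteriors, covars, nSplits = 100,
                                   seed = NULL, covariate = "qids",
                                   connection = "mPFC->VS",
                                   include = c("qids", "hads_a", "age",
                                               "sex", "site", "mde")) {
  n <- length(subjectPosteriors)
  stopifnot(n >= 8, nrow(covars) == n)
  .withSeed(seed, {
    vals <- numeric(0)
    for (s in seq_len(nSplits)) {
      perm <- sample(n)
      h1 <- perm[seq_len(ceiling(n / 2))]
      h2 <- perm[(ceiling(n / 2) + 1):n]
      for (h in list(h1, h2)) {
        fit <- pebFit(subjectPosteriors[h],
                      pebDesign(covars[h, , drop = FALSE], include = include))
        vals <- c(vals, fit@beta[covariate, connection])
      }
    }
    list(proportionNegative = mean(vals < 0), values = vals,
         nFits = 2L * nSplits)
  })
}
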