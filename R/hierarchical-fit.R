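# Hierarchical empirical-Bayes fitting: per-subject MAP estimates under a
# Gaussian group prior, EM over the prior moments, and integrated-BIC model
# comparison with a Monte-Carlo marginal likelihood.

# Penalised objective and gradient in unconstrained space.
.mapObjective <- function(theta, vint, modelId, prior) {
  r <- .rl_replay_cpp(theta, modelId, vint$condition, vint$action,
                      vint$outcome, vint$missed, TRUE, FALSE, FALSE)
  pen <- 0.5 * sum((theta - prior@mu)^2 / prior@sigma2)
  list(value = r$nll + pen, grad = r$grad + (theta - prior@mu) / prior@sigma2)
}

#' Maximum a posteriori fit of one subject
#'
#' Minimises `NLL(theta) - log N(theta; mu, diag(sigma2))` by quasi-Newton
#' (BFGS) with analytic gradients and jittered restarts, and returns the best
#' optimum together with the inverse-Hessian Laplace covariance at the mode.
#'
#' @param subject a [SubjectRecord-class] or trials data.frame.
#' @param model an [RLModel-class].
#' @param prior a [GroupPrior-class] matching `nParams(model)`.
#' @param nRestarts jittered starting points (first start is the prior mean).
#' @param seed integer seed for the restart jitter.
#' @param start optional warm-start vector used as the first starting point.
#' @return a [SubjectFit-class].
#' @export
fitMAP <- function(subject, model, prior, nRestarts = 5, seed = NULL,
                   start = NULL) {
  stopifnot(length(prior@mu) == model@nParams)
  tr <- if (is(subject, "SubjectRecord")) subject@trials else subject
  vint <- .trialsToInt(tr)
  d <- model@nParams
  .withSeed(seed, {
    starts <- lapply(seq_len(nRestarts), function(k) {
      if (k == 1L) {
        if (is.null(start)) prior@mu else start
      } else prior@mu + rnorm(d, 0, pmin(sqrt(prior@sigma2), 2))
    })
    best <- NULL
    evals <- 0L
    for (s0 in starts) {
      fit <- tryCatch(
        optim(s0,
              fn = function(th) .mapObjective(th, vint, model@modelId, prior)$value,
              gr = function(th) .mapObjective(th, vint, model@modelId, prior)$grad,
              method = "BFGS",
              control = list(maxit = 200, reltol = 1e-9)),
        error = function(e) NULL)
      if (is.null(fit)) next
      evals <- evals + fit$counts[["function"]]
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) stop("fit error: all restarts failed to converge")
    H <- optimHess(best$par,
                   fn = function(th) .mapObjective(th, vint, model@modelId, prior)$value,
                   gr = function(th) .mapObjective(th, vint, model@modelId, prior)$grad)
    H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE)
    lam <- pmax(ev$values, 1e-6)
    cov <- ev$vectors %*% diag(1 / lam, d) %*% t(ev$vectors)
    new("SubjectFit", thetaMap = best$par, laplaceCov = (cov + t(cov)) / 2,
        logPosterior = -best$value -
          0.5 * sum(log(2 * pi * prior@sigma2)),
        marginalLoglik = NA_real_, nLLEvals = as.integer(evals))
  })
}

#' Empirical-Bayes EM over a cohort
#'
#' Alternates per-subject MAP fitting (E step, with Laplace covariances) and
#' moment updates of the Gaussian group prior (M step):
#' `mu <- mean(theta)`, `sigma2 <- mean(theta^2 + diag(cov)) - mu^2`, floored
#' at 1e-4. Initialised at the pooled maximum-likelihood fit with unit
#' variances. After the first iteration subjects are warm-started at their
#' previous optimum with a single restart, which the jittered first sweep
#' makes safe.
#'
#' @param cohort a [Cohort-class] or list of subjects (>= 2).
#' @param model an [RLModel-class].
#' @param maxIter maximum EM iterations.
#' @param tol stop when `max(abs(delta mu))` falls below this.
#' @param nRestarts restarts used on the first sweep.
#' @param seed integer seed.
#' @return list with `prior` ([GroupPrior-class]), `fits` (list of
#'   [SubjectFit-class]), `iterations`, `converged`.
#' @export
emGroupFit <- function(cohort, model, maxIter = 40, tol = 1e-3,
                       nRestarts = 5, seed = NULL) {
  subjects <- if (is(cohort, "Cohort")) cohort@.Data else cohort
  stopifnot(length(subjects) >= 2)
  d <- model@nParams
  .withSeed(seed, {
    # pooled MLE initialisation: one parameter vector for the concatenated data
    vints <- lapply(subjects, function(s)
      .trialsToInt(if (is(s, "SubjectRecord")) s@trials else s))
    # a light ridge (prior SD 5 in unconstrained space) keeps the pooled
    # initialiser finite when the pooled MLE would diverge (e.g. saturated
    # choice probabilities)
    pooledObj <- function(th) {
      tot <- 0; g <- numeric(d)
      for (v in vints) {
        r <- .rl_replay_cpp(th, model@modelId, v$condition, v$action,
                            v$outcome, v$missed, TRUE, FALSE, FALSE)
        tot <- tot + r$nll; g <- g + r$grad
      }
      list(value = tot + sum(th^2) / 50, grad = g + th / 25)
    }
    init <- optim(numeric(d), fn = function(th) pooledObj(th)$value,
                  gr = function(th) pooledObj(th)$grad, method = "BFGS",
                  control = list(maxit = 200))$par
    prior <- new("GroupPrior", mu = init, sigma2 = rep(1, d))
    fits <- vector("list", length(subjects))
    converged <- FALSE
    iter <- 0L
    for (iter in seq_len(maxIter)) {
      for (i in seq_along(subjects)) {
        fits[[i]] <- fitMAP(subjects[[i]], model, prior,
                            nRestarts = if (iter == 1L) nRestarts else 1L,
                            start = if (iter == 1L) NULL else fits[[i]]@thetaMap)
      }
      th <- do.call(rbind, lapply(fits, function(f) f@thetaMap))
      vr <- do.call(rbind, lapply(fits, function(f) diag(f@laplaceCov)))
      muNew <- colMeans(th)
      s2New <- pmax(colMeans(th^2 + vr) - muNew^2, 1e-4)
      delta <- max(abs(muNew - prior@mu))
      prior <- new("GroupPrior", mu = muNew, sigma2 = s2New)
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning("EM did not converge within maxIter; returning last iterate")
    list(prior = prior, fits = fits, iterations = iter, converged = converged)
  })
}

#' Integrated BIC of a model for a cohort
#'
#' Monte-Carlo marginal likelihood under the fitted empirical prior,
#' `log (1/K) sum_k exp(-NLL_i(theta_k))` with `theta_k ~ N(mu, diag(sigma2))`
#' (log-sum-exp guarded), summed over subjects, times -2, plus a BIC penalty
#' of (number of prior parameters) x log(total choice-trial count). The data
#' count is choice trials only, the likelihood-bearing events; the prior
#' parameter count is `2 * nParams` (a mean and a variance per parameter).
#'
#' @param cohort a [Cohort-class] or list of subjects.
#' @param model an [RLModel-class].
#' @param prior fitted [GroupPrior-class] from [emGroupFit()].
#' @param nMcSamples Monte-Carlo draws K.
#' @param seed integer seed.
#' @return iBIC value with attribute `"marginalLogliks"` (per subject).
#' @export
iBIC <- function(cohort, model, prior, nMcSamples = 2000, seed = NULL) {
  subjects <- if (is(cohort, "Cohort")) cohort@.Data else cohort
  d <- model@nParams
  .withSeed(seed, {
    draws <- matrix(rnorm(nMcSamples * d), nMcSamples, d)
    draws <- sweep(sweep(draws, 2, sqrt(prior@sigma2), "*"), 2, prior@mu, "+")
    nChoice <- 0L
    mll <- vapply(subjects, function(s) {
      tr <- if (is(s, "SubjectRecord")) s@trials else s
      v <- .trialsToInt(tr)
      nChoice <<- nChoice + sum(v$condition == 1L & v$missed == 0L)
      .rl_log_marglik_cpp(draws, model@modelId, v$condition, v$action,
                          v$outcome, v$missed)
    }, numeric(1))
    out <- -2 * sum(mll) + 2 * d * log(nChoice)
    attr(out, "marginalLogliks") <- mll
    out
  })
}

#' Fit and compare a set of models on a cohort
#'
#' Runs [emGroupFit()] followed by [iBIC()] for each candidate model; the
#' winner attains the minimum iBIC.
#'
#' @param cohort a [Cohort-class] or list of subjects.
#' @param modelSet list of [RLModel-class] objects (default all five).
#' @param seed integer seed (per-model seeds are derived from it).
#' @param nMcSamples Monte-Carlo draws for [iBIC()].
#' @param ... further arguments for [emGroupFit()].
#' @return a [ModelComparison-class].
#' @export
compareModels <- function(cohort, modelSet = lapply(1:5, rlModel),
                          seed = NULL, nMcSamples = 2000, ...) {
  stopifnot(length(modelSet) >= 1)
  ids <- vapply(modelSet, function(m) m@modelId, integer(1))
  ib <- setNames(numeric(length(modelSet)), ids)
  mll <- priors <- fits <- setNames(vector("list", length(modelSet)), ids)
  for (j in seq_along(modelSet)) {
    m <- modelSet[[j]]
    sj <- if (is.null(seed)) NULL else seed + 1000L * j
    em <- emGroupFit(cohort, m, seed = sj, ...)
    val <- iBIC(cohort, m, em$prior, nMcSamples = nMcSamples,
                seed = if (is.null(sj)) NULL else sj + 1L)
    ib[j] <- as.numeric(val)
    mll[[j]] <- attr(val, "marginalLogliks")
    priors[[j]] <- em$prior
    fits[[j]] <- em$fits
  }
  new("ModelComparison", ibic = ib, winner = ids[which.min(ib)],
      marginalLogliks = mll, priors = priors, fits = fits)
}

#' Proportion of subjects learning faster from free choices
#'
#' Fraction of fitted subjects whose choice-trial learning rate exceeds their
#' no-choice learning rate, computed from MAP fits of a split-learning-rate
#' model (3 or 5).
#'
#' @param fits list of [SubjectFit-class] from that model.
#' @param model the [RLModel-class] fitted (must split learning rates).
#' @return proportion in `[0, 1]`.
#' @export
proportionFasterChoiceLearning <- function(fits, model) {
  stopifnot(model@splitLearningRate)
  mean(vapply(fits, function(f) f@thetaMap[1] > f@thetaMap[2], logical(1)))
}
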