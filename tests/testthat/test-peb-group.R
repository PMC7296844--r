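aNames <- c("VIS->VS", "VIS->mPFC", "VS->VIS", "VS->mPFC",
            "mPFC->VIS", "mPFC->VS", "self_VIS", "self_VS", "self_mPFC")

nullBeta <- function(X) {
  b <- matrix(0, ncol(X), 9, dimnames = list(colnames(X), aNames))
  b["mean", ] <- c(0, 0.3, 0.3, 0, 0.3, 0.3, 0, 0, 0)
  b
}

test_that("the PEB design centres covariates and codes factors symmetrically", {
  set.seed(1)
  cv <- makeCovars(30)
  X <- pebDesign(cv)
  expect_equal(colnames(X), c("mean", "qids", "hads_a", "age", "sex",
                              "site", "mde"))
  expect_equal(unname(X[, "mean"]), rep(1, 30))
  expect_equal(unname(colMeans(X[, -1])), rep(0, 6), tolerance = 1e-12)
  Xq <- pebDesign(cv, include = "qids")
  expect_equal(ncol(Xq), 2)
  # any numeric column can serve as the covariate of interest
  cv$item_concentration <- pmin(3, cv$qids %/% 4)
  expect_silent(pebDesign(cv, include = "item_concentration"))
  expect_error(pebDesign(cv, include = "nonexistent"), "not found")
})

test_that("PEB recovers planted commonalities and covariate slopes", {
  set.seed(2)
  cv <- makeCovars(40)
  X <- pebDesign(cv)
  beta <- nullBeta(X)
  beta["qids", "mPFC->VS"] <- -0.02
  post <- makeSubjectPosteriors(X, beta)
  fit <- pebFit(post, X)
  expect_lt(fit@beta["qids", "mPFC->VS"], 0)
  expect_gt(fit@beta["mean", "VIS->mPFC"], 0.15)
  # planted positive group mean detected with high posterior certainty
  i <- which(fit@covariateNames == "mean")
  j <- which(fit@paramNames == "VIS->mPFC")
  idx <- (i - 1) * 9 + j
  z <- fit@beta["mean", "VIS->mPFC"] / sqrt(fit@cov[idx, idx])
  expect_gt(pnorm(z), 0.95)
  # an all-zero covariate column shrinks its effects to the prior mean
  X0 <- cbind(X, zero = 0)
  fit0 <- pebFit(post, X0)
  expect_lt(max(abs(fit0@beta["zero", ])), 1e-3)
  # duplicated covariates are rejected
  expect_error(pebFit(post, cbind(X, dup = X[, "qids"])), "rank")
})

test_that("commonality estimates ignore constant shifts of a covariate", {
  set.seed(3)
  cv <- makeCovars(24)
  X <- pebDesign(cv)
  post <- makeSubjectPosteriors(X, nullBeta(X))
  f1 <- pebFit(post, X)
  cv2 <- cv; cv2$age <- cv2$age + 100   # recentred away inside pebDesign
  f2 <- pebFit(post, pebDesign(cv2))
  expect_equal(f1@beta["mean", ], f2@beta["mean", ], tolerance = 1e-9)
})

test_that("Bayesian model reduction is exact against a refit oracle", {
  # conjugate linear-Gaussian toy: y = H theta + noise, evidence computable
  # in closed form for any prior, so BMR must match refitting exactly
  set.seed(4)
  H <- cbind(1, c(-1, 0, 1, 2, 4))
  thTrue <- c(0.5, -0.3)
  y <- drop(H %*% thTrue) + rnorm(5, 0, 0.3)
  tau <- 1 / 0.3^2
  evidence <- function(m0, v0) {
    P0 <- diag(1 / v0)
    P <- P0 + tau * crossprod(H)
    m <- solve(P, P0 %*% m0 + tau * crossprod(H, y))
    lt <- -0.5 * sum(log(2 * pi * v0)) - 0.5 * 5 * log(2 * pi / tau)
    quad <- -0.5 * (tau * sum(y^2) + drop(t(m0) %*% P0 %*% m0) -
                      drop(t(m) %*% P %*% m))
    list(F = lt + quad - 0.5 * determinant(P)$modulus, m = m,
         S = solve(P))
  }
  full <- evidence(c(0, 0), c(1, 1))
  red <- evidence(c(0, 0), c(1, 1e-8))
  got <- bmrReduce(drop(full$m), full$S, c(0, 0), c(1, 1),
                   c(0, 0), c(1, 1e-8))
  expect_equal(got$dF, as.numeric(red$F - full$F), tolerance = 1e-3)
  expect_equal(got$mu, drop(red$m), tolerance = 1e-6)
  expect_equal(got$cov, red$S, tolerance = 1e-6)

  # identity reduction changes nothing
  same <- bmrReduce(drop(full$m), full$S, c(0, 0), c(1, 1), c(0, 0), c(1, 1))
  expect_equal(same$dF, 0, tolerance = 1e-10)
  expect_equal(same$mu, drop(full$m))

  # switching off a parameter whose posterior is already near zero helps
  yNull <- drop(H %*% c(0.5, 0)) + rnorm(5, 0, 0.1)
  fullN <- evidence(c(0, 0), c(1, 1))
  postN <- {
    P0 <- diag(c(1, 1)); P <- P0 + tau * crossprod(H)
    m <- solve(P, tau * crossprod(H, yNull))
    list(m = drop(m), S = solve(P))
  }
  gotN <- bmrReduce(postN$m, postN$S, c(0, 0), c(1, 1), c(0, 0), c(1, 1e-8))
  expect_gt(gotN$dF, -0.5)
})

test_that("greedy search prunes null effects, keeps real ones, deterministically", {
  set.seed(5)
  cv <- makeCovars(40)
  X <- pebDesign(cv)
  betaNull <- nullBeta(X)
  postNull <- makeSubjectPosteriors(X, betaNull)
  fitNull <- pebFit(postNull, X)
  gsNull <- greedySearch(fitNull)
  covIdx <- which(rep(fitNull@covariateNames, each = 9) != "mean")
  meanIdxStrong <- which(rep(fitNull@covariateNames, each = 9) == "mean" &
                           rep(abs(betaNull["mean", ]) > 0, 7))
  expect_gt(mean(covIdx %in% gsNull$offSet), 0.9)   # covariate effects pruned
  expect_false(any(meanIdxStrong %in% gsNull$offSet))  # commonalities retained

  beta <- betaNull
  beta["qids", "mPFC->VS"] <- -0.03
  post <- makeSubjectPosteriors(X, beta, reSd = 0.01, obsSd = 0.03)
  fit <- pebFit(post, X)
  gs <- greedySearch(fit)
  qidsIdx <- (which(fit@covariateNames == "qids") - 1) * 9 +
    which(fit@paramNames == "mPFC->VS")
  expect_false(qidsIdx %in% gs$offSet)  # the planted effect survives
  expect_identical(gs$offSet, greedySearch(fit)$offSet)
})

test_that("model averaging weights, probabilities and symmetric cancellations", {
  set.seed(6)
  cv <- makeCovars(30)
  X <- pebDesign(cv)
  fit <- pebFit(makeSubjectPosteriors(X, nullBeta(X)), X)
  gs <- greedySearch(fit)
  avg <- bmaAverage(gs$models, fit)
  expect_equal(sum(avg@weights), 1, tolerance = 1e-12)
  expect_true(all(avg@pNonzero >= 0 & avg@pNonzero <= 1))
  # single-model average is that model
  one <- bmaAverage(gs$models[1], fit)
  expect_equal(as.numeric(t(one@effects)), gs$models[[1]]$mu)
  expect_true(all(one@pNonzero %in% c(0, 1)))
  # two equal-evidence models with opposite effects cancel
  m1 <- list(off = integer(), dF = 0, mu = rep(1, length(gs$models[[1]]$mu)),
             cov = diag(1, length(gs$models[[1]]$mu)))
  m2 <- m1; m2$mu <- -m1$mu
  sym <- bmaAverage(list(m1, m2), fit)
  expect_equal(max(abs(sym@effects)), 0, tolerance = 1e-12)
})

test_that("split-sample replication counts fits and detects planted signs", {
  set.seed(7)
  cv <- makeCovars(30)
  X <- pebDesign(cv)
  beta <- nullBeta(X)
  beta["qids", "mPFC->VS"] <- -0.03
  post <- makeSubjectPosteriors(X, beta, reSd = 0.01, obsSd = 0.03)
  sp <- splitSampleReplication(post, cv, nSplits = 25, seed = 8)
  expect_equal(sp$nFits, 50L)
  expect_equal(length(sp$values), 50L)
  expect_gte(sp$proportionNegative, 0.9)
  # odd cohort: halves differ by one, all subjects used once per split
  cv2 <- makeCovars(31)
  post2 <- makeSubjectPosteriors(pebDesign(cv2), nullBeta(pebDesign(cv2)))
  sp2 <- splitSampleReplication(post2, cv2, nSplits = 3, seed = 9)
  expect_equal(sp2$nFits, 6L)
  expect_error(splitSampleReplication(post[1:6], cv[1:6, ], nSplits = 2,
                                      seed = 1))
})

test_that("the QIDS effect sign is robust to dropping the MDE covariate", {
  set.seed(10)
  cv <- makeCovars(40)
  X <- pebDesign(cv)
  beta <- nullBeta(X)
  beta["qids", "mPFC->VS"] <- -0.03
  post <- makeSubjectPosteriors(X, beta, reSd = 0.01, obsSd = 0.03)
  full <- pebFit(post, X)
  noMde <- pebFit(post, pebDesign(cv, include = c("qids", "hads_a", "age",
                                                  "sex", "site")))
  expect_lt(full@beta["qids", "mPFC->VS"], 0)
  expect_lt(noMde@beta["qids", "mPFC->VS"], 0)
  expect_equal(sign(full@beta["qids", "mPFC->VS"]),
               sign(noMde@beta["qids", "mPFC->VS"]))
})
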