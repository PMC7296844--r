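test_that("canonical HRF peaks near 5 s and decays by 32 s", {
  dt <- 0.05
  h <- canonicalHRF(dt)
  tPeak <- (which.max(h) - 1) * dt
  expect_gt(tPeak, 4.5); expect_lt(tPeak, 5.5)
  expect_lt(abs(h[length(h)]) / max(h), 0.01)
  expect_true(all(is.finite(h)))
})

test_that("a single event at t = 0 reproduces the HRF sampled at TR", {
  tr <- 1.56; nS <- 40; mt <- 16L
  ev <- data.frame(index = 1, condition = "choice", cue_onset = 0,
                   response_onset = 1, outcome_onset = 2, action = "high",
                   forced_action = NA, outcome = 1, missed = FALSE)
  X <- buildDesign(ev, "categorical", tr = tr, nScans = nS, cueDuration = 0,
                   microtime = mt)
  hrf <- canonicalHRF(tr / mt)
  idx <- (seq_len(nS) - 1) * mt + 1
  expected <- ifelse(idx <= length(hrf), hrf[idx], 0)
  expect_equal(unname(X[, "cue_choice"]), expected, tolerance = 1e-12)
})

test_that("design has the documented columns and centring kills flat modulators", {
  cfg <- taskConfigDefault()
  sch <- generateSchedule(cfg, seed = 1)
  m <- rlModel(3)
  trl <- simulateAgent(sch, m, groupPriorDefault(m)@mu, cfg, seed = 2,
                       missRate = 0.05)
  motion <- matrix(rnorm(cfg@nScans * 6), ncol = 6)
  Xc <- buildDesign(trl, "categorical", motion = motion, tr = cfg@tr,
                    nScans = cfg@nScans)
  # 2 cue + 4 outcome + 2 response + nuisance + 6 motion (+ intercept)
  expect_equal(ncol(Xc), 15 + 1)
  Xm <- buildDesign(trl, "modulated",
                    modulatorValues = rep(1, sum(!trl$missed)),
                    motion = motion, tr = cfg@tr, nScans = cfg@nScans)
  expect_equal(ncol(Xm), 13 + 1)
  expect_lt(max(abs(Xm[, "outcome_mod"])), 1e-12)
  expect_error(buildDesign(trl, "modulated", modulatorValues = 1:3,
                           tr = cfg@tr, nScans = cfg@nScans), "align")
  late <- trl; late$outcome_onset[1] <- cfg@nScans * cfg@tr + 5
  expect_error(buildDesign(late, "categorical", tr = cfg@tr,
                           nScans = cfg@nScans), "outside")
})

test_that("categorical and binary-modulated designs span the same outcome space", {
  cfg <- taskConfigDefault()
  sch <- generateSchedule(cfg, seed = 3)
  m <- rlModel(3)
  trl <- simulateAgent(sch, m, groupPriorDefault(m)@mu, cfg, seed = 4)
  Xc <- buildDesign(trl, "categorical", tr = cfg@tr, nScans = cfg@nScans)
  Xm <- buildDesign(trl, "modulated", modulatorValues = trl$outcome,
                    tr = cfg@tr, nScans = cfg@nScans)
  outc <- Xc[, grep("^outcome", colnames(Xc))]
  outm <- Xm[, c("outcome_all", "outcome_mod")]
  # each modulated column is reproduced exactly by the categorical columns
  res <- lm.fit(outc, outm)$residuals
  expect_lt(max(abs(res)), 1e-8)
})

test_that("first-level OLS recovers noiseless coefficients and flags collinearity", {
  set.seed(5)
  X <- cbind(a = rnorm(100), b = rnorm(100), intercept = 1)
  beta <- c(2, -1, 0.5)
  fit <- fitFirstLevel(X %*% beta, X)
  expect_equal(drop(fit$betas), beta, tolerance = 1e-10, ignore_attr = TRUE)
  ce <- contrastEstimate(fit, c(a = 1, b = -1), X)
  expect_equal(unname(ce$estimate), 3, tolerance = 1e-10)
  Xbad <- cbind(X, aCopy = X[, "a"])
  expect_error(fitFirstLevel(rnorm(100), Xbad), "aCopy")
})

test_that("planted modulator amplitude is recovered with nominal CI coverage", {
  cfg <- taskConfigDefault()
  sch <- generateSchedule(cfg, seed = 6)
  m <- rlModel(3)
  trl <- simulateAgent(sch, m, groupPriorDefault(m)@mu, cfg, seed = 7)
  rpe <- rpeSeries(trl, m, groupPriorDefault(m)@mu)
  X <- buildDesign(trl, "modulated", modulatorValues = rpe$rpe, tr = cfg@tr,
                   nScans = cfg@nScans)
  set.seed(8)
  cover <- mean(vapply(1:60, function(r) {
    y <- X[, "outcome_mod"] * 1.0 + rnorm(cfg@nScans, 0, 1)
    f <- fitFirstLevel(y, X)
    ce <- contrastEstimate(f, c(outcome_mod = 1), X)
    abs(ce$estimate - 1) < qnorm(0.975) * ce$se
  }, logical(1)))
  expect_gte(cover, 0.85)
})

test_that("second-level correlation recovers planted dependence and nulls", {
  set.seed(9)
  scores <- rnbinom(60, size = 2, mu = 4.5)
  amp <- 2 - 0.1 * scores + rnorm(60, 0, 0.3)
  res <- secondLevelCorrelation(amp, scores)
  expect_lt(res$rho, -0.5)
  resPerm <- secondLevelCorrelation(amp, sample(scores))
  expect_lt(abs(resPerm$rho), 0.35)
  # single-ROI case is exactly behavioral_stats' Spearman
  expect_equal(res$rho, spearmanCor(amp, scores)$rho)
  expect_equal(res$p, spearmanCor(amp, scores)$p)
})

test_that("cluster labelling agrees with a naive depth-first oracle", {
  dfsSizes <- function(mask) {
    d <- dim(mask)
    lab <- array(0L, d)
    cur <- 0L
    sizes <- integer()
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (!mask[i, j, k] || lab[i, j, k] > 0) next
      cur <- cur + 1L
      stack <- list(c(i, j, k))
      lab[i, j, k] <- cur
      n <- 0L
      while (length(stack)) {
        v <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        n <- n + 1L
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          w <- v + c(dx, dy, dz)
          if (any(w < 1) || any(w > d)) next
          if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
            lab[w[1], w[2], w[3]] <- cur
            stack[[length(stack) + 1]] <- w
          }
        }
      }
      sizes <- c(sizes, n)
    }
    sizes
  }
  set.seed(10)
  for (r in 1:12) {
    mask <- array(runif(10 * 10 * 3) < 0.15, c(10, 10, 3))
    a <- sort(rewardConn:::.clusterSizes(mask))
    b <- sort(dfsSizes(mask))
    expect_equal(a, b, ignore_attr = TRUE)
  }
})

test_that("unsmoothed extent threshold matches a direct binomial-field oracle", {
  # with no smoothing the field is iid, so max-cluster statistics can be
  # reproduced by an independent simulation using the DFS-free oracle above
  k <- mcClusterThreshold(c(10, 10, 1), 3, 3, voxelP = 0.05, fweP = 0.01,
                          nSims = 400, seed = 11)
  maxSizes <- attr(k, "maxSizes")
  set.seed(99)
  oracleMax <- vapply(1:400, function(s) {
    m <- array(abs(rnorm(100)) > qnorm(0.975), c(10, 10, 1))
    cs <- rewardConn:::.clusterSizes(m)
    if (length(cs)) as.integer(max(cs)) else 0L
  }, integer(1))
  # same distribution: compare upper quantiles within 1 voxel
  expect_lt(abs(quantile(maxSizes, 0.99) - quantile(oracleMax, 0.99)), 2)
  expect_equal(k, as.integer(ceiling(quantile(maxSizes, 0.99, names = FALSE))),
               ignore_attr = TRUE)
})

test_that("extent threshold grows with smoothness and is seed-reproducible", {
  k1 <- mcClusterThreshold(c(12, 12, 6), 3, 3, nSims = 150, seed = 12)
  k2 <- mcClusterThreshold(c(12, 12, 6), 3, 6, nSims = 150, seed = 12)
  k3 <- mcClusterThreshold(c(12, 12, 6), 3, 9, nSims = 150, seed = 12)
  expect_lte(k1, k2); expect_lte(k2, k3)
  expect_identical(as.integer(k2),
                   as.integer(mcClusterThreshold(c(12, 12, 6), 3, 6,
                                                 nSims = 150, seed = 12)))
  expect_warning(mcClusterThreshold(c(8, 8, 2), 3, 3, nSims = 50, seed = 1),
                 "simulations")
})

test_that("conjunction masks are sign-consistent voxelwise ANDs", {
  a <- array(0, c(4, 4, 2)); b <- array(0, c(4, 4, 2))
  a[1:2, 1, 1] <- 1; b[3:4, 1, 1] <- 1
  expect_equal(sum(conjunctionMask(a, b) != 0), 0)     # disjoint -> empty
  expect_equal(conjunctionMask(a, a), a)               # identical -> identity
  b2 <- array(0, c(4, 4, 2)); b2[2:3, 1, 1] <- 1; b2[1, 2, 2] <- -1
  a2 <- a; a2[1, 2, 2] <- -1
  cj <- conjunctionMask(a2, b2)
  expect_equal(sum(cj == 1), 1)    # planted positive overlap of size 1
  expect_equal(sum(cj == -1), 1)   # sign-consistent negative overlap
  a3 <- a; a3[3, 1, 1] <- -1       # opposite signs do not conjoin
  expect_equal(conjunctionMask(a3, b)[3, 1, 1], 0)
  expect_error(conjunctionMask(a, array(0, c(2, 2, 2))), "shape")
})

test_that("ROI first principal component behaves like a PCA summary", {
  set.seed(13)
  s <- sin(seq(0, 6 * pi, length.out = 120))
  block <- rbind(s, s, s)  # identical voxels: PC1 is the standardized series
  pc <- roiFirstPC(block)
  expect_equal(abs(cor(pc, s)), 1, tolerance = 1e-10)
  expect_equal(sd(pc), 1, tolerance = 1e-12)
  expect_equal(attr(pc, "varianceExplained"), 1, tolerance = 1e-12)
  # dominant anti-correlated group decides the sign
  block2 <- rbind(s + rnorm(120, 0, 0.05), s + rnorm(120, 0, 0.05),
                  s + rnorm(120, 0, 0.05), -s + rnorm(120, 0, 0.05))
  pc2 <- roiFirstPC(block2)
  expect_gt(cor(pc2, s), 0.9)
  # eigen oracle: PC1 variance share from the covariance spectrum
  ev <- eigen(cov(t(block2)))$values
  expect_equal(attr(pc2, "varianceExplained"), ev[1] / sum(ev),
               tolerance = 1e-9)
  expect_error(roiFirstPC(matrix(1, 3, 10)), "constant")
})
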