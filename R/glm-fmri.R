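# Event-related GLM utilities: canonical HRF, design construction at
# microtime resolution, first-level OLS with contrasts, second-level rank
# correlations, Monte-Carlo cluster-extent thresholds, conjunction masks and
# first-principal-component ROI extraction.

#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF: a gamma density peaking around 5 s minus a
#' one-sixth-weighted undershoot gamma peaking around 15 s (peak delay 6,
#' undershoot delay 16, unit dispersions, 32 s support), sampled at `dt` and
#' normalised to unit sum.
#'
#' @param dt sampling interval in seconds.
#' @param duration kernel support in seconds.
#' @return numeric vector of kernel weights.
#' @export
canonicalHRF <- function(dt, duration = 32) {
  t <- seq(0, duration, by = dt)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

# Boxcar stick train at microtime resolution; heights may encode a modulator.
.deltaTrain <- function(onsets, durations, heights, nBins, dtm) {
  x <- numeric(nBins)
  if (!length(onsets)) return(x)
  if (any(onsets < 0)) stop("event before session start")
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dtm) + 1
    b <- min(max(a, a + ceiling(durations[i] / dtm) - 1), nBins)
    if (a > nBins) stop("event outside scan window")
    x[a:b] <- x[a:b] + heights[i]
  }
  x
}

.convDown <- function(x, hrf, nScans, microtime) {
  y <- convolve(x, rev(hrf), type = "open")[seq_along(x)]
  y[(seq_len(nScans) - 1) * microtime + 1]
}

#' Build an event-related first-level design matrix
#'
#' Events are modelled as truncated delta functions (boxcars at microtime
#' resolution, 16 bins per TR), convolved with the canonical HRF and sampled
#' on the TR grid. Two variants mirror the study GLMs:
#' \describe{
#'   \item{categorical}{two cue columns (choice / no-choice), four outcome
#'     columns (reward / no-reward x choice / no-choice), two response
#'     columns, plus a nuisance column for missed trials when present.}
#'   \item{modulated}{the four outcome columns are replaced by a single
#'     all-outcomes column plus one parametric modulator column (binary win
#'     or model-derived prediction error), mean-centred before convolution.}
#' }
#' Six motion covariates, when given, are appended unconvolved, and an
#' intercept column completes the matrix.
#'
#' @param events trials data.frame (see [SubjectRecord-class]).
#' @param variant "categorical" or "modulated".
#' @param modulatorValues one value per non-missed outcome event (required
#'   for the modulated variant), e.g. `rpeSeries()$rpe` or the binary win.
#' @param motion optional `nScans` x 6 matrix of motion covariates.
#' @param tr repetition time (s).
#' @param nScans number of volumes.
#' @param cueDuration,outcomeDuration event durations in seconds.
#' @param microtime bins per TR.
#' @return design matrix (`nScans` rows) with named columns.
#' @export
buildDesign <- function(events, variant = c("categorical", "modulated"),
                        modulatorValues = NULL, motion = NULL,
                        tr = 1.56, nScans = 560, cueDuration = 2,
                        outcomeDuration = 1.5, microtime = 16L) {
  variant <- match.arg(variant)
  dtm <- tr / microtime
  nBins <- nScans * microtime
  hrf <- canonicalHRF(dtm)
  ok <- !events$missed
  if (any(events$outcome_onset[ok] + outcomeDuration > nScans * tr))
    stop("event outside scan window")
  col <- function(on, dur, h = rep(1, length(on)))
    .convDown(.deltaTrain(on, rep(dur, length(on)), h, nBins, dtm),
              hrf, nScans, microtime)
  isC <- events$condition == "choice"
  X <- cbind(
    cue_choice = col(events$cue_onset[isC], cueDuration),
    cue_nochoice = col(events$cue_onset[!isC], cueDuration))
  if (variant == "categorical") {
    win <- !is.na(events$outcome) & events$outcome == 1
    for (nm in c("outcome_win_choice", "outcome_win_nochoice",
                 "outcome_nowin_choice", "outcome_nowin_nochoice")) {
      sel <- switch(nm,
        outcome_win_choice = ok & win & isC,
        outcome_win_nochoice = ok & win & !isC,
        outcome_nowin_choice = ok & !win & isC,
        outcome_nowin_nochoice = ok & !win & !isC)
      X <- cbind(X, col(events$outcome_onset[sel], outcomeDuration))
      colnames(X)[ncol(X)] <- nm
    }
  } else {
    if (is.null(modulatorValues) || length(modulatorValues) != sum(ok))
      stop("modulatorValues must align to the non-missed outcome events")
    m <- modulatorValues - mean(modulatorValues)
    X <- cbind(X,
      outcome_all = col(events$outcome_onset[ok], outcomeDuration),
      outcome_mod = col(events$outcome_onset[ok], outcomeDuration, m))
  }
  X <- cbind(X,
    response_choice = col(events$response_onset[isC & ok], 0),
    response_nochoice = col(events$response_onset[!isC & ok], 0))
  if (any(events$missed))
    X <- cbind(X, nuisance_missed = col(events$cue_onset[events$missed],
                                        cueDuration))
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == nScans)
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    X <- cbind(X, motion)
  }
  cbind(X, intercept = 1)
}

#' First-level ordinary least squares
#'
#' @param Y numeric matrix (scans x voxels/ROIs) or vector.
#' @param X design matrix from [buildDesign()].
#' @return list with `betas` (coef x units), `residualVar` (per unit),
#'   `df`, and `XtXinv` for contrast variances.
#' @export
fitFirstLevel <- function(Y, X) {
  Y <- as.matrix(Y)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qrX, Y)
  res <- Y - X %*% betas
  df <- nrow(X) - ncol(X)
  list(betas = betas, residualVar = colSums(res^2) / df, df = df,
       XtXinv = chol2inv(qr.R(qrX)))
}

#' Contrast estimate from a first-level fit
#'
#' @param fit result of [fitFirstLevel()].
#' @param contrast numeric contrast vector over design columns, or a named
#'   vector naming a subset of columns (others zero).
#' @param X the design matrix (for names when `contrast` is named).
#' @return list with `estimate` and `se` per unit.
#' @export
contrastEstimate <- function(fit, contrast, X = NULL) {
  if (!is.null(names(contrast))) {
    stopifnot(!is.null(X))
    cvec <- setNames(numeric(ncol(X)), colnames(X))
    cvec[names(contrast)] <- contrast
    contrast <- cvec
  }
  est <- drop(crossprod(contrast, fit$betas))
  se <- sqrt(drop(crossprod(contrast, fit$XtXinv %*% contrast)) *
               fit$residualVar)
  list(estimate = est, se = se)
}

#' Second-level across-subject correlation
#'
#' Rank-correlates per-subject contrast values with a per-subject score
#' (e.g. depressive symptom severity), unit by unit.
#'
#' @param contrastValues numeric vector (one unit) or subjects x units matrix.
#' @param scores per-subject scores.
#' @return data.frame with `unit`, `rho`, `p`.
#' @export
secondLevelCorrelation <- function(contrastValues, scores) {
  cv <- as.matrix(contrastValues)
  stopifnot(nrow(cv) == length(scores), nrow(cv) >= 3)
  res <- lapply(seq_len(ncol(cv)), function(j) spearmanCor(cv[, j], scores))
  data.frame(unit = seq_len(ncol(cv)),
             rho = vapply(res, `[[`, numeric(1), "rho"),
             p = vapply(res, `[[`, numeric(1), "p"))
}

# Truncated Gaussian smoothing matrix along one axis plus its row 2-norms
# (for exact variance renormalisation of the wrap-free convolution).
.smoothKernelMatrix <- function(n, sigmaVox) {
  if (sigmaVox <= 0) return(list(K = diag(n), norm2 = rep(1, n)))
  R <- max(1L, ceiling(4 * sigmaVox))
  w <- dnorm(seq(-R, R), sd = sigmaVox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - R):(i + R)
    keep <- j >= 1 & j <= n
    K[i, j[keep]] <- w[keep]
  }
  list(K = K, norm2 = sqrt(rowSums(K^2)))
}

.smoothAxis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, d[axis])
  a <- array(m, d[perm])
  aperm(a, order(perm))
}

# 26-connected components of a logical 3D array; returns cluster sizes.
.clusterSizes <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(integer())
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  shifts <- shifts[shifts[, 1] > 0 | (shifts[, 1] == 0 & shifts[, 2] > 0) |
                     (shifts[, 1] == 0 & shifts[, 2] == 0 & shifts[, 3] > 0),
                   , drop = FALSE]
  co <- arrayInd(idx, d)
  id <- match(idx, idx)
  edges <- list()
  lin <- function(m) (m[, 3] - 1) * d[1] * d[2] + (m[, 2] - 1) * d[1] + m[, 1]
  for (s in seq_len(nrow(shifts))) {
    nb <- sweep(co, 2, shifts[s, ], "+")
    okr <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(okr)) next
    nbl <- lin(nb[okr, , drop = FALSE])
    hit <- mask[nbl]
    if (!any(hit)) next
    from <- which(okr)[hit]
    to <- match(nbl[hit], idx)
    edges[[length(edges) + 1]] <- cbind(from, to)
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  igraph::components(g)$csize
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates white Gaussian fields on a voxel grid, smooths them to the
#' target FWHM (truncated separable Gaussian, sigma = FWHM / 2.355 per axis,
#' with exact variance renormalisation at the edges), thresholds two-sided at
#' `voxelP`, and records the maximum 26-connected cluster size per
#' simulation. The extent threshold is the ceiling of the `1 - fweP`
#' quantile of those maxima: clusters at least this large are rarer than
#' `fweP` under the null.
#'
#' @param gridShape integer(3) voxel grid.
#' @param voxelSizeMm isotropic voxel size (mm).
#' @param fwhmMm smoothness target (mm, >= voxelSizeMm).
#' @param voxelP two-sided voxel-level threshold.
#' @param fweP family-wise cluster-level rate.
#' @param nSims simulated fields (a warning below 100).
#' @param seed integer seed.
#' @return integer extent threshold (voxels), with attribute `"maxSizes"`.
#' @export
mcClusterThreshold <- function(gridShape, voxelSizeMm, fwhmMm,
                               voxelP = 0.05, fweP = 0.001, nSims = 1000,
                               seed = NULL) {
  stopifnot(length(gridShape) == 3, fwhmMm >= voxelSizeMm)
  if (nSims < 100) warning("fewer than 100 simulations; threshold will be noisy")
  sigmaVox <- (fwhmMm / 2.355) / voxelSizeMm
  smooth <- fwhmMm > voxelSizeMm
  ks <- lapply(gridShape, .smoothKernelMatrix, sigmaVox = if (smooth) sigmaVox else 0)
  normArr <- array(1, gridShape)
  if (smooth) {
    normArr <- outer(outer(ks[[1]]$norm2, ks[[2]]$norm2), ks[[3]]$norm2)
    dim(normArr) <- gridShape
  }
  zthr <- qnorm(1 - voxelP / 2)
  .withSeed(seed, {
    maxSizes <- vapply(seq_len(nSims), function(s) {
      f <- array(rnorm(prod(gridShape)), gridShape)
      if (smooth) for (ax in 1:3) f <- .smoothAxis(f, ks[[ax]]$K, ax)
      f <- f / normArr
      cs <- .clusterSizes(abs(f) > zthr)
      if (length(cs)) as.integer(max(cs)) else 0L
    }, integer(1))
    k <- as.integer(ceiling(quantile(maxSizes, 1 - fweP, names = FALSE)))
    attr(k, "maxSizes") <- maxSizes
    k
  })
}

#' Sign-consistent conjunction of two statistical masks
#'
#' Voxelwise AND: a voxel survives when it is nonzero in both masks with the
#' same sign; the result carries that sign.
#'
#' @param maskA,maskB numeric arrays of identical shape (signed masks) or
#'   logical arrays.
#' @return array of the common shape.
#' @export
conjunctionMask <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB))) stop("shape mismatch")
  if (is.logical(maskA) && is.logical(maskB)) return(maskA & maskB)
  keep <- maskA != 0 & maskB != 0 & sign(maskA) == sign(maskB)
  out <- array(0, dim(maskA))
  out[keep] <- sign(maskA[keep])
  out
}

#' First principal component of an ROI voxel block
#'
#' The representative ROI time series: the first principal component over
#' voxels, sign-aligned so the mean voxel loading is positive, standardised
#' to unit variance.
#'
#' @param voxelBlock voxels x time numeric matrix (>= 2 voxels).
#' @return numeric time series with attribute `"varianceExplained"` (fraction
#'   of voxel variance carried by the component).
#' @export
roiFirstPC <- function(voxelBlock) {
  stopifnot(nrow(voxelBlock) >= 2)
  if (all(apply(voxelBlock, 1, sd) == 0)) stop("constant voxel block")
  pc <- prcomp(t(voxelBlock), center = TRUE, scale. = FALSE)
  s <- pc$x[, 1]
  if (mean(pc$rotation[, 1]) < 0) s <- -s
  out <- s / sd(s)
  attr(out, "varianceExplained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  out
}
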