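# Behavioural statistics: rank correlation, Welch's t, the default Bayes
# factor for a Pearson correlation, and session summaries.

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; two-sided p from the t approximation (delegated to
#' [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p`.
#' @export
spearmanCor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant input vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided t statistic with Welch-Satterthwaite degrees of freedom
#' (delegated to [stats::t.test()]).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `t`, `df` and `p`.
#' @export
welchT <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    stop("zero variance in both groups")
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

# Jeffreys' approximate likelihood of a sample correlation r given the
# population correlation rho (n observations): the classical reduction used
# by default Bayesian correlation tests.
.corLikRatio <- function(rho, r, n) {
  exp((n - 1) / 2 * log1p(-rho^2) + (3 / 2 - n) * log1p(-rho * r))
}

#' Default Bayes factor for a Pearson correlation
#'
#' Jeffreys-style default test of H1 (rho != 0, uniform prior on (-1, 1),
#' i.e. a kappa = 1 stretched beta) against the point null rho = 0, computed
#' by numerical integration of the correlation likelihood ratio:
#' `BF10 = int_{-1}^{1} 0.5 * L(rho; r, n) / L(0; r, n) drho`.
#' Values below 1 favour the null; below 1/10 indicate strong evidence of
#' absence.
#'
#' @param x,y numeric vectors (length >= 4), or give `r` and `n` directly.
#' @param r sample Pearson correlation (used if `x` missing).
#' @param n sample size accompanying `r`.
#' @return BF10 (numeric scalar).
#' @examples
#' defaultBFCorrelation(r = 0, n = 475)  # strong evidence for the null
#' @export
defaultBFCorrelation <- function(x, y, r = NULL, n = NULL) {
  if (!missing(x)) {
    stopifnot(length(x) == length(y), length(x) >= 4)
    r <- cor(x, y)
    n <- length(x)
  }
  stopifnot(!is.null(r), !is.null(n), abs(r) < 1, n >= 4)
  int <- integrate(function(rho) 0.5 * .corLikRatio(rho, r, n),
                   lower = -1, upper = 1, rel.tol = 1e-9,
                   stop.on.error = FALSE)
  if (int$message != "OK" && int$message != "roundoff error was detected")
    stop("numerical error: BF integration failed: ", int$message)
  int$value
}

#' Summarise a subject's session
#'
#' @param subject a [SubjectRecord-class] or trials data.frame.
#' @return list with `n_rewards` (wins over the session) and `n_missed`.
#' @export
summarizeBehavior <- function(subject) {
  tr <- if (is(subject, "SubjectRecord")) subject@trials else subject
  list(n_rewards = as.integer(sum(tr$outcome == 1, na.rm = TRUE)),
       n_missed = as.integer(sum(tr$missed)))
}
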