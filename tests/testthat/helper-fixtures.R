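# Shared fixtures: tiny hand-built sessions and an independent R replay
# oracle for the RL likelihood, kept deliberately separate from the package's
# compiled implementation.

# A minimal trials data.frame with evenly spaced onsets.
makeTrials <- function(condition, action, outcome,
                       missed = rep(FALSE, length(condition)),
                       forced = ifelse(condition == "no_choice", action, NA)) {
  n <- length(condition)
  t0 <- 10 + (seq_len(n) - 1) * 12
  data.frame(index = seq_len(n), condition = condition,
             cue_onset = t0, response_onset = t0 + 4, outcome_onset = t0 + 8,
             action = action, forced_action = forced,
             outcome = ifelse(missed, NA, outcome), missed = missed,
             stringsAsFactors = FALSE)
}

# Slow, direct replay of a model: returns per-trial P(high) before update,
# the NLL over choice trials, and the RPE series. Independent of the
# compiled path (plain R, explicit case analysis).
oracleReplay <- function(trials, modelId, theta) {
  sig <- function(x) 1 / (1 + exp(-x))
  par <- switch(modelId,
    list(ac = sig(theta[1]), anc = 0, rc = exp(theta[2]), rnc = exp(theta[2])),
    list(ac = sig(theta[1]), anc = sig(theta[1]), rc = exp(theta[2]),
         rnc = exp(theta[2])),
    list(ac = sig(theta[1]), anc = sig(theta[2]), rc = exp(theta[3]),
         rnc = exp(theta[3])),
    list(ac = sig(theta[1]), anc = sig(theta[1]), rc = exp(theta[2]),
         rnc = exp(theta[3])),
    list(ac = sig(theta[1]), anc = sig(theta[2]), rc = exp(theta[3]),
         rnc = exp(theta[4])))
  q <- c(low = 0, high = 0)
  nll <- 0
  p <- rpe <- rep(NA_real_, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    if (trials$missed[i]) next
    ph <- sig(q[["high"]] - q[["low"]])
    p[i] <- ph
    a <- trials$action[i]
    ch <- trials$condition[i] == "choice"
    if (ch) nll <- nll - log(if (a == "high") ph else 1 - ph)
    alpha <- if (ch) par$ac else par$anc
    rho <- if (ch) par$rc else par$rnc
    r <- trials$outcome[i]
    rpe[i] <- rho * r - q[[a]]
    if (ch || modelId != 1) q[[a]] <- q[[a]] + alpha * rpe[i]
  }
  list(nll = nll, p = p, rpe = rpe, q = q)
}

# Simulate synthetic nine-parameter subject posteriors straight from the
# PEB generative model (no DCM inversion): theta_i = X_i beta + random
# effect + observation noise, observed with covariance obsCov.
makeSubjectPosteriors <- function(design, beta, reSd = 0.02, obsSd = 0.05) {
  n <- nrow(design)
  q <- ncol(beta)
  lapply(seq_len(n), function(i) {
    th <- drop(design[i, ] %*% beta) + rnorm(q, 0, reSd)
    mu <- th + rnorm(q, 0, obsSd)
    names(mu) <- colnames(beta)
    list(mu = mu, cov = diag(obsSd^2, q))
  })
}

# Covariate table with the layout covariates() produces.
makeCovars <- function(n, qids = NULL) {
  if (is.null(qids)) qids <- pmin(rnbinom(n, size = 2, mu = 4.5), 27)
  data.frame(subject_id = sprintf("sub-%03d", seq_len(n)), qids = qids,
             hads_a = pmin(pmax(round(7 + 0.5 * (qids - mean(qids)) +
                                        rnorm(n, 0, 2)), 0), 21),
             age = rnorm(n, 58, 9),
             sex = sample(c("F", "M"), n, TRUE),
             site = sample(c("A", "B"), n, TRUE),
             mde = sample(c("never", "past", "current"), n, TRUE,
                          prob = c(0.65, 0.2, 0.15)),
             stringsAsFactors = FALSE)
}
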