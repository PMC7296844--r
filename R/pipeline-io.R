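# Readers/writers for the on-disk formats (BIDS-like events.tsv, covariate
# CSV, ROI time-series CSV, results JSON) and the end-to-end pipeline driver.

.stopLine <- function(file, lines, what) {
  stop(sprintf("%s: malformed %s at line(s) %s", file, what,
               paste(lines, collapse = ", ")), call. = FALSE)
}

#' Write / read a session as a BIDS-like events.tsv
#'
#' Long format, one row per event: columns `onset`, `duration`,
#' `trial_type` (`cue_choice`, `cue_nochoice`, `response`, `outcome_win`,
#' `outcome_nowin`), `trial`, `condition`, `action`, `outcome`, `missed`.
#' Onsets are seconds with dot decimal separator regardless of locale.
#'
#' @param trials trials data.frame (see [SubjectRecord-class]).
#' @param file path to write / read.
#' @param config [TaskConfig-class] supplying event durations.
#' @return `readEvents`: the reconstructed trials data.frame.
#' @export
writeEvents <- function(trials, file, config = taskConfigDefault()) {
  rows <- list()
  for (i in seq_len(nrow(trials))) {
    t <- trials[i, ]
    ttype <- if (is.na(t$outcome)) "outcome_nowin" else
      if (t$outcome == 1) "outcome_win" else "outcome_nowin"
    rows[[i]] <- data.frame(
      onset = c(t$cue_onset, t$response_onset, t$outcome_onset),
      duration = c(config@cueDuration, 0, config@outcomeDuration),
      trial_type = c(paste0("cue_", sub("no_choice", "nochoice", t$condition)),
                     "response", ttype),
      trial = t$index, condition = t$condition,
      action = ifelse(is.na(t$action), "n/a", t$action),
      forced_action = ifelse(is.na(t$forced_action), "n/a", t$forced_action),
      outcome = ifelse(is.na(t$outcome), "n/a", t$outcome),
      missed = tolower(t$missed), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$onset <- sprintf("%.6f", df$onset)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeEvents
#' @param nScans,tr optional session bounds; onsets beyond `nScans * tr`
#'   trigger a validation warning.
#' @export
readEvents <- function(file, nScans = NULL, tr = NULL) {
  ev <- read.delim(file, stringsAsFactors = FALSE, dec = ".",
                   na.strings = "n/a")
  need <- c("onset", "duration", "trial_type", "trial", "condition",
            "action", "outcome", "missed")
  if (!all(need %in% names(ev)))
    stop(file, ": missing required columns: ",
         paste(setdiff(need, names(ev)), collapse = ", "))
  onum <- suppressWarnings(as.numeric(ev$onset))
  if (anyNA(onum)) .stopLine(file, which(is.na(onum)) + 1L, "onset")
  ev$onset <- onum
  if (!is.null(nScans) && !is.null(tr) && any(onum > nScans * tr))
    warning("events with onset beyond the scan session")
  byTrial <- split(ev, ev$trial)
  out <- lapply(byTrial, function(g) {
    cue <- g[startsWith(g$trial_type, "cue"), ]
    rsp <- g[g$trial_type == "response", ]
    outc <- g[startsWith(g$trial_type, "outcome"), ]
    if (nrow(cue) != 1 || nrow(rsp) != 1 || nrow(outc) != 1)
      .stopLine(file, as.integer(rownames(g)) + 1L, "trial grouping")
    data.frame(index = g$trial[1], condition = g$condition[1],
               cue_onset = cue$onset, response_onset = rsp$onset,
               outcome_onset = outc$onset,
               action = if (is.na(g$action[1])) NA_character_ else g$action[1],
               forced_action = if (is.na(g$forced_action[1])) NA_character_
                               else g$forced_action[1],
               outcome = if (is.na(outc$outcome[1])) NA_real_
                         else as.numeric(outc$outcome[1]),
               missed = as.logical(toupper(g$missed[1])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[order(as.integer(names(byTrial)))])
  rownames(out) <- NULL
  out
}

#' Write / read per-subject covariates as CSV
#' @param covars data.frame from `covariates()`.
#' @param file path.
#' @export
writeCovariates <- function(covars, file) {
  write.table(covars, file, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCovariates
#' @export
readCovariates <- function(file) {
  cv <- read.delim(file, sep = ",", stringsAsFactors = FALSE, dec = ".")
  num <- c("qids", "hads_a", "age")
  for (nm in intersect(num, names(cv))) {
    v <- suppressWarnings(as.numeric(cv[[nm]]))
    if (anyNA(v) && !anyNA(cv[[nm]]))
      .stopLine(file, which(is.na(v)) + 1L, nm)
    cv[[nm]] <- v
  }
  cv
}

#' Write / read a 3-region ROI time series as CSV
#'
#' Columns `time_s`, `vis`, `vs`, `mpfc`.
#' @param roi data.frame from [synthesizeBold()].
#' @param file path.
#' @export
writeROITimeSeries <- function(roi, file) {
  out <- roi
  for (nm in names(out)) out[[nm]] <- sprintf("%.8g", out[[nm]])
  write.table(out, file, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeROITimeSeries
#' @export
readROITimeSeries <- function(file) {
  df <- read.delim(file, sep = ",", stringsAsFactors = FALSE, dec = ".")
  need <- c("time_s", "vis", "vs", "mpfc")
  if (!all(need %in% names(df)))
    stop(file, ": expected columns ", paste(need, collapse = ", "))
  for (nm in need) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (anyNA(v)) .stopLine(file, which(is.na(v)) + 1L, nm)
    df[[nm]] <- v
  }
  df
}

#' Run the full synthetic pipeline from a configuration
#'
#' Stages: `simulate` (cohort + BOLD), `fit_behavior` (EM fit of the
#' generating model), `compare_models` (iBIC over a model set), `glm`
#' (RPE-modulated first-level design on the first subject), `fit_dcm`
#' (variational-Laplace inversion per subject + variance filter), `peb`
#' (group PEB + greedy search + BMA), `replicate` (split-sample). Results
#' are written as JSON (and per-subject CSV/TSV when `outDir` is given)
#' together with a run log recording seeds.
#'
#' @param config named list or path to a YAML file. Recognised keys (with
#'   defaults): `seed` (1), `n_subjects` (12), `generating_model` (3),
#'   `model_set` (1:5), `qids_slope` (-0.03), `snr` (1), `n_splits` (20),
#'   `free_b` (TRUE), `stages` (all).
#' @param outDir optional output directory.
#' @return invisible list of stage results.
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 1L, n_subjects = 12L, generating_model = 3L,
                   model_set = 1:5, qids_slope = -0.03, snr = 1,
                   n_splits = 20L, free_b = TRUE,
                   stages = c("simulate", "fit_behavior", "compare_models",
                              "glm", "fit_dcm", "peb", "replicate"))
  unknown <- setdiff(names(config), c(names(defaults)))
  if (length(unknown))
    stop("schema error: unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  for (key in c("seed", "n_subjects", "generating_model"))
    if (!is.numeric(cfg[[key]]))
      stop("schema error: key '", key, "' must be numeric")
  stages <- cfg$stages
  res <- list(config = cfg)
  withStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  model <- rlModel(cfg$generating_model)
  spec <- dcmSpecDefault(freeB = cfg$free_b)
  config0 <- taskConfigDefault()

  sim <- withStage("simulate",
    generateDcmCohort(cfg$n_subjects, qidsSlope = cfg$qids_slope,
                      snr = cfg$snr, seed = cfg$seed, spec = spec,
                      model = model))
  res$simulate <- list(n_subjects = length(sim$cohort),
                       mean_qids = mean(qids(sim$cohort)))

  if ("fit_behavior" %in% stages) {
    em <- withStage("fit_behavior",
      emGroupFit(sim$cohort, model, seed = cfg$seed + 1L))
    res$fit_behavior <- list(prior_mu = em$prior@mu,
                             prior_sigma2 = em$prior@sigma2,
                             converged = em$converged)
  }
  if ("compare_models" %in% stages) {
    cmp <- withStage("compare_models",
      compareModels(sim$cohort, lapply(cfg$model_set, rlModel),
                    seed = cfg$seed + 2L))
    res$compare_models <- list(ibic = as.list(ibicValues(cmp)),
                               winner = winner(cmp))
  }
  if ("glm" %in% stages) {
    res$glm <- withStage("glm", {
      s1 <- sim$cohort[[1]]
      th <- s1@trueParams
      rpe <- rpeSeries(s1, model, th)
      X <- buildDesign(trials(s1), "modulated", modulatorValues = rpe$rpe,
                       tr = config0@tr, nScans = config0@nScans)
      fit <- fitFirstLevel(as.matrix(sim$bold[[1]][, c("vis", "vs", "mpfc")]), X)
      ce <- contrastEstimate(fit, c(outcome_mod = 1), X)
      list(rpe_beta = as.list(setNames(ce$estimate, c("vis", "vs", "mpfc"))))
    })
  }
  dcmFits <- NULL
  if (any(c("fit_dcm", "peb", "replicate") %in% stages)) {
    dcmFits <- withStage("fit_dcm", lapply(seq_along(sim$cohort), function(i) {
      U <- dcmInputs(trials(sim$cohort[[i]]), config0, spec)
      invertVL(spec, sim$bold[[i]], U)
    }))
    keep <- filterSubjects(dcmFits, 10, qids(sim$cohort))
    res$fit_dcm <- list(
      mean_explained_variance = mean(keep$explainedVariance),
      n_excluded = keep$nExcluded)
  }
  if (any(c("peb", "replicate") %in% stages)) {
    post <- lapply(dcmFits, aParameters)
    cv <- covariates(sim$cohort)
    # small demo cohorts cannot support the full six-covariate design;
    # fall back to QIDS alone when subjects are scarce
    incl <- if (length(post) >= 16) c("qids", "hads_a", "age", "sex",
                                      "site", "mde") else "qids"
    if ("peb" %in% stages) {
      res$peb <- withStage("peb", {
        peb <- pebFit(post, pebDesign(cv, include = incl))
        gs <- greedySearch(peb)
        avg <- bmaAverage(gs$models, peb)
        list(qids_mpfc_vs = peb@beta["qids", "mPFC->VS"],
             bma_qids_mpfc_vs = avg@effects["qids", "mPFC->VS"],
             p_nonzero = avg@pNonzero["qids", "mPFC->VS"],
             free_energy = freeEnergy(peb))
      })
    }
    if ("replicate" %in% stages) {
      res$replicate <- withStage("replicate", {
        sp <- splitSampleReplication(post, cv, nSplits = cfg$n_splits,
                                     seed = cfg$seed + 3L, include = incl)
        list(proportion_negative = sp$proportionNegative, n_fits = sp$nFits)
      })
    }
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(res[setdiff(names(res), "config")],
                         file.path(outDir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeCovariates(covariates(sim$cohort), file.path(outDir, "covariates.csv"))
    writeEvents(trials(sim$cohort[[1]]), file.path(outDir, "sub-001_events.tsv"),
                config0)
    writeLines(c(sprintf("seed: %d", cfg$seed),
                 sprintf("R: %s", R.version.string),
                 sprintf("rewardConn: %s",
                         as.character(utils::packageVersion("rewardConn")))),
               file.path(outDir, "run.log"))
  }
  invisible(res)
}
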