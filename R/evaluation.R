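#' Stratified calibration/validation split with outlier elimination
#'
#' Samples are ranked by the target value and cut from high to low into
#' `nClasses` equal-size strata; values beyond `outlierSd` standard
#' deviations of their group mean are eliminated first; within each stratum
#' a random two-thirds (by default) enter the calibration (modelling) set
#' and the rest the validation set. Calibration quotas are allocated across
#' strata by largest remainder so the overall ratio is met exactly
#' (240 retained samples split 160/80).
#'
#' @param y target values.
#' @param ratio calibration fraction (default 2/3).
#' @param nClasses number of strata (default 3).
#' @param outlierSd outlier threshold in within-group standard deviations
#'   (default 3; `Inf` disables removal).
#' @param group optional factor (e.g. sampling date) within which the
#'   outlier rule is applied; default: all samples as one group.
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return A [DataSplit].
#' @export
#' @examples
#' sp <- splitDataset(rnorm(240), seed = 3)
#' length(validationIndices(sp))
splitDataset <- function(y, ratio = 2/3, nClasses = 3, outlierSd = 3,
                        group = NULL, seed = 1) {
  n <- length(y)
  if (n < nClasses) stop("need at least ", nClasses, " samples")
  if (is.null(group)) group <- rep(1L, n)
  mu <- stats::ave(y, group, FUN = mean)
  s <- stats::ave(y, group, FUN = stats::sd)
  keep <- which(is.na(s) | s == 0 | abs(y - mu) <= outlierSd * s)
  removed <- setdiff(seq_len(n), keep)
  if (length(keep) == 0) stop("all samples removed by the outlier rule")

  ranked <- keep[order(y[keep], decreasing = TRUE)]
  m <- length(ranked)
  base <- m %/% nClasses
  sizes <- rep(base, nClasses) + (seq_len(nClasses) <= m %% nClasses)
  stratum <- rep(seq_len(nClasses), sizes)

  nCalTotal <- round(ratio * m)
  quota <- ratio * sizes
  nCal <- floor(quota)
  rem <- nCalTotal - sum(nCal)
  if (rem > 0) {
    extra <- order(quota - floor(quota), decreasing = TRUE)[seq_len(rem)]
    nCal[extra] <- nCal[extra] + 1
  }
  nCal <- pmin(nCal, sizes)

  cal <- withSeed(seed, unlist(lapply(seq_len(nClasses), function(k) {
    members <- ranked[stratum == k]
    sort(sample(members, nCal[k]))
  })))
  new("DataSplit",
      calibration = as.integer(sort(cal)),
      validation = as.integer(sort(setdiff(keep, cal))),
      removed = as.integer(removed),
      seed = as.integer(seed))
}

#' Calibration/validation accuracy metrics
#'
#' RMSE and R2 for the calibration and validation sets (each R2 computed
#' against the mean of its own set) and the residual prediction deviation.
#' RPD is the validation-set standard deviation divided by the
#' cross-validation RMSE; `rpdP` (S_D / RMSEP) is reported alongside for
#' comparison, labelled distinctly.
#'
#' @param yCal,yhatCal measured and predicted calibration values.
#' @param yVal,yhatVal measured and predicted validation values.
#' @param rmsecv cross-validation RMSE of the calibration model (NA omits
#'   the RPD).
#' @return One-row `data.frame`: `r2c, rmsec, r2p, rmsep, rmsecv, sdVal,
#'   rpd, rpdP`.
#' @export
#' @examples
#' computeMetrics(1:3, 1:3, c(1, 2, 3), c(1, 2, 4), rmsecv = 0.5)
computeMetrics <- function(yCal, yhatCal, yVal, yhatVal, rmsecv = NA_real_) {
  if (length(yCal) != length(yhatCal) || length(yVal) != length(yhatVal))
    stop("measured and predicted vectors must match in length")
  if (length(yCal) < 2 || length(yVal) < 2)
    stop("at least 2 samples per set required")
  ssCal <- sum((yCal - mean(yCal))^2)
  ssVal <- sum((yVal - mean(yVal))^2)
  if (ssCal == 0 || ssVal == 0)
    stop("zero-variance measured values: R2 undefined")
  if (!is.na(rmsecv) && rmsecv == 0)
    stop("zero RMSECV: RPD undefined")
  rmsec <- sqrt(mean((yCal - yhatCal)^2))
  rmsep <- sqrt(mean((yVal - yhatVal)^2))
  sdVal <- stats::sd(yVal)
  data.frame(
    r2c = 1 - sum((yCal - yhatCal)^2) / ssCal,
    rmsec = rmsec,
    r2p = 1 - sum((yVal - yhatVal)^2) / ssVal,
    rmsep = rmsep,
    rmsecv = rmsecv,
    sdVal = sdVal,
    rpd = if (is.na(rmsecv)) NA_real_ else sdVal / rmsecv,
    rpdP = if (rmsep == 0) NA_real_ else sdVal / rmsep
  )
}

# preprocessing labels of the scale-comparison experiment
preprocessingLabels <- function() c("R", "SNV", paste0("CWT-", 1:10))

# samples x bands matrix for one preprocessing label, with provenance;
# `transforms` may carry precomputed matrices keyed by label
transformForLabel <- function(dataset, label, transforms = NULL) {
  if (!is.null(transforms) && !is.null(transforms[[label]])) {
    i <- if (grepl("^CWT-", label)) as.integer(sub("CWT-", "", label)) else NULL
    prov <- if (is.null(i)) list(preprocessing = label)
            else list(preprocessing = label, scaleIndex = i)
    return(list(matrix = transforms[[label]], provenance = prov))
  }
  m <- spectraMatrix(dataset)
  if (label == "R")
    return(list(matrix = m, provenance = list(preprocessing = "R")))
  if (label == "SNV")
    return(list(matrix = snvTransform(m), provenance = list(preprocessing = "SNV")))
  i <- as.integer(sub("CWT-", "", label))
  res <- cwtTransform(m, i)
  list(matrix = res$coefficients,
       provenance = list(preprocessing = label, scaleIndex = i))
}

#' Preprocessing scale comparison
#'
#' Fits a full-band model of one CFPGE parameter for each preprocessing
#' label (raw reflectance `R`, `SNV`, and the ten CWT scales `CWT-1` ..
#' `CWT-10`) on a fixed calibration set and tabulates both the calibration
#' R2 (`r2c`, in-sample) and the cross-validated R2 (`r2cv`, from the RMSECV
#' at the chosen number of latent variables). The best label is the `r2cv`
#' argmax, ties resolving to the lower scale: at these sample sizes the
#' in-sample R2 saturates for every preprocessing, so only the
#' cross-validated figure discriminates between them.
#'
#' @param dataset a [SpectraSet] with CFPGE parameters in its colData.
#' @param parameter CFPGE parameter name.
#' @param modelType `"plsr"` (default) or `"svr"`.
#' @param split optional [DataSplit]; drawn from `parameter` with `seed`
#'   when omitted.
#' @param maxLV,cvFolds PLSR controls.
#' @param seed seed for the split and fold assignment.
#' @param transforms optional named list of precomputed transformed matrices
#'   (labels as in `preprocessingLabels()`), e.g. from one [cwtAllScales()]
#'   call shared across experiments.
#' @return List with `table` (label, r2c, r2cv, nLV) and `best` (winning
#'   label).
#' @export
runScaleComparison <- function(dataset, parameter, modelType = c("plsr", "svr"),
                               split = NULL, maxLV = 10, cvFolds = 5, seed = 1,
                               transforms = NULL) {
  modelType <- match.arg(modelType)
  y <- cfpgeTable(dataset)[[parameter]]
  if (is.null(y)) stop("unknown parameter: ", parameter)
  if (is.null(split)) split <- splitDataset(y, seed = seed)
  cal <- split@calibration
  labels <- preprocessingLabels()
  rows <- lapply(labels, function(lab) {
    tf <- transformForLabel(dataset, lab, transforms)
    Xcal <- tf$matrix[cal, , drop = FALSE]
    if (modelType == "plsr") {
      fit <- fitPLSR(Xcal, y[cal], maxLV = maxLV, cvFolds = cvFolds, seed = seed,
                     parameter = parameter, provenance = tf$provenance)
      pred <- predict(fit, Xcal)
      rmsecv <- fit@rmsecv[fit@nLV]
      hp <- fit@nLV
    } else {
      fit <- fitSVR(Xcal, y[cal], seed = seed, parameter = parameter,
                    provenance = tf$provenance)
      pred <- predict(fit, Xcal)
      rmsecv <- fit@cvRMSE
      hp <- NA_integer_
    }
    ssTot <- sum((y[cal] - mean(y[cal]))^2)
    data.frame(preprocessing = lab, parameter = parameter,
               r2c = 1 - sum((y[cal] - pred)^2) / ssTot,
               r2cv = 1 - rmsecv^2 * length(cal) / ssTot,
               nLV = hp)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, best = tab$preprocessing[which.max(tab$r2cv)], split = split)
}

#' Region-fusion experiment: red-only vs fused feature sets
#'
#' Runs the full paper pipeline for one parameter under a shared split and
#' preprocessing: SPA feature selection under the red-only mask (RSF,
#' 600--800 nm) and under the full mask (FSF: blue-green + red + NIR), then
#' PLSR and/or SVR calibration on each selected set, evaluated with
#' [computeMetrics()]. Both arms use identical calibration/validation
#' samples and the identical transformed matrix.
#'
#' @param dataset a [SpectraSet].
#' @param parameter CFPGE parameter name.
#' @param models character subset of `c("plsr", "svr")`.
#' @param scaleLabel preprocessing label to model on; `NULL` (default) picks
#'   the winner of [runScaleComparison()].
#' @param maxVars largest SPA subset size (default 15).
#' @param split optional [DataSplit].
#' @param nMcSplits Monte-Carlo splits for the SVR grid search (default 50).
#' @param seed seed shared by split, folds and grid search.
#' @param transforms optional precomputed transform cache, as in
#'   [runScaleComparison()].
#' @return List with `reports` (one row per arm x model), `selections`
#'   (FeatureSelection per arm), `split`, `scaleLabel` and the scale table
#'   when it was computed.
#' @export
runRegionExperiment <- function(dataset, parameter, models = c("plsr", "svr"),
                                scaleLabel = NULL, maxVars = 15, split = NULL,
                                nMcSplits = 50, seed = 1, transforms = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  y <- cfpgeTable(dataset)[[parameter]]
  if (is.null(y)) stop("unknown parameter: ", parameter)
  if (is.null(split)) split <- splitDataset(y, seed = seed)
  scaleTable <- NULL
  if (is.null(scaleLabel)) {
    sc <- runScaleComparison(dataset, parameter, split = split, seed = seed,
                             transforms = transforms)
    scaleLabel <- sc$best
    scaleTable <- sc$table
  }
  tf <- transformForLabel(dataset, scaleLabel, transforms)
  wl <- wavelengths(dataset)
  cal <- split@calibration
  val <- split@validation

  arms <- list(RSF = regionMask(wl, "red"),
               FSF = regionMask(wl, c("blue_green", "red", "nir")))
  selections <- list()
  reports <- list()
  for (arm in names(arms)) {
    fs <- spaSelect(tf$matrix, y, split, wavelengths = wl, mask = arms[[arm]],
                    maxVars = maxVars, parameter = parameter)
    selections[[arm]] <- fs
    colIdx <- match(fs@wavelengths, wl)
    Xsel <- tf$matrix[, colIdx, drop = FALSE]
    prov <- c(tf$provenance, list(featureSet = arm))
    for (model in models) {
      if (model == "plsr") {
        fit <- fitPLSR(Xsel[cal, , drop = FALSE], y[cal],
                       maxLV = min(10, length(colIdx)), seed = seed,
                       wavelengths = fs@wavelengths, parameter = parameter,
                       provenance = prov)
        rmsecv <- fit@rmsecv[fit@nLV]
        hyper <- sprintf("nLV=%d", fit@nLV)
      } else {
        fit <- fitSVR(Xsel[cal, , drop = FALSE], y[cal], nMcSplits = nMcSplits,
                      seed = seed, wavelengths = fs@wavelengths,
                      parameter = parameter, provenance = prov)
        rmsecv <- fit@cvRMSE
        hyper <- sprintf("c=%.4g,g=%.4g", fit@cost, fit@gamma)
      }
      met <- computeMetrics(y[cal], predict(fit, Xsel[cal, , drop = FALSE]),
                            y[val], predict(fit, Xsel[val, , drop = FALSE]),
                            rmsecv = rmsecv)
      reports[[paste(arm, model, sep = ".")]] <- cbind(
        data.frame(parameter = parameter, preprocessing = scaleLabel,
                   featureSet = arm, model = model,
                   nSelected = fs@chosenSize, hyperparameters = hyper),
        met)
    }
  }
  list(reports = do.call(rbind, reports), selections = selections,
       split = split, scaleLabel = scaleLabel, scaleTable = scaleTable)
}

#' Write experiment tables and a run manifest
#'
#' Writes a preprocessing-by-parameter calibration-R2 matrix, the long-form
#' region-experiment reports, and a JSON manifest (seed, package version,
#' any extra fields). Output is deterministic: re-running with identical
#' inputs reproduces byte-identical files.
#'
#' @param outDir output directory (created if absent).
#' @param scaleTables optional list of (or single) scale-comparison tables.
#' @param regionReports optional `data.frame` of region-experiment reports.
#' @param manifest named list stored as `manifest.json`.
#' @return Invisibly, the paths written.
#' @export
reportTables <- function(outDir, scaleTables = NULL, regionReports = NULL,
                         manifest = list()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(scaleTables)) {
    if (is.data.frame(scaleTables)) scaleTables <- list(scaleTables)
    long <- do.call(rbind, scaleTables)
    wide <- data.frame(preprocessing = preprocessingLabels())
    for (par in unique(long$parameter))
      wide[[par]] <- long$r2c[match(
        paste(wide$preprocessing, par),
        paste(long$preprocessing, long$parameter))]
    f <- file.path(outDir, "scale_comparison_r2c.csv")
    utils::write.csv(wide, f, row.names = FALSE)
    paths <- c(paths, f)
  }
  if (!is.null(regionReports)) {
    f <- file.path(outDir, "region_experiment_reports.csv")
    utils::write.csv(regionReports, f, row.names = FALSE)
    paths <- c(paths, f)
  }
  manifest <- c(list(package = "fluorspec",
                     version = as.character(utils::packageVersion("fluorspec"))),
                manifest)
  f <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, f)
  invisible(paths)
}
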