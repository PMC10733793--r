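#' @importFrom data.table fread fwrite
#' @importFrom jsonlite write_json read_json
#' @importFrom yaml read_yaml write_yaml
NULL

#' Write / read spectra as CSV
#'
#' Layout: first column `sample_id`, then one column per band named by its
#' integer wavelength in nm. Wavelet coefficient sets use the same layout;
#' their scale index and edge flags travel in a JSON sidecar
#' (`<path>.meta.json`).
#'
#' @param x a [SpectraSet] (or [WaveletSet]).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeSpectraCSV <- function(x, path) {
  m <- spectraMatrix(x)
  dt <- data.table::as.data.table(m)
  data.table::setnames(dt, as.character(wavelengths(x)))
  dt <- cbind(data.table::data.table(sample_id = colnames(x)), dt)
  data.table::fwrite(dt, path)
  if (is(x, "WaveletSet")) {
    jsonlite::write_json(
      list(scale_index = scaleIndex(x),
           edge_affected_bands = wavelengths(x)[edgeAffected(x)]),
      paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeSpectraCSV
#' @param paramPath optional CSV of CFPGE parameters (keyed by `sample_id`)
#'   to attach as colData.
#' @return `readSpectraCSV` returns a [SpectraSet].
#' @export
readSpectraCSV <- function(path, paramPath = NULL) {
  dt <- data.table::fread(path, header = TRUE)
  wl <- as.numeric(colnames(dt)[-1])
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$sample_id
  sdata <- data.frame(sample_id = dt$sample_id, row.names = dt$sample_id)
  if (!is.null(paramPath)) {
    par <- as.data.frame(data.table::fread(paramPath))
    rownames(par) <- par$sample_id
    sdata <- par[dt$sample_id, , drop = FALSE]
  }
  SpectraSet(m, wl, sampleData = sdata)
}

#' Write / read the CFPGE parameter table as CSV
#'
#' Columns are named exactly `Pn, Tr, gs, Ci, PhiPSII, FvFm, FvF0, qP, NPQ,
#' ETR`, keyed by `sample_id`; raw fluorescence and scenario columns are
#' carried along when present.
#'
#' @param x a [SpectraSet] or a `data.frame` with a `sample_id` column.
#' @param path CSV path.
#' @return Invisibly `path`; `readCFPGECSV` returns a `data.frame`.
#' @export
writeCFPGECSV <- function(x, path) {
  tab <- if (is(x, "SpectraSet")) cfpgeTable(x) else as.data.frame(x)
  if (!"sample_id" %in% colnames(tab))
    tab <- cbind(sample_id = rownames(tab), tab)
  data.table::fwrite(tab, path)
  invisible(path)
}

#' @rdname writeCFPGECSV
#' @export
readCFPGECSV <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Serialise a feature selection to CSV + JSON sidecar
#'
#' CSV columns: `wavelength, region, order`; the JSON sidecar stores the
#' validation-RMSE curve, chosen size, start wavelength and the
#' collinearity diagnostic.
#'
#' @param fs a [FeatureSelection].
#' @param path CSV path (sidecar at `<path>.json`).
#' @return Invisibly, `path`.
#' @export
writeFeatureSelectionCSV <- function(fs, path) {
  utils::write.csv(
    data.frame(wavelength = fs@wavelengths, region = fs@regionLabels,
               order = fs@selectionOrder),
    path, row.names = FALSE)
  jsonlite::write_json(
    list(parameter = fs@parameter, chosen_size = fs@chosenSize,
         start_wavelength = fs@startWavelength,
         max_abs_correlation = fs@maxAbsCorrelation,
         rmse_curve = fs@rmseCurve),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialise a model to JSON (no opaque binary formats)
#'
#' PLSR models store their coefficient arrays directly; SVR models store the
#' support vectors, dual coefficients and kernel parameters, from which
#' [predict][fitSVR] reconstructs the decision function exactly.
#'
#' @param model a [PLSRModel] or [SVRModel].
#' @param path JSON path.
#' @return Invisibly, `path`.
#' @export
writeModelJSON <- function(model, path) {
  if (is(model, "PLSRModel")) {
    doc <- list(
      type = "plsr",
      parameter = model@parameter,
      n_latent_variables = model@nLV,
      coefficients = model@coefficients,
      intercept = model@intercept,
      weights = model@weights,
      loadings = model@loadings,
      y_loadings = model@yLoadings,
      x_means = model@xMeans, x_scales = model@xScales, y_mean = model@yMean,
      rmsecv = model@rmsecv,
      feature_wavelengths = model@featureWavelengths,
      provenance = model@provenance)
  } else if (is(model, "SVRModel")) {
    doc <- list(
      type = "svr",
      parameter = model@parameter,
      c = model@cost, g = model@gamma, epsilon = model@epsilon,
      support_vectors = unclass(model@fit$SV),
      dual_coefficients = as.numeric(model@fit$coefs),
      rho = model@fit$rho,
      cv_rmse = model@cvRMSE,
      x_means = model@xMeans, x_scales = model@xScales,
      y_mean = model@yMean, y_scale = model@yScale,
      feature_wavelengths = model@featureWavelengths,
      provenance = model@provenance)
  } else stop("unsupported model class: ", class(model))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModelJSON
#' @return `readModelJSON` returns the reconstructed model object.
#' @export
readModelJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (doc$type == "plsr") {
    new("PLSRModel",
        coefficients = as.numeric(doc$coefficients),
        intercept = doc$intercept,
        nLV = as.integer(doc$n_latent_variables),
        weights = as.matrix(doc$weights),
        loadings = as.matrix(doc$loadings),
        yLoadings = as.numeric(doc$y_loadings),
        xMeans = as.numeric(doc$x_means),
        xScales = as.numeric(doc$x_scales),
        yMean = doc$y_mean,
        rmsecv = as.numeric(doc$rmsecv),
        featureWavelengths = as.numeric(doc$feature_wavelengths),
        parameter = doc$parameter,
        provenance = as.list(doc$provenance))
  } else if (doc$type == "svr") {
    new("SVRModel",
        fit = list(SV = as.matrix(doc$support_vectors),
                   coefs = as.numeric(doc$dual_coefficients),
                   rho = doc$rho),
        cost = doc$c, gamma = doc$g, epsilon = doc$epsilon,
        gridRMSE = matrix(NA_real_, 0, 0),
        cvRMSE = doc$cv_rmse,
        xMeans = as.numeric(doc$x_means),
        xScales = as.numeric(doc$x_scales),
        yMean = doc$y_mean, yScale = doc$y_scale,
        featureWavelengths = as.numeric(doc$feature_wavelengths),
        parameter = doc$parameter,
        provenance = as.list(doc$provenance))
  } else stop("unknown model type in ", path)
}

#' Read / write a simulation configuration (YAML or JSON)
#'
#' The file mirrors [defaultSimConfig()]: scenario list (group, day,
#' n_samples), band features, noise and scatter levels and the base seed.
#' Format is chosen by extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path configuration file path.
#' @return `readSimConfig` returns a config list for [generateDataset()].
#' @export
readSimConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  asRows <- function(x) {
    if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
    else x
  }
  scen <- lapply(asRows(raw$scenarios), function(s)
    salinityScenario(s$group, day = s$day, nSamples = s$n_samples))
  feats <- do.call(rbind, lapply(asRows(raw$features), function(f)
    bandFeature(f$center, f$width, f$depth_coefficient, f$driver)))
  if (is.null(feats)) feats <- defaultBandFeatures()
  base <- defaultSimConfig(seed = if (is.null(raw$seed)) 1 else raw$seed)
  base$scenarios <- scen
  base$features <- feats
  for (fld in c("noiseSd", "noiseScale", "par"))
    if (!is.null(raw[[fld]])) base[[fld]] <- raw[[fld]]
  if (!is.null(raw$scatterSd)) base$scatterSd <- unlist(raw$scatterSd)
  base
}

#' @rdname readSimConfig
#' @param config a config list as from [defaultSimConfig()].
#' @export
writeSimConfig <- function(config, path) {
  doc <- list(
    scenarios = lapply(config$scenarios, function(s)
      list(group = s$group, day = s$day, n_samples = s$nSamples)),
    features = lapply(seq_len(nrow(config$features)), function(i) {
      f <- config$features[i, ]
      list(center = f$center, width = f$width,
           depth_coefficient = f$depthCoefficient, driver = f$driver)
    }),
    noiseSd = config$noiseSd,
    scatterSd = as.list(config$scatterSd),
    noiseScale = config$noiseScale,
    par = config$par,
    seed = config$seed)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(doc, path)
  else jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                            digits = NA)
  invisible(path)
}
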