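# NOx quantification: min-max scaling, goodness-of-fit metrics, grid-searched
# support-vector regression with 10-fold cross-validation, prediction with
# extrapolation flagging, and site-specific local calibration.

#' Coefficient of determination (squared Pearson correlation)
#'
#' The R2 used throughout this package is the squared Pearson correlation
#' between observed and predicted values. Note this is not 1 - SSres/SStot:
#' it is invariant under any affine transform of the predictions (a
#' perfectly anticorrelated prediction also scores 1), which is why model
#' selection uses RMSE instead.
#'
#' @param observed,predicted numeric vectors of equal length >= 2
#' @return value in [0, 1], or NaN (with a warning) when either vector is
#'   constant
#' @export
rSquared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    .stopValidation("observed and predicted must have equal length")
  if (length(observed) < 2L) .stopValidation("need at least 2 points")
  if (stats::sd(observed) < 1e-15 || stats::sd(predicted) < 1e-15) {
    warning("R2 undefined for a constant vector; returning NaN", call. = FALSE)
    return(NaN)
  }
  stats::cor(observed, predicted)^2
}

#' Root mean square error
#'
#' @param observed,predicted numeric vectors of equal length >= 1
#' @return sqrt of the mean squared residual, >= 0
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    .stopValidation("observed and predicted must have equal length")
  if (!length(observed)) .stopValidation("empty vectors")
  sqrt(mean((predicted - observed)^2))
}

#' Fit a min-max scaler onto [-1, +1]
#'
#' @param x numeric matrix (rows = samples) or vector
#' @return a \code{FeatureScaler}
#' @export
fitScaler <- function(x) {
  x <- as.matrix(x)
  if (!nrow(x)) .stopValidation("need at least one row")
  if (any(!is.finite(x))) .stopValidation("non-finite values in features")
  new("FeatureScaler", mins = apply(x, 2, min), maxs = apply(x, 2, max))
}

#' Apply a min-max scaler
#'
#' Training minima map to -1 and maxima to +1; constant features map to 0;
#' values outside the training range map outside [-1, +1] (affine extension,
#' no clipping).
#'
#' @param scaler a \code{FeatureScaler}
#' @param x matrix or vector with the same number of features
#' @return scaled matrix
#' @export
applyScaler <- function(scaler, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(scaler@mins))
    .stopValidation("feature count mismatch with the scaler")
  span <- scaler@maxs - scaler@mins
  out <- x
  for (j in seq_len(ncol(x))) {
    out[, j] <- if (span[j] > 0)
      2 * (x[, j] - scaler@mins[j]) / span[j] - 1 else 0
  }
  out
}

#' Invert a min-max scaler
#'
#' @param scaler a \code{FeatureScaler}
#' @param x scaled matrix or vector
#' @return matrix on the original scale (constant features return the
#'   training constant)
#' @export
invertScaler <- function(scaler, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(scaler@mins))
    .stopValidation("feature count mismatch with the scaler")
  span <- scaler@maxs - scaler@mins
  out <- x
  for (j in seq_len(ncol(x))) {
    out[, j] <- if (span[j] > 0)
      (x[, j] + 1) / 2 * span[j] + scaler@mins[j] else scaler@mins[j]
  }
  out
}

#' Absorbance feature matrix of spectra over a wavelength window
#'
#' Features are the absorbances at every grid point inside the window
#' (default 200--245 nm: 91 features at 0.5 nm, where the NOx signal lives).
#'
#' @param spectra list of \code{Spectrum}/\code{NOxSpectrum}, or a numeric
#'   matrix already in feature form (returned unchanged)
#' @param windowNm c(min, max) window in nm
#' @return samples-by-wavelengths matrix with wavelength column names
#' @export
featureMatrix <- function(spectra, windowNm = c(200, 245)) {
  if (is.matrix(spectra)) return(spectra)
  if (is(spectra, "Spectrum") || is(spectra, "NOxSpectrum"))
    spectra <- list(spectra)
  rows <- lapply(spectra, function(s) {
    wl <- wavelengths(s)
    if (wl[1] > windowNm[1] + .WL_TOL || wl[length(wl)] < windowNm[2] - .WL_TOL)
      .stopValidation("spectrum does not cover the feature window ",
                      windowNm[1], "-", windowNm[2], " nm")
    keep <- wl >= windowNm[1] - .WL_TOL & wl <= windowNm[2] + .WL_TOL
    stats::setNames(absorbance(s)[keep], format(wl[keep]))
  })
  do.call(rbind, rows)
}

.kernelMatrix <- function(kernel, X, Y, gamma, degree = 3, coef0 = 0) {
  switch(kernel,
         linear = X %*% t(Y),
         polynomial = (gamma * (X %*% t(Y)) + coef0)^degree,
         radial = {
           d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
           exp(-gamma * pmax(d2, 0))
         },
         sigmoid = tanh(gamma * (X %*% t(Y)) + coef0),
         .stopValidation("unknown kernel: ", kernel))
}

.svrPredictScaled <- function(model, Xs) {
  K <- .kernelMatrix(model@kernel, Xs, model@sv, model@gamma,
                     model@degree, model@coef0)
  as.numeric(K %*% model@svCoefs - model@rho)
}

.fitSvr <- function(Xs, ys, kernel, C, gamma, epsilon) {
  e1071::svm(x = Xs, y = ys, type = "eps-regression", kernel = kernel,
             cost = C, gamma = gamma, epsilon = epsilon, scale = FALSE)
}

.svmPredict <- function(fit, Xs) as.numeric(stats::predict(fit, Xs))

#' Grid-searched SVR training with 10-fold cross-validation
#'
#' Exhaustively searches the C x gamma grid; for each tuple the data are
#' split into seeded folds and the pooled validation RMSE (in mg-N/L, after
#' inverse label scaling) is computed. The best tuple (ties broken toward
#' smaller C, then smaller gamma) is refit on all data. Features and labels
#' are min-max scaled to [-1, +1] from the full training set before the
#' search; selection uses RMSE rather than R2 because the squared-correlation
#' R2 is blind to affine distortions.
#'
#' @param spectra list of \code{Spectrum}/\code{NOxSpectrum} or a feature
#'   matrix
#' @param labels combined NOx-N concentrations, mg-N/L, >= 0
#' @param cGrid,gammaGrid search grids
#' @param epsilon insensitivity margin in scaled label units
#' @param folds number of CV folds (default 10)
#' @param seed RNG seed for the fold shuffle
#' @param kernel kernel name, default \code{"radial"} (RBF)
#' @param windowNm feature wavelength window
#' @return list with \code{model} (a \code{NOxRegressor}) and \code{report}
#'   (a \code{CVReport})
#' @export
gridSearchTrain <- function(spectra, labels,
                            cGrid = c(0.1, 1, 10, 100, 1000),
                            gammaGrid = c(0.001, 0.01, 0.1, 1),
                            epsilon = 0.001, folds = 10, seed = 1,
                            kernel = "radial", windowNm = c(200, 245)) {
  X <- featureMatrix(spectra, windowNm)
  y <- as.numeric(labels)
  n <- nrow(X)
  if (length(y) != n) .stopValidation("one label per spectrum required")
  if (any(y < 0)) .stopValidation("labels must be >= 0 mg-N/L")
  if (n < folds)
    .stopConfig("fewer samples (", n, ") than folds (", folds, ")")
  fScaler <- fitScaler(X)
  lScaler <- fitScaler(matrix(y, ncol = 1))
  Xs <- applyScaler(fScaler, X)
  ys <- as.numeric(applyScaler(lScaler, matrix(y, ncol = 1)))
  set.seed(seed)
  foldAssign <- sample(rep_len(seq_len(folds), n))
  unscale <- function(p) as.numeric(invertScaler(lScaler, matrix(p, ncol = 1)))

  cvPred <- function(C, gamma) {
    pred <- numeric(n)
    for (f in seq_len(folds)) {
      hold <- foldAssign == f
      fit <- .fitSvr(Xs[!hold, , drop = FALSE], ys[!hold], kernel, C, gamma,
                     epsilon)
      pred[hold] <- .svmPredict(fit, Xs[hold, , drop = FALSE])
    }
    unscale(pred)
  }

  grid <- expand.grid(C = cGrid, gamma = gammaGrid)
  scores <- vapply(seq_len(nrow(grid)),
                   function(i) rmse(y, cvPred(grid$C[i], grid$gamma[i])),
                   numeric(1))
  trace <- cbind(grid, cv_rmse = scores)
  ord <- order(scores, grid$C, grid$gamma)
  best <- ord[1]
  C <- grid$C[best]; gamma <- grid$gamma[best]

  predBest <- cvPred(C, gamma)
  perFold <- do.call(rbind, lapply(seq_len(folds), function(f) {
    hold <- foldAssign == f
    data.frame(fold = f, n = sum(hold),
               r2 = if (sum(hold) >= 2)
                 suppressWarnings(rSquared(y[hold], predBest[hold]))
               else NA_real_,
               rmse = rmse(y[hold], predBest[hold]))
  }))

  fit <- .fitSvr(Xs, ys, kernel, C, gamma, epsilon)
  model <- new("NOxRegressor", kernel = kernel, cost = C, gamma = gamma,
               epsilon = epsilon, degree = 3, coef0 = 0,
               featureScaler = fScaler, labelScaler = lScaler,
               windowNm = as.numeric(windowNm),
               wavelengthsNm = as.numeric(colnames(X) %||% seq_len(ncol(X))),
               sv = as.matrix(fit$SV), svCoefs = as.numeric(fit$coefs),
               rho = as.numeric(fit$rho), nSamples = n, maxLabel = max(y))
  trainPred <- unscale(.svrPredictScaled(model, Xs))
  report <- new("CVReport", folds = as.integer(folds),
                foldAssign = as.integer(foldAssign), perFold = perFold,
                cvR2 = rSquared(y, predBest), cvRmse = rmse(y, predBest),
                trainR2 = rSquared(y, trainPred),
                trainRmse = rmse(y, trainPred), trace = trace, seed = seed)
  list(model = model, report = report)
}

#' Predict relative NOx-N concentration from isolated NOx spectra
#'
#' Extracts the model's wavelength window, scales features, evaluates the
#' kernel expansion, inverse-transforms the label and clips at 0 mg-N/L.
#' Predictions above the training maximum are flagged in the
#' \code{"extrapolated"} attribute.
#'
#' @param model a \code{NOxRegressor}
#' @param x a \code{NOxSpectrum}/\code{Spectrum}, list of them, or feature
#'   matrix covering the model window
#' @return numeric vector of mg-N/L (relative to baseline), with a logical
#'   attribute \code{extrapolated}
#' @export
predictNox <- function(model, x) {
  X <- featureMatrix(x, model@windowNm)
  if (ncol(X) != length(model@wavelengthsNm))
    .stopValidation("spectrum resolution does not match the model window (",
                    length(model@wavelengthsNm), " features expected)")
  Xs <- applyScaler(model@featureScaler, X)
  raw <- as.numeric(invertScaler(model@labelScaler,
                                 matrix(.svrPredictScaled(model, Xs),
                                        ncol = 1)))
  out <- pmax(raw, 0)
  attr(out, "extrapolated") <- raw > model@maxLabel + 1e-12
  out
}

.REG_SCHEMA <- "nox-regressor-1"

#' Persist a trained NOx regressor as JSON
#'
#' The full kernel expansion (support vectors, coefficients, offset) plus
#' both scalers are stored, so the file alone reproduces predictions.
#'
#' @param model a \code{NOxRegressor}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
saveNoxRegressor <- function(model, path) {
  obj <- list(schema = .REG_SCHEMA, kernel = model@kernel, C = model@cost,
              gamma = model@gamma, epsilon = model@epsilon,
              degree = model@degree, coef0 = model@coef0,
              feature_mins = model@featureScaler@mins,
              feature_maxs = model@featureScaler@maxs,
              label_min = model@labelScaler@mins,
              label_max = model@labelScaler@maxs,
              window_nm = model@windowNm,
              wavelengths_nm = model@wavelengthsNm,
              sv = model@sv, sv_coefs = model@svCoefs, rho = model@rho,
              n_samples = model@nSamples, max_label = model@maxLabel)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a NOx regressor persisted by \code{\link{saveNoxRegressor}}
#'
#' @param path JSON model bundle
#' @return a \code{NOxRegressor}
#' @export
readNoxRegressor <- function(path) {
  if (!file.exists(path)) .stopConfig("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, .REG_SCHEMA))
    .stopConfig("unrecognized regressor schema: ", obj$schema)
  new("NOxRegressor", kernel = obj$kernel, cost = obj$C, gamma = obj$gamma,
      epsilon = obj$epsilon, degree = obj$degree, coef0 = obj$coef0,
      featureScaler = new("FeatureScaler", mins = obj$feature_mins,
                          maxs = obj$feature_maxs),
      labelScaler = new("FeatureScaler", mins = obj$label_min,
                        maxs = obj$label_max),
      windowNm = obj$window_nm, wavelengthsNm = obj$wavelengths_nm,
      sv = as.matrix(obj$sv), svCoefs = obj$sv_coefs, rho = obj$rho,
      nSamples = as.integer(obj$n_samples), maxLabel = obj$max_label)
}

#' Fit a site-specific local calibration line
#'
#' Least squares of laboratory NOx-N values against raw model predictions:
#' lab = slope * predicted + intercept.
#'
#' @param predicted raw model predictions, mg-N/L
#' @param lab laboratory measurements, mg-N/L
#' @return a \code{LocalCalibration}
#' @export
fitLocalCalibration <- function(predicted, lab) {
  if (length(predicted) != length(lab))
    .stopValidation("predicted and lab must have equal length")
  if (length(predicted) < 2L)
    .stopValidation("need >= 2 calibration points")
  if (stats::sd(predicted) < 1e-12)
    .stopNumerical("rank deficiency: all predicted values are identical")
  fit <- stats::lm(lab ~ predicted)
  new("LocalCalibration", slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r2 = suppressWarnings(rSquared(lab, stats::fitted(fit))),
      n = length(lab))
}

#' Apply a local calibration to raw predictions
#'
#' @param cal a \code{LocalCalibration}
#' @param predicted raw predictions, mg-N/L
#' @return calibrated values, mg-N/L
#' @export
applyCalibration <- function(cal, predicted) {
  cal@slope * predicted + cal@intercept
}
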