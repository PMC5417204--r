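#' Fit a single-response PLSR model (NIPALS)
#'
#' Sequential latent-variable extraction: after mean-centring X and y, each
#' component takes the weight vector w proportional to X'y (unit norm),
#' scores t = Xw, x-loading p = X't/(t't), y-loading q = y't/(t't), then
#' deflates X <- X - t p' and y <- y - q t. The regression vector is
#' beta = W (P'W)^-1 q, so prediction is a single affine map of the raw
#' spectrum.
#'
#' @param X Numeric matrix, one preprocessed spectrum per row.
#' @param y Numeric response (percent of stated content).
#' @param a Number of latent components (default 3).
#' @param grid Optional wavelength grid recorded for input checking.
#' @return Object of class `plsr_model`.
#' @export
fit_plsr <- function(X, y, a = 3L, grid = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X); a <- as.integer(a)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (a < 1L) stop("a must be >= 1", call. = FALSE)
  if (n < a + 1L) stop(sprintf("need at least a + 1 = %d samples, got %d", a + 1L, n),
                       call. = FALSE)
  if (stats::sd(y) == 0) stop("constant y: no concentration signal to fit", call. = FALSE)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xd <- sweep(X, 2L, x_mean); yd <- y - y_mean
  W <- matrix(0, p, a); P <- matrix(0, p, a); q <- numeric(a)
  for (j in seq_len(a)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop(sprintf("component %d: residual X carries no covariance with y (a exceeds the usable rank)", j),
           call. = FALSE)
    }
    w <- w / nw
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-24) stop(sprintf("component %d: degenerate scores", j), call. = FALSE)
    pj <- drop(crossprod(Xd, t_)) / tt
    qj <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, pj)
    yd <- yd - qj * t_
    W[, j] <- w; P[, j] <- pj; q[j] <- qj
  }
  beta <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(x_mean = x_mean, y_mean = y_mean, weights = W, loadings = P,
                 y_loadings = q, coefficients = beta, a = a, grid = grid),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent component(s), %d channels\n",
              x$a, length(x$coefficients)))
  invisible(x)
}

predict_linear <- function(object, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
  if (ncol(X) != length(object$x_mean)) {
    stop("prediction input has the wrong number of spectral channels", call. = FALSE)
  }
  if (!is.null(object$grid) && !is.null(colnames(X))) {
    # colnames are only advisory; the hard grid check is on spectrum inputs
  }
  drop(object$y_mean + sweep(X, 2L, object$x_mean) %*% object$coefficients)
}

#' Predict content from spectra
#'
#' yhat = y_mean + (x - x_mean)' beta. Spectrum-object inputs are checked
#' against the model's training grid.
#'
#' @param object A `plsr_model` (or `pcr_model`).
#' @param newdata Numeric matrix (rows = spectra), a single numeric vector,
#'   or a list of `nir_spectrum` objects.
#' @param ... Unused.
#' @return Numeric vector of predicted percent content.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.data.frame(newdata) && !is.matrix(newdata) &&
      inherits(newdata[[1L]], "nir_spectrum")) {
    if (!is.null(object$grid)) {
      for (s in newdata) if (!same_grid(s$wavelengths, object$grid)) {
        stop("spectrum is not on the model's training wavelength grid", call. = FALSE)
      }
    }
    newdata <- do.call(rbind, lapply(newdata, function(s) s$values))
  }
  predict_linear(object, newdata)
}

#' @export
predict.pcr_model <- function(object, newdata, ...) predict.plsr_model(object, newdata, ...)

#' Leave-one-out cross-validated predictions
#'
#' Each sample's content is predicted by a calibration fitted without that
#' sample.
#'
#' @inheritParams fit_plsr
#' @param fit_fun Calibration fitter, default [fit_plsr()] (use [fit_pcr()]
#'   for the principal-components alternative).
#' @return Numeric vector of cross-validated predictions.
#' @export
loocv_predict <- function(X, y, a = 3L, fit_fun = fit_plsr) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < a + 2L) {
    stop(sprintf("leave-one-out needs at least a + 2 = %d samples, got %d", a + 2L, n),
         call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    m <- fit_fun(X[-i, , drop = FALSE], y[-i], a)
    predict_linear(m, X[i, , drop = FALSE])
  }, numeric(1))
}

#' Principal components regression (alternative calibration)
#'
#' Regresses y on the top-a principal component scores of X; same prediction
#' contract as [fit_plsr()]. Kept as the comparison method that tends to
#' waste components on concentration-irrelevant variance.
#'
#' @inheritParams fit_plsr
#' @return Object of class `pcr_model` (shares the linear prediction
#'   contract of `plsr_model`).
#' @export
fit_pcr <- function(X, y, a = 3L, grid = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); a <- as.integer(a)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (a < 1L) stop("a must be >= 1", call. = FALSE)
  if (n < a + 1L) stop(sprintf("need at least a + 1 = %d samples", a + 1L), call. = FALSE)
  if (stats::sd(y) == 0) stop("constant y: no concentration signal to fit", call. = FALSE)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xd <- sweep(X, 2L, x_mean)
  sv <- svd(Xd)
  pos <- sum(sv$d > sv$d[1L] * 1e-10)
  if (a > pos) stop(sprintf("a = %d exceeds rank(X) = %d", a, pos), call. = FALSE)
  V <- sv$v[, seq_len(a), drop = FALSE]
  scores <- Xd %*% V
  gamma <- drop(solve(crossprod(scores), crossprod(scores, y - y_mean)))
  structure(list(x_mean = x_mean, y_mean = y_mean, coefficients = drop(V %*% gamma),
                 a = a, grid = grid),
            class = "pcr_model")
}

#' Coefficient of determination
#'
#' R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2). Computed on
#' cross-validated predictions it can be negative.
#'
#' @param y Observed values (variance must be positive, n >= 2).
#' @param yhat Predictions, same length.
#' @return Unitless scalar.
#' @export
r_squared <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need n >= 2", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("zero variance in y", call. = FALSE)
  1 - sum((y - yhat)^2) / sst
}

#' Standard deviation of the normalized residuals
#'
#' Residuals are prediction minus truth, both already expressed as a
#' percentage of the stated content, so no further normalization is applied;
#' the sample standard deviation (n - 1 denominator) summarizes quantitation
#' accuracy in percent-of-label units.
#'
#' @param y True percent of stated content.
#' @param yhat_cv Cross-validated predicted percent.
#' @return Non-negative percent.
#' @export
normalized_residual_sd <- function(y, yhat_cv) {
  y <- as.numeric(y); yhat_cv <- as.numeric(yhat_cv)
  if (length(y) != length(yhat_cv)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need n >= 2 residuals", call. = FALSE)
  stats::sd(yhat_cv - y)
}

#' Coverage half-width of the quantitation interval
#'
#' halfwidth = factor * resid_sd. The default factor is 2: the convention
#' that maps a residual standard deviation to the half-width of an
#' approximately-95-percent coverage interval (2 rather than 1.96, matching
#' how such plus/minus claims are conventionally rounded in screening
#' practice).
#'
#' @param resid_sd Residual standard deviation in percent (>= 0).
#' @param factor Coverage factor (> 0), default 2.
#' @return Percent half-width.
#' @export
coverage_halfwidth <- function(resid_sd, factor = 2) {
  if (resid_sd < 0) stop("resid_sd must be >= 0", call. = FALSE)
  if (factor < 0) stop("factor must be >= 0", call. = FALSE)
  factor * resid_sd
}

#' Tolerance-band quality classification
#'
#' A content value is quality-assured iff it lies inside the band,
#' boundaries included. The default band is 85-115 percent of label (the
#' wider band reflecting HPLC lab variation at small per-formulation sample
#' counts); the stricter pharmacopeia band is `c(90, 110)`.
#'
#' @param sapi_percent Numeric vector of percent-of-label values (>= 0).
#' @param band Length-2 numeric `c(low, high)`, `low <= high`.
#' @return Character vector: `"quality_assured"` or `"substandard"`.
#' @export
tolerance_classify <- function(sapi_percent, band = c(85, 115)) {
  sapi_percent <- as.numeric(sapi_percent)
  if (any(sapi_percent < 0)) stop("sapi_percent must be >= 0", call. = FALSE)
  if (length(band) != 2L || band[1L] > band[2L]) {
    stop("band must be c(low, high) with low <= high", call. = FALSE)
  }
  ifelse(sapi_percent >= band[1L] & sapi_percent <= band[2L],
         "quality_assured", "substandard")
}

#' End-to-end quantitation report for one brand/component
#'
#' Runs the quantitative preprocessing pipeline on every sample carrying
#' ground truth for `component`, leave-one-out cross-validates a PLSR
#' calibration, and reports R2, the normalized-residual SD, the coverage
#' half-width and a tolerance-band classification of each prediction.
#'
#' @param samples A [sample_set()].
#' @param component Component (API) name to quantify.
#' @param brand Optional brand filter.
#' @param a Latent components (default 3).
#' @param band Tolerance band, default `c(85, 115)`.
#' @param coverage_factor Coverage factor, default 2.
#' @param window,polyorder,baseline Quantitative-pipeline settings.
#' @return Object of class `quant_report`: `samples` data frame (truth,
#'   cross-validated prediction, residual, predicted class), `r2`,
#'   `resid_sd`, `coverage_halfwidth`, `coverage_factor`, `n`, `a`.
#' @export
quantify_brand <- function(samples, component, brand = NULL, a = 3L,
                           band = c(85, 115), coverage_factor = 2,
                           window = 11L, polyorder = 3L,
                           baseline = "linear_endpoints") {
  stopifnot(inherits(samples, "sample_set"))
  sub <- if (is.null(brand)) samples else filter_samples(samples, brand = brand)
  recs <- Filter(function(r) component %in% names(r$sapi), sub$records)
  if (length(recs) < a + 2L) {
    stop(sprintf("quantifying %s needs at least a + 2 = %d samples with ground truth, got %d",
                 component, a + 2L, length(recs)), call. = FALSE)
  }
  spectra <- lapply(recs, preprocess_record, pipeline = "quantitative",
                    window = window, polyorder = polyorder, baseline = baseline)
  X <- do.call(rbind, lapply(spectra, function(s) s$values))
  y <- vapply(recs, function(r) r$sapi[[component]], numeric(1))
  yhat <- loocv_predict(X, y, a = a)
  rs <- normalized_residual_sd(y, yhat)
  structure(list(
    samples = data.frame(
      sample_id = vapply(recs, function(r) r$sample_id, character(1)),
      true_percent = y, predicted_percent = yhat, residual_percent = yhat - y,
      predicted_class = tolerance_classify(pmax(yhat, 0), band),
      stringsAsFactors = FALSE),
    component = component, r2 = r_squared(y, yhat), resid_sd = rs,
    coverage_halfwidth = coverage_halfwidth(rs, coverage_factor),
    coverage_factor = coverage_factor, band = band,
    n = length(y), a = as.integer(a)),
    class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat(sprintf("<quant_report> %s: n=%d, a=%d, LOOCV R2=%.3f, residual SD=%.2f%%, +/-%.2f%% (factor %g)\n",
              x$component, x$n, x$a, x$r2, x$resid_sd, x$coverage_halfwidth,
              x$coverage_factor))
  tab <- table(x$samples$predicted_class)
  cat("  predicted classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}
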