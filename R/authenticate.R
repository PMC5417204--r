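#' Chi-square acceptance threshold for a Mahalanobis classifier
#'
#' If a test spectrum's scores were Gaussian around the library mean, its
#' squared Mahalanobis distance would follow a chi-square law with `k`
#' degrees of freedom; the acceptance radius is the square root of the
#' requested quantile.
#'
#' @param k Retained principal components (>= 1).
#' @param quantile Coverage quantile in (0, 1); default 0.9999 (flag only spectra practically impossible for the genuine class).
#' @return Non-negative distance threshold.
#' @export
calibrate_threshold <- function(k, quantile = 0.9999) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (!is.finite(quantile) || quantile <= 0 || quantile >= 1) {
    stop("quantile must lie strictly between 0 and 1", call. = FALSE)
  }
  sqrt(stats::qchisq(quantile, df = k))
}

#' Fit a spectral library class model
#'
#' Builds the library entry for one genuine product class from
#' second-derivative spectra: the training mean, the top-k principal axes
#' (k = smallest number of axes explaining at least `variance_kept` of the
#' variance, capped at n - 2), the score mean and regularized score
#' covariance, and a chi-square acceptance threshold. Falsified samples are
#' refused as training input by design: a falsified product could have any
#' composition, so the library must describe only the genuine class.
#'
#' @param spectra List of `nir_spectrum` objects in `"second_derivative"`
#'   state; metadata `quality_class` (if present) must not be
#'   `"falsified"`.
#' @param batch_ids Character vector of batch identifiers (recycled from
#'   spectrum metadata when `NULL`).
#' @param variance_kept Fraction of variance the retained axes must explain
#'   (default 0.99).
#' @param shrinkage Covariance shrinkage weight toward `trace(S)/k * I`
#'   (default 0.05).
#' @param threshold_quantile Chi-square quantile for the acceptance radius.
#' @return Object of class `class_model`.
#' @export
fit_class_model <- function(spectra, batch_ids = NULL, variance_kept = 0.99,
                            shrinkage = 0.05, threshold_quantile = 0.9999) {
  info <- check_common_grid_state(spectra, "training spectra")
  if (info$state != "second_derivative") {
    stop("class models are fit on second-derivative (qualitative) spectra", call. = FALSE)
  }
  n <- length(spectra)
  if (n < 3L) stop("need at least 3 training spectra", call. = FALSE)
  qc <- vapply(spectra, function(s) {
    q <- s$meta$quality_class
    if (is.null(q)) "unknown" else q
  }, character(1))
  if (any(qc == "falsified")) {
    stop("falsified samples must be excluded from all training sets", call. = FALSE)
  }
  if (is.null(batch_ids)) {
    batch_ids <- vapply(spectra, function(s) {
      b <- s$meta$batch_id
      if (is.null(b)) NA_character_ else b
    }, character(1))
  }
  if (length(batch_ids) != n) stop("batch_ids length mismatch", call. = FALSE)
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]", call. = FALSE)
  if (variance_kept <= 0 || variance_kept > 1) {
    stop("variance_kept must be in (0, 1]", call. = FALSE)
  }

  x <- do.call(rbind, lapply(spectra, function(s) s$values))
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  sv <- svd(xc)
  ev <- sv$d^2 / (n - 1)
  total <- sum(ev)
  if (total < 1e-24) {
    stop("training spectra are (numerically) identical; the class has no variation to model",
         call. = FALSE)
  }
  k <- which(cumsum(ev) / total >= variance_kept)[1L]
  k <- max(1L, min(k, n - 2L))
  proj <- t(sv$v[, seq_len(k), drop = FALSE])      # k x p, rows orthonormal
  scores <- xc %*% t(proj)                         # n x k
  mu <- colMeans(scores)
  sigma <- stats::cov(scores)
  sigma <- (1 - shrinkage) * sigma +
    shrinkage * (sum(diag(sigma)) / k) * diag(k)
  manifest <- data.frame(
    sample_id = vapply(spectra, function(s) {
      id <- s$meta$sample_id
      if (is.null(id)) NA_character_ else id
    }, character(1)),
    batch_id = batch_ids, stringsAsFactors = FALSE)
  structure(list(grid = info$grid, projection = proj, center = center,
                 mean = mu, covariance = sigma,
                 threshold = calibrate_threshold(k, threshold_quantile),
                 threshold_quantile = threshold_quantile, k = k,
                 variance_kept = variance_kept, shrinkage = shrinkage,
                 explained = ev / total, manifest = manifest),
            class = "class_model")
}

#' @export
print.class_model <- function(x, ...) {
  cat(sprintf("<class_model> k=%d axes, threshold=%.3f (chi-square %.3g), n_train=%d\n",
              x$k, x$threshold, x$threshold_quantile, nrow(x$manifest)))
  invisible(x)
}

check_model_input <- function(spec, model) {
  stopifnot(inherits(spec, "nir_spectrum"), inherits(model, "class_model"))
  if (!same_grid(spec$wavelengths, model$grid)) {
    stop("spectrum is not on the model's training wavelength grid", call. = FALSE)
  }
  if (spec$state != "second_derivative") {
    stop(sprintf("library matching expects second-derivative spectra, got state %s",
                 spec$state), call. = FALSE)
  }
  invisible(TRUE)
}

#' Mahalanobis distance of a spectrum from a library class
#'
#' d = sqrt((s - mu)' Sigma^-1 (s - mu)) with s the spectrum's scores on the
#' model's principal axes — the multivariate analog of a z-score against the
#' genuine-product cluster.
#'
#' @param spec Second-derivative `nir_spectrum` on the model grid.
#' @param model A [fit_class_model()] result.
#' @return Non-negative scalar distance.
#' @export
mahalanobis_distance <- function(spec, model) {
  check_model_input(spec, model)
  s <- drop(model$projection %*% (spec$values - model$center)) - model$mean
  sqrt(drop(crossprod(s, solve(model$covariance, s))))
}

#' Classify a spectrum against a library class
#'
#' Accepts (genuine) iff the Mahalanobis distance does not exceed the model
#' threshold; a distance exactly on the boundary is accepted.
#'
#' @inheritParams mahalanobis_distance
#' @return List with `verdict` (`"accept"`/`"reject"`), `distance`,
#'   `threshold`.
#' @export
classify <- function(spec, model) {
  d <- mahalanobis_distance(spec, model)
  list(verdict = if (d <= model$threshold) "accept" else "reject",
       distance = d, threshold = model$threshold)
}

#' Sensitivity/specificity summary
#'
#' Positive = rejection of a falsified sample. Sensitivity = 100 TP/(TP+FN),
#' specificity = 100 TN/(TN+FP); `NA` when a denominator is zero.
#'
#' @param tp,fp,tn,fn Decision counts.
#' @return Object of class `sens_spec`.
#' @export
sens_spec <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_),
            class = "sens_spec")
}

#' @export
print.sens_spec <- function(x, ...) {
  cat(sprintf("<sens_spec> sensitivity=%s specificity=%s (TP=%d FP=%d TN=%d FN=%d)\n",
              format(x$sensitivity), format(x$specificity), x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Leave-batch-out evaluation of the library-matching classifier
#'
#' Emulates field validation: each quality-assured sample is classified by a
#' model trained on the quality-assured samples of all *other* batches (the
#' batch under test never trains its own classifier); each falsified sample
#' is classified by a model trained on all quality-assured samples (a
#' falsified product belongs to no genuine batch, and falsified samples never
#' enter any training set). Substandard/degraded/unknown records are ignored
#' here — they are genuine products and belong to the quantitation stage.
#'
#' @param samples A [sample_set()].
#' @param brand Brand to evaluate.
#' @param variance_kept,shrinkage,threshold_quantile Passed to
#'   [fit_class_model()].
#' @param window,polyorder Savitzky-Golay settings of the qualitative
#'   pipeline.
#' @return A `sens_spec` object with extra fields: `details` (per-sample
#'   data frame with distance, threshold, verdict and the training batches
#'   used) and `specificity_only` flag.
#' @export
leave_batch_out_evaluate <- function(samples, brand,
                                     variance_kept = 0.99, shrinkage = 0.05,
                                     threshold_quantile = 0.9999,
                                     window = 11L, polyorder = 3L) {
  stopifnot(inherits(samples, "sample_set"))
  sub <- filter_samples(samples, brand = brand)
  if (!length(sub$records)) stop(sprintf("no samples of brand %s", brand), call. = FALSE)
  qa <- Filter(function(r) r$quality_class == "quality_assured", sub$records)
  fk <- Filter(function(r) r$quality_class == "falsified", sub$records)
  if (!length(qa)) stop("no quality-assured samples to train on", call. = FALSE)
  qa_batches <- vapply(qa, function(r) r$batch_id, character(1))
  if (length(unique(qa_batches)) < 2L) {
    stop(paste("batch-exclusion cross-validation needs >= 2 quality-assured batches;",
               "a single-batch brand cannot be evaluated this way"), call. = FALSE)
  }
  qa_spec <- lapply(qa, preprocess_record, pipeline = "qualitative",
                    window = window, polyorder = polyorder)
  fit <- function(spectra) {
    fit_class_model(spectra, variance_kept = variance_kept, shrinkage = shrinkage,
                    threshold_quantile = threshold_quantile)
  }
  rows <- list()
  tn <- 0L; fp <- 0L
  for (b in unique(qa_batches)) {
    model_b <- fit(qa_spec[qa_batches != b])
    for (i in which(qa_batches == b)) {
      res <- classify(qa_spec[[i]], model_b)
      if (res$verdict == "accept") tn <- tn + 1L else fp <- fp + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = qa[[i]]$sample_id, batch_id = b, quality_class = "quality_assured",
        distance = res$distance, threshold = res$threshold, verdict = res$verdict,
        train_batches = paste(sort(unique(qa_batches[qa_batches != b])), collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  tp <- 0L; fn <- 0L
  if (length(fk)) {
    model_all <- fit(qa_spec)
    for (r in fk) {
      sp <- preprocess_record(r, pipeline = "qualitative",
                              window = window, polyorder = polyorder)
      res <- classify(sp, model_all)
      if (res$verdict == "reject") tp <- tp + 1L else fn <- fn + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = r$sample_id, batch_id = r$batch_id, quality_class = "falsified",
        distance = res$distance, threshold = res$threshold, verdict = res$verdict,
        train_batches = paste(sort(unique(qa_batches)), collapse = "|"),
        stringsAsFactors = FALSE)
    }
  } else {
    warning("no falsified samples: specificity-only evaluation", call. = FALSE)
  }
  if (!length(rows)) stop("no samples were evaluated", call. = FALSE)
  out <- sens_spec(tp, fp, tn, fn)
  out$details <- do.call(rbind, rows)
  out$specificity_only <- length(fk) == 0L
  out
}

#' Principal component scores of a spectra collection
#'
#' @param spectra List of `nir_spectrum` objects on one grid (any single
#'   state), or a numeric matrix (rows = spectra).
#' @param n_components Number of components, at most `min(n - 1, p)`.
#' @return List with `scores` (n x n_components), `explained_variance`
#'   (fractions, non-increasing) and `loadings` (p x n_components).
#' @export
pca_scores <- function(spectra, n_components = 2L) {
  x <- if (is.matrix(spectra)) spectra else spectra_matrix(spectra)
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("need at least 2 spectra", call. = FALSE)
  if (n_components > min(n - 1L, p)) {
    stop(sprintf("n_components must not exceed min(n - 1, p) = %d", min(n - 1L, p)),
         call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  idx <- seq_len(n_components)
  list(scores = pc$x[, idx, drop = FALSE],
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[idx],
       loadings = pc$rotation[, idx, drop = FALSE])
}
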