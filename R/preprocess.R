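#' Preprocessing configuration
#'
#' @param window Odd number of points in the Savitzky-Golay window
#'   (default 11, about 11 nm at 1-nm spacing).
#' @param polyorder Polynomial order of the sliding fit (default 3).
#' @param deriv Derivative order, 0 (smoothing) or 2 (second derivative).
#' @param baseline `"linear_endpoints"` or `"none"` — background subtraction
#'   mode for the quantitative pipeline.
#' @param pipeline `"qualitative"` (second-derivative, for library matching)
#'   or `"quantitative"` (smoothed absorbance minus baseline, for
#'   regression).
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(window = 11L, polyorder = 3L, deriv = 2L,
                              baseline = c("linear_endpoints", "none"),
                              pipeline = c("qualitative", "quantitative")) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window <= polyorder) stop("window must exceed polyorder", call. = FALSE)
  if (!deriv %in% c(0L, 2L)) stop("deriv must be 0 or 2", call. = FALSE)
  if (deriv > polyorder) stop("deriv must not exceed polyorder", call. = FALSE)
  structure(list(window = window, polyorder = polyorder, deriv = deriv,
                 baseline = match.arg(baseline), pipeline = match.arg(pipeline)),
            class = "preprocess_config")
}

#' Average replicate scans pointwise
#'
#' @param scans List of `nir_spectrum` replicates on one grid and state.
#' @return One `nir_spectrum`; metadata records `n_averaged`.
#' @export
average_replicates <- function(scans) {
  info <- check_common_grid_state(scans, "replicate scans")
  m <- do.call(rbind, lapply(scans, function(s) s$values))
  meta <- scans[[1L]]$meta
  meta$replicate <- NULL
  meta$n_averaged <- length(scans)
  spectrum(info$grid, colMeans(m), info$state, meta)
}

#' Convert reflectance to absorbance
#'
#' A(lambda) = -log10 R(lambda).
#'
#' @param spec Reflectance `nir_spectrum` with all values > 0.
#' @return Absorbance `nir_spectrum`.
#' @export
to_absorbance <- function(spec) {
  stopifnot(inherits(spec, "nir_spectrum"))
  if (spec$state != "reflectance") {
    stop(sprintf("to_absorbance expects a reflectance spectrum, got state %s", spec$state),
         call. = FALSE)
  }
  if (any(spec$values <= 0)) {
    bad <- spec$wavelengths[which(spec$values <= 0)[1L]]
    stop(sprintf("non-positive reflectance at %g nm cannot be converted to absorbance", bad),
         call. = FALSE)
  }
  spectrum(spec$wavelengths, -log10(spec$values), "absorbance", spec$meta)
}

# Savitzky-Golay weights for estimating the deriv-th derivative (in point
# units) at position `pos` (1..window) from a window of raw points: row
# deriv+1 of (V'V)^-1 V' times deriv!, where V[i,j] = (i - pos)^(j-1).
sg_coefficients <- function(window, polyorder, deriv, pos = (window + 1L) %/% 2L) {
  x <- seq_len(window) - pos
  v <- outer(x, 0:polyorder, `^`)
  cmat <- solve(crossprod(v), t(v))
  factorial(deriv) * cmat[deriv + 1L, ]
}

#' Savitzky-Golay filtering and differentiation
#'
#' Slides a least-squares polynomial of degree `polyorder` over `window`
#' points and evaluates its `deriv`-th derivative at the centre. Edge points
#' are evaluated from the polynomial fitted to the first/last full window, so
#' output length equals input length. Derivatives are scaled by the grid
#' spacing (`AU / nm^deriv`), so results do not depend on the sampling
#' density. The grid must be uniformly spaced.
#'
#' @param spec An absorbance (or smoothed) `nir_spectrum`.
#' @param window Odd window length in points; must not exceed the spectrum
#'   length.
#' @param polyorder Polynomial degree, `> deriv`, `< window`.
#' @param deriv Derivative order (0 or 2 for the pipelines here; any
#'   `0 <= deriv <= polyorder` is computed).
#' @return `nir_spectrum` with state `"smoothed"` (`deriv = 0`) or
#'   `"second_derivative"` (`deriv = 2`).
#' @export
savitzky_golay <- function(spec, window = 11L, polyorder = 3L, deriv = 0L) {
  stopifnot(inherits(spec, "nir_spectrum"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be smaller than window", call. = FALSE)
  if (deriv < 0L || deriv > polyorder) stop("need 0 <= deriv <= polyorder", call. = FALSE)
  n <- length(spec$values)
  if (n < window) stop("spectrum shorter than the filter window", call. = FALSE)
  d <- diff(spec$wavelengths)
  if (max(d) - min(d) > 1e-6 * mean(d)) {
    stop("Savitzky-Golay requires a uniformly spaced wavelength grid", call. = FALSE)
  }
  h <- (window - 1L) %/% 2L
  y <- spec$values
  out <- numeric(n)
  cc <- sg_coefficients(window, polyorder, deriv)
  for (i in seq.int(h + 1L, n - h)) {
    out[i] <- sum(cc * y[(i - h):(i + h)])
  }
  for (i in seq_len(h)) {
    out[i] <- sum(sg_coefficients(window, polyorder, deriv, pos = i) * y[1:window])
    out[n - i + 1L] <- sum(sg_coefficients(window, polyorder, deriv,
                                           pos = window - i + 1L) *
                             y[(n - window + 1L):n])
  }
  out <- out / mean(d)^deriv
  state <- if (deriv == 0L) "smoothed" else if (deriv == 2L) "second_derivative"
           else spec$state
  spectrum(spec$wavelengths, out, state, spec$meta)
}

#' Second-derivative spectrum
#'
#' Convenience wrapper: `savitzky_golay(spec, window, polyorder, deriv = 2)`.
#' The second derivative removes any affine (offset + slope) baseline exactly
#' and sharpens overlapping bands, which is why it feeds the library-matching
#' classifier.
#'
#' @inheritParams savitzky_golay
#' @return `nir_spectrum` in state `"second_derivative"`.
#' @export
second_derivative <- function(spec, window = 11L, polyorder = 3L) {
  savitzky_golay(spec, window, polyorder, deriv = 2L)
}

#' Subtract a linear endpoint baseline
#'
#' Fits the straight line through the mean of the first five and the mean of
#' the last five points and subtracts it (`method = "linear_endpoints"`);
#' `method = "none"` is the identity. This is the declared background
#' subtraction convention of the quantitative pipeline.
#'
#' @param spec Absorbance or smoothed `nir_spectrum` of length >= 10.
#' @param method `"linear_endpoints"` or `"none"`.
#' @return `nir_spectrum`, same state.
#' @export
subtract_baseline <- function(spec, method = c("linear_endpoints", "none")) {
  stopifnot(inherits(spec, "nir_spectrum"))
  method <- match.arg(method)
  if (!spec$state %in% c("absorbance", "smoothed")) {
    stop(sprintf("baseline subtraction applies to absorbance/smoothed spectra, got %s",
                 spec$state), call. = FALSE)
  }
  if (method == "none") return(spec)
  n <- length(spec$values)
  if (n < 10L) stop("linear_endpoints baseline needs at least 10 points", call. = FALSE)
  wl <- spec$wavelengths
  x1 <- mean(wl[1:5]); y1 <- mean(spec$values[1:5])
  x2 <- mean(wl[(n - 4):n]); y2 <- mean(spec$values[(n - 4):n])
  slope <- (y2 - y1) / (x2 - x1)
  line <- y1 + slope * (wl - x1)
  spectrum(wl, spec$values - line, spec$state, spec$meta)
}

#' Qualitative preprocessing pipeline
#'
#' average replicates -> absorbance -> Savitzky-Golay second derivative.
#' The output feeds library matching / class modelling.
#'
#' @param scans List of replicate reflectance scans.
#' @param window,polyorder Savitzky-Golay settings.
#' @return `nir_spectrum` in state `"second_derivative"`.
#' @export
preprocess_qualitative <- function(scans, window = 11L, polyorder = 3L) {
  second_derivative(to_absorbance(average_replicates(scans)), window, polyorder)
}

#' Quantitative preprocessing pipeline
#'
#' average replicates -> absorbance -> Savitzky-Golay smoothing -> linear
#' endpoint background subtraction. The output feeds regression.
#'
#' @param scans List of replicate reflectance scans.
#' @param window,polyorder Savitzky-Golay settings.
#' @param baseline Background subtraction mode.
#' @return `nir_spectrum` in state `"smoothed"`.
#' @export
preprocess_quantitative <- function(scans, window = 11L, polyorder = 3L,
                                    baseline = "linear_endpoints") {
  subtract_baseline(
    savitzky_golay(to_absorbance(average_replicates(scans)), window, polyorder,
                   deriv = 0L),
    method = baseline)
}

#' Preprocess one sample record into a single spectrum
#'
#' Runs the chosen pipeline on a record's replicate scans and stamps the
#' result with the record's identity (`sample_id`, `batch_id`,
#' `quality_class`) so downstream models can audit their training manifests.
#'
#' @param record A [sample_record()] with at least one scan.
#' @param pipeline `"qualitative"` or `"quantitative"`.
#' @param window,polyorder Savitzky-Golay settings.
#' @param baseline Background mode for the quantitative pipeline.
#' @return One `nir_spectrum`.
#' @export
preprocess_record <- function(record, pipeline = c("qualitative", "quantitative"),
                              window = 11L, polyorder = 3L,
                              baseline = "linear_endpoints") {
  pipeline <- match.arg(pipeline)
  if (!length(record$scans)) {
    stop(sprintf("sample %s has no scans", record$sample_id), call. = FALSE)
  }
  out <- if (pipeline == "qualitative") {
    preprocess_qualitative(record$scans, window, polyorder)
  } else {
    preprocess_quantitative(record$scans, window, polyorder, baseline)
  }
  out$meta$sample_id <- record$sample_id
  out$meta$batch_id <- record$batch_id
  out$meta$quality_class <- record$quality_class
  out
}
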