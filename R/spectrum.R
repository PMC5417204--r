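#' @keywords internal
"_PACKAGE"

SPECTRUM_STATES <- c("reflectance", "absorbance", "smoothed", "second_derivative")
QUALITY_CLASSES <- c("quality_assured", "substandard", "falsified", "degraded", "unknown")

#' Construct a single spectrum
#'
#' A spectrum is one wavelength-indexed trace together with a processing-state
#' tag. Reflectance is a fraction of the reference intensity in (0, 1];
#' absorbance is -log10(reflectance); `smoothed` is Savitzky-Golay-smoothed
#' absorbance; `second_derivative` is the second derivative of absorbance with
#' respect to wavelength (units absorbance / nm^2).
#'
#' @param wavelengths Strictly increasing numeric vector of wavelengths (nm).
#' @param values Numeric vector, same length as `wavelengths`.
#' @param state One of `"reflectance"`, `"absorbance"`, `"smoothed"`,
#'   `"second_derivative"`.
#' @param meta Named list of free-form metadata (`sample_id`, `replicate`,
#'   `side`, ...).
#' @return An object of class `nir_spectrum`.
#' @export
spectrum <- function(wavelengths, values, state, meta = list()) {
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  state <- match.arg(state, SPECTRUM_STATES)
  if (length(wavelengths) == 0L) {
    stop("spectrum needs at least one wavelength", call. = FALSE)
  }
  if (length(values) != length(wavelengths)) {
    stop(sprintf("length mismatch: %d wavelengths but %d values",
                 length(wavelengths), length(values)), call. = FALSE)
  }
  if (anyNA(wavelengths) || anyNA(values)) {
    stop("NA in wavelengths or values", call. = FALSE)
  }
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (state == "reflectance") {
    if (any(values <= 0) || any(values > 1 + 1e-12)) {
      bad <- wavelengths[which(values <= 0 | values > 1 + 1e-12)[1L]]
      stop(sprintf("reflectance values must lie in (0, 1]; offending wavelength %g nm",
                   bad), call. = FALSE)
    }
  }
  structure(list(wavelengths = wavelengths, values = values,
                 state = state, meta = meta),
            class = "nir_spectrum")
}

#' @export
print.nir_spectrum <- function(x, ...) {
  cat(sprintf("<nir_spectrum> %d points, %g-%g nm, state=%s\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$state))
  if (!is.null(x$meta$sample_id)) cat("  sample_id:", x$meta$sample_id, "\n")
  invisible(x)
}

same_grid <- function(g1, g2, tol = 1e-9) {
  length(g1) == length(g2) && all(abs(g1 - g2) <= tol * pmax(1, abs(g1)))
}

stop_grid_mismatch <- function(what = "spectra") {
  stop(sprintf("wavelength grid mismatch: %s are not on the same grid", what),
       call. = FALSE)
}

check_common_grid_state <- function(spectra, what = "spectra") {
  if (length(spectra) == 0L) stop("no spectra supplied", call. = FALSE)
  g <- spectra[[1L]]$wavelengths
  st <- spectra[[1L]]$state
  for (s in spectra) {
    if (!inherits(s, "nir_spectrum")) stop("inputs must be nir_spectrum objects", call. = FALSE)
    if (!same_grid(g, s$wavelengths)) stop_grid_mismatch(what)
    if (!identical(st, s$state)) {
      stop(sprintf("mixed processing states among %s: %s vs %s", what, st, s$state),
           call. = FALSE)
    }
  }
  invisible(list(grid = g, state = st))
}

#' Stack spectra into a matrix
#'
#' @param spectra List of `nir_spectrum` objects on one common grid and state.
#' @return Numeric matrix, one row per spectrum, columns named by wavelength.
#' @export
spectra_matrix <- function(spectra) {
  info <- check_common_grid_state(spectra)
  m <- do.call(rbind, lapply(spectra, function(s) s$values))
  colnames(m) <- format(info$grid, trim = TRUE)
  rownames(m) <- vapply(spectra, function(s) {
    id <- s$meta$sample_id
    if (is.null(id)) "" else as.character(id)
  }, character(1))
  m
}

#' Construct a sample record
#'
#' One physical dose (or one side of a bilayer tablet): identity, quality
#' class, per-component content as a percentage of the stated amount
#' (HPLC-style ground truth), and the attached replicate scans.
#'
#' @param sample_id Unique sample identifier.
#' @param brand Brand name.
#' @param batch_id Manufacturing batch identifier.
#' @param quality_class One of `"quality_assured"`, `"substandard"`,
#'   `"falsified"`, `"degraded"`, `"unknown"`.
#' @param sapi Named numeric vector: percent of stated content per component
#'   (may be empty when ground truth is unknown).
#' @param scans List of `nir_spectrum` scans sharing one grid.
#' @param side Optional bilayer side label (`"A"`/`"B"`), `NA` for monolayer.
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(sample_id, brand, batch_id, quality_class = "unknown",
                          sapi = numeric(0), scans = list(), side = NA_character_) {
  quality_class <- match.arg(quality_class, QUALITY_CLASSES)
  if (length(sapi) && (is.null(names(sapi)) || any(!nzchar(names(sapi))))) {
    stop("sapi must be a named numeric vector", call. = FALSE)
  }
  if (length(sapi) && any(sapi < 0)) stop("sapi percentages must be >= 0", call. = FALSE)
  if (length(scans)) check_common_grid_state(scans, sprintf("scans of %s", sample_id))
  structure(list(sample_id = as.character(sample_id), brand = as.character(brand),
                 batch_id = as.character(batch_id), quality_class = quality_class,
                 sapi = sapi, scans = scans, side = side),
            class = "sample_record")
}

#' Construct a sample set
#'
#' @param records List of [sample_record()] objects with unique sample ids,
#'   all scans on one shared wavelength grid.
#' @param grid Shared wavelength grid; inferred from the first scanned record
#'   when `NULL`.
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(records, grid = NULL) {
  ids <- vapply(records, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  if (is.null(grid)) {
    for (r in records) if (length(r$scans)) { grid <- r$scans[[1L]]$wavelengths; break }
  }
  if (is.null(grid)) stop("cannot infer grid: no record has scans and no grid given", call. = FALSE)
  for (r in records) {
    for (s in r$scans) if (!same_grid(grid, s$wavelengths)) {
      stop(sprintf("record %s is not on the shared wavelength grid", r$sample_id),
           call. = FALSE)
    }
  }
  names(records) <- ids
  structure(list(records = records, grid = as.numeric(grid)), class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cls <- table(factor(vapply(x$records, function(r) r$quality_class, character(1)),
                      levels = QUALITY_CLASSES))
  cat(sprintf("<sample_set> %d records on %d-point grid (%g-%g nm)\n",
              length(x$records), length(x$grid), min(x$grid), max(x$grid)))
  cat("  quality:", paste(sprintf("%s=%d", names(cls), cls), collapse = " "), "\n")
  invisible(x)
}

#' Subset a sample set
#'
#' @param set A [sample_set()].
#' @param brand Keep only records of this brand (optional).
#' @param quality_class Keep only records of these classes (optional).
#' @return A `sample_set` (possibly with zero records; the grid is kept).
#' @export
filter_samples <- function(set, brand = NULL, quality_class = NULL) {
  stopifnot(inherits(set, "sample_set"))
  keep <- rep(TRUE, length(set$records))
  if (!is.null(brand)) {
    keep <- keep & vapply(set$records, function(r) r$brand %in% brand, logical(1))
  }
  if (!is.null(quality_class)) {
    keep <- keep & vapply(set$records, function(r) r$quality_class %in% quality_class,
                          logical(1))
  }
  structure(list(records = set$records[keep], grid = set$grid), class = "sample_set")
}
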