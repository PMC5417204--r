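META_COLS <- c("sample_id", "batch_id", "brand", "replicate", "side", "state")

fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

split_csv_line <- function(line) strsplit(line, ",", fixed = TRUE)[[1L]]

#' Write a spectra table
#'
#' One row per scan: `sample_id,batch_id,brand,replicate,side,state`
#' followed by one column per wavelength, named by its nm value. Numbers are
#' rendered with 12 significant digits and a fixed column order, so repeated
#' writes are byte-identical and roundtrips are stable to about 1e-9
#' relative error.
#'
#' @param set A [sample_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(set, path) {
  stopifnot(inherits(set, "sample_set"))
  header <- paste(c(META_COLS, fmt_num(set$grid)), collapse = ",")
  lines <- character(0)
  for (r in set$records) {
    for (s in r$scans) {
      rep_i <- if (is.null(s$meta$replicate)) 1L else s$meta$replicate
      side <- if (is.null(r$side) || is.na(r$side)) "" else r$side
      lines <- c(lines, paste(c(r$sample_id, r$batch_id, r$brand, rep_i, side,
                                s$state, fmt_num(s$values)), collapse = ","))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n")
  invisible(path)
}

#' Read a spectra table
#'
#' Parses the CSV format of [write_spectra_table()]. Wavelength columns may
#' appear in any order and are sorted ascending; replicate rows are grouped
#' under their sample record. Quality classes and ground-truth content are
#' not part of this file — join them in with [read_sample_metadata()] /
#' [attach_metadata()].
#'
#' @param path CSV path.
#' @return A [sample_set()]; records have quality class `"unknown"`.
#' @export
read_spectra_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty spectra table", call. = FALSE)
  header <- split_csv_line(lines[1L])
  if (length(header) < length(META_COLS) ||
      !identical(header[seq_along(META_COLS)], META_COLS)) {
    stop(sprintf("spectra table header must start with %s",
                 paste(META_COLS, collapse = ",")), call. = FALSE)
  }
  wl_raw <- header[-seq_along(META_COLS)]
  if (!length(wl_raw)) stop("spectra table has no wavelength columns", call. = FALSE)
  wl <- suppressWarnings(as.numeric(wl_raw))
  if (anyNA(wl)) {
    stop(sprintf("non-numeric wavelength column header: %s", wl_raw[which(is.na(wl))[1L]]),
         call. = FALSE)
  }
  ord <- order(wl)
  grid <- wl[ord]
  if (any(diff(grid) <= 0)) stop("duplicate wavelength columns", call. = FALSE)

  n_field <- length(header)
  seen <- character(0)
  by_sample <- list()
  for (li in seq_along(lines)[-1L]) {
    f <- split_csv_line(lines[li])
    if (!nzchar(paste(f, collapse = ""))) next
    if (length(f) != n_field) {
      stop(sprintf("ragged row %d: %d fields, expected %d", li, length(f), n_field),
           call. = FALSE)
    }
    key <- paste(f[1L], f[4L], f[5L], sep = "\r")
    if (key %in% seen) {
      stop(sprintf("duplicate (sample_id, replicate, side) = (%s, %s, %s) at row %d",
                   f[1L], f[4L], f[5L], li), call. = FALSE)
    }
    seen <- c(seen, key)
    vals <- suppressWarnings(as.numeric(f[-seq_along(META_COLS)]))[ord]
    if (anyNA(vals)) stop(sprintf("non-numeric spectral value at row %d", li), call. = FALSE)
    sp <- spectrum(grid, vals, f[6L],
                   meta = list(sample_id = f[1L],
                               replicate = suppressWarnings(as.integer(f[4L])),
                               side = if (nzchar(f[5L])) f[5L] else NA_character_))
    sid <- f[1L]
    if (is.null(by_sample[[sid]])) {
      by_sample[[sid]] <- list(batch_id = f[2L], brand = f[3L],
                               side = if (nzchar(f[5L])) f[5L] else NA_character_,
                               scans = list())
    }
    by_sample[[sid]]$scans <- c(by_sample[[sid]]$scans, list(sp))
  }
  records <- lapply(names(by_sample), function(sid) {
    e <- by_sample[[sid]]
    sample_record(sid, e$brand, e$batch_id, "unknown", numeric(0), e$scans, e$side)
  })
  sample_set(records, grid = grid)
}

#' Write sample metadata (ground truth)
#'
#' CSV `sample_id,brand,batch_id,quality_class,component,sapi_percent`, one
#' row per (sample, component); samples without content ground truth get a
#' single row with empty component/percent fields.
#'
#' @param set A [sample_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(set, path) {
  stopifnot(inherits(set, "sample_set"))
  lines <- "sample_id,brand,batch_id,quality_class,component,sapi_percent"
  for (r in set$records) {
    if (length(r$sapi)) {
      for (comp in names(r$sapi)) {
        lines <- c(lines, paste(c(r$sample_id, r$brand, r$batch_id, r$quality_class,
                                  comp, fmt_num(r$sapi[[comp]])), collapse = ","))
      }
    } else {
      lines <- c(lines, paste(c(r$sample_id, r$brand, r$batch_id, r$quality_class,
                                "", ""), collapse = ","))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read sample metadata
#'
#' @param path CSV path in the [write_sample_metadata()] format.
#' @return Data frame with columns `sample_id`, `brand`, `batch_id`,
#'   `quality_class`, `component`, `sapi_percent`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character", brand = "character",
                                       batch_id = "character",
                                       quality_class = "character",
                                       component = "character"))
  need <- c("sample_id", "brand", "batch_id", "quality_class", "component",
            "sapi_percent")
  if (!all(need %in% names(df))) {
    stop(sprintf("metadata must have columns %s", paste(need, collapse = ",")),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$quality_class), QUALITY_CLASSES)
  if (length(bad)) {
    stop(sprintf("unknown quality_class token(s) %s; allowed: %s",
                 paste(bad, collapse = ", "), paste(QUALITY_CLASSES, collapse = ", ")),
         call. = FALSE)
  }
  df$sapi_percent <- suppressWarnings(as.numeric(df$sapi_percent))
  df
}

#' Attach metadata (quality class and content) to a sample set
#'
#' Joins by `sample_id`. Metadata rows with no matching spectra produce a
#' warning, not an error.
#'
#' @param set A [sample_set()] (e.g. from [read_spectra_table()]).
#' @param meta Data frame from [read_sample_metadata()].
#' @return The updated `sample_set`.
#' @export
attach_metadata <- function(set, meta) {
  stopifnot(inherits(set, "sample_set"))
  orphan <- setdiff(unique(meta$sample_id), names(set$records))
  if (length(orphan)) {
    warning(sprintf("metadata rows with no matching spectra: %s",
                    paste(orphan, collapse = ", ")), call. = FALSE)
  }
  for (sid in intersect(unique(meta$sample_id), names(set$records))) {
    rows <- meta[meta$sample_id == sid, , drop = FALSE]
    r <- set$records[[sid]]
    r$quality_class <- rows$quality_class[1L]
    comp_rows <- rows[nzchar(rows$component) & !is.na(rows$sapi_percent), , drop = FALSE]
    if (nrow(comp_rows)) {
      r$sapi <- stats::setNames(comp_rows$sapi_percent, comp_rows$component)
    }
    set$records[[sid]] <- r
  }
  set
}

MODEL_SCHEMAS <- c(class_model = "nirscreen/class_model/1",
                   plsr_model = "nirscreen/plsr_model/1",
                   pcr_model = "nirscreen/pcr_model/1")

#' Save a trained model as JSON
#'
#' Class models and regression models are serialized with full numeric
#' precision (matrices row-major, grid included), so a loaded model
#' reproduces distances and predictions exactly.
#'
#' @param model A `class_model`, `plsr_model` or `pcr_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  type <- intersect(class(model), names(MODEL_SCHEMAS))[1L]
  if (is.na(type)) stop("save_model supports class_model, plsr_model and pcr_model",
                        call. = FALSE)
  payload <- unclass(model)
  payload$schema <- unname(MODEL_SCHEMAS[[type]])
  if (!is.null(payload$manifest)) payload$manifest <- as.list(payload$manifest)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON path.
#' @return The model object; errors on truncated files or schema-version
#'   mismatch.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop(sprintf("cannot parse model file %s: %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  if (is.null(obj$schema) || !obj$schema %in% MODEL_SCHEMAS) {
    stop(sprintf("unsupported model schema: %s",
                 if (is.null(obj$schema)) "<missing>" else obj$schema), call. = FALSE)
  }
  type <- names(MODEL_SCHEMAS)[match(obj$schema, MODEL_SCHEMAS)]
  obj$schema <- NULL
  if (type == "class_model") {
    obj$projection <- as.matrix(obj$projection)
    obj$covariance <- as.matrix(obj$covariance)
    if (obj$k == 1L) {
      obj$projection <- matrix(as.numeric(obj$projection), nrow = 1L)
      obj$covariance <- matrix(as.numeric(obj$covariance), 1L, 1L)
    }
    obj$manifest <- as.data.frame(obj$manifest, stringsAsFactors = FALSE)
  } else if (type == "plsr_model") {
    obj$weights <- as.matrix(obj$weights)
    obj$loadings <- as.matrix(obj$loadings)
    if (obj$a == 1L) {
      obj$weights <- matrix(as.numeric(obj$weights), ncol = 1L)
      obj$loadings <- matrix(as.numeric(obj$loadings), ncol = 1L)
    }
  }
  structure(obj, class = type)
}
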