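#' Default instrument wavelength grid
#'
#' 1-nm spacing across the 740-1060 nm working range of handheld
#' diffuse-reflectance NIR devices of the class this package targets.
#'
#' @return Numeric vector of 321 wavelengths (nm).
#' @export
default_grid <- function() seq(740, 1060, by = 1)

#' Build a synthetic component signature
#'
#' A component's pure absorbance signature is modelled as a sum of Gaussian
#' bands evaluated on a wavelength grid:
#' curve(lambda) = sum_b amplitude_b * exp(-(lambda - center_b)^2 / (2 width_b^2)).
#' These are synthetic stand-ins for pure-compound NIR fingerprints; no real
#' compound spectra are embedded in the package.
#'
#' @param name Component name.
#' @param bands List of numeric triples `c(center, width, amplitude)` —
#'   center in nm (must lie in 740-1060), width in nm (> 0), amplitude in
#'   absorbance units. An empty list gives an all-zero signature.
#' @param grid Strictly increasing wavelength vector (nm).
#' @return Object of class `component_signature` with the evaluated `curve`.
#' @export
component_signature <- function(name, bands, grid = default_grid()) {
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop("empty wavelength grid", call. = FALSE)
  if (length(grid) > 1L && any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  bands <- lapply(bands, as.numeric)
  for (b in bands) {
    if (length(b) != 3L) stop("each band must be c(center, width, amplitude)", call. = FALSE)
    if (b[2L] <= 0) stop(sprintf("non-positive band width %g for component %s", b[2L], name),
                         call. = FALSE)
    if (b[1L] < 740 || b[1L] > 1060) {
      stop(sprintf("band center %g nm outside the 740-1060 nm device range", b[1L]),
           call. = FALSE)
    }
  }
  curve <- rep(0, length(grid))
  for (b in bands) {
    curve <- curve + b[3L] * exp(-(grid - b[1L])^2 / (2 * b[2L]^2))
  }
  structure(list(name = as.character(name), bands = bands,
                 grid = grid, curve = curve),
            class = "component_signature")
}

#' @export
print.component_signature <- function(x, ...) {
  cat(sprintf("<component_signature> %s: %d band(s) on %d-point grid\n",
              x$name, length(x$bands), length(x$grid)))
  invisible(x)
}

#' Built-in synthetic signature library
#'
#' Stand-in pure-component signatures used by the example scenarios: three
#' narrow bands per active ingredient, a broad cellulose/starch-like excipient
#' background, and a "wrong compound" whose band sits at least three
#' band-widths away from every active-ingredient band (the regime in which a
#' falsified tablet is spectrally resolvable from the genuine product).
#'
#' @param grid Wavelength grid (nm).
#' @return Named list of [component_signature()] objects.
#' @export
default_signatures <- function(grid = default_grid()) {
  list(
    artemether  = component_signature("artemether",
      list(c(810, 9, 0.65), c(900, 9, 0.75), c(990, 9, 0.50)), grid),
    lumefantrine = component_signature("lumefantrine",
      list(c(830, 9, 0.60), c(940, 9, 0.70), c(1020, 9, 0.55)), grid),
    artesunate  = component_signature("artesunate",
      list(c(820, 9, 0.70), c(930, 9, 0.60), c(1010, 9, 0.55)), grid),
    amodiaquine = component_signature("amodiaquine",
      list(c(850, 9, 0.55), c(960, 9, 0.65), c(1040, 9, 0.45)), grid),
    excipient   = component_signature("excipient",
      list(c(780, 35, 0.30), c(920, 55, 0.40), c(1035, 40, 0.30)), grid),
    wrong_compound = component_signature("wrong_compound",
      list(c(762, 7, 0.85)), grid)
  )
}

#' Define a tablet formulation
#'
#' @param brand Brand name.
#' @param components Named list of [component_signature()] objects (the
#'   excipient is just another component, conventionally named
#'   `"excipient"`).
#' @param nominal Named numeric vector of nominal concentrations as fractions
#'   of label (1.0 = 100 percent); names must match `components`.
#' @param apis Character vector naming which components are active
#'   pharmaceutical ingredients (candidates for falsification / substandard
#'   content).
#' @param bilayer Logical; `TRUE` for a two-layer tablet scanned per side.
#' @param sides When `bilayer`, a list `list(A = <names>, B = <names>)`
#'   partitioning `names(components)` into exactly two sides.
#' @return Object of class `formulation_spec`.
#' @export
formulation_spec <- function(brand, components, nominal, apis,
                             bilayer = FALSE, sides = NULL) {
  cn <- names(components)
  if (is.null(cn) || any(!nzchar(cn))) stop("components must be a named list", call. = FALSE)
  if (!all(names(nominal) %in% cn) || !all(cn %in% names(nominal))) {
    stop("nominal concentrations must be keyed exactly by component names", call. = FALSE)
  }
  if (any(nominal < 0)) stop("nominal concentrations must be >= 0", call. = FALSE)
  if (!all(apis %in% cn)) stop("apis must name formulation components", call. = FALSE)
  g <- components[[1L]]$grid
  for (s in components) {
    if (!same_grid(g, s$grid)) stop("all component signatures must share one grid", call. = FALSE)
  }
  if (bilayer) {
    if (is.null(sides) || !setequal(names(sides), c("A", "B"))) {
      stop("bilayer formulation needs sides = list(A = ..., B = ...)", call. = FALSE)
    }
    both <- c(sides$A, sides$B)
    if (length(intersect(sides$A, sides$B)) > 0L || !setequal(both, cn)) {
      stop("sides must partition the components into exactly two disjoint sides",
           call. = FALSE)
    }
  } else if (!is.null(sides)) {
    stop("sides given for a monolayer formulation", call. = FALSE)
  }
  structure(list(brand = as.character(brand), components = components,
                 nominal = nominal[cn], apis = apis, bilayer = isTRUE(bilayer),
                 sides = sides, grid = g),
            class = "formulation_spec")
}
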