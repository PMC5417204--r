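#' Default noise model for the synthetic generator
#'
#' Conventions for an instrument the source device class resembles (the device
#' noise floor was never characterized publicly, so these are declared
#' choices, not estimates): per-scan absorbance noise 5e-5 AU; per-sample
#' baseline offset sd 0.01 AU and slope sd 2e-5 AU/nm (placement/contact
#' variation); per-batch shared baseline offset sd 0.02 AU (pressing and
#' coating differences between batches). All baseline terms are affine in
#' wavelength, which second-derivative preprocessing removes exactly.
#'
#' @return Named list with elements `baseline_offset_sd`, `baseline_slope_sd`,
#'   `batch_sd`, `scan_sd`, `baseline_offset_mean`.
#' @export
default_noise_model <- function() {
  list(baseline_offset_sd = 0.01,
       baseline_slope_sd  = 2e-5,
       batch_sd           = 0.02,
       scan_sd            = 5e-5,
       baseline_offset_mean = 0.20)
}

#' Simulate a noiseless-to-noisy absorbance spectrum (Beer-Lambert model)
#'
#' A(lambda) = sum_i c_i * eps_i(lambda) + offset + slope * (lambda - min)
#' + N(0, noise_sd), where eps_i are the formulation's component signature
#' curves.
#'
#' @param formulation A [formulation_spec()].
#' @param concentrations Named numeric vector of concentrations (fraction of
#'   label) keyed to formulation components; missing components default to 0.
#' @param baseline Numeric `c(offset, slope)`: offset in AU, slope in AU/nm.
#' @param noise_sd Gaussian noise sd on absorbance (>= 0).
#' @param components Optional character vector restricting which components
#'   contribute (used for bilayer sides); default all.
#' @param meta Metadata list attached to the result.
#' @return `nir_spectrum` in state `"absorbance"`.
#' @export
simulate_absorbance <- function(formulation, concentrations,
                                baseline = c(0, 0), noise_sd = 0,
                                components = NULL, meta = list()) {
  stopifnot(inherits(formulation, "formulation_spec"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  cn <- names(formulation$components)
  if (length(concentrations) && (is.null(names(concentrations)) ||
                                 !all(names(concentrations) %in% cn))) {
    stop("concentrations must be named by formulation components", call. = FALSE)
  }
  use <- if (is.null(components)) cn else intersect(cn, components)
  grid <- formulation$grid
  a <- rep(0, length(grid))
  for (nm in use) {
    ci <- if (nm %in% names(concentrations)) concentrations[[nm]] else 0
    if (ci != 0) a <- a + ci * formulation$components[[nm]]$curve
  }
  a <- a + baseline[1L] + baseline[2L] * (grid - grid[1L])
  if (noise_sd > 0) a <- a + stats::rnorm(length(grid), 0, noise_sd)
  spectrum(grid, a, "absorbance", meta)
}

#' Simulate a replicate scan set (reflectance)
#'
#' Each replicate applies independent additive Gaussian noise to the
#' absorbance and converts to reflectance, R = 10^-(A + noise). Triplicate
#' scanning is the field convention this emulates.
#'
#' @param absorbance `nir_spectrum` in state `"absorbance"`.
#' @param scan_noise_sd Per-scan absorbance noise sd (>= 0).
#' @param replicates Number of replicate scans (>= 1), default 3.
#' @return List of `replicates` reflectance `nir_spectrum` objects; each
#'   carries `replicate` in its metadata.
#' @export
simulate_scan_set <- function(absorbance, scan_noise_sd = default_noise_model()$scan_sd,
                              replicates = 3L) {
  stopifnot(inherits(absorbance, "nir_spectrum"))
  if (absorbance$state != "absorbance") {
    stop("simulate_scan_set expects an absorbance spectrum", call. = FALSE)
  }
  if (scan_noise_sd < 0) stop("scan_noise_sd must be >= 0", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  lapply(seq_len(replicates), function(i) {
    a <- absorbance$values
    if (scan_noise_sd > 0) a <- a + stats::rnorm(length(a), 0, scan_noise_sd)
    meta <- absorbance$meta
    meta$replicate <- i
    spectrum(absorbance$wavelengths, 10^(-a), "reflectance", meta)
  })
}

#' Generate one bilayer dose: independent scan sets per side
#'
#' Each side of a bilayer tablet is scanned on its own and treated downstream
#' as an independent sample; a side's spectrum contains only that side's
#' components.
#'
#' @param formulation A bilayer [formulation_spec()].
#' @param concentrations Named concentrations (fraction of label); defaults to
#'   the nominal formulation.
#' @param baseline `c(offset, slope)` shared by both sides.
#' @param scan_noise_sd Per-scan absorbance noise sd.
#' @param replicates Scans per side (default 3).
#' @return `list(A = <scan list>, B = <scan list>)`.
#' @export
generate_bilayer_dose <- function(formulation, concentrations = formulation$nominal,
                                  baseline = c(default_noise_model()$baseline_offset_mean, 0),
                                  scan_noise_sd = default_noise_model()$scan_sd,
                                  replicates = 3L) {
  stopifnot(inherits(formulation, "formulation_spec"))
  if (!formulation$bilayer) {
    stop("generate_bilayer_dose called on a monolayer formulation", call. = FALSE)
  }
  out <- lapply(c(A = "A", B = "B"), function(side) {
    a <- simulate_absorbance(formulation, concentrations, baseline = baseline,
                             noise_sd = 0, components = formulation$sides[[side]],
                             meta = list(side = side))
    simulate_scan_set(a, scan_noise_sd, replicates)
  })
  out
}

#' Library generation configuration
#'
#' Describes a synthetic sample library: which brands, how many batches and
#' samples per quality class, the substandard content range, the noise model,
#' and the seed that fixes all randomness.
#'
#' @param brands List of [formulation_spec()] objects.
#' @param qa_batches,qa_samples Quality-assured batches / total QA samples per
#'   brand (samples are spread across the batches as evenly as possible).
#' @param substandard_batches,substandard_samples As above for substandard.
#' @param falsified_batches,falsified_samples As above for falsified.
#' @param substandard_range Percent-of-label interval `(low, high)` from which
#'   substandard content of the affected component is drawn (open interval).
#' @param substandard_component Component whose content is substandard;
#'   default the first API of each brand.
#' @param qa_content_range Fraction-of-label interval for the common
#'   tablet-mass factor of quality-assured (and the unaffected components of
#'   substandard) samples; default `(0.93, 1.07)`, i.e. 93-107 percent,
#'   comfortably inside the 85-115 percent tolerance band.
#' @param falsified_mode `"wrong_compound"` (APIs replaced by a distinct
#'   compound) or `"absent"` (APIs simply missing).
#' @param noise Noise model list, see [default_noise_model()].
#' @param replicates Scans per sample (default 3).
#' @param seed Integer seed; mandatory, fixes all randomness.
#' @return Object of class `library_config`.
#' @export
library_config <- function(brands,
                           qa_batches = 2L, qa_samples = 6L,
                           substandard_batches = 0L, substandard_samples = 0L,
                           falsified_batches = 0L, falsified_samples = 0L,
                           substandard_range = c(66, 85),
                           substandard_component = NULL,
                           qa_content_range = c(0.93, 1.07),
                           falsified_mode = c("wrong_compound", "absent"),
                           noise = default_noise_model(),
                           replicates = 3L,
                           seed) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop("library_config requires an explicit integer seed", call. = FALSE)
  }
  if (inherits(brands, "formulation_spec")) brands <- list(brands)
  for (b in brands) stopifnot(inherits(b, "formulation_spec"))
  counts <- c(qa_batches, qa_samples, substandard_batches, substandard_samples,
              falsified_batches, falsified_samples, replicates)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (qa_samples > 0 && qa_batches == 0) stop("qa samples need >= 1 qa batch", call. = FALSE)
  if (substandard_samples > 0 && substandard_batches == 0) {
    stop("substandard samples need >= 1 substandard batch", call. = FALSE)
  }
  if (falsified_samples > 0 && falsified_batches == 0) {
    stop("falsified samples need >= 1 falsified batch", call. = FALSE)
  }
  if (substandard_range[1L] >= substandard_range[2L] ||
      qa_content_range[1L] >= qa_content_range[2L]) {
    stop("ranges must be ordered (low < high)", call. = FALSE)
  }
  falsified_mode <- match.arg(falsified_mode)
  structure(list(brands = brands, qa_batches = as.integer(qa_batches),
                 qa_samples = as.integer(qa_samples),
                 substandard_batches = as.integer(substandard_batches),
                 substandard_samples = as.integer(substandard_samples),
                 falsified_batches = as.integer(falsified_batches),
                 falsified_samples = as.integer(falsified_samples),
                 substandard_range = as.numeric(substandard_range),
                 substandard_component = substandard_component,
                 qa_content_range = as.numeric(qa_content_range),
                 falsified_mode = falsified_mode,
                 noise = noise, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "library_config")
}

# spread n samples over k batches as evenly as possible: first batches get extras
split_counts <- function(n, k) {
  if (k == 0L) return(integer(0))
  base <- n %/% k
  extra <- n %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

#' Generate a synthetic sample library
#'
#' Draws a full library per the configuration: quality-assured samples share a
#' common bounded tablet-mass content factor; substandard samples have one
#' component's content drawn uniformly in the configured percent range;
#' falsified samples lack the stated APIs (replaced by a wrong compound or
#' absent). Batches share a random affine baseline (batch effect); every
#' sample gets `replicates` reflectance scans. Bilayer brands produce two
#' records per dose (one per side), each carrying only that side's
#' components. Deterministic given the config seed; the caller's RNG state is
#' left untouched.
#'
#' @param config A [library_config()].
#' @return A [sample_set()] with ground-truth quality labels and percent
#'   content per API.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "library_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(config$seed)
  noise <- config$noise
  records <- list()
  grid <- config$brands[[1L]]$grid

  for (form in config$brands) {
    if (!same_grid(grid, form$grid)) stop("all brands must share one grid", call. = FALSE)
    classes <- list(
      quality_assured = list(nb = config$qa_batches, ns = config$qa_samples, tag = "QA"),
      substandard = list(nb = config$substandard_batches,
                         ns = config$substandard_samples, tag = "SS"),
      falsified = list(nb = config$falsified_batches,
                       ns = config$falsified_samples, tag = "FK"))
    sub_comp <- config$substandard_component
    if (is.null(sub_comp)) sub_comp <- form$apis[1L]
    if (!sub_comp %in% form$apis) {
      stop(sprintf("substandard component %s is not an API of brand %s",
                   sub_comp, form$brand), call. = FALSE)
    }
    for (qc in names(classes)) {
      cl <- classes[[qc]]
      if (cl$ns == 0L) next
      per_batch <- split_counts(cl$ns, cl$nb)
      sidx <- 0L
      for (b in seq_len(cl$nb)) {
        if (per_batch[b] == 0L) next
        batch_id <- sprintf("%s-%s%02d", form$brand, cl$tag, b)
        batch_baseline <- c(stats::rnorm(1, noise$baseline_offset_mean, noise$batch_sd),
                            stats::rnorm(1, 0, noise$baseline_slope_sd))
        for (j in seq_len(per_batch[b])) {
          sidx <- sidx + 1L
          sample_id <- sprintf("%s-%s%02d-%03d", form$brand, cl$tag, b, sidx)
          draw <- draw_concentrations(form, qc, config, sub_comp)
          base <- batch_baseline +
            c(stats::rnorm(1, 0, noise$baseline_offset_sd),
              stats::rnorm(1, 0, noise$baseline_slope_sd))
          records <- c(records,
                       make_dose_records(form, draw, base, config, sample_id,
                                         batch_id, qc))
        }
      }
    }
  }
  sample_set(records, grid = grid)
}

# concentration + ground-truth draw for one dose
draw_concentrations <- function(form, quality_class, config, sub_comp) {
  nominal <- form$nominal
  qa_rng <- config$qa_content_range
  m <- stats::runif(1, qa_rng[1L], qa_rng[2L])
  conc <- nominal * m
  sapi <- stats::setNames(rep(100 * m, length(form$apis)), form$apis)
  if (quality_class == "substandard") {
    lo <- config$substandard_range[1L] / 100
    hi <- config$substandard_range[2L] / 100
    cs <- stats::runif(1, lo, hi)
    conc[sub_comp] <- nominal[sub_comp] * cs
    sapi[sub_comp] <- 100 * cs
  } else if (quality_class == "falsified") {
    conc[form$apis] <- 0
    sapi[form$apis] <- 0
    if (config$falsified_mode == "wrong_compound") {
      conc <- c(conc, wrong_compound = stats::runif(1, 0.9, 1.1))
    }
  }
  list(conc = conc, sapi = sapi)
}

# build the sample_record(s) for one dose; bilayer doses give one record per side
make_dose_records <- function(form, draw, base, config, sample_id, batch_id,
                              quality_class) {
  noise <- config$noise
  sim_form <- form
  if (quality_class == "falsified" && config$falsified_mode == "wrong_compound" &&
      !"wrong_compound" %in% names(form$components)) {
    wc <- component_signature("wrong_compound", list(c(762, 7, 0.85)), form$grid)
    sim_form$components$wrong_compound <- wc
    sim_form$nominal <- c(sim_form$nominal, wrong_compound = 0)
    if (sim_form$bilayer) {
      # a falsifier does not reproduce the bilayer chemistry; put the wrong
      # compound in both layers
      sim_form$sides$A <- c(sim_form$sides$A, "wrong_compound")
      sim_form$sides$B <- c(sim_form$sides$B, "wrong_compound")
    }
  }
  sides <- if (form$bilayer) c("A", "B") else NA_character_
  lapply(sides, function(side) {
    comps <- if (is.na(side)) NULL else sim_form$sides[[side]]
    a <- simulate_absorbance(sim_form, draw$conc, baseline = base, noise_sd = 0,
                             components = comps,
                             meta = list(sample_id = sample_id, side = side))
    scans <- simulate_scan_set(a, noise$scan_sd, config$replicates)
    rid <- if (is.na(side)) sample_id else paste0(sample_id, "-", side)
    for (k in seq_along(scans)) scans[[k]]$meta$sample_id <- rid
    side_apis <- if (is.na(side)) form$apis else intersect(form$apis, form$sides[[side]])
    sapi <- draw$sapi[intersect(names(draw$sapi), side_apis)]
    sample_record(rid, form$brand, batch_id, quality_class, sapi, scans, side)
  })
}
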