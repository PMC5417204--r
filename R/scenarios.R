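#' Example library scenarios
#'
#' Preset [library_config()]s emulating the structure of well-known field
#' screening situations, used by the test-suite and the acceptance script.
#'
#' * `scenario_act_duo()`: a WHO-prequalified artemether-lumefantrine brand
#'   with 23 quality-assured batches (60 samples) and 3 falsified batches
#'   (22 samples) — the large, well-characterized library case.
#' * `scenario_mono_small()`: an artesunate monotherapy with 36
#'   quality-assured samples in 2 batches and a single falsified sample —
#'   the minimal two-batch cross-validation case.
#' * `scenario_bilayer()`: a bilayer artesunate-amodiaquine formulation
#'   scanned per side.
#' * `scenario_quant(analyte_present)`: a monotherapy calibration set with a
#'   wide content spread for regression; with `analyte_present = FALSE` the
#'   analyte's signature is removed from the spectra (content varies but the
#'   spectra carry no information about it), the regime in which quantitation
#'   must fail.
#'
#' @param seed Integer seed.
#' @param grid Wavelength grid.
#' @param n Number of samples (quantitation scenarios).
#' @param analyte_present Logical; see above.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_act_duo <- function(seed, grid = default_grid()) {
  sig <- default_signatures(grid)
  form <- formulation_spec(
    brand = "ACTduo",
    components = sig[c("artemether", "lumefantrine", "excipient")],
    nominal = c(artemether = 1, lumefantrine = 1, excipient = 1),
    apis = c("artemether", "lumefantrine"))
  library_config(form, qa_batches = 23L, qa_samples = 60L,
                 falsified_batches = 3L, falsified_samples = 22L,
                 seed = seed)
}

#' @rdname scenarios
#' @export
scenario_mono_small <- function(seed, grid = default_grid()) {
  sig <- default_signatures(grid)
  form <- formulation_spec(
    brand = "MonoAS",
    components = sig[c("artesunate", "excipient")],
    nominal = c(artesunate = 1, excipient = 1),
    apis = "artesunate")
  library_config(form, qa_batches = 2L, qa_samples = 36L,
                 falsified_batches = 1L, falsified_samples = 1L,
                 seed = seed)
}

#' @rdname scenarios
#' @export
scenario_bilayer <- function(seed, grid = default_grid()) {
  sig <- default_signatures(grid)
  form <- formulation_spec(
    brand = "BiASAQ",
    components = sig[c("artesunate", "amodiaquine", "excipient")],
    nominal = c(artesunate = 1, amodiaquine = 1, excipient = 1),
    apis = c("artesunate", "amodiaquine"),
    bilayer = TRUE,
    sides = list(A = c("artesunate", "excipient"), B = "amodiaquine"))
  library_config(form, qa_batches = 4L, qa_samples = 10L,
                 falsified_batches = 1L, falsified_samples = 2L,
                 seed = seed)
}

#' @rdname scenarios
#' @export
scenario_quant <- function(seed, n = 30L, analyte_present = TRUE,
                           grid = default_grid()) {
  sig <- default_signatures(grid)
  analyte <- if (analyte_present) {
    sig$artesunate
  } else {
    # content varies on paper but leaves no trace in the spectrum
    component_signature("artesunate", list(), grid)
  }
  form <- formulation_spec(
    brand = "QuantAS",
    components = list(artesunate = analyte, excipient = sig$excipient),
    nominal = c(artesunate = 1, excipient = 1),
    apis = "artesunate")
  # wide substandard spread (70-110% of label) so the calibration has leverage
  library_config(form, qa_batches = 0L, qa_samples = 0L,
                 substandard_batches = 5L, substandard_samples = n,
                 substandard_range = c(70, 110),
                 seed = seed)
}
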