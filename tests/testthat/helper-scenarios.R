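# shared fixtures: small synthetic worlds built in code

tiny_grid <- function() seq(740, 1060, by = 2)

tiny_formulation <- function(grid = tiny_grid()) {
  sig <- default_signatures(grid)
  formulation_spec("TinyBrand",
                   components = sig[c("artesunate", "excipient")],
                   nominal = c(artesunate = 1, excipient = 1),
                   apis = "artesunate")
}

tiny_config <- function(seed = 42L, qa_samples = 6L, falsified_samples = 2L, ...) {
  library_config(tiny_formulation(), qa_batches = 2L, qa_samples = qa_samples,
                 falsified_batches = 1L, falsified_samples = falsified_samples,
                 seed = seed, ...)
}

bilayer_formulation <- function(grid = tiny_grid(),
                                amodiaquine_amplitude = 0.55) {
  sig <- default_signatures(grid)
  amo <- component_signature("amodiaquine",
                             list(c(850, 9, amodiaquine_amplitude),
                                  c(960, 9, amodiaquine_amplitude * 0.65 / 0.55),
                                  c(1040, 9, amodiaquine_amplitude * 0.45 / 0.55)),
                             grid)
  formulation_spec("TinyBi",
                   components = list(artesunate = sig$artesunate,
                                     amodiaquine = amo,
                                     excipient = sig$excipient),
                   nominal = c(artesunate = 1, amodiaquine = 1, excipient = 1),
                   apis = c("artesunate", "amodiaquine"),
                   bilayer = TRUE,
                   sides = list(A = c("artesunate", "excipient"), B = "amodiaquine"))
}

# a flat synthetic spectrum wrapper for hand-built inputs
mk_spec <- function(values, state = "absorbance", wl = seq_along(values) + 739,
                    meta = list()) {
  spectrum(wl, values, state, meta)
}

quality_of <- function(set) {
  vapply(set$records, function(r) r$quality_class, character(1))
}
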