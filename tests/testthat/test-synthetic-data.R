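test_that("component signatures are Gaussian band sums with validated inputs", {
  grid <- tiny_grid()
  one <- component_signature("x", list(c(900, 30, 1)), grid)
  expect_equal(grid[which.max(one$curve)], 900)
  expect_equal(max(one$curve), 1)

  expect_equal(component_signature("none", list(), grid)$curve, rep(0, length(grid)))

  # additivity oracle: a multi-band curve equals the pointwise sum of its
  # single-band curves, so two identical bands double the single-band curve
  set.seed(7)
  for (i in 1:5) {
    band <- c(runif(1, 760, 1040), runif(1, 5, 40), runif(1, 0.1, 1))
    single <- component_signature("s", list(band), grid)$curve
    double <- component_signature("d", list(band, band), grid)$curve
    expect_equal(double, 2 * single, tolerance = 1e-12)
  }

  expect_error(component_signature("bad", list(c(900, -1, 1)), grid), "width")
  expect_error(component_signature("bad", list(c(600, 10, 1)), grid), "740-1060")
  expect_error(component_signature("bad", list(c(900, 10, 1)), numeric(0)), "empty")
  expect_error(component_signature("bad", list(c(900, 10, 1)), c(800, 800, 900)),
               "increasing")
})

test_that("simulate_absorbance follows the Beer-Lambert additive model", {
  form <- tiny_formulation()
  zero <- simulate_absorbance(form, c(artesunate = 0, excipient = 0))
  expect_equal(zero$values, rep(0, length(form$grid)))
  expect_identical(zero$state, "absorbance")

  c1 <- c(artesunate = 0.8, excipient = 1.1)
  a1 <- simulate_absorbance(form, c1)
  a2 <- simulate_absorbance(form, 2 * c1)
  expect_equal(a2$values, 2 * a1$values, tolerance = 1e-12)

  # linearity in each component by finite differences
  delta <- 0.37
  for (comp in names(form$components)) {
    cb <- c1; cb[comp] <- cb[comp] + delta
    diffed <- simulate_absorbance(form, cb)$values - a1$values
    expect_equal(diffed, delta * form$components[[comp]]$curve, tolerance = 1e-10)
  }

  # baseline is affine in wavelength
  ab <- simulate_absorbance(form, c1, baseline = c(0.3, 1e-3))
  expect_equal(ab$values - a1$values, 0.3 + 1e-3 * (form$grid - form$grid[1]),
               tolerance = 1e-12)

  expect_error(simulate_absorbance(form, c1, noise_sd = -1), "noise_sd")
  expect_error(simulate_absorbance(form, c(nope = 1)), "named")
})

test_that("simulated absorbance noise has the nominal standard deviation", {
  form <- tiny_formulation()
  set.seed(11)
  draws <- replicate(1000,
    simulate_absorbance(form, c(artesunate = 1, excipient = 1),
                        noise_sd = 0.01)$values[50])
  expect_equal(sd(draws), 0.01, tolerance = 0.1)
})

test_that("scan sets are reflectance replicates that invert exactly at zero noise", {
  form <- tiny_formulation()
  a0 <- simulate_absorbance(form, c(artesunate = 0, excipient = 0))
  scans <- simulate_scan_set(a0, scan_noise_sd = 0, replicates = 3)
  expect_length(scans, 3)
  for (s in scans) {
    expect_identical(s$state, "reflectance")
    expect_equal(s$values, rep(1, length(form$grid)))
  }

  a <- simulate_absorbance(form, c(artesunate = 0.9, excipient = 1),
                           baseline = c(0.2, 0))
  clean <- simulate_scan_set(a, scan_noise_sd = 0, replicates = 2)
  expect_equal(to_absorbance(clean[[1]])$values, a$values, tolerance = 1e-12)

  set.seed(3)
  noisy <- simulate_scan_set(a, scan_noise_sd = 1e-3, replicates = 3)
  expect_length(noisy, 3)
  expect_false(identical(noisy[[1]]$values, noisy[[2]]$values))
  expect_equal(vapply(noisy, function(s) s$meta$replicate, integer(1)), 1:3)

  expect_error(simulate_scan_set(a, scan_noise_sd = -0.1), "scan_noise_sd")
  expect_error(simulate_scan_set(a, replicates = 0), "replicates")
  expect_error(simulate_scan_set(clean[[1]]), "absorbance")
})

test_that("generate_library conserves configured class and batch counts", {
  cfg <- library_config(tiny_formulation(), qa_batches = 23L, qa_samples = 60L,
                        falsified_batches = 3L, falsified_samples = 22L, seed = 5L)
  set <- generate_library(cfg)
  qc <- quality_of(set)
  expect_equal(sum(qc == "quality_assured"), 60)
  expect_equal(sum(qc == "falsified"), 22)
  batches <- vapply(set$records, function(r) r$batch_id, character(1))
  expect_equal(length(unique(batches[qc == "quality_assured"])), 23)
  expect_equal(length(unique(batches[qc == "falsified"])), 3)
  # replicate count per sample
  expect_true(all(vapply(set$records, function(r) length(r$scans), integer(1)) == 3L))
})

test_that("substandard content lands in the configured range and QA in band", {
  cfg <- library_config(tiny_formulation(), qa_batches = 2L, qa_samples = 8L,
                        substandard_batches = 3L, substandard_samples = 15L,
                        substandard_range = c(66, 85), seed = 9L)
  set <- generate_library(cfg)
  ss <- Filter(function(r) r$quality_class == "substandard", set$records)
  vals <- vapply(ss, function(r) r$sapi[["artesunate"]], numeric(1))
  expect_length(vals, 15)
  expect_true(all(vals > 66 & vals < 85))
  qa <- Filter(function(r) r$quality_class == "quality_assured", set$records)
  qa_vals <- vapply(qa, function(r) r$sapi[["artesunate"]], numeric(1))
  expect_true(all(qa_vals >= 85 & qa_vals <= 115))
})

test_that("generation is seed-deterministic and restores the caller's RNG", {
  cfg <- tiny_config(seed = 123L)
  set.seed(77)
  before <- .Random.seed
  s1 <- generate_library(cfg)
  expect_identical(.Random.seed, before)
  s2 <- generate_library(cfg)
  expect_identical(s1, s2)
  s3 <- generate_library(tiny_config(seed = 124L))
  expect_false(identical(s1, s3))
})

test_that("config validation rejects impossible quality mixes", {
  expect_error(library_config(tiny_formulation(), qa_batches = -1L, seed = 1L), ">= 0")
  expect_error(library_config(tiny_formulation(), qa_batches = 0L, qa_samples = 5L,
                              seed = 1L), "batch")
  expect_error(library_config(tiny_formulation(), falsified_samples = 2L,
                              falsified_batches = 0L, seed = 1L), "batch")
  expect_error(library_config(tiny_formulation(), substandard_range = c(85, 66),
                              seed = 1L), "ordered")
  expect_error(library_config(tiny_formulation()), "seed")
})

test_that("falsified samples carry no API and differ by mode", {
  for (mode in c("wrong_compound", "absent")) {
    set <- generate_library(tiny_config(seed = 31L, falsified_mode = mode))
    fk <- Filter(function(r) r$quality_class == "falsified", set$records)
    expect_true(all(vapply(fk, function(r) r$sapi[["artesunate"]], numeric(1)) == 0))
  }
  # wrong-compound spectra show the displaced 762 nm band, absent-mode ones do not
  grid <- tiny_grid()
  at762 <- which(grid == 762)
  mean_abs_at <- function(set, idx) {
    fk <- Filter(function(r) r$quality_class == "falsified", set$records)
    mean(vapply(fk, function(r) to_absorbance(r$scans[[1]])$values[idx], numeric(1)))
  }
  wc <- generate_library(tiny_config(seed = 31L, falsified_mode = "wrong_compound"))
  ab <- generate_library(tiny_config(seed = 31L, falsified_mode = "absent"))
  expect_gt(mean_abs_at(wc, at762) - mean_abs_at(ab, at762), 0.5)
})

test_that("bilayer doses yield independent per-side scan sets", {
  form <- bilayer_formulation()
  set.seed(1)
  dose <- generate_bilayer_dose(form, replicates = 3)
  expect_named(dose, c("A", "B"))
  expect_length(dose$A, 3)
  expect_length(dose$B, 3)

  # side A is built from side-A components only: changing the amodiaquine
  # amplitude cannot change side A
  form0 <- bilayer_formulation(amodiaquine_amplitude = 0)
  set.seed(1)
  dose0 <- generate_bilayer_dose(form0, replicates = 3)
  for (i in 1:3) {
    expect_identical(dose$A[[i]]$values, dose0$A[[i]]$values)
    expect_false(identical(dose$B[[i]]$values, dose0$B[[i]]$values))
  }

  expect_error(generate_bilayer_dose(tiny_formulation()), "monolayer")
})

test_that("bilayer brands generate one record per side, treated independently", {
  cfg <- library_config(bilayer_formulation(), qa_batches = 2L, qa_samples = 4L,
                        seed = 8L)
  set <- generate_library(cfg)
  expect_length(set$records, 8)
  sides <- vapply(set$records, function(r) r$side, character(1))
  expect_equal(sum(sides == "A"), 4)
  expect_equal(sum(sides == "B"), 4)
  a_rec <- set$records[[which(sides == "A")[1]]]
  b_rec <- set$records[[which(sides == "B")[1]]]
  expect_named(a_rec$sapi, "artesunate")
  expect_named(b_rec$sapi, "amodiaquine")
  # independent sample records with their own ids
  expect_false(a_rec$sample_id == b_rec$sample_id)
})

test_that("falsified and QA clusters separate in the top-2 PCA plane", {
  for (seed in 1:5) {
    set <- generate_library(tiny_config(seed = 600L + seed, qa_samples = 10L,
                                        falsified_samples = 4L))
    spectra <- lapply(set$records, preprocess_record, pipeline = "qualitative")
    sc <- pca_scores(spectra, n_components = 2)$scores
    qa <- quality_of(set) == "quality_assured"
    # linear separability along the direction joining the class means
    dir <- colMeans(sc[!qa, , drop = FALSE]) - colMeans(sc[qa, , drop = FALSE])
    proj <- sc %*% dir
    expect_gt(min(proj[!qa]), max(proj[qa]))
  }
})
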