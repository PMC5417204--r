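# hand-build a class model with known score geometry
manual_model <- function(mu, sigma, threshold, p = 4L) {
  k <- length(mu)
  proj <- diag(1, k, p)   # scores = first k channels
  structure(list(grid = as.numeric(740:(739 + p)), projection = proj,
                 center = rep(0, p), mean = mu, covariance = sigma,
                 threshold = threshold, threshold_quantile = NA_real_, k = k,
                 variance_kept = 1, shrinkage = 0, explained = rep(1 / k, k),
                 manifest = data.frame(sample_id = character(0),
                                       batch_id = character(0))),
            class = "class_model")
}

d2_spec <- function(values, wl = 740:(739 + length(values))) {
  spectrum(wl, values, "second_derivative")
}

qual_spectra <- function(set, classes = "quality_assured") {
  recs <- Filter(function(r) r$quality_class %in% classes, set$records)
  lapply(recs, preprocess_record, pipeline = "qualitative")
}

test_that("fit_class_model enforces the falsified-exclusion rule and degeneracy checks", {
  set <- generate_library(tiny_config(seed = 41L))
  all_spec <- qual_spectra(set, c("quality_assured", "falsified"))
  expect_error(fit_class_model(all_spec), "falsified.*excluded from all training sets")

  qa <- qual_spectra(set)
  expect_error(fit_class_model(qa[1:2]), "at least 3")

  same <- replicate(5, d2_spec(c(1, 2, 3, 4)), simplify = FALSE)
  expect_error(fit_class_model(same), "identical.*variation")

  m <- fit_class_model(qa, variance_kept = 0.99)
  expect_lte(m$k, length(qa) - 2L)
  expect_gte(m$k, 1L)
  # projection rows orthonormal
  expect_equal(tcrossprod(m$projection), diag(m$k), tolerance = 1e-10)
  # covariance symmetric positive definite
  expect_equal(m$covariance, t(m$covariance))
  expect_true(all(eigen(m$covariance, symmetric = TRUE)$values > 0))
  expect_false(any(m$manifest$sample_id %in%
                     names(Filter(function(r) r$quality_class == "falsified",
                                  set$records))))
})

test_that("mahalanobis_distance matches hand and z-score geometry", {
  # score exactly at the class mean
  m1 <- manual_model(mu = c(1, -2), sigma = diag(2), threshold = 3)
  at_mean <- d2_spec(c(1, -2, 0, 0))
  expect_equal(mahalanobis_distance(at_mean, m1), 0)

  # k = 1: distance reduces to |z|
  mz <- manual_model(mu = 5, sigma = matrix(4), threshold = 3, p = 4L)
  expect_equal(mahalanobis_distance(d2_spec(c(9, 0, 0, 0)), mz), 2)

  # k = 2 quadratic form against the explicit 2x2 inverse
  sig <- matrix(c(2, 1, 1, 2), 2)
  m2 <- manual_model(mu = c(0, 0), sigma = sig, threshold = 3)
  expect_equal(mahalanobis_distance(d2_spec(c(1, 1, 0, 0)), m2), sqrt(2 / 3),
               tolerance = 1e-12)

  expect_error(mahalanobis_distance(d2_spec(c(1, 1, 0, 0), wl = 800:803), m2), "grid")
  wrong_state <- spectrum(m2$grid, c(1, 1, 0, 0), "absorbance")
  expect_error(mahalanobis_distance(wrong_state, m2), "second-derivative")
})

test_that("fitted distances agree with a brute-force oracle for k <= 3", {
  set.seed(51)
  for (trial in 1:5) {
    r <- sample(1:3, 1)
    n <- sample((r + 3):10, 1)
    p <- 8L
    # data with exactly r directions of variation
    scoresT <- matrix(rnorm(n * r), n, r)
    load <- matrix(rnorm(r * p), r, p)
    X <- scoresT %*% load + matrix(rnorm(n * p, sd = 1e-8), n, p)
    spectra <- lapply(seq_len(n), function(i) d2_spec(X[i, ]))
    m <- fit_class_model(spectra, batch_ids = rep("b", n),
                         variance_kept = 1 - 1e-9, shrinkage = 0)
    expect_equal(m$k, r)
    # oracle: explicit projection + stats::mahalanobis with a dense inverse
    sc <- sweep(X, 2, m$center) %*% t(m$projection)
    d_oracle <- sqrt(stats::mahalanobis(sc, m$mean, m$covariance))
    d_impl <- vapply(spectra, mahalanobis_distance, numeric(1), model = m)
    expect_equal(d_impl, unname(d_oracle), tolerance = 1e-8)
  }
})

test_that("distances are invariant to invertible linear maps of the spectra", {
  set.seed(52)
  n <- 7L; r <- 2L; p <- 6L
  X <- matrix(rnorm(n * r), n, r) %*% matrix(rnorm(r * p), r, p)
  M <- diag(p) + matrix(rnorm(p * p, sd = 0.2), p, p)   # invertible w.h.p.
  expect_gt(abs(det(M)), 1e-6)
  fit_on <- function(mat) {
    fit_class_model(lapply(seq_len(n), function(i) d2_spec(mat[i, ])),
                    batch_ids = rep("b", n), variance_kept = 1 - 1e-9,
                    shrinkage = 0)
  }
  m0 <- fit_on(X)
  m1 <- fit_on(X %*% M)
  d0 <- vapply(seq_len(n), function(i) mahalanobis_distance(d2_spec(X[i, ]), m0),
               numeric(1))
  d1 <- vapply(seq_len(n), function(i) mahalanobis_distance(d2_spec((X %*% M)[i, ]), m1),
               numeric(1))
  expect_equal(d0, d1, tolerance = 1e-8)
})

test_that("calibrate_threshold matches chi-square geometry", {
  expect_equal(calibrate_threshold(1, 0.6827), 1.0, tolerance = 1e-3)
  for (q in c(0.5, 0.9, 0.99, 0.9999)) {
    expect_equal(calibrate_threshold(2, q), sqrt(-2 * log(1 - q)), tolerance = 1e-12)
  }
  qs <- c(0.5, 0.9, 0.99, 0.999, 0.99999)
  expect_true(all(diff(vapply(qs, calibrate_threshold, numeric(1), k = 3)) > 0))
  expect_error(calibrate_threshold(2, 1), "quantile")
  expect_error(calibrate_threshold(0, 0.99), "k")
})

test_that("classify accepts the training mean, the boundary, and rejects falsifieds", {
  set <- generate_library(tiny_config(seed = 43L))
  qa <- qual_spectra(set)
  m <- fit_class_model(qa)
  center_spec <- spectrum(m$grid, m$center, "second_derivative")
  expect_identical(classify(center_spec, m)$verdict, "accept")

  fk <- qual_spectra(set, "falsified")
  for (s in fk) {
    res <- classify(s, m)
    expect_identical(res$verdict, "reject")
    expect_gt(res$distance, res$threshold)
  }

  # declared tie rule: d exactly at the threshold is genuine
  m_tie <- m
  m_tie$threshold <- mahalanobis_distance(qa[[1]], m)
  expect_identical(classify(qa[[1]], m_tie)$verdict, "accept")
})

test_that("leave-batch-out evaluation separates the two-batch monotherapy world", {
  set <- generate_library(scenario_mono_small(71L, grid = tiny_grid()))
  res <- leave_batch_out_evaluate(set, "MonoAS")
  expect_equal(res$sensitivity, 100)
  expect_equal(res$specificity, 100)
  expect_equal(res$tp + res$fp + res$tn + res$fn, 37)

  # exclusion audit: no QA decision used a model trained on the test batch,
  # and falsified decisions trained on all (and only) QA batches
  dd <- res$details
  qa_rows <- dd[dd$quality_class == "quality_assured", ]
  expect_true(all(vapply(seq_len(nrow(qa_rows)), function(i) {
    !qa_rows$batch_id[i] %in% strsplit(qa_rows$train_batches[i], "|", fixed = TRUE)[[1]]
  }, logical(1))))
  fk_rows <- dd[dd$quality_class == "falsified", ]
  qa_batches <- sort(unique(qa_rows$batch_id))
  expect_true(all(fk_rows$train_batches ==
                    paste(qa_batches, collapse = "|")))
})

test_that("leave-batch-out degenerate inputs fail or flag as specified", {
  single <- generate_library(library_config(tiny_formulation(), qa_batches = 1L,
                                            qa_samples = 5L, seed = 61L))
  expect_error(leave_batch_out_evaluate(single, "TinyBrand"), "2 quality-assured batches")

  no_fk <- generate_library(library_config(tiny_formulation(), qa_batches = 2L,
                                           qa_samples = 8L, seed = 62L))
  expect_warning(res <- leave_batch_out_evaluate(no_fk, "TinyBrand"),
                 "specificity-only")
  expect_true(res$specificity_only)
  expect_true(is.na(res$sensitivity))
  expect_equal(res$specificity, 100)

  expect_error(leave_batch_out_evaluate(no_fk, "NoSuchBrand"), "no samples")
})

test_that("pca_scores centers, orders and reconstructs", {
  set.seed(53)
  X <- matrix(rnorm(60), 10, 6)
  full <- pca_scores(X, n_components = 6)
  expect_equal(unname(colMeans(full$scores)), rep(0, 6), tolerance = 1e-10)
  expect_true(all(diff(full$explained_variance) <= 1e-12))
  recon <- full$scores %*% t(full$loadings) +
    matrix(colMeans(X), 10, 6, byrow = TRUE)
  expect_equal(recon, X, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pca_scores(X, n_components = 10), "n_components")
})
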