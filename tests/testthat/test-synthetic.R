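test_that("mean imputation and min/range scaling follow the stated rules", {
  X <- cbind(1, c(2, NA, 4), c(1, 3, 5))
  ds <- gwas_dataset(X, matrix(0, 3, 2), c(1, -1, 1))
  out <- preprocess_covariates(ds)
  # (2, NA, 4) -> imputed 3 -> scaled (0, 0.5, 1)
  expect_equal(out$X[, 2], c(0, 0.5, 1))
  expect_equal(out$X[, 3], c(0, 0.5, 1))
  expect_equal(out$X[, 1], rep(1, 3))
})

test_that("degenerate covariate columns are rejected", {
  Xc <- cbind(1, c(2, 2, 2))
  ds <- gwas_dataset(Xc, matrix(0, 3, 1), c(1, -1, 1))
  expect_error(preprocess_covariates(ds), "zero range")
  Xm <- cbind(1, c(NA_real_, NA_real_, NA_real_))
  dm <- gwas_dataset(Xm, matrix(0, 3, 1), c(1, -1, 1))
  expect_error(preprocess_covariates(dm), "all-missing")
})

test_that("generated data respect their declared moments and ranges", {
  ds <- simulate_gwas_data(n = 400, p = 200, k = 4, maf_range = c(0.1, 0.4),
                           n_causal = 5, seed = 21)
  truth <- attr(ds, "truth")
  emp <- colMeans(ds$S)
  se3 <- 3 * sqrt(truth$maf * (1 - truth$maf) / 400)
  expect_gt(mean(abs(emp - truth$maf) <= se3), 0.98)
  prep <- preprocess_covariates(ds)
  expect_true(all(prep$X[, -1] >= 0 & prep$X[, -1] <= 1))
  expect_true(all(prep$X[, 1] == 1))
  expect_true(all(ds$y %in% c(-1, 1)))
})

test_that("generation is deterministic under a fixed seed", {
  a <- simulate_gwas_data(n = 50, p = 20, seed = 5)
  b <- simulate_gwas_data(n = 50, p = 20, seed = 5)
  expect_identical(a$S, b$S)
  expect_identical(a$X, b$X)
  expect_identical(a$y, b$y)
  d1 <- tempfile(); d2 <- tempfile(); g1 <- tempfile(); g2 <- tempfile()
  write_gwas_data(a, d1, g1); write_gwas_data(b, d2, g2)
  expect_identical(readLines(d1), readLines(d2))
  expect_identical(readLines(g1), readLines(g2))
})

test_that("invalid generator settings are rejected", {
  expect_error(simulate_gwas_data(maf_range = c(0, 0.5)), "degenerate maf")
  expect_error(simulate_gwas_data(p = 10, n_causal = 11))
})

test_that("datasets round-trip through the TSV/CSV dialect", {
  ds <- simulate_gwas_data(n = 20, p = 10, missing_rate = 0, seed = 6)
  ph <- tempfile(fileext = ".tsv"); ge <- tempfile(fileext = ".csv")
  write_gwas_data(ds, ph, ge)
  back <- read_gwas_data(ph, ge)
  expect_equal(unname(back$X), unname(ds$X), tolerance = 1e-9)
  expect_equal(unname(back$S), unname(ds$S))
  expect_equal(back$y, ds$y)
})
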