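test_that("the y'X layout packs row copies as specified", {
  # n = 2, k = 2, N2 = 8: (y1 X1, y1 X1, y2 X2, y2 X2)
  ctx <- emu_ctx(logN = 4, L = 19)
  X <- cbind(c(1, 1), c(0.5, 0.25))
  S <- cbind(c(1, 0), c(0, 1))
  y <- c(1, -1)
  ds <- gwas_dataset(X, S, y)
  plan <- level_plan(2, 0, 0, k = 2, params = he_params(4, 19, 43, 51, 60))
  enc <- encode_dataset(ds, ctx, plan)
  expect_equal(ct_decrypt(enc$ct_yX),
               c(1, 0.5, 1, 0.5, -1, -0.25, -1, -0.25))
  expect_equal(ct_decrypt(enc$ct_y), c(1, 1, 1, 1, 0, 0, 0, 0))
})

test_that("the intercept-column SNP ciphertexts encrypt the SNP rows exactly", {
  ctx <- emu_ctx(logN = 7, L = 19)
  ds <- toy_dataset(n = 8, p = 16, k = 4, seed = 9)
  plan <- level_plan(2, 3, 0, k = 4, params = ctx$params)
  enc <- encode_dataset(ds, ctx, plan)
  for (i in c(1, 5)) {
    expect_equal(ct_decrypt(enc$ct_xS[[1]][[i]][[1]], n = 16), ds$S[i, ])
  }
  # and levels follow the plan
  expect_equal(enc$ct_xS[[1]][[1]][[1]]$level, plan$levels$xS)
  expect_equal(enc$ct_sigma[[1]]$level, plan$levels$Sigma)
})

test_that("the packed family decodes back to X, S, y", {
  ctx <- emu_ctx(logN = 7, L = 19)
  ds <- toy_dataset(n = 8, p = 16, k = 4, seed = 10)
  plan <- level_plan(2, 3, 0, k = 4, params = ctx$params)
  enc <- encode_dataset(ds, ctx, plan)
  back <- decode_encoded_dataset(enc)
  expect_equal(back$X, unname(ds$X), tolerance = 1e-12)
  expect_equal(back$S, unname(ds$S), tolerance = 1e-12)
  expect_equal(back$y01, ifelse(ds$y > 0, 1, 0), tolerance = 1e-12)
})

test_that("padding to powers of two leaves the estimates unchanged", {
  ds <- simulate_gwas_data(n = 13, p = 16, k = 3, n_causal = 1, effect_size = 2,
                           missing_rate = 0, seed = 11)
  prep <- preprocess_covariates(ds)
  raw <- semi_parallel_plain(prep$X, prep$S, prep$y, num_iter = 2)
  padded <- pad_dataset(prep)           # 13 -> 16 samples, 3 -> 4 covariates
  expect_equal(padded$n, 16L)
  expect_equal(padded$k, 4L)
  expect_true(all(padded$X[14:16, ] == 0))   # intercept position included
  pp <- semi_parallel_plain(padded$X, padded$S, padded$y, num_iter = 2)
  # numerators/denominators share one padding factor; the estimates match
  expect_equal(pp$result$beta, raw$result$beta, tolerance = 1e-9)
  expect_equal(pp$result$z, raw$result$z, tolerance = 1e-9)
  expect_equal(pp$result$pvalue, raw$result$pvalue, tolerance = 1e-9)
  fac <- pp$det_a / raw$det_a
  expect_equal(pp$beta_star, fac * raw$beta_star, tolerance = 1e-8)
  expect_equal(pp$beta_dagger, fac * raw$beta_dagger, tolerance = 1e-8)
  # idempotent on power-of-two sizes
  again <- pad_dataset(padded)
  expect_equal(dim(again$X), dim(padded$X))
})

test_that("packing violations are reported", {
  ctx <- emu_ctx(logN = 4, L = 19)     # 8 slots
  ds <- toy_dataset(n = 8, p = 4, k = 4, seed = 12)
  plan <- level_plan(2, 3, 0, k = 4, params = ctx$params)
  expect_error(encode_dataset(ds, ctx, plan), "packing error")
  Xb <- cbind(1, matrix(0.5, 4, 1)); Sb <- matrix(2, 4, 2)
  expect_error(gwas_dataset(Xb, Sb, rep(1, 4)), "validation error")
})
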