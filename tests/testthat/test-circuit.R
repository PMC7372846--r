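# step-level verification of the encrypted pipeline on the exact emulator,
# against dense linear-algebra oracles computed straight from the data

toy_run <- function(seed = 50, n = 8, p = 16, k = 4, s = 3, logN = 7) {
  ctx <- emu_ctx(logN = logN, L = 19)
  ds <- toy_dataset(n = n, p = p, k = k, seed = seed)
  plan <- level_plan(2, s, 0, k = k, params = ctx$params)
  enc <- encode_dataset(ds, ctx, plan)
  out <- run_encrypted_gwas(enc, keep_intermediates = TRUE)
  sp <- semi_parallel_plain(ds$X, ds$S, ds$y, num_iter = 2)
  list(ds = ds, enc = enc, out = out, sp = sp, plan = plan, ctx = ctx)
}

test_that("first training iteration matches its closed form", {
  ctx <- emu_ctx(logN = 7, L = 19)
  ds <- toy_dataset(n = 8, p = 16, k = 4, seed = 51)
  plan <- level_plan(2, 3, 0, k = 4, params = ctx$params)
  enc <- encode_dataset(ds, ctx, plan)
  b1 <- train_covariate_model(enc, num_iter = 1)
  V <- ds$y * ds$X
  expected <- default_gd_step(1) * 0.5 * colSums(V) / ds$n_real
  expect_equal(ct_decrypt(b1, n = 4), expected, tolerance = 1e-10)
  expect_equal(b1$level, ctx$L - 1L)
})

test_that("training is inert on antisymmetric balanced data", {
  X0 <- cbind(1, matrix(runif(9), 3))
  X <- rbind(X0, X0)
  S <- matrix(rbinom(12, 1, 0.5), 6, 2)
  ds <- pad_dataset(gwas_dataset(X, S, c(1, 1, 1, -1, -1, -1)))
  ctx <- emu_ctx(logN = 7, L = 19)
  plan <- level_plan(2, 3, 0, k = 4, params = ctx$params)
  enc <- encode_dataset(ds, ctx, plan)
  b <- train_covariate_model(enc, num_iter = 2)
  expect_lt(max(abs(ct_decrypt(b, n = 4))), 1e-12)
})

test_that("steps 1-2 produce predictions, weights and working response", {
  tr <- toy_run(seed = 52)
  ints <- tr$out$intermediates
  n <- tr$enc$n; N2 <- tr$ctx$N2
  sel <- seq(1, by = N2 / n, length.out = n)
  expect_equal(ct_decrypt(ints$yhat)[sel], tr$sp$yhat, tolerance = 1e-9)
  # garbage annihilated: yhat is constant within each sample block
  yh <- ct_decrypt(ints$yhat)
  expect_lt(max(abs(yh - rep(tr$sp$yhat, each = N2 / n))), 1e-9)
  p <- ct_decrypt(ints$p)[sel]
  w <- ct_decrypt(ints$w)[sel]
  wz <- ct_decrypt(ints$Wz)[sel]
  expect_equal(p, sigmoid3(tr$sp$yhat), tolerance = 1e-9)
  expect_equal(w, tr$sp$w, tolerance = 1e-9)
  expect_equal(wz, tr$sp$wz, tolerance = 1e-9)
  # scalar check: yhat = 0, y = 1 gives p = 1/2, w = 1/4, Wz = 1/2
  expect_equal(sigmoid3(0) * (1 - sigmoid3(0)), 0.25)
})

test_that("step 3 replication yields constant per-sample ciphertexts", {
  tr <- toy_run(seed = 53)
  ints <- tr$out$intermediates
  for (i in c(1, 4, 8)) {
    wi <- ct_decrypt(ints$w_i[[i]])
    expect_lt(diff(range(wi)), 1e-12)
    expect_equal(wi[1], tr$sp$w[i], tolerance = 1e-9)
  }
  expect_equal(ints$w_i[[1]]$level, tr$plan$levels$w_i)
})

test_that("steps 4-6 compute the weighted cross-products", {
  tr <- toy_run(seed = 54)
  ints <- tr$out$intermediates
  p <- tr$enc$p; k <- tr$enc$k
  w <- tr$sp$w; wz <- tr$sp$wz
  X <- tr$ds$X; S <- tr$ds$S
  for (l in seq_len(k)) {
    B_l <- ct_decrypt(ints$B[[1]][[l]], n = p)
    expect_equal(B_l, as.vector(t(S) %*% (w * X[, l])), tolerance = 1e-9)
  }
  # c_j = b_1j: the first B vector is the SNP diagonal weight sum
  expect_equal(ct_decrypt(ints$B[[1]][[1]], n = p),
               as.vector(t(S) %*% w), tolerance = 1e-9)
  expect_equal(ct_decrypt(ints$sWz[[1]], n = p),
               as.vector(t(S) %*% wz), tolerance = 1e-9)
  xwz <- vapply(ints$xWz, function(ct) ct_decrypt(ct, n = 1), numeric(1))
  expect_equal(xwz, as.vector(t(X) %*% wz), tolerance = 1e-9)
  # intercept column: x_1' W z is the plain sum of the working response
  expect_equal(xwz[1], sum(wz), tolerance = 1e-9)
})

test_that("step 7 reproduces the adjugate and determinant of X'WX", {
  tr <- toy_run(seed = 55)
  ints <- tr$out$intermediates
  k <- tr$enc$k
  adj_ref <- tr$sp$adj_a
  for (j in seq_len(k)) {
    for (l in seq_len(k)) {
      expect_equal(ct_decrypt(ints$adj[[j]][[l]], n = 1), adj_ref[j, l],
                   tolerance = 1e-8)
    }
  }
  expect_equal(ct_decrypt(tr$out$ct_detA, n = 1), tr$sp$det_a, tolerance = 1e-9)
})

test_that("step 8 outputs match the plain semi-parallel quantities", {
  tr <- toy_run(seed = 56)
  res <- decrypt_gwas(tr$out, tr$enc)
  expect_equal(res$beta_star, tr$sp$beta_star, tolerance = 1e-8)
  expect_equal(res$beta_dagger, tr$sp$beta_dagger, tolerance = 1e-8)
  # algebraic identity: beta*/beta+ is the one-step Newton coefficient
  ok <- res$flag == ""
  expect_equal(res$beta[ok], tr$sp$result$beta[ok], tolerance = 1e-8)
})

test_that("a SNP identical to a covariate column degenerates cleanly", {
  set.seed(57)
  n <- 8
  X <- cbind(1, matrix(runif(n * 3), n))
  S <- cbind(rbinom(n, 1, 0.5), X[, 1])   # second SNP collinear with intercept
  ds <- pad_dataset(gwas_dataset(X, S, 2 * rbinom(n, 1, 0.5) - 1))
  ctx <- emu_ctx(logN = 7, L = 19)
  plan <- level_plan(2, 3, 0, k = 4, params = ctx$params)
  enc <- encode_dataset(ds, ctx, plan)
  out <- run_encrypted_gwas(enc)
  res <- decrypt_gwas(out, enc)
  expect_lt(abs(res$beta_dagger[2]), 1e-8)     # singular Fisher block
  # an exactly singular block either flags or collapses the denominator;
  # informative SNPs keep a healthy one
  expect_gt(abs(res$beta_dagger[1]), 1e-6)
})

test_that("the realized level trace equals the plan at Set-II structure", {
  tr <- toy_run(seed = 58)
  chk <- check_level_trace(tr$out$trace, tr$plan)
  expect_true(all(chk$match))
})

test_that("nondegenerate toy data give positive denominators", {
  tr <- toy_run(seed = 59, n = 16, p = 32, s = 4, logN = 8)
  res <- decrypt_gwas(tr$out, tr$enc)
  informative <- colSums(tr$ds$S) > 0 & colSums(tr$ds$S) < tr$ds$n_real
  expect_true(all(res$beta_dagger[informative] > 0))
})
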