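test_that("Wald statistics and p-values follow their definitions", {
  res <- reconstruct_gwas(c(0, 2, 1), c(1, 1, 0), det_a = 4)
  expect_equal(res$z[1], 0)
  expect_equal(res$pvalue[1], 1)
  # beta* = 2, beta+ = 1, |A| = 4: z = 2/sqrt(4) = 1
  expect_equal(res$z[2], 1)
  expect_equal(res$pvalue[2], 2 * pnorm(-1), tolerance = 1e-9)
  expect_equal(res$pvalue[2], 0.3173105, tolerance = 1e-6)
  # degenerate denominator flagged, not raised
  expect_equal(res$flag[3], "degenerate")
  expect_true(is.nan(res$pvalue[3]))
  expect_error(reconstruct_gwas(1:3, 1:2, 1), "input error")
})

test_that("multiplicative masking leaves z and p invariant", {
  ctx <- emu_ctx(logN = 7, L = 20)   # one spare level for the masking cmult
  ds <- toy_dataset(n = 8, p = 16, k = 4, seed = 40)
  plan <- level_plan(2, 3, 0, k = 4, params = ctx$params)
  enc <- encode_dataset(ds, ctx, plan)
  out <- run_encrypted_gwas(enc)
  plainres <- decrypt_gwas(out, enc)
  masked <- apply_mask(out$ct_beta_star[[1]], out$ct_beta_dagger[[1]],
                       out$ct_detA, p = enc$p, seed = 3)
  mres <- reconstruct_gwas(ct_decrypt(masked$star, n = enc$p),
                           ct_decrypt(masked$dagger, n = enc$p),
                           ct_decrypt(masked$det, n = 1))
  ok <- plainres$flag == "" & mres$flag == ""
  expect_gt(sum(ok), 0)
  expect_equal(mres$z[ok], plainres$z[ok], tolerance = 1e-9)
  expect_equal(mres$pvalue[ok], plainres$pvalue[ok], tolerance = 1e-9)
  # the masked numerators themselves are changed (leak reduction)
  expect_gt(max(abs(ct_decrypt(masked$star, n = enc$p) - plainres$beta_star)), 1e-6)
  # all-ones masks are the identity on the statistics and the values
  expect_equal(masked$masks$r_star^2,
               masked$masks$r_dagger * masked$masks$r_a, tolerance = 1e-12)
})

test_that("model comparison counts a worked contingency example", {
  p_ref <- c(1e-6, 1e-6, 1e-6, 0.5, 0.5, 0.5, 1e-6, 0.2, 0.9, NaN)
  p_tst <- c(1e-6, 1e-6, 0.4, 0.5, 1e-6, 0.5, 1e-6, 0.3, 0.8, 0.1)
  m <- compare_models(p_tst, p_ref, cutoff = 1e-5)
  # by hand over the 9 finite pairs: TP 3, FN 1, FP 1, TN 4
  expect_equal(m$tp, 3); expect_equal(m$fn, 1)
  expect_equal(m$fp, 1); expect_equal(m$tn, 4)
  expect_equal(m$f1, 2 * 3 / (2 * 3 + 1 + 1))
  expect_equal(m$excluded, 1)
  expect_equal(m$type1, 1 / 5)
  expect_equal(m$type2, 1 / 4)
  ident <- compare_models(p_ref[1:9], p_ref[1:9], 1e-5)
  expect_equal(ident$f1, 1); expect_equal(ident$type1, 0); expect_equal(ident$type2, 0)
  disjoint <- compare_models(rep(1e-9, 4), rep(0.9, 4), 1e-5)
  expect_equal(disjoint$f1, 0)
  expect_error(compare_models(p_tst, p_ref, 2), "cutoff")
})
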