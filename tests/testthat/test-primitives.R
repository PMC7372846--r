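# AllSum and Replicate against brute-force slot oracles (emulator, exact)

naive_allsum <- function(m, psi, alpha) {
  N2 <- length(m)
  out <- numeric(N2)
  for (i in seq_len(N2)) {
    idx <- ((i - 1 + psi * (0:(alpha - 1))) %% N2) + 1
    out[i] <- sum(m[idx])
  }
  out
}

test_that("allsum equals naive strided summation for all small (psi, alpha)", {
  ctx <- emu_ctx(logN = 6, L = 3)   # 32 slots
  set.seed(1)
  m <- runif(ctx$N2)
  ct <- ct_encrypt(ctx, m)
  for (psi in c(1, 2, 4, 8, -1, -2, -4, 3)) {
    for (alpha in c(1, 2, 3, 4, 6, 8, 16)) {
      if (abs(psi) * alpha > 64) next
      out <- allsum(ct, psi, alpha)
      expect_equal(ct_decrypt(out), naive_allsum(m, psi, alpha),
                   tolerance = 1e-12,
                   info = paste("psi", psi, "alpha", alpha))
      expect_equal(out$level, ct$level)    # zero level consumption
      expect_equal(out$scale, ct$scale)
    }
  }
})

test_that("allsum with psi = 1 sums all elements and replicates", {
  ctx <- emu_ctx(logN = 4, L = 3)   # 8 slots; packing period psi * alpha
  ct <- ct_encrypt(ctx, rep(c(1, 2, 3, 4), 2))
  expect_equal(ct_decrypt(allsum(ct, 1, 4)), rep(10, 8))
  ct2 <- ct_encrypt(ctx, rep(c(1, 2, 3, 4), 2))
  expect_equal(ct_decrypt(allsum(ct2, 2, 2)), rep(c(4, 6), 4))
  ct3 <- ct_encrypt(ctx, c(7, rep(0, 7)))
  expect_equal(ct_decrypt(allsum(ct3, -1, 8)), rep(7, 8))
})

naive_replicate <- function(m, n) {
  N2 <- length(m)
  run <- N2 / n
  lapply(seq_len(n), function(i) rep(m[(i - 1) * run + 1], N2))
}

test_that("replicate matches the naive mask-then-allsum construction", {
  ctx <- emu_ctx(logN = 6, L = 19)
  set.seed(2)
  for (n in c(2, 4, 8, 16)) {
    vals <- runif(n)
    m <- rep(vals, each = ctx$N2 / n)
    ref <- naive_replicate(m, n)
    for (s in 0:log2(n)) {
      ct <- ct_encrypt(ctx, m, level = 10L)
      out <- replicate_ct(ct, n, s)
      expect_length(out, n)
      for (i in seq_len(n)) {
        expect_equal(ct_decrypt(out[[i]]), ref[[i]], tolerance = 1e-12,
                     info = paste("n", n, "s", s, "i", i))
      }
      # replication consumes exactly s + 1 levels
      expect_equal(out[[1]]$level, 10L - (s + 1L))
    }
  }
  expect_error(replicate_ct(ct_encrypt(ctx, 1, level = 10L), 4, 3),
               "configuration error")
})

test_that("masks keep the requested grid columns and are idempotent", {
  ctx <- emu_ctx(logN = 4, L = 3)
  m1 <- make_mask(ctx, 4, 1)
  expect_equal(m1, rep(c(1, 0, 0, 0), 2))
  ct <- ct_encrypt(ctx, 1:8)
  once <- ct_rescale(ct_cmult(ct, m1))
  expect_equal(ct_decrypt(once), c(1, 0, 0, 0, 5, 0, 0, 0))
  twice <- ct_rescale(ct_cmult(once, m1))
  expect_equal(ct_decrypt(twice), ct_decrypt(once))
  allones <- make_mask(ctx, 4, 1:4)
  kept <- ct_rescale(ct_cmult(ct, allones))
  expect_equal(ct_decrypt(kept), as.numeric(1:8))
  expect_equal(kept$level, ct$level - 1L)
})
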