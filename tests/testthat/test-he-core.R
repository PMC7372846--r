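# operation-level checks of the RNS scheme on a small real context
# (logN = 12, L = 6, eta = 40); tolerances are ~8x the observed maxima

test_that("NTT round-trips exactly on every chain prime", {
  ctx <- tiny_he_ctx()
  for (seed in 1:5) expect_true(hegwas:::cpp_ntt_roundtrip(ctx$cpp, seed))
})

test_that("encode/decode round-trip error is bounded by the scale", {
  ctx <- tiny_he_ctx()
  set.seed(1)
  for (rep in 1:5) {
    v <- runif(ctx$N2, -4, 4)
    rt <- hegwas:::cpp_encode_roundtrip(ctx$cpp, v, 2^ctx$eta)
    expect_lt(max(abs(rt - v)), 2^-ctx$eta * (1 + max(abs(v))) * 1e3)
  }
})

test_that("encryption round-trips at every level with seeded determinism", {
  ctx <- tiny_he_ctx()
  set.seed(2)
  v <- runif(ctx$N2, -2, 2)
  for (lev in c(1L, 3L, ctx$L)) {
    ct <- ct_encrypt(ctx, v, level = lev, seed = 11)
    expect_lt(max(abs(ct_decrypt(ct) - v)), 1e-6)
  }
  a <- ct_encrypt(ctx, v, level = 4L, seed = 99)
  b <- ct_encrypt(ctx, v, level = 4L, seed = 99)
  expect_true(hegwas:::cpp_ct_equal(ctx$cpp, a$payload, b$payload, 4L))
  # all-zero message decrypts to ~0
  z <- ct_encrypt(ctx, numeric(ctx$N2), seed = 5)
  expect_lt(max(abs(ct_decrypt(z))), 1e-6)
})

test_that("secret is ternary and public-key error is Gaussian-small", {
  ctx <- tiny_he_ctx()
  sk <- hegwas:::cpp_sk_coeffs(ctx$keys$sk)
  expect_true(all(sk %in% -1:1))
  for (seed in 1:20) {
    s <- hegwas:::cpp_sk_gen(ctx$cpp, seed)
    p <- hegwas:::cpp_pk_gen(ctx$cpp, s, seed + 1000)
    err <- hegwas:::cpp_pk_error(ctx$cpp, p, s)
    expect_gte(err, 0)           # rows consistent
    expect_lte(err, 6 * 3.2)     # tail bound on the rounded Gaussian
  }
})

test_that("switching keys satisfy the KSGen relation", {
  ctx <- tiny_he_ctx()
  s1 <- hegwas:::cpp_sk_gen(ctx$cpp, 201)
  s2 <- hegwas:::cpp_sk_gen(ctx$cpp, 202)
  swk <- ct_ksgen(ctx, s1, s2, seed = 203)
  err <- hegwas:::cpp_swk_error(ctx$cpp, swk, s1, s2)
  expect_gte(err, 0)
  expect_lte(err, 6 * 3.2)
  # zero secrets: payload reduces to the error polynomial alone
  z <- hegwas:::cpp_sk_const(ctx$cpp, integer(2^ctx$logN))
  swk0 <- ct_ksgen(ctx, z, z, seed = 204)
  expect_lte(hegwas:::cpp_swk_error(ctx$cpp, swk0, z, z), 6 * 3.2)
})

test_that("key switching moves a ciphertext between secrets", {
  ctx <- tiny_he_ctx()
  set.seed(3)
  v <- runif(ctx$N2, -1, 1)
  s2 <- hegwas:::cpp_sk_gen(ctx$cpp, 301)
  p2 <- hegwas:::cpp_pk_gen(ctx$cpp, s2, 302)
  swk <- ct_ksgen(ctx, s2, ctx$keys$sk, seed = 303)
  for (seed in 1:5) {
    ptr <- hegwas:::cpp_encrypt(ctx$cpp, p2, v, ctx$L, 2^ctx$eta, 400 + seed)
    ct <- hegwas:::new_ct(ctx, ptr, ctx$L, 2^ctx$eta)
    out <- ct_keyswitch(ct, swk)
    expect_lt(max(abs(ct_decrypt(out) - v)), 1e-5)
  }
})

test_that("key switch with zero c1 is the exact identity", {
  ctx <- tiny_he_ctx()
  ct <- ct_trivial(ctx, runif(ctx$N2), level = 4L)   # c1 = 0
  expect_true(hegwas:::cpp_c1_is_zero(ctx$cpp, ct$payload, 4L))
  s2 <- hegwas:::cpp_sk_gen(ctx$cpp, 501)
  swk <- ct_ksgen(ctx, s2, ctx$keys$sk, seed = 502)
  out <- ct_keyswitch(ct, swk)
  expect_true(hegwas:::cpp_ct_equal(ctx$cpp, ct$payload, out$payload, 4L))
})

test_that("add, sub, mult and cmult are homomorphic", {
  ctx <- tiny_he_ctx()
  set.seed(4)
  v <- runif(ctx$N2, -2, 2); w <- runif(ctx$N2, -2, 2)
  a <- ct_encrypt(ctx, v, seed = 601)
  b <- ct_encrypt(ctx, w, seed = 602)
  expect_lt(max(abs(ct_decrypt(ct_add(a, b)) - (v + w))), 1e-6)
  expect_lt(max(abs(ct_decrypt(ct_sub(ct_add(a, b), b)) - v)), 1e-6)
  m <- ct_rescale(ct_mult(a, b))
  expect_lt(max(abs(ct_decrypt(m) - v * w)), 1e-5)
  mask <- rep(c(1, 0), ctx$N2 / 2)
  cm <- ct_rescale(ct_cmult(a, mask))
  expect_lt(max(abs(ct_decrypt(cm) - v * mask)), 1e-5)
  expect_equal(cm$level, a$level - 1L)
  # multiplying by encrypted ones is the identity up to noise
  ones <- ct_encrypt(ctx, rep(1, ctx$N2), seed = 603)
  mi <- ct_rescale(ct_mult(a, ones))
  expect_lt(max(abs(ct_decrypt(mi) - v)), 1e-5)
})

test_that("rescale divides the message scale by the chain prime", {
  ctx <- tiny_he_ctx()
  set.seed(5)
  v <- runif(ctx$N2, -2, 2)
  for (seed in 1:5) {
    ct <- ct_encrypt(ctx, v, scale = 2^(2 * ctx$eta), seed = 700 + seed)
    rs <- ct_rescale(ct)
    expect_equal(rs$level, ct$level - 1L)
    expect_equal(rs$scale, ct$scale / ctx$q_dbl[ct$level])
    expect_lt(max(abs(ct_decrypt(rs) - v)), 1e-5)
  }
  expect_error(ct_rescale(ct_encrypt(ctx, v, level = 1L, seed = 99)), "no level left")
})

test_that("rotation shifts slots, composes additively and respects keys", {
  ctx <- tiny_he_ctx()
  v <- as.numeric(seq_len(ctx$N2))
  ct <- ct_encrypt(ctx, v, seed = 801)
  r1 <- ct_decrypt(ct_rotate(ct, 1))
  expect_lt(max(abs(r1 - c(v[-1], v[1]))), 1e-4)
  # composition through the declared key set (3 = 1 + 2)
  r3a <- ct_decrypt(ct_rotate(ct_rotate(ct, 1), 2))
  r3b <- ct_decrypt(ct_rotate(ct, 3))
  expect_lt(max(abs(r3a - r3b)), 1e-4)
  # negative amount via its dedicated key
  rn <- ct_decrypt(ct_rotate(ct, -1))
  expect_lt(max(abs(rn - c(v[ctx$N2], v[-ctx$N2]))), 1e-4)
  expect_identical(ct_rotate(ct, 0), ct)
  expect_error(ct_rotate(ct, 3000), "missing rotation key")
})

test_that("mod_down preserves the message and the scale", {
  ctx <- tiny_he_ctx()
  set.seed(6)
  v <- runif(ctx$N2, -2, 2)
  ct <- ct_encrypt(ctx, v, seed = 901)
  md <- ct_mod_down(ct, ct$level - 3L)
  expect_equal(md$scale, ct$scale)
  expect_lt(max(abs(ct_decrypt(md) - v)), 1e-6)
  expect_error(ct_mod_down(ct, ct$level + 1L), "out of range")
})

test_that("lazy key switching equals eager per-product relinearization", {
  ctx <- tiny_he_ctx()
  set.seed(7)
  va <- replicate(4, runif(ctx$N2, -1, 1), simplify = FALSE)
  vb <- replicate(4, runif(ctx$N2, -1, 1), simplify = FALSE)
  cta <- lapply(seq_len(4), function(i) ct_encrypt(ctx, va[[i]], seed = 1000 + i))
  ctb <- lapply(seq_len(4), function(i) ct_encrypt(ctx, vb[[i]], seed = 1100 + i))
  lazy <- ct_raw_mult(cta[[1]], ctb[[1]])
  for (i in 2:4) lazy <- ct_add(lazy, ct_raw_mult(cta[[i]], ctb[[i]]))
  lazy <- ct_rescale(ct_relin(lazy))
  eager <- ct_rescale(ct_mult(cta[[1]], ctb[[1]]))
  for (i in 2:4) eager <- ct_add(eager, ct_rescale(ct_mult(cta[[i]], ctb[[i]])))
  truth <- Reduce(`+`, Map(`*`, va, vb))
  expect_lt(max(abs(ct_decrypt(lazy) - truth)), 1e-5)
  expect_lt(max(abs(ct_decrypt(lazy) - ct_decrypt(eager))), 1e-5)
})

test_that("contract violations raise instead of coercing", {
  ctx <- tiny_he_ctx()
  a <- ct_encrypt(ctx, rep(1, 8), level = 4L, seed = 1)
  b <- ct_encrypt(ctx, rep(1, 8), level = 3L, seed = 2)
  expect_error(ct_add(a, b), "level mismatch")
  expect_error(ct_mult(a, b), "level mismatch")
  c2 <- ct_encrypt(ctx, rep(1, 8), level = 4L, scale = 2^20, seed = 3)
  expect_error(ct_add(a, c2), "scale mismatch")
  expect_error(ct_encrypt(ctx, numeric(ctx$N2 + 1)), "longer than N/2")
})
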