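# shared fixtures: contexts are expensive (prime scans, NTT tables, keygen),
# so they are built lazily once per test run

.cache <- new.env()

# small real-HE context for operation-level property tests
tiny_he_ctx <- function() {
  if (is.null(.cache$tiny)) {
    params <- he_params(12, 6, 40, 45, 50, name = "tiny-test")
    ctx <- he_context(params, backend = "heaan")
    keygen(ctx, seed = 42, rot_amounts = c(1, 2, 4, -1, 1024))
    .cache$tiny <- ctx
  }
  .cache$tiny
}

# reduced production-structure context (logN = 13, Set-II level structure)
small_he_ctx <- function() {
  if (is.null(.cache$small)) {
    ctx <- he_context("set2_small", backend = "heaan")
    keygen(ctx, seed = 7)
    .cache$small <- ctx
  }
  .cache$small
}

# emulator context with few slots for exhaustive primitive checks
emu_ctx <- function(logN = 7, L = 19) {
  key <- paste0("emu", logN, "_", L)
  if (is.null(.cache[[key]])) {
    params <- he_params(logN, L, 43, 51, 60, name = "emu-test")
    .cache[[key]] <- he_context(params, backend = "emulator")
  }
  .cache[[key]]
}

# a small padded, preprocessed dataset ready for encoding
toy_dataset <- function(n = 16, p = 64, k = 4, seed = 3, ...) {
  ds <- simulate_gwas_data(n = n, p = p, k = k, n_causal = 2, effect_size = 2,
                           missing_rate = 0, seed = seed, ...)
  pad_dataset(preprocess_covariates(ds))
}

# normalized maximum difference (packed outputs contain exact zeros, so the
# comparison is relative to the vector scale)
nrel <- function(a, b) max(abs(a - b)) / max(abs(b))
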