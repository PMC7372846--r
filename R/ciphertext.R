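#' Ciphertext operations
#'
#' Both backends expose the same operation surface with identical level and
#' scale bookkeeping; the circuit layer is written once against it.
#' Multiplications do \emph{not} rescale automatically: the circuit issues
#' rescalings explicitly so that level consumption is auditable against the
#' plan.
#'
#' Scale bookkeeping is exact: rescaling divides the tracked scale by the true
#' chain prime (not by the nominal \eqn{2^\eta}), so the encrypted and
#' emulated paths agree bit-for-bit in their metadata.  Operands of an
#' addition must agree in level exactly and in scale within a small relative
#' tolerance (the drift between primes and \eqn{2^\eta} over a full-depth
#' circuit); larger mismatches are contract violations, never coerced.
#'
#' @name ciphertext-ops
NULL

.scale_rtol <- 1e-4

new_ct <- function(ctx, payload, level, scale, extended = FALSE) {
  cls <- if (ctx$backend == "heaan") "heaan_ct" else "emu_ct"
  structure(list(ctx = ctx, payload = payload, level = as.integer(level),
                 scale = scale, extended = extended),
            class = c(cls, "hegwas_ct"))
}

#' @export
print.hegwas_ct <- function(x, ...) {
  cat("<", class(x)[1], "> level=", x$level, " scale=2^",
      round(log2(x$scale), 3), if (x$extended) " extended" else "", "\n", sep = "")
  invisible(x)
}

check_pair <- function(a, b, scales = FALSE) {
  if (a$level != b$level) {
    stop("level mismatch: ", a$level, " vs ", b$level)
  }
  if (scales && abs(a$scale / b$scale - 1) > .scale_rtol) {
    stop("scale mismatch: 2^", round(log2(a$scale), 4), " vs 2^",
         round(log2(b$scale), 4))
  }
  invisible(TRUE)
}

pad_slots <- function(ctx, values) {
  values <- as.numeric(values)
  if (length(values) > ctx$N2) stop("slot vector longer than N/2")
  if (length(values) < ctx$N2) values <- c(values, numeric(ctx$N2 - length(values)))
  values
}

#' Encrypt a slot vector
#'
#' @param ctx context (keys required on the heaan backend).
#' @param values real slot vector of length at most N/2 (zero-padded).
#' @param level encryption level (1..L); defaults to L.
#' @param scale fixed-point scale; defaults to \eqn{2^\eta}.
#' @param seed per-ciphertext randomness seed (heaan backend).
#' @return a ciphertext object.
#' @export
ct_encrypt <- function(ctx, values, level = ctx$L, scale = 2^ctx$eta, seed = NULL) {
  values <- pad_slots(ctx, values)
  if (level < 1 || level > ctx$L) stop("level out of range")
  if (ctx$backend == "emulator") {
    if (ctx$emu_noise_sd > 0) values <- values + rnorm(length(values), 0, ctx$emu_noise_sd)
    return(new_ct(ctx, values, level, scale))
  }
  if (!has_keys(ctx)) stop("keygen() has not been run on this context")
  if (is.null(seed)) seed <- floor(runif(1, 0, 2^31))
  ptr <- cpp_encrypt(ctx$cpp, ctx$keys$pk, values, as.integer(level), scale, seed)
  new_ct(ctx, ptr, level, scale)
}

#' A trivial (noiseless) encryption of known constants
#' @inheritParams ct_encrypt
#' @export
ct_trivial <- function(ctx, values, level = ctx$L, scale = 2^ctx$eta) {
  values <- pad_slots(ctx, values)
  if (ctx$backend == "emulator") return(new_ct(ctx, values, level, scale))
  new_ct(ctx, cpp_trivial_encrypt(ctx$cpp, values, as.integer(level), scale),
         level, scale)
}

#' Decrypt to a slot vector
#' @param ct ciphertext.
#' @param n number of leading slots to return (default all N/2).
#' @export
ct_decrypt <- function(ct, n = ct$ctx$N2) {
  if (ct$extended) stop("cannot decrypt an extended ciphertext; relinearize first")
  if (inherits(ct, "emu_ct")) return(ct$payload[seq_len(n)])
  ctx <- ct$ctx
  cpp_decrypt(ctx$cpp, ct$payload, ctx$keys$sk, ct$level, ct$scale, as.integer(n))
}

#' @rdname ciphertext-ops
#' @param a,b ciphertexts (equal level; for addition also matching scale).
#' @export
ct_add <- function(a, b) {
  check_pair(a, b, scales = TRUE)
  if (a$extended != b$extended) stop("cannot mix extended and ordinary ciphertexts")
  if (inherits(a, "emu_ct")) {
    return(new_ct(a$ctx, a$payload + b$payload, a$level, a$scale, a$extended))
  }
  p <- if (a$extended) cpp_ext_add(a$ctx$cpp, a$payload, b$payload, a$level, FALSE)
       else cpp_add(a$ctx$cpp, a$payload, b$payload, a$level, FALSE)
  new_ct(a$ctx, p, a$level, a$scale, a$extended)
}

#' @rdname ciphertext-ops
#' @export
ct_sub <- function(a, b) {
  check_pair(a, b, scales = TRUE)
  if (a$extended != b$extended) stop("cannot mix extended and ordinary ciphertexts")
  if (inherits(a, "emu_ct")) {
    return(new_ct(a$ctx, a$payload - b$payload, a$level, a$scale, a$extended))
  }
  p <- if (a$extended) cpp_ext_add(a$ctx$cpp, a$payload, b$payload, a$level, TRUE)
       else cpp_add(a$ctx$cpp, a$payload, b$payload, a$level, TRUE)
  new_ct(a$ctx, p, a$level, a$scale, a$extended)
}

#' @rdname ciphertext-ops
#' @export
ct_negate <- function(a) {
  if (inherits(a, "emu_ct")) return(new_ct(a$ctx, -a$payload, a$level, a$scale, a$extended))
  if (a$extended) stop("negate on extended ciphertexts not needed")
  new_ct(a$ctx, cpp_negate(a$ctx$cpp, a$payload, a$level), a$level, a$scale)
}

#' Raw product: an extended ciphertext under the secret (1, s, s^2)
#' @rdname ciphertext-ops
#' @export
ct_raw_mult <- function(a, b) {
  check_pair(a, b)
  if (a$extended || b$extended) stop("operands must be ordinary ciphertexts")
  sc <- a$scale * b$scale
  if (inherits(a, "emu_ct")) {
    return(new_ct(a$ctx, a$payload * b$payload, a$level, sc, extended = TRUE))
  }
  new_ct(a$ctx, cpp_raw_mult(a$ctx$cpp, a$payload, b$payload, a$level),
         a$level, sc, extended = TRUE)
}

#' Relinearize an extended ciphertext with the evaluation key
#' @rdname ciphertext-ops
#' @export
ct_relin <- function(a) {
  if (!a$extended) stop("not an extended ciphertext")
  if (inherits(a, "emu_ct")) return(new_ct(a$ctx, a$payload, a$level, a$scale))
  new_ct(a$ctx, cpp_relinearize(a$ctx$cpp, a$payload, a$ctx$keys$evk, a$level),
         a$level, a$scale)
}

#' Full homomorphic product (raw multiply + relinearize; rescale separately)
#' @rdname ciphertext-ops
#' @export
ct_mult <- function(a, b) ct_relin(ct_raw_mult(a, b))

#' Multiply by a plaintext constant vector or scalar
#'
#' @param ct ciphertext.
#' @param const scalar or slot vector; encoded at scale \code{cscale}.
#' @param cscale encoding scale of the constant (default \eqn{2^\eta}).
#' @export
ct_cmult <- function(ct, const, cscale = 2^ct$ctx$eta) {
  if (ct$extended) stop("cmult on extended ciphertexts not supported")
  ctx <- ct$ctx
  const <- if (length(const) == 1) rep(as.numeric(const), ctx$N2) else pad_slots(ctx, const)
  if (inherits(ct, "emu_ct")) {
    return(new_ct(ctx, ct$payload * const, ct$level, ct$scale * cscale))
  }
  new_ct(ctx, cpp_cmult(ctx$cpp, ct$payload, const, ct$level, cscale),
         ct$level, ct$scale * cscale)
}

#' Add a plaintext constant, encoded at the ciphertext's own scale
#' @rdname ciphertext-ops
#' @param const scalar or slot vector.
#' @export
ct_add_plain <- function(a, const) {
  ctx <- a$ctx
  if (a$extended) stop("add_plain on extended ciphertexts not supported")
  const <- if (length(const) == 1) rep(as.numeric(const), ctx$N2) else pad_slots(ctx, const)
  if (inherits(a, "emu_ct")) return(new_ct(ctx, a$payload + const, a$level, a$scale))
  new_ct(ctx, cpp_add_plain(ctx$cpp, a$payload, const, a$level, a$scale),
         a$level, a$scale)
}

#' Rescale: divide the message by the current level prime, dropping one level
#' @rdname ciphertext-ops
#' @export
ct_rescale <- function(a) {
  if (a$level < 2) stop("no level left to rescale")
  ctx <- a$ctx
  if (a$extended) stop("rescale extended ciphertexts after relinearization")
  q <- ctx$q_dbl[a$level]   # q_{level-1}, the prime divided out
  if (inherits(a, "emu_ct")) {
    return(new_ct(ctx, a$payload, a$level - 1L, a$scale / q))
  }
  new_ct(ctx, cpp_rescale(ctx$cpp, a$payload, a$level), a$level - 1L, a$scale / q)
}

#' Drop to a lower level without changing the message or scale
#' @rdname ciphertext-ops
#' @param target target level (1..level).
#' @export
ct_mod_down <- function(a, target) {
  if (target > a$level || target < 1) stop("mod_down target out of range")
  if (target == a$level) return(a)
  if (a$extended) stop("mod_down extended ciphertexts after relinearization")
  ctx <- a$ctx
  if (inherits(a, "emu_ct")) return(new_ct(ctx, a$payload, target, a$scale))
  new_ct(ctx, cpp_mod_down(ctx$cpp, a$payload, a$level, as.integer(target)),
         target, a$scale)
}

#' Rotate plaintext slots
#'
#' Cyclically shifts the packed vector: slot i of the output holds slot
#' \eqn{i + r} of the input.  On the heaan backend the rotation uses the
#' switching key for the normalized amount if declared, otherwise it is
#' composed from the binary expansion of the amount over the declared
#' power-of-two keys.
#'
#' @param a ciphertext.
#' @param r rotation amount (may be negative; interpreted modulo N/2).
#' @export
ct_rotate <- function(a, r) {
  ctx <- a$ctx
  rr <- ((r %% ctx$N2) + ctx$N2) %% ctx$N2
  if (rr == 0) return(a)
  if (a$extended) stop("rotate extended ciphertexts after relinearization")
  if (inherits(a, "emu_ct")) {
    idx <- ((seq_len(ctx$N2) - 1L + rr) %% ctx$N2) + 1L
    return(new_ct(ctx, a$payload[idx], a$level, a$scale))
  }
  if (!has_keys(ctx)) stop("keygen() has not been run on this context")
  steps <- decompose_rotation(rr, ctx$keys$amounts, ctx$N2)
  out <- a$payload
  for (st in steps) {
    out <- cpp_rotate(ctx$cpp, out, ctx$keys$rot[[as.character(st)]], st, a$level)
  }
  new_ct(ctx, out, a$level, a$scale)
}

# express a rotation as a short sequence of declared amounts
decompose_rotation <- function(r, amounts, N2) {
  if (r %in% amounts) return(r)
  neg <- N2 - r   # same rotation reached backwards
  if (neg %in% amounts) return(neg)
  bits <- which(intToBits(r)[1:32] == 1) - 1L
  steps <- 2L^bits
  missing <- setdiff(steps, amounts)
  if (length(missing)) {
    stop("missing rotation key for amount ", r,
         " (needs keys for ", paste(missing, collapse = ", "), ")")
  }
  steps
}

#' Generic key switch of a ciphertext to another secret
#' @param a ciphertext valid under the source secret of \code{swk}.
#' @param swk a switching key from [ct_ksgen()].
#' @export
ct_keyswitch <- function(a, swk) {
  if (inherits(a, "emu_ct")) return(a)
  new_ct(a$ctx, cpp_keyswitch(a$ctx$cpp, a$payload, swk, a$level),
         a$level, a$scale)
}

#' Generate a switching key between two explicit secrets (heaan backend)
#' @param ctx context.
#' @param sk1,sk2 secret-key pointers (source, destination).
#' @param seed integer seed.
#' @export
ct_ksgen <- function(ctx, sk1, sk2, seed = 1L) {
  if (ctx$backend != "heaan") stop("switching keys exist only on the heaan backend")
  cpp_ksgen(ctx$cpp, sk1, sk2, seed)
}
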