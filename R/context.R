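#' Create an evaluation context
#'
#' A context bundles a parameter set, its modulus chain, and the selected
#' backend.  The \code{"heaan"} backend evaluates on real RNS ciphertexts via
#' the compiled core; the \code{"emulator"} backend runs the identical
#' operation surface on exact plaintext slot vectors with the same level and
#' scale bookkeeping, and is the correctness oracle for every circuit.
#'
#' The context is an environment so that ciphertexts can reference it without
#' copying; keys generated with [keygen()] are stored inside it.
#'
#' @param params a \code{hegwas_params} object or preset name
#'   (see [he_presets()]).
#' @param backend \code{"emulator"} or \code{"heaan"}.
#' @param emu_noise_sd optional per-slot Gaussian noise injected by the
#'   emulator at encryption (robustness studies only; 0 = exact).
#' @return A \code{hegwas_ctx} environment.
#' @export
he_context <- function(params = "set2_small", backend = c("emulator", "heaan"),
                       emu_noise_sd = 0) {
  backend <- match.arg(backend)
  if (is.character(params)) params <- he_preset(params)
  chain <- setup_modulus_chain(params)
  ctx <- new.env(parent = emptyenv())
  ctx$params <- params
  ctx$chain <- chain
  ctx$backend <- backend
  ctx$logN <- params$ring_log_dim
  ctx$N2 <- as.integer(2^(params$ring_log_dim - 1L))
  ctx$L <- params$num_levels
  ctx$eta <- params$scale_bits
  ctx$q_dbl <- 2^chain$q$bits + chain$q$delta
  ctx$emu_noise_sd <- emu_noise_sd
  ctx$keys <- NULL
  if (backend == "heaan") {
    bits <- c(chain$special$bits, chain$q$bits)
    delta <- c(chain$special$delta, chain$q$delta)
    ctx$cpp <- cpp_ctx_new(params$ring_log_dim, as.integer(bits), as.numeric(delta))
  }
  class(ctx) <- "hegwas_ctx"
  ctx
}

#' @export
print.hegwas_ctx <- function(x, ...) {
  cat("<hegwas_ctx> backend=", x$backend, " preset=", x$params$name,
      " N2=", x$N2, " L=", x$L, if (!is.null(x$keys)) " [keys]" else "", "\n", sep = "")
  invisible(x)
}

#' Generate key material
#'
#' Samples a ternary secret, the public key, the evaluation key
#' \eqn{evk = KSGen(s^2, s)}, and switching keys for the declared set of slot
#' rotation amounts.  All randomness comes from a seedable generator so key
#' material is reproducible.  On the emulator backend this records the amount
#' set only (the emulator needs no keys).
#'
#' @param ctx a \code{hegwas_ctx}.
#' @param seed integer seed.
#' @param rot_amounts rotation amounts (slots, interpreted modulo N/2;
#'   negative values rotate backwards).  Default: all powers of two up to
#'   N/4 in both directions.  Amounts not in the set are composed from the
#'   binary expansion of the requested rotation.
#' @return the context, invisibly; keys are stored in \code{ctx$keys}.
#' @export
keygen <- function(ctx, seed = 1L,
                   rot_amounts = default_rotation_amounts(ctx)) {
  stopifnot(inherits(ctx, "hegwas_ctx"))
  amounts <- sort(unique(vapply(rot_amounts, function(r) {
    as.integer(((r %% ctx$N2) + ctx$N2) %% ctx$N2)
  }, integer(1))))
  amounts <- amounts[amounts != 0L]
  if (ctx$backend == "emulator") {
    ctx$keys <- list(amounts = amounts, seed = seed)
    return(invisible(ctx))
  }
  sk <- cpp_sk_gen(ctx$cpp, seed)
  pk <- cpp_pk_gen(ctx$cpp, sk, seed + 1)
  evk <- cpp_evk_gen(ctx$cpp, sk, seed + 2)
  rot <- list()
  for (i in seq_along(amounts)) {
    rot[[as.character(amounts[i])]] <-
      cpp_rotkey_gen(ctx$cpp, sk, amounts[i], seed + 2 + i)
  }
  ctx$keys <- list(sk = sk, pk = pk, evk = evk, rot = rot,
                   amounts = amounts, seed = seed)
  invisible(ctx)
}

#' @rdname keygen
#' @export
default_rotation_amounts <- function(ctx) {
  pows <- 2^(0:(log2(ctx$N2) - 1))
  c(pows, -pows)
}

has_keys <- function(ctx) !is.null(ctx$keys)
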