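#' Scheme parameter sets
#'
#' A parameter set fixes the ring dimension \eqn{N = 2^{\log N}}, the number of
#' levels \eqn{L} in the modulus chain, the per-level scale \eqn{2^\eta}
#' (\code{scale_bits}, which is also the bit size of the level primes), and the
#' bit sizes of the base prime \eqn{q_0} and the special (key-switching) prime
#' \eqn{p_0}.  Secrets are ternary (uniform over \{-1, 0, 1\}) and errors are
#' drawn from a rounded Gaussian with standard deviation 3.2.
#'
#' @param ring_log_dim log2 of the ring dimension N (power-of-two ring
#'   \eqn{Z[X]/(X^N+1)}).
#' @param num_levels number of level primes L; a fresh ciphertext at level L
#'   supports L-1 rescalings.
#' @param scale_bits per-level scale exponent \eqn{\eta}; level primes are the
#'   NTT-friendly primes nearest \eqn{2^\eta}.
#' @param base_prime_bits bit size of the base prime q0 (the last modulus left
#'   at level 1, so it bounds the decryptable payload).
#' @param special_prime_bits bit size of the special prime p0 used by the
#'   decomposition + modulus-raising key switch.
#' @param target_security_bits advertised security level (metadata; asserted
#'   against an embedded standardization table, not recomputed).
#' @param name optional preset name.
#' @return An object of class \code{hegwas_params}.
#' @seealso [he_presets()] for the shipped presets.
#' @export
he_params <- function(ring_log_dim, num_levels, scale_bits, base_prime_bits,
                      special_prime_bits, target_security_bits = 128L,
                      name = NULL) {
  stopifnot(ring_log_dim >= 2, ring_log_dim <= 17,
            num_levels >= 1,
            scale_bits >= 10, scale_bits <= 60,
            base_prime_bits <= 62, special_prime_bits <= 62)
  structure(list(
    name = name %||% "custom",
    ring_log_dim = as.integer(ring_log_dim),
    num_levels = as.integer(num_levels),
    scale_bits = as.integer(scale_bits),
    base_prime_bits = as.integer(base_prime_bits),
    special_prime_bits = as.integer(special_prime_bits),
    target_security_bits = as.integer(target_security_bits),
    secret_dist = "ternary",
    enc_dist = "ternary",
    error_stddev = 3.2
  ), class = "hegwas_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# maximum ciphertext-modulus bits (special prime excluded) for 128-bit
# classical security with ternary secrets, from the HE standardization tables
.security_table <- c(`10` = 27, `11` = 54, `12` = 109, `13` = 218,
                     `14` = 438, `15` = 881, `16` = 1772)

#' Shipped parameter presets
#'
#' Three production presets sized for 1, 2 and 3 iterations of the encrypted
#' covariate training (Sets I-III), plus \code{set2_small}, a reduced test
#' preset with the same level structure as Set-II but ring dimension
#' \eqn{2^{13}}.  \code{set2_small} is fast enough for continuous testing but
#' is \emph{insecure for research use} (its modulus far exceeds the 128-bit
#' bound at that dimension); it is flagged accordingly.
#'
#' @param name one of "set1", "set2", "set3", "set2_small".
#' @return For [he_presets()], a named list of \code{hegwas_params}; for
#'   [he_preset()], a single parameter set with preset metadata
#'   (\code{num_iter}, \code{s}, \code{s_prime}, \code{security_ok}).
#' @export
he_presets <- function() {
  list(
    set1 = .with_meta(he_params(15, 15, 43, 51, 60, name = "set1"),
                      num_iter = 1L, s = 4L, s_prime = 0L),
    set2 = .with_meta(he_params(15, 19, 43, 51, 60, name = "set2"),
                      num_iter = 2L, s = 4L, s_prime = 0L),
    set3 = .with_meta(he_params(16, 23, 45, 54, 62, name = "set3"),
                      num_iter = 3L, s = 4L, s_prime = 0L),
    set2_small = .with_meta(he_params(13, 19, 43, 51, 60, name = "set2_small"),
                            num_iter = 2L, s = 4L, s_prime = 0L)
  )
}

.with_meta <- function(p, num_iter, s, s_prime) {
  p$num_iter <- num_iter
  p$s <- s
  p$s_prime <- s_prime
  cmod <- p$base_prime_bits + (p$num_levels - 1L) * p$scale_bits
  bound <- .security_table[as.character(p$ring_log_dim)]
  p$security_ok <- !is.na(bound) && cmod <= bound
  p
}

#' @rdname he_presets
#' @export
he_preset <- function(name) {
  ps <- he_presets()
  if (!name %in% names(ps)) {
    stop("unknown preset '", name, "'; available: ", paste(names(ps), collapse = ", "))
  }
  ps[[name]]
}

#' @export
print.hegwas_params <- function(x, ...) {
  cat("<hegwas_params '", x$name, "'>  logN=", x$ring_log_dim,
      " L=", x$num_levels, " eta=", x$scale_bits,
      " logq0=", x$base_prime_bits, " logp0=", x$special_prime_bits, "\n", sep = "")
  if (!is.null(x$security_ok) && !x$security_ok) {
    cat("  [insecure-for-research test preset]\n")
  }
  invisible(x)
}
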