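#' Build the RNS modulus chain for a parameter set
#'
#' Chooses the special prime \eqn{p_0} and the level primes \eqn{q_0, \ldots,
#' q_{L-1}} by a deterministic nearest-first outward scan over integers
#' congruent to 1 modulo 2N (so every prime supports a negacyclic NTT of the
#' ring).  \eqn{q_0} is scanned near \eqn{2^{\log q_0}}, the remaining level
#' primes near \eqn{2^\eta}, and \eqn{p_0} near \eqn{2^{\log p_0}}; the scan is
#' a fixed procedure, so the chain is a pure function of the parameters.
#'
#' Primes are represented exactly as \code{(bits, delta)} with
#' \eqn{q = 2^{bits} + delta}; \code{delta} is a small integer, so congruence
#' checks stay exact in double precision even for 60-bit primes.
#'
#' A ciphertext at level \eqn{\ell} lives over the sub-basis
#' \eqn{\{q_0, \ldots, q_{\ell-1}\}}; valid levels are 1..L, and the largest
#' switching-key modulus is \eqn{p_0 \cdot q_0 \cdots q_{L-1}}.
#'
#' @param params a \code{hegwas_params} object.
#' @return An object of class \code{hegwas_chain} with components
#'   \code{special} (the \eqn{p_0} record), \code{q} (a data frame of level
#'   primes with columns bits, delta, log2), and \code{log2_partial_products}
#'   (\eqn{\log_2 Q_\ell} for \eqn{\ell = 1..L}).
#' @export
setup_modulus_chain <- function(params) {
  stopifnot(inherits(params, "hegwas_params"))
  logN <- params$ring_log_dim
  L <- params$num_levels
  d_p0 <- cpp_scan_primes(params$special_prime_bits, logN, 1L, numeric(0))
  d_q0 <- cpp_scan_primes(params$base_prime_bits, logN, 1L,
                          if (params$base_prime_bits == params$special_prime_bits) d_p0 else numeric(0))
  avoid <- numeric(0)
  if (params$scale_bits == params$special_prime_bits) avoid <- c(avoid, d_p0)
  if (params$scale_bits == params$base_prime_bits) avoid <- c(avoid, d_q0)
  d_qi <- if (L > 1) cpp_scan_primes(params$scale_bits, logN, L - 1L, avoid) else numeric(0)

  bits <- c(params$base_prime_bits, rep(params$scale_bits, L - 1L))
  delta <- c(d_q0, d_qi)
  log2q <- bits + log2(1 + delta * 2^(-bits))
  q <- data.frame(bits = bits, delta = delta, log2 = log2q)
  special <- list(bits = params$special_prime_bits, delta = d_p0,
                  log2 = params$special_prime_bits + log2(1 + d_p0 * 2^(-params$special_prime_bits)))
  structure(list(
    params = params,
    special = special,
    q = q,
    log2_partial_products = cumsum(log2q),
    total_log2 = special$log2 + sum(log2q)
  ), class = "hegwas_chain")
}

#' @export
print.hegwas_chain <- function(x, ...) {
  cat("<hegwas_chain> ", nrow(x$q) + 1L, " primes (p0 + q0..q_",
      nrow(x$q) - 1L, "), total ", round(x$total_log2, 2), " bits\n", sep = "")
  invisible(x)
}

# approximate double value of level prime l (1-based; l = 1 is q_0)
chain_prime_dbl <- function(chain, l) {
  2^chain$q$bits[l] + chain$q$delta[l]
}
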