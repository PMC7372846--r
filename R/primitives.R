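#' Rotate-and-sum over strided slot blocks
#'
#' For a packed vector \eqn{m}, returns a ciphertext whose slot \eqn{i} holds
#' \eqn{\sum_{j=0}^{\alpha-1} m_{\psi j + i}}; with \eqn{\psi \cdot \alpha}
#' equal to the packing period the result is replicated with period
#' \eqn{\psi}.  Negative \eqn{\psi} replicates in the reverse direction (the
#' slot ring is cyclic, so \eqn{-r} is a rotation by \eqn{N_2 - r}).
#'
#' Power-of-two \eqn{\alpha} uses \eqn{\log_2 \alpha} rotate-and-add rounds;
#' other values decompose as \eqn{f(2m) = f(m) + rot(f(m), m\psi)},
#' \eqn{f(2m+1) = ct + rot(f(2m), \psi)}.  No multiplicative level is
#' consumed.
#'
#' @param ct a ciphertext.
#' @param psi stride (slots, may be negative).
#' @param alpha number of summands (>= 1).
#' @return a ciphertext at the same level and scale.
#' @export
allsum <- function(ct, psi, alpha) {
  if (alpha < 1) stop("alpha must be at least 1")
  alpha <- as.integer(alpha)
  if (alpha == 1L) return(ct)
  if (alpha %% 2L == 0L) {
    h <- allsum(ct, psi, alpha %/% 2L)
    ct_add(h, ct_rotate(h, psi * (alpha %/% 2L)))
  } else {
    ct_add(ct, ct_rotate(allsum(ct, psi, alpha - 1L), psi))
  }
}

#' Hybrid replication of a packed ciphertext
#'
#' The input packs \code{n} distinct values, value \eqn{i} occupying the
#' \eqn{N_2/n} contiguous slots of its run.  Returns \code{n} ciphertexts, the
#' i-th holding value \eqn{i} in every slot.  Phase 1 extracts \eqn{n/2^s}
#' blocks of \eqn{2^s} values by multiplicative masking and tiles each across
#' the array (one constant-multiplication level); phase 2 splits each block
#' binary-tree fashion over \code{s} stages (one constant-multiplication level
#' each).  Total level consumption is exactly \eqn{s + 1}.
#'
#' @param ct packed ciphertext (n runs of \eqn{N_2/n} identical slots).
#' @param n number of distinct values (power of two dividing \eqn{N_2}).
#' @param s phase-2 depth, \eqn{0 \le s \le \log_2 n}.
#' @return list of \code{n} ciphertexts in value order.
#' @export
replicate_ct <- function(ct, n, s) {
  ctx <- ct$ctx
  N2 <- ctx$N2
  if (n < 1 || N2 %% n != 0 || bitwAnd(n, n - 1L) != 0)
    stop("n must be a power of two dividing N2")
  if (s < 0 || s > log2(n)) stop("configuration error: s must lie in [0, log2(n)]")
  run <- N2 %/% n
  span <- as.integer(2^s * run)
  nblocks <- n %/% as.integer(2^s)
  cts <- vector("list", nblocks)
  for (g in seq_len(nblocks)) {
    mask <- numeric(N2)
    mask[((g - 1L) * span + 1L):(g * span)] <- 1
    mg <- ct_rescale(ct_cmult(ct, mask))
    cts[[g]] <- allsum(mg, -span, nblocks)
  }
  width <- span
  for (stage in seq_len(s)) {
    half <- width %/% 2L
    lowmask <- rep(c(rep(1, half), rep(0, half)), N2 %/% width)
    nxt <- vector("list", 2L * length(cts))
    for (gi in seq_along(cts)) {
      lo <- ct_rescale(ct_cmult(cts[[gi]], lowmask))
      hi <- ct_rescale(ct_cmult(cts[[gi]], 1 - lowmask))
      nxt[[2L * gi - 1L]] <- allsum(lo, -half, 2L)
      nxt[[2L * gi]] <- allsum(hi, half, 2L)
    }
    cts <- nxt
    width <- half
  }
  cts
}

#' Build a slot mask for a (n, k, copies) grid layout
#'
#' The packed layouts place each sample's k covariate positions contiguously
#' and tile them; a column mask keeps one position of every k-run.
#'
#' @param ctx context (for the slot count).
#' @param k run length of the grid.
#' @param keep columns (1-based, within each k-run) to keep.
#' @return a 0/1 vector of length \eqn{N_2}.
#' @export
make_mask <- function(ctx, k, keep = 1L) {
  unit <- numeric(k)
  unit[keep] <- 1
  rep(unit, ctx$N2 %/% k)
}
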