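#' Reconstruct association statistics from decrypted outputs
#'
#' The server releases (encrypted) per-SNP numerators \eqn{\beta_j^*},
#' denominators \eqn{\beta_j^\dagger} and the shared determinant
#' \eqn{|A|}.  After decryption the key owner computes
#' \eqn{\beta_j = \beta_j^*/\beta_j^\dagger},
#' \eqn{var_j = |A|/\beta_j^\dagger}, the Wald statistic
#' \eqn{z_j = \beta_j^* / \sqrt{|A| \beta_j^\dagger}}, and the two-sided
#' normal p-value \eqn{2(1 - \Phi(|z_j|))}.  SNPs with
#' \eqn{|A| \beta_j^\dagger \le 0} (collinear with a covariate, or noise-
#' corrupted) are flagged and get NaN statistics.
#'
#' @param beta_star,beta_dagger equal-length numeric vectors.
#' @param det_a scalar determinant.
#' @param snp_names optional names.
#' @return a tibble: snp, beta_star, beta_dagger, det_a, beta, se, z, pvalue,
#'   flag.
#' @export
reconstruct_gwas <- function(beta_star, beta_dagger, det_a, snp_names = NULL) {
  if (length(beta_star) != length(beta_dagger)) {
    stop("input error: beta_star and beta_dagger lengths differ")
  }
  p <- length(beta_star)
  denom <- det_a * beta_dagger
  bad <- !is.finite(denom) | denom <= 0
  denom[bad] <- NA_real_
  z <- ifelse(bad, NaN, beta_star / sqrt(denom))
  tibble(
    snp = snp_names %||% paste0("snp", seq_len(p)),
    beta_star = beta_star,
    beta_dagger = beta_dagger,
    det_a = rep(det_a, p),
    beta = ifelse(bad, NaN, beta_star / beta_dagger),
    se = ifelse(bad, NaN, sqrt(denom) / abs(beta_dagger)),
    z = z,
    pvalue = ifelse(bad, NaN, 2 * pnorm(-abs(z))),
    flag = ifelse(bad, "degenerate", "")
  )
}

#' Multiplicative release masking
#'
#' Before releasing \eqn{(\beta^*, \beta^\dagger, |A|)} the server can blind
#' them with random positive factors \eqn{r_j^*, r_j^\dagger, r_A} satisfying
#' \eqn{(r_j^*)^2 = r_j^\dagger r_A}, which leaves every Wald statistic (and
#' hence every p-value) invariant while hiding the raw regression quantities.
#'
#' Masking is itself one constant multiplication, so the release ciphertexts
#' must still have one level left: run the circuit with L one above the
#' planner minimum when masking is enabled.
#'
#' @param ct_star,ct_dagger,ct_det ciphertexts packing \eqn{\beta^*},
#'   \eqn{\beta^\dagger} and \eqn{|A|}.
#' @param p number of SNP slots being protected.
#' @param seed mask randomness seed.
#' @return list of masked ciphertexts plus the mask record (server-side
#'   secret).
#' @export
apply_mask <- function(ct_star, ct_dagger, ct_det, p, seed = 1L) {
  set.seed(seed)
  r_a <- exp(runif(1, -0.5, 0.5))
  r_dag <- exp(runif(p, -0.5, 0.5))
  r_star <- sqrt(r_dag * r_a)
  ctx <- ct_star$ctx
  pad <- function(v) c(v, rep(1, ctx$N2 - length(v)))
  list(
    star = ct_rescale(ct_cmult(ct_star, pad(r_star))),
    dagger = ct_rescale(ct_cmult(ct_dagger, pad(r_dag))),
    det = ct_rescale(ct_cmult(ct_det, r_a)),
    masks = list(r_star = r_star, r_dagger = r_dag, r_a = r_a)
  )
}

#' Compare two p-value vectors at a significance cutoff
#'
#' Binarizes both vectors at \code{cutoff} (test vs reference calls) and
#' reports the confusion counts, type-I/type-II error rates and the F1 score
#' \eqn{2TP/(2TP+FP+FN)}.  Non-finite p-values are excluded from the counts
#' and reported separately.
#'
#' @param p_test,p_reference equal-length p-value vectors.
#' @param cutoff significance threshold in (0, 1).
#' @return a one-row tibble of metrics.
#' @export
compare_models <- function(p_test, p_reference, cutoff = 1e-5) {
  if (length(p_test) != length(p_reference)) stop("input error: length mismatch")
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  ok <- is.finite(p_test) & is.finite(p_reference)
  te <- p_test[ok] < cutoff
  re <- p_reference[ok] < cutoff
  tp <- sum(te & re); fp <- sum(te & !re)
  fn <- sum(!te & re); tn <- sum(!te & !re)
  f1 <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  tibble(
    cutoff = cutoff, tp = tp, fp = fp, fn = fn, tn = tn,
    type1 = if (fp + tn > 0) fp / (fp + tn) else 0,
    type2 = if (tp + fn > 0) fn / (tp + fn) else 0,
    f1 = f1, excluded = sum(!ok)
  )
}
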