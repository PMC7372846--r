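#' Simulate a genotype/phenotype dataset
#'
#' Emulates the structure of a small case/control GWAS cohort: n samples,
#' p binary SNPs with per-SNP allele frequencies drawn from \code{maf_range},
#' and k covariates (intercept plus age/weight/height analogues).  The
#' phenotype follows a logistic model on the \emph{normalized} covariates and
#' a small planted set of causal SNPs:
#' \deqn{logit Pr(y = +1) = X \beta_X + \sum_{c} s_{ic} \beta_c.}
#' Covariates are generated on natural scales (years, kg, cm) with missing
#' cells inserted at \code{missing_rate}; [preprocess_covariates()] recovers
#' the model scale up to a per-column affine map, which leaves the SNP
#' association tests invariant.  The intercept of the model is chosen so the
#' expected logit is zero (balanced phenotype).
#'
#' No linkage structure, population stratification or Hardy-Weinberg
#' modelling: SNPs are independent Bernoulli columns.
#'
#' @param n,p,k samples, SNPs, covariate columns (intercept included; k >= 1).
#' @param maf_range range for per-SNP minor-allele frequencies.
#' @param n_causal number of causal SNPs (<= p).
#' @param effect_size causal log-odds effect(s), recycled to n_causal.
#' @param covar_effects log-odds effects of the k-1 normalized covariates.
#' @param missing_rate fraction of missing covariate cells.
#' @param seed integer seed (fixed seed gives byte-identical output).
#' @return a \code{gwas_dataset} with attribute \code{truth}: list of causal
#'   indices, effects, covariate effects and per-SNP maf.
#' @export
simulate_gwas_data <- function(n = 245, p = 1024, k = 4,
                               maf_range = c(0.05, 0.5),
                               n_causal = 10, effect_size = 3,
                               covar_effects = c(0.4, -0.6, 0.5),
                               missing_rate = 0.02, seed = 1L) {
  stopifnot(k >= 1, n_causal <= p)
  if (min(maf_range) <= 0 || max(maf_range) >= 1) {
    stop("degenerate maf: frequencies must lie strictly inside (0, 1)")
  }
  set.seed(seed)
  covar_effects <- rep_len(covar_effects, k - 1L)
  maf <- runif(p, maf_range[1], maf_range[2])
  S <- matrix(rbinom(n * p, 1L, rep(maf, each = n)), n, p)
  # normalized covariates in [0,1]; natural scales written to the dataset
  U <- matrix(runif(n * (k - 1L)), n, k - 1L)
  scales <- list(c(30, 40), c(50, 50), c(150, 40))  # age, weight, height analogues
  Xnat <- U
  for (j in seq_len(k - 1L)) {
    sc <- scales[[((j - 1L) %% 3L) + 1L]]
    Xnat[, j] <- sc[1] + sc[2] * U[, j]
  }
  causal <- if (n_causal > 0) sort(sample.int(p, n_causal)) else integer(0)
  beta_c <- rep_len(effect_size, n_causal)
  eta <- as.vector(U %*% covar_effects)
  if (n_causal > 0) eta <- eta + as.vector(S[, causal, drop = FALSE] %*% beta_c)
  intercept <- -(sum(covar_effects) * 0.5 +
                 if (n_causal > 0) sum(beta_c * maf[causal]) else 0)
  prob <- plogis(intercept + eta)
  y <- 2L * rbinom(n, 1L, prob) - 1L
  if (missing_rate > 0 && k > 1) {
    miss <- matrix(runif(n * (k - 1L)) < missing_rate, n, k - 1L)
    Xnat[miss] <- NA
  }
  ds <- gwas_dataset(cbind(1, Xnat), S, y,
                     covar_names = c("intercept",
                                     paste0("cov", seq_len(k - 1L))))
  attr(ds, "truth") <- list(causal = causal, beta = beta_c,
                            covar_effects = covar_effects,
                            intercept = intercept, maf = maf, seed = seed)
  ds
}
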