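#' GWAS dataset container
#'
#' Holds the covariate matrix X (first column all ones, the intercept), the
#' binary SNP matrix S, and the phenotype y coded in \{-1, +1\} (\{0, 1\}
#' accepted on input and mapped).  Real-valued or \{0,1,2\} dosage genotypes
#' are accepted behind \code{allow_dosage}, but the packed circuit's
#' \eqn{c_j = b_{1j}} identity assumes binary coding, so dosage data are for
#' the clear-text oracles only.
#'
#' @param X n-by-k numeric covariate matrix, column 1 all ones (NAs allowed
#'   until [preprocess_covariates()]).
#' @param S n-by-p genotype matrix in \{0, 1\}.
#' @param y length-n phenotype in \{-1, +1\} or \{0, 1\}.
#' @param snp_names,covar_names optional names.
#' @param allow_dosage accept non-binary S.
#' @return a \code{gwas_dataset}.
#' @export
gwas_dataset <- function(X, S, y, snp_names = NULL, covar_names = NULL,
                         allow_dosage = FALSE) {
  X <- as.matrix(X); S <- as.matrix(S)
  n <- nrow(X)
  stopifnot(nrow(S) == n, length(y) == n)
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1))) stop("validation error: y must be coded {-1,+1} or {0,1}")
  if (!isTRUE(all.equal(unname(X[, 1]), rep(1, n)))) {
    stop("validation error: column 1 of X must be the all-ones intercept")
  }
  if (!allow_dosage && !all(S %in% c(0, 1))) {
    stop("validation error: S must be binary {0,1} (set allow_dosage for dosage data)")
  }
  structure(list(
    X = X, S = S, y = as.numeric(y),
    snp_names = snp_names %||% paste0("snp", seq_len(ncol(S))),
    covar_names = covar_names %||% c("intercept", paste0("cov", seq_len(ncol(X) - 1L))),
    n = n, k = ncol(X), p = ncol(S),
    n_real = n
  ), class = "gwas_dataset")
}

#' @export
print.gwas_dataset <- function(x, ...) {
  cat("<gwas_dataset> n=", x$n_real, if (x$n > x$n_real) paste0(" (padded ", x$n, ")"),
      " k=", x$k, " p=", x$p, "\n", sep = "")
  invisible(x)
}

#' Pad samples and covariates to powers of two
#'
#' The packed encodings assume power-of-two n and k.  Padded sample rows are
#' all-zero in X (including the intercept position), S and y, so they vanish
#' in every AllSum aggregate: the weights computed for padded rows (sigmoid of
#' zero) are always multiplied by zero data, and every estimate equals the one
#' on the raw data.  Padded covariate columns are all-zero in X; the packed
#' covariance encodings (and the plain oracle) give such columns a unit
#' diagonal entry so the weighted covariance block stays nonsingular, which
#' multiplies the released numerators, denominators and determinant by one
#' common factor and leaves each SNP's coefficient, Wald statistic and
#' p-value identical to the unpadded analysis.
#'
#' @param ds a \code{gwas_dataset}.
#' @param n_target,k_target targets (powers of two, default next power of two).
#' @return the padded \code{gwas_dataset} (original size kept in
#'   \code{n_real}).
#' @export
pad_dataset <- function(ds, n_target = NULL, k_target = NULL) {
  next2 <- function(x) 2^ceiling(log2(x))
  n_target <- as.integer(n_target %||% next2(ds$n))
  k_target <- as.integer(k_target %||% next2(ds$k))
  if (n_target < ds$n || k_target < ds$k) stop("padding targets below current size")
  if (bitwAnd(n_target, n_target - 1L) != 0 || bitwAnd(k_target, k_target - 1L) != 0)
    stop("padding targets must be powers of two")
  X <- ds$X; S <- ds$S; y <- ds$y
  if (k_target > ds$k) {
    X <- cbind(X, matrix(0, ds$n, k_target - ds$k))
  }
  if (n_target > ds$n) {
    X <- rbind(X, matrix(0, n_target - ds$n, k_target))
    S <- rbind(S, matrix(0, n_target - ds$n, ds$p))
    y <- c(y, rep(0, n_target - ds$n))
  }
  out <- ds
  out$X <- X; out$S <- S; out$y <- y
  out$n <- n_target; out$k <- k_target
  out$covar_names <- c(ds$covar_names, rep("pad", k_target - ds$k))
  out
}

#' Impute and normalize covariates
#'
#' Missing covariate cells are imputed with the per-column sample mean; each
#' non-intercept column is then shifted by its minimum and divided by its
#' range, mapping it into [0, 1] (the proportionality constant of the range
#' scaling is fixed at 1; any other constant only rescales the covariate
#' coefficients).  The intercept column is untouched.
#'
#' @param ds a \code{gwas_dataset} (unpadded).
#' @return the dataset with preprocessed X.
#' @export
preprocess_covariates <- function(ds) {
  X <- ds$X
  for (j in seq_len(ds$k)[-1]) {
    col <- X[, j]
    if (all(is.na(col))) stop("validation error: covariate column ", j, " is all-missing")
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    rng <- max(col) - min(col)
    if (rng == 0) stop("validation error: covariate column ", j, " has zero range")
    X[, j] <- (col - min(col)) / rng
  }
  ds$X <- X
  ds
}

#' Write / read the TSV/CSV dialect of a dataset
#'
#' Phenotype and covariates go to a TSV (columns sample_id, y, then the
#' non-intercept covariates); genotypes to a CSV (samples by SNPs, header row
#' of SNP ids).
#'
#' @param ds a \code{gwas_dataset}.
#' @param pheno_file,geno_file file paths.
#' @return [read_gwas_data()] returns a \code{gwas_dataset}.
#' @export
write_gwas_data <- function(ds, pheno_file, geno_file) {
  ph <- data.frame(sample_id = seq_len(ds$n), y = ds$y,
                   ds$X[, -1, drop = FALSE])
  names(ph)[-(1:2)] <- ds$covar_names[-1]
  write.table(ph, pheno_file, sep = "\t", row.names = FALSE, quote = FALSE)
  geno <- as.data.frame(ds$S)
  names(geno) <- ds$snp_names
  write.table(geno, geno_file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(c(pheno_file, geno_file))
}

#' @rdname write_gwas_data
#' @export
read_gwas_data <- function(pheno_file, geno_file) {
  ph <- read.delim(pheno_file, sep = "\t", check.names = FALSE)
  geno <- read.delim(geno_file, sep = ",", check.names = FALSE)
  X <- cbind(1, as.matrix(ph[, -(1:2), drop = FALSE]))
  gwas_dataset(X, as.matrix(geno), ph$y,
               snp_names = names(geno),
               covar_names = c("intercept", names(ph)[-(1:2)]))
}
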