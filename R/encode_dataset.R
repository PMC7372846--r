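#' Pack a dataset into the encrypted input family
#'
#' Produces the ciphertext family the semi-parallel circuit consumes, with the
#' exact copy counts of the packed layouts:
#' \itemize{
#'   \item \code{ct_xS}: for every sample i and covariate column l, the SNP
#'     slots of \eqn{x_{il} S_i} (split into \eqn{\lceil p/N_2 \rceil} blocks
#'     when p exceeds the slot count); the l = 1 ciphertexts encrypt the SNP
#'     rows themselves since \eqn{x_{i1} = 1};
#'   \item \code{ct_yX}, \code{ct_X}: \eqn{N_2/(k n)} copies of each row
#'     \eqn{y_i X_i} (resp. \eqn{X_i}), rows concatenated;
#'   \item \code{ct_y}: \eqn{N_2/n} copies of each 0/1 phenotype indicator
#'     (aligned with the per-sample blocks);
#'   \item \code{ct_sigma}: for \eqn{1 \le j \le \ell \le k},
#'     \eqn{1 \le t \le k-1}, the signed minor vectors of each per-sample
#'     covariance \eqn{X_i^T X_i}, tiled per sample.  The \eqn{(k-1)!}-slot
#'     unit is zero-padded to the next power of two so the layout stays
#'     periodic (padded slots carry exact zeros through the product tree);
#'   \item \code{ct_xcol}: the k covariate columns in the \eqn{N_2/n}-copies
#'     layout (trivial encryptions of client-known values, used for the
#'     determinant row expansion in Step 7).
#' }
#' Per-sample covariances are computed in the clear before encryption.
#' Encryption levels follow the plan.
#'
#' @param ds a padded, preprocessed \code{gwas_dataset} (power-of-two n, k).
#' @param ctx a \code{hegwas_ctx} (keys required on the heaan backend).
#' @param plan a \code{hegwas_plan} for the matching k.
#' @param seed encryption randomness seed (heaan backend).
#' @return an \code{encoded_dataset}.
#' @export
encode_dataset <- function(ds, ctx, plan = level_plan(k = ds$k, params = ctx$params),
                           seed = 1L) {
  n <- ds$n; k <- ds$k; p <- ds$p; N2 <- ctx$N2
  if (bitwAnd(n, n - 1L) != 0 || bitwAnd(k, k - 1L) != 0)
    stop("packing error: n and k must be powers of two (pad_dataset first)")
  if (n * k > N2) stop("packing error: log n + log k exceeds log N2")
  fact_unit <- 2^ceiling(log2(max(1, factorial(k - 1))))
  if (n * fact_unit > N2) stop("packing error: n * (k-1)! (padded) exceeds N2")
  if (anyNA(ds$X)) stop("validation error: preprocess_covariates before encoding")
  lv <- plan$levels
  scheme <- build_minor_index_scheme(max(k, 2L))
  copies_yX <- N2 %/% (k * n)
  copies_y <- N2 %/% n
  y01 <- ifelse(ds$y > 0, 1, 0)
  seed_i <- seed

  nxt <- function() { seed_i <<- seed_i + 1L; seed_i }
  enc <- function(v, level) ct_encrypt(ctx, v, level = level, seed = nxt())

  # y'X and X in the row-replicated layout
  pack_rows <- function(M) {
    as.vector(vapply(seq_len(n), function(i) rep(M[i, ], copies_yX),
                     numeric(k * copies_yX)))
  }
  ct_yX <- enc(pack_rows(ds$y * ds$X), lv$yX)
  ct_X <- enc(pack_rows(ds$X), lv$X)
  ct_y <- enc(rep(y01, each = copies_y), lv$y)

  # SNP blocks
  nblk <- max(1L, as.integer(ceiling(p / N2)))
  blocks <- lapply(seq_len(nblk), function(b) {
    seq.int((b - 1L) * N2 + 1L, min(b * N2, p))
  })
  ct_xS <- lapply(blocks, function(idx) {
    lapply(seq_len(n), function(i) {
      lapply(seq_len(k), function(l) {
        enc(ds$X[i, l] * ds$S[i, idx], lv$xS)
      })
    })
  })

  # per-sample covariance minors.  All-zero (padded) covariate columns get a
  # unit diagonal entry on real samples, which keeps A = X'WX nonsingular and
  # multiplies beta*, beta+ and |A| by a common factor, leaving the
  # coefficient, Wald statistic and p-value of every SNP unchanged.
  phi <- N2 %/% (n * fact_unit)
  zero_cols <- which(colSums(abs(ds$X)) == 0)
  ct_sigma <- list()
  for (j in seq_len(k)) {
    for (l in j:k) {
      for (t in seq_len(k - 1L)) {
        slots <- numeric(N2)
        for (i in seq_len(n)) {
          Mi <- tcrossprod(ds$X[i, ])
          if (length(zero_cols) && ds$X[i, 1] == 1) {
            Mi[cbind(zero_cols, zero_cols)] <- 1
          }
          vec <- minor_value_vector(scheme, Mi, j, l, t)
          unit <- c(vec, numeric(fact_unit - length(vec)))
          slots[((i - 1) * N2 / n + 1):(i * N2 / n)] <- rep(unit, phi)
        }
        ct_sigma[[sig_key(j, l, t)]] <- enc(slots, lv$Sigma)
      }
    }
  }

  # covariate columns for the determinant expansion (client-known scalars)
  ct_xcol <- lapply(seq_len(k), function(r) {
    ct_trivial(ctx, rep(ds$X[, r], each = copies_y), level = lv$w)
  })

  structure(list(
    ctx = ctx, plan = plan, scheme = scheme,
    n = n, k = k, p = p, n_eff = ds$n_real,
    blocks = blocks, fact_unit = fact_unit, phi = phi,
    copies_yX = copies_yX, copies_y = copies_y,
    snp_names = ds$snp_names,
    ct_yX = ct_yX, ct_X = ct_X, ct_y = ct_y,
    ct_xS = ct_xS, ct_sigma = ct_sigma, ct_xcol = ct_xcol
  ), class = "encoded_dataset")
}

sig_key <- function(j, l, t) paste(j, l, t, sep = ".")

#' @export
print.encoded_dataset <- function(x, ...) {
  cat("<encoded_dataset> n=", x$n, " k=", x$k, " p=", x$p,
      " blocks=", length(x$blocks), " backend=", x$ctx$backend, "\n", sep = "")
  invisible(x)
}

#' Read back a packed dataset (decoding inverse, for verification)
#'
#' De-interleaves the packed ciphertext family back into X, S and y.  On the
#' emulator this is exact; on the heaan backend it is correct up to
#' encryption noise.
#'
#' @param enc an \code{encoded_dataset}.
#' @return list with X, S, y01.
#' @export
decode_encoded_dataset <- function(enc) {
  n <- enc$n; k <- enc$k; N2 <- enc$ctx$N2
  xv <- ct_decrypt(enc$ct_X)
  X <- t(vapply(seq_len(n), function(i) {
    xv[((i - 1) * k * enc$copies_yX + 1):((i - 1) * k * enc$copies_yX + k)]
  }, numeric(k)))
  yv <- ct_decrypt(enc$ct_y)
  y01 <- yv[seq(1, by = enc$copies_y, length.out = n)]
  S <- matrix(0, n, enc$p)
  for (b in seq_along(enc$blocks)) {
    idx <- enc$blocks[[b]]
    for (i in seq_len(n)) {
      S[i, idx] <- ct_decrypt(enc$ct_xS[[b]][[i]][[1]], n = length(idx))
    }
  }
  list(X = X, S = S, y01 = y01)
}
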