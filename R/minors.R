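#' Signed index vectors that linearize the minor determinants
#'
#' The encrypted pipeline inverts the k-by-k weighted covariance block through
#' its adjugate: \eqn{adj(A)_{j\ell} = (-1)^{j+\ell} |\hat A_{\ell j}|}, where
#' \eqn{\hat A_{\ell j}} removes row \eqn{\ell} and column \eqn{j}.  Each such
#' minor determinant is a sum of \eqn{(k-1)!} signed permutation products, and
#' the scheme lays those products out as the slotwise product of \eqn{k-1}
#' vectors of length \eqn{(k-1)!}: vector \eqn{t}'s slot \eqn{m} references
#' entry \eqn{A[r_t, c_{\pi_m(t)}]}, and the permutation sign (times
#' \eqn{(-1)^{j+\ell}}) is carried on the first vector.  Summing the slotwise
#' product over the \eqn{(k-1)!} slots then reproduces the adjugate entry
#' exactly, which is what the circuit's product tree and AllSum evaluate.
#'
#' @param k covariate count, 2..6 (the factorial layout grows as (k-1)!).
#' @return a \code{hegwas_minor_scheme}: for each (j, l) a list with
#'   \code{rows}, \code{cols} (matrices (k-1) x (k-1)! of A indices) and
#'   \code{signs} (same shape; +-1, sign on t = 1).
#' @export
build_minor_index_scheme <- function(k) {
  if (k < 2 || k > 6) stop("configuration error: k must lie in 2..6")
  k <- as.integer(k)
  perms <- .permutations(k - 1L)
  nperm <- nrow(perms)
  sgn <- apply(perms, 1, .perm_sign)
  pairs <- vector("list", k)
  for (j in seq_len(k)) {
    pairs[[j]] <- vector("list", k)
    for (l in seq_len(k)) {
      rows_keep <- setdiff(seq_len(k), l)
      cols_keep <- setdiff(seq_len(k), j)
      rows <- matrix(0L, k - 1L, nperm)
      cols <- matrix(0L, k - 1L, nperm)
      signs <- matrix(1, k - 1L, nperm)
      for (m in seq_len(nperm)) {
        for (t in seq_len(k - 1L)) {
          rows[t, m] <- rows_keep[t]
          cols[t, m] <- cols_keep[perms[m, t]]
        }
        signs[1L, m] <- sgn[m] * (-1)^(j + l)
      }
      pairs[[j]][[l]] <- list(rows = rows, cols = cols, signs = signs)
    }
  }
  structure(list(k = k, n_slots = nperm, pairs = pairs),
            class = "hegwas_minor_scheme")
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

.perm_sign <- function(p) {
  inv <- 0L
  n <- length(p)
  for (i in seq_len(n - 1L)) inv <- inv + sum(p[(i + 1L):n] < p[i])
  if (inv %% 2L == 0L) 1 else -1
}

#' Reconstruct the adjugate of a symmetric matrix from the scheme
#'
#' Clear-text evaluation of the linearized layout, used as the scheme's own
#' consistency check (the circuit performs the same arithmetic under
#' encryption).
#'
#' @param scheme from [build_minor_index_scheme()].
#' @param A symmetric k-by-k matrix.
#' @return the adjugate matrix \eqn{|A| A^{-1}}.
#' @export
scheme_adjugate <- function(scheme, A) {
  k <- scheme$k
  stopifnot(nrow(A) == k, ncol(A) == k)
  adj <- matrix(0, k, k)
  for (j in seq_len(k)) {
    for (l in seq_len(k)) {
      sc <- scheme$pairs[[j]][[l]]
      prod_slots <- rep(1, scheme$n_slots)
      for (t in seq_len(k - 1L)) {
        prod_slots <- prod_slots *
          (sc$signs[t, ] * A[cbind(sc$rows[t, ], sc$cols[t, ])])
      }
      adj[j, l] <- sum(prod_slots)
    }
  }
  adj
}

# the signed value vector for one (j, l, t), evaluated on a per-sample matrix;
# this is what gets packed into the Sigma ciphertexts
minor_value_vector <- function(scheme, M, j, l, t) {
  sc <- scheme$pairs[[j]][[l]]
  sc$signs[t, ] * M[cbind(sc$rows[t, ], sc$cols[t, ])]
}
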