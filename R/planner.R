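#' Ciphertext-level schedule for the semi-parallel circuit
#'
#' Derives the level of every named intermediate of the encrypted pipeline
#' from the number of Nesterov iterations (\code{num_iter}), the replication
#' block exponents \code{s} (Step 3) and \code{s_prime} (Step 6), and the
#' covariate count \code{k}.  The bookkeeping is:
#' \itemize{
#'   \item training consumes 1 level in the first iteration and 4 in each
#'     further one, so \eqn{lvl(\beta_X) = L - (4(NumIter-1)+1)};
#'   \item Steps 1 and 2 consume two levels each
#'     (\eqn{lvl(p) = L - (4 NumIter + 1)});
#'   \item weights and working response:
#'     \eqn{lvl(w) = L - (4 NumIter + 2)}, \eqn{lvl(Wz) = L - (4 NumIter + 3)};
#'   \item replication consumes \eqn{s+1} levels:
#'     \eqn{lvl(w_i) = L - (4 NumIter + s + 3)};
#'   \item Steps 4 and 5 consume one more level each, and the Step-7 product
#'     tree consumes \eqn{1 + \lceil \log_2(k-1) \rceil} levels below the
#'     \eqn{\Sigma} encryption level.
#' }
#' The minimum feasible L is \eqn{(4 NumIter + s + 4) + 3}: the Step-8 double
#' sum needs the B vectors and adjugate entries at level 3 so that the final
#' numerator/denominator land at level 1.
#'
#' @param num_iter Nesterov iterations of the covariate-only training (>= 1).
#' @param s block exponent of the Step-3 hybrid replication (phase-2 depth).
#' @param s_prime block exponent of the Step-6 replication.
#' @param k number of covariate columns (intercept included).
#' @param params optional \code{hegwas_params}; defaults to a preset whose L is
#'   the minimum feasible for (num_iter, s).
#' @return A \code{hegwas_plan}: the level of every named ciphertext, the
#'   encryption levels of the packed input family, and \code{log_Q}.
#' @export
level_plan <- function(num_iter = 2L, s = 4L, s_prime = 0L, k = 4L,
                       params = NULL) {
  stopifnot(num_iter >= 1, s >= 0, s_prime >= 0, k >= 1)
  min_L <- 4L * num_iter + s + 7L
  if (is.null(params)) {
    params <- he_params(15, min_L, 43, 51, 60, name = "auto")
  }
  L <- params$num_levels
  if (L < min_L) {
    stop("planner error: L >= (4*NumIter + s + 4) + 3 violated (L = ", L,
         ", required ", min_L, ")")
  }
  lv <- list(
    yX        = L,
    beta_X    = L - (4L * (num_iter - 1L) + 1L),
    X         = L - (4L * (num_iter - 1L) + 1L),
    yhat      = L - (4L * (num_iter - 1L) + 3L),
    y         = L - (4L * num_iter + 1L),
    p         = L - (4L * num_iter + 1L),
    w         = L - (4L * num_iter + 2L),
    Wz        = L - (4L * num_iter + 3L),
    w_i       = L - (4L * num_iter + s + 3L),
    xS        = L - (4L * num_iter + s + 3L),
    wz_i      = L - (4L * num_iter + s + 4L),
    B         = L - (4L * num_iter + s + 4L),
    sWz       = L - (4L * num_iter + s + 5L),
    XoWz      = L - (4L * num_iter + 4L),
    xWz       = L - (4L * num_iter + s_prime + 5L)
  )
  tree_depth <- if (k > 1) as.integer(ceiling(log2(k - 1))) else 0L
  lv$adj   <- lv$B
  lv$Sigma <- lv$adj + 1L + tree_depth
  lv$A_rst <- lv$Sigma - 1L
  lv$xcolW <- lv$w - 1L
  lv$detA  <- lv$adj - 1L
  lv$beta_star   <- min(lv$detA, lv$sWz) - 1L
  lv$beta_dagger <- min(lv$detA, lv$B - 1L) - 1L
  bad <- names(lv)[unlist(lv) < 1L]
  if (length(bad)) {
    stop("planner error: level of ", paste(bad, collapse = ", "),
         " falls below 1; increase L")
  }
  structure(list(
    params = params,
    num_iter = as.integer(num_iter), s = as.integer(s),
    s_prime = as.integer(s_prime), k = as.integer(k),
    L = L, min_L = min_L,
    levels = lapply(lv, as.integer),
    log_Q = total_modulus_bits(params)
  ), class = "hegwas_plan")
}

#' Nominal total modulus bit size
#'
#' \eqn{\log Q = \log q_0 + (L-1)\log q_i + \log p_0}: the bit size of the
#' largest RLWE modulus (fresh-ciphertext modulus times the special prime),
#' using the nominal prime bit sizes of the parameter set.
#'
#' @param params a \code{hegwas_params} object or preset name.
#' @return integer bit count.
#' @export
total_modulus_bits <- function(params) {
  if (is.character(params)) params <- he_preset(params)
  params$base_prime_bits + (params$num_levels - 1L) * params$scale_bits +
    params$special_prime_bits
}

#' @export
print.hegwas_plan <- function(x, ...) {
  cat("<hegwas_plan> NumIter=", x$num_iter, " s=", x$s, " s'=", x$s_prime,
      " k=", x$k, " L=", x$L, " (min ", x$min_L, "), logQ=", x$log_Q, "\n", sep = "")
  lv <- unlist(x$levels)
  for (i in seq_along(lv)) cat(sprintf("  %-12s %d\n", names(lv)[i], lv[i]))
  invisible(x)
}
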