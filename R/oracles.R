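#' Degree-3 sigmoid approximation
#'
#' \eqn{\sigma_3(x) = 0.5 + 0.15012 x - 0.001593 x^3}, the least-squares
#' cubic approximation of the logistic function on [-8, 8].  This is the
#' polynomial the encrypted circuit evaluates (two multiplicative levels).
#'
#' @param x numeric.
#' @export
sigmoid3 <- function(x) 0.5 + 0.15012 * x - 0.001593 * x^3

sigmoid_fun <- function(variant = c("sigma3", "exact")) {
  variant <- match.arg(variant)
  if (variant == "sigma3") sigmoid3 else plogis
}

#' Nesterov-accelerated gradient fit of the covariate-only logistic model
#'
#' Minimizes \eqn{L(\beta) = n^{-1} \sum_i \log(1 + e^{-y_i x_i^T \beta})}
#' (y in \{-1,+1\}) with the accelerated recurrence
#' \eqn{u_{t-1} = \beta_{t-1} + \lambda_{t-1}(\beta_{t-1} - \beta_{t-2})},
#' \eqn{\beta_t = u_{t-1} + \gamma_t n^{-1} \sum_i \sigma(-y_i x_i^T u_{t-1})
#' y_i x_i}, with \eqn{\lambda_t = (a_t - 1)/a_{t+1}},
#' \eqn{a_{t+1} = (1 + \sqrt{1 + 4 a_t^2})/2}, \eqn{a_1 = 1}, and step size
#' \eqn{\gamma_t} from \code{gamma}.  Starting from zero, the first iteration
#' has \eqn{\sigma(0) = 1/2} exactly, which is why it costs a single
#' multiplicative level under encryption.  This is the schedule the encrypted
#' trainer follows step for step.
#'
#' @param X n-by-k covariate matrix (intercept first column; padded zero rows
#'   allowed, they contribute nothing).
#' @param y phenotype in \{-1, +1\} (0 allowed on padded rows).
#' @param num_iter iterations (>= 1).
#' @param sigmoid \code{"sigma3"} (the circuit's polynomial) or
#'   \code{"exact"}.
#' @param gamma step-size schedule, a function of the iteration index.
#' @param n_eff effective sample count used in the 1/n normalization
#'   (defaults to the number of nonzero-phenotype rows, so padding does not
#'   change the fit).
#' @return list with \code{beta} (the final iterate) and \code{trace}
#'   (matrix of iterates).
#' @export
nesterov_logistic <- function(X, y, num_iter = 2L,
                              sigmoid = c("sigma3", "exact"),
                              gamma = default_gd_step, n_eff = NULL) {
  sig <- sigmoid_fun(match.arg(sigmoid))
  V <- y * X                     # rows v_i = y_i X_i (zero on padded rows)
  n_eff <- n_eff %||% sum(y != 0)
  k <- ncol(X)
  beta_prev <- beta <- rep(0, k)
  a_prev <- 1
  lam <- 0                       # momentum entering iteration t
  trace <- matrix(0, num_iter, k)
  for (t in seq_len(num_iter)) {
    u <- beta + lam * (beta - beta_prev)
    g <- colSums(as.vector(sig(-(V %*% u))) * V) / n_eff
    # padded rows contribute sig(0)*0 = 0 through the zero rows of V
    beta_new <- u + gamma(t) * g
    beta_prev <- beta
    beta <- beta_new
    a_next <- (1 + sqrt(1 + 4 * a_prev^2)) / 2
    lam <- (a_prev - 1) / a_next
    a_prev <- a_next
    trace[t, ] <- beta
  }
  list(beta = beta, trace = trace)
}

#' @rdname nesterov_logistic
#' @param t iteration index.
#' @export
default_gd_step <- function(t) 10 / (t + 1)

#' Plaintext semi-parallel logistic GWAS
#'
#' The clear-text reference for the encrypted pipeline: fit the covariate-only
#' model by Nesterov GD (same schedule as the circuit), then take a single
#' Newton step per SNP starting from \eqn{\beta = (\beta_X, 0)}, vectorized
#' over all SNPs through the block Fisher-information inverse:
#' \deqn{\beta_j = \frac{|A| s_j^T W z - b_j^T adj(A) (X^T W z)}
#'                     {|A| c_j - b_j^T adj(A) b_j}}
#' with \eqn{A = X^T W X}, \eqn{b_j = X^T W s_j}, \eqn{c_j = s_j^T W s_j},
#' weights \eqn{w_i = p_i(1-p_i)} and working response
#' \eqn{(Wz)_i = w_i \hat y_i + (y_i - p_i)} (y as 0/1 indicator).  The Wald
#' statistic is \eqn{z_j = \beta_j^* / \sqrt{|A| \beta_j^\dagger}} with
#' \eqn{\beta_j^*} the numerator and \eqn{\beta_j^\dagger} the denominator
#' above.
#'
#' The \code{"sigma3"} variant replaces the sigmoid by the circuit's cubic
#' polynomial throughout and is the emulator-equivalence oracle; the
#' \code{"exact"} variant is the statistical-quality reference.
#'
#' @param X,S,y covariates (intercept first), binary SNP matrix, phenotype in
#'   \{-1,+1\}.
#' @param num_iter Nesterov iterations for the covariate model.
#' @param sigmoid \code{"sigma3"} or \code{"exact"}.
#' @param gamma GD step schedule.
#' @return a list: per-SNP \code{beta_star}, \code{beta_dagger}, shared
#'   \code{det_a}, \code{beta_x}, and the [reconstruct_gwas()] tibble in
#'   \code{result}.
#' @export
semi_parallel_plain <- function(X, S, y, num_iter = 2L,
                                sigmoid = c("sigma3", "exact"),
                                gamma = default_gd_step) {
  sigmoid <- match.arg(sigmoid)
  sig <- sigmoid_fun(sigmoid)
  fit <- nesterov_logistic(X, y, num_iter, sigmoid, gamma)
  beta_x <- fit$beta
  yhat <- as.vector(X %*% beta_x)
  pr <- sig(yhat)
  w <- pr * (1 - pr)
  y01 <- ifelse(y > 0, 1, 0)            # padded rows (y = 0) map to 0
  wz <- w * yhat + (y01 - pr)
  # padded rows carry nonzero w, wz; every aggregate multiplies them by the
  # zero rows of X and S, so they drop out exactly as in the circuit
  A <- t(X) %*% (w * X)
  # padded (all-zero) covariate columns get a unit diagonal contribution from
  # every real sample, exactly as the packed covariance encodings do: this
  # rescales beta*, beta+ and |A| jointly without moving beta, z or p
  zero_cols <- which(colSums(abs(X)) == 0)
  if (length(zero_cols)) {
    A[cbind(zero_cols, zero_cols)] <- sum(w[X[, 1] == 1])
  }
  detA <- det(A)
  adjA <- detA * solve(A)
  bmat <- t(S) %*% (w * X)              # p x k, rows b_j
  cvec <- as.vector(t(S^2) %*% w)       # = colSums(w * S) for binary S
  sWz <- as.vector(t(S) %*% wz)
  xWz <- as.vector(t(X) %*% wz)
  beta_star <- detA * sWz - as.vector((bmat %*% adjA) %*% xWz)
  beta_dagger <- detA * cvec - rowSums((bmat %*% adjA) * bmat)
  res <- reconstruct_gwas(beta_star, beta_dagger, detA,
                          snp_names = colnames(S) %||% paste0("snp", seq_len(ncol(S))))
  list(beta_star = beta_star, beta_dagger = beta_dagger, det_a = detA,
       beta_x = beta_x, w = w, wz = wz, yhat = yhat, A = A, adj_a = adjA,
       result = res)
}

#' Full per-SNP logistic regression (gold standard)
#'
#' Fits \code{y ~ X + s_j} by binomial IRLS (via \code{stats::glm.fit}) for
#' every SNP and reports the Wald statistic of the SNP coefficient.  SNPs
#' whose design is rank-deficient or whose fit fails to converge (separation)
#' are flagged rather than raised.
#'
#' @param X,S,y as in [semi_parallel_plain()].
#' @param max_iter,tol IRLS control.
#' @return a tibble: snp, beta, se, z, pvalue, flag.
#' @export
fit_full_logistic <- function(X, S, y, max_iter = 25L, tol = 1e-8) {
  y01 <- ifelse(y > 0, 1, 0)
  live <- y != 0
  p <- ncol(S)
  kk <- ncol(X) + 1L
  out <- matrix(NA_real_, p, 4)
  flag <- character(p)
  for (j in seq_len(p)) {
    U <- cbind(X[live, , drop = FALSE], S[live, j])
    if (qr(U)$rank < kk) { flag[j] <- "singular"; next }
    fit <- tryCatch(
      suppressWarnings(glm.fit(U, y01[live], family = binomial(),
                               control = list(maxit = max_iter, epsilon = tol))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { flag[j] <- "nonconverged"; next }
    wfit <- fit$weights
    cov <- tryCatch(solve(t(U) %*% (wfit * U)), error = function(e) NULL)
    if (is.null(cov)) { flag[j] <- "singular"; next }
    b <- coef(fit)[kk]
    se <- sqrt(cov[kk, kk])
    out[j, ] <- c(b, se, b / se, 2 * pnorm(-abs(b / se)))
    flag[j] <- ""
  }
  tibble(
    snp = colnames(S) %||% paste0("snp", seq_len(p)),
    beta = out[, 1], se = out[, 2], z = out[, 3], pvalue = out[, 4],
    flag = flag
  )
}
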