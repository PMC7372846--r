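test_that("the cubic sigmoid evaluates its polynomial", {
  expect_equal(sigmoid3(0), 0.5)
  expect_equal(sigmoid3(1), 0.5 + 0.15012 - 0.001593)
  expect_equal(sigmoid3(8), 0.5 + 0.15012 * 8 - 0.001593 * 512)
  # over the fitted domain it tracks the sigmoid within the global
  # least-squares error of the cubic (worst near |x| ~ 2)
  x <- seq(-8, 8, by = 0.25)
  expect_lt(max(abs(sigmoid3(x) - plogis(x))), 0.12)
})

test_that("gradient training vanishes on antisymmetric balanced data", {
  # samples come in (X, +1) / (X, -1) pairs: every v_i = y_i X_i cancels
  X0 <- cbind(1, matrix(runif(12), 4))
  X <- rbind(X0, X0)
  y <- c(rep(1, 4), rep(-1, 4))
  fit <- nesterov_logistic(X, y, num_iter = 4)
  expect_equal(max(abs(fit$trace)), 0)
})

test_that("full logistic agrees with a direct likelihood optimizer", {
  ds <- simulate_gwas_data(n = 200, p = 3, k = 3, n_causal = 1, effect_size = 1.5,
                           missing_rate = 0, seed = 30)
  prep <- preprocess_covariates(ds)
  res <- fit_full_logistic(prep$X, prep$S, prep$y)
  y01 <- (prep$y + 1) / 2
  for (j in 1:3) {
    U <- cbind(prep$X, prep$S[, j])
    nll <- function(b) sum(log(1 + exp(-(2 * y01 - 1) * (U %*% b))))
    opt <- optim(rep(0, ncol(U)), nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    expect_lt(abs(res$beta[j] - opt$par[ncol(U)]), 1e-5)
  }
})

test_that("intercept-only model with balanced outcomes estimates zero", {
  X <- matrix(1, 40, 1)
  y <- rep(c(1, -1), 20)
  fit <- nesterov_logistic(X, y, num_iter = 8, sigmoid = "exact")
  expect_lt(abs(fit$beta[1]), 1e-10)
})

test_that("one-step update equals the closed scalar formula at k = 1", {
  set.seed(31)
  n <- 40
  X <- matrix(1, n, 1)
  S <- matrix(rbinom(n * 2, 1, 0.4), n, 2)
  y <- 2 * rbinom(n, 1, 0.5) - 1
  sp <- semi_parallel_plain(X, S, y, num_iter = 2)
  # k = 1: A = sum w, adj = 1
  fit <- nesterov_logistic(X, y, 2)
  yhat <- as.vector(X %*% fit$beta)
  p <- sigmoid3(yhat); w <- p * (1 - p)
  wz <- w * yhat + ((y + 1) / 2 - p)
  A <- sum(w)
  for (j in 1:2) {
    b <- sum(w * S[, j]); cc <- sum(w * S[, j]^2)
    num <- A * sum(S[, j] * wz) - b * sum(wz)
    den <- A * cc - b^2
    expect_equal(sp$beta_star[j], num, tolerance = 1e-12)
    expect_equal(sp$beta_dagger[j], den, tolerance = 1e-12)
  }
})

test_that("adjugate form equals the direct one-step Newton solve", {
  set.seed(32)
  for (rep in 1:30) {
    k <- sample(2:5, 1)
    n <- 60
    X <- cbind(1, matrix(runif(n * (k - 1)), n))
    s <- rbinom(n, 1, 0.4)
    y <- 2 * rbinom(n, 1, 0.5) - 1
    sp <- semi_parallel_plain(X, matrix(s), y, num_iter = 2)
    U <- cbind(X, s)
    fit <- nesterov_logistic(X, y, 2)
    yhat <- as.vector(X %*% fit$beta)
    p <- sigmoid3(yhat); w <- p * (1 - p)
    z_num <- w * yhat + ((y + 1) / 2 - p)
    direct <- solve(t(U) %*% (w * U), t(U) %*% z_num)
    expect_lt(abs(sp$result$beta[1] - direct[k + 1]), 1e-9)
  }
})

test_that("semi-parallel p-values track the gold standard on moderate effects", {
  ds <- simulate_gwas_data(n = 300, p = 300, k = 4, n_causal = 15,
                           effect_size = 1.5, missing_rate = 0, seed = 33)
  prep <- preprocess_covariates(ds)
  sp <- semi_parallel_plain(prep$X, prep$S, prep$y, num_iter = 2,
                            sigmoid = "exact")
  gold <- fit_full_logistic(prep$X, prep$S, prep$y)
  ok <- is.finite(sp$result$pvalue) & is.finite(gold$pvalue)
  rho <- cor(-log10(sp$result$pvalue[ok]), -log10(gold$pvalue[ok]),
             method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("planted causal SNPs attain the smallest p-values", {
  ds <- simulate_gwas_data(n = 400, p = 100, k = 4, n_causal = 3,
                           effect_size = 3, missing_rate = 0, seed = 34)
  prep <- preprocess_covariates(ds)
  sp <- semi_parallel_plain(prep$X, prep$S, prep$y, num_iter = 2)
  truth <- attr(ds, "truth")
  top <- order(sp$result$pvalue)[1:3]
  expect_setequal(top, truth$causal)
})
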