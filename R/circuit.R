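#' Encrypted covariate-only training (Step 0)
#'
#' Runs the Nesterov-accelerated GD of [nesterov_logistic()] under encryption.
#' The first iteration starts from zero, where the sigmoid is exactly 1/2, so
#' it costs a single constant multiplication; every further iteration costs
#' exactly four multiplicative levels:
#' \enumerate{
#'   \item inner products \eqn{\langle v_i, \beta \rangle} by a ciphertext
#'     product with the packed \eqn{y^T X} plus a k-strided AllSum;
#'   \item the masked cubic-sigmoid combination.  The momentum iterate
#'     \eqn{u = (1+\lambda)\beta_t - \lambda\beta_{t-1}} is never
#'     materialized on the critical path: the scalars fold into the
#'     constant multiplications of the polynomial evaluation (and the
#'     three squared/cross products of the two inner-product ciphertexts),
#'     so \eqn{\sigma_3(-\langle v_i, u\rangle)}, pre-multiplied by the
#'     step size, the 1/n normalization and the column mask, comes out
#'     after two more levels;
#'   \item replication of the masked column across the k grid columns
#'     (AllSum, level-free) and the product with \eqn{y^T X};
#' }
#' followed by the level-free sample aggregation.  The additive momentum
#' combination for the state update happens off the critical path (one
#' constant multiplication in parallel, then a mod-down).
#'
#' @param enc an \code{encoded_dataset}.
#' @param num_iter iterations (>= 1).
#' @param gamma step schedule.
#' @param trace an environment collecting realized levels (optional).
#' @return a ciphertext with \eqn{N_2/k} copies of \eqn{\beta_X}.
#' @export
train_covariate_model <- function(enc, num_iter = enc$plan$num_iter,
                                  gamma = default_gd_step, trace = NULL) {
  ctx <- enc$ctx
  n <- enc$n; k <- enc$k; N2 <- ctx$N2
  n_eff <- enc$n_eff
  mask1 <- make_mask(ctx, k, 1L)
  # lambda sequence of the accelerated recurrence
  a <- 1
  lam <- numeric(num_iter)
  for (t in seq_len(num_iter)) {
    a_next <- (1 + sqrt(1 + 4 * a^2)) / 2
    lam[t] <- (a - 1) / a_next
    a <- a_next
  }
  # iteration 1 from zero: sigma(0) = 1/2 exactly
  g0 <- allsum(enc$ct_yX, N2 %/% n, n)
  beta <- ct_rescale(ct_cmult(g0, gamma(1) * 0.5 / n_eff))
  beta_prev <- NULL
  for (t in seq_len(num_iter)[-1]) {
    lamt <- lam[t - 1]                      # momentum entering u_{t-1}
    cA <- 1 + lamt
    cB <- -lamt
    use_b <- (cB != 0) && !is.null(beta_prev)
    yX_a <- ct_mod_down(enc$ct_yX, beta$level)
    ipA <- ct_rescale(allsum(ct_mult(beta, yX_a), 1L, k))
    if (use_b) {
      bp <- ct_mod_down(beta_prev, beta$level)
      ipB <- ct_rescale(allsum(ct_mult(bp, yX_a), 1L, k))
    }
    # sigma3(-x) coefficients, folded with step size, 1/n and the column mask
    C0 <- 0.5 * gamma(t) / n_eff
    C1 <- -0.15012 * gamma(t) / n_eff
    C3 <- 0.001593 * gamma(t) / n_eff
    lc <- function(coefA, coefB) {        # coef * mask * x as one level
      out <- ct_rescale(ct_cmult(ipA, coefA * mask1))
      if (use_b) out <- ct_add(out, ct_rescale(ct_cmult(ipB, coefB * mask1)))
      out
    }
    # x^2 * (C3 mask x) with the momentum scalars distributed over the
    # three products of the two inner-product ciphertexts
    sqA <- ct_rescale(ct_relin(ct_raw_mult(ipA, ipA)))
    tA1 <- lc(C3 * cA^3, C3 * cA^2 * cB)
    cub_ext <- ct_raw_mult(sqA, tA1)
    if (use_b) {
      ab <- ct_rescale(ct_relin(ct_raw_mult(ipA, ipB)))
      sqB <- ct_rescale(ct_relin(ct_raw_mult(ipB, ipB)))
      tA2 <- lc(2 * C3 * cA^2 * cB, 2 * C3 * cA * cB^2)
      tA3 <- lc(C3 * cA * cB^2, C3 * cB^3)
      cub_ext <- ct_add(cub_ext, ct_raw_mult(ab, tA2))
      cub_ext <- ct_add(cub_ext, ct_raw_mult(sqB, tA3))
    }
    cub <- ct_rescale(ct_relin(cub_ext))
    lin <- ct_mod_down(lc(C1 * cA, C1 * cB), cub$level)
    sig_m <- ct_add_plain(ct_add(cub, lin), C0 * mask1)
    rep_all <- allsum(sig_m, -1L, k)
    ct6 <- ct_rescale(ct_mult(rep_all, ct_mod_down(enc$ct_yX, rep_all$level)))
    ct7 <- allsum(ct6, N2 %/% n, n)
    # state update: u = cA beta + cB beta_prev, off the critical path
    u <- if (!use_b) beta
         else ct_rescale(ct_add(ct_cmult(beta, cA),
                                ct_cmult(ct_mod_down(beta_prev, beta$level), cB)))
    beta_new <- ct_add(ct_mod_down(u, ct7$level), ct7)
    beta_prev <- beta
    beta <- beta_new
  }
  if (!is.null(trace)) trace$beta_X <- beta$level
  beta
}

#' Run the encrypted semi-parallel pipeline (Steps 1-8)
#'
#' Produces encryptions of the per-SNP numerators \eqn{\beta^*}, denominators
#' \eqn{\beta^\dagger} and the determinant \eqn{|A|} of the weighted
#' covariance block, mapped over SNP blocks.  Every multiplication is
#' followed by an explicit rescale and every alignment by an explicit
#' mod-down, so the realized level of each named intermediate can be compared
#' with the plan.
#'
#' @param enc an \code{encoded_dataset}.
#' @param gamma GD step schedule for Step 0.
#' @param keep_intermediates also return the named intermediate ciphertexts
#'   (predicted values, weights, B vectors, adjugate entries, ...), used by
#'   the step-level verification tests.
#' @return list with \code{ct_beta_star}, \code{ct_beta_dagger} (lists over
#'   SNP blocks), \code{ct_detA}, the covariate model ciphertext, and
#'   \code{trace} (realized levels of all named intermediates).
#' @export
run_encrypted_gwas <- function(enc, gamma = default_gd_step,
                               keep_intermediates = FALSE) {
  ctx <- enc$ctx
  plan <- enc$plan
  n <- enc$n; k <- enc$k; N2 <- ctx$N2
  trace <- new.env()
  trace$yX <- enc$ct_yX$level
  trace$X <- enc$ct_X$level
  trace$y <- enc$ct_y$level
  trace$xS <- enc$ct_xS[[1]][[1]][[1]]$level
  trace$Sigma <- enc$ct_sigma[[1]]$level

  ## Step 0
  ct_beta <- train_covariate_model(enc, plan$num_iter, gamma, trace)

  ## Step 1: predicted values, replicated
  mask1 <- make_mask(ctx, k, 1L)
  yhat_star <- ct_rescale(allsum(ct_mult(ct_beta, ct_mod_down(enc$ct_X, ct_beta$level)), 1L, k))
  ct_yhat <- allsum(ct_rescale(ct_cmult(yhat_star, mask1)), -1L, k)
  trace$yhat <- ct_yhat$level

  ## Step 2: sigmoid, weights, working response
  x2 <- ct_rescale(ct_mult(ct_yhat, ct_yhat))
  t3 <- ct_rescale(ct_cmult(ct_yhat, -0.001593))
  cub <- ct_rescale(ct_mult(x2, t3))
  lin <- ct_mod_down(ct_rescale(ct_cmult(ct_yhat, 0.15012)), cub$level)
  ct_p <- ct_add_plain(ct_add(cub, lin), 0.5)
  trace$p <- ct_p$level
  one_minus_p <- ct_add_plain(ct_negate(ct_p), 1)
  ct_w <- ct_rescale(ct_mult(ct_p, one_minus_p))
  trace$w <- ct_w$level
  wy <- ct_rescale(ct_mult(ct_w, ct_mod_down(ct_yhat, ct_w$level)))
  ymp <- ct_mod_down(ct_sub(enc$ct_y, ct_p), wy$level)
  ct_Wz <- ct_add(wy, ymp)
  trace$Wz <- ct_Wz$level

  ## Step 3: replication into per-sample constants
  w_i <- replicate_ct(ct_w, n, plan$s)
  wz_i <- replicate_ct(ct_Wz, n, plan$s)
  trace$w_i <- w_i[[1]]$level
  trace$wz_i <- wz_i[[1]]$level

  nblk <- length(enc$blocks)

  ## Step 4: B_l = sum_i w_i * x_il S_i (lazy key switching)
  ct_B <- lapply(seq_len(nblk), function(b) {
    lapply(seq_len(k), function(l) {
      acc <- ct_raw_mult(w_i[[1]], enc$ct_xS[[b]][[1]][[l]])
      for (i in seq_len(n)[-1]) {
        acc <- ct_add(acc, ct_raw_mult(w_i[[i]], enc$ct_xS[[b]][[i]][[l]]))
      }
      ct_rescale(ct_relin(acc))
    })
  })
  trace$B <- ct_B[[1]][[1]]$level

  ## Step 5: s_j' W z (the l = 1 ciphertexts encrypt S_i exactly)
  ct_sWz <- lapply(seq_len(nblk), function(b) {
    acc <- ct_raw_mult(wz_i[[1]], ct_mod_down(enc$ct_xS[[b]][[1]][[1]], wz_i[[1]]$level))
    for (i in seq_len(n)[-1]) {
      acc <- ct_add(acc, ct_raw_mult(wz_i[[i]],
                                     ct_mod_down(enc$ct_xS[[b]][[i]][[1]], wz_i[[i]]$level)))
    }
    ct_rescale(ct_relin(acc))
  })
  trace$sWz <- ct_sWz[[1]]$level

  ## Step 6: X' W z, replicated per column
  if (plan$s_prime != 0L) stop("only s' = 0 column replication is implemented")
  XoWz <- ct_rescale(ct_mult(ct_mod_down(enc$ct_X, ct_Wz$level), ct_Wz))
  trace$XoWz <- XoWz$level
  XtWz <- allsum(XoWz, N2 %/% n, n)
  ct_xWz <- lapply(seq_len(k), function(c) {
    allsum(ct_rescale(ct_cmult(XtWz, make_mask(ctx, k, c))), -1L, k)
  })
  trace$xWz <- ct_xWz[[1]]$level

  ## Step 7: adjugate and determinant of A = X' W X
  w_md <- ct_mod_down(ct_w, enc$ct_sigma[[1]]$level)
  adj <- vector("list", k)
  for (j in seq_len(k)) adj[[j]] <- vector("list", k)
  for (j in seq_len(k)) {
    for (l in j:k) {
      parts <- lapply(seq_len(k - 1L), function(t) {
        Sp <- ct_rescale(ct_mult(w_md, enc$ct_sigma[[sig_key(j, l, t)]]))
        allsum(Sp, N2 %/% n, n)
      })
      if (j == 1 && l == 1) trace$A_rst <- parts[[1]]$level
      prod <- product_tree(ctx, parts)
      entry <- allsum(prod, 1L, enc$fact_unit)
      adj[[j]][[l]] <- entry
      adj[[l]][[j]] <- entry     # A symmetric, adjugate symmetric
    }
  }
  trace$adj <- adj[[1]][[1]]$level
  xcolW <- lapply(seq_len(k), function(r) {
    allsum(ct_rescale(ct_mult(enc$ct_xcol[[r]], ct_w)), N2 %/% n, n)
  })
  trace$xcolW <- xcolW[[1]]$level
  det_acc <- NULL
  for (r in seq_len(k)) {
    term <- ct_raw_mult(ct_mod_down(xcolW[[r]], adj[[1]][[r]]$level), adj[[1]][[r]])
    det_acc <- if (is.null(det_acc)) term else ct_add(det_acc, term)
  }
  ct_detA <- ct_rescale(ct_relin(det_acc))
  trace$detA <- ct_detA$level

  ## Step 8: numerators and denominators over SNP slots
  ct_beta_star <- vector("list", nblk)
  ct_beta_dagger <- vector("list", nblk)
  for (b in seq_len(nblk)) {
    m <- min(ct_detA$level, ct_sWz[[b]]$level)
    acc <- ct_raw_mult(ct_mod_down(ct_detA, m), ct_mod_down(ct_sWz[[b]], m))
    for (r in seq_len(k)) {
      for (s2 in seq_len(k)) {
        D <- ct_rescale(ct_mult(adj[[r]][[s2]],
                                ct_mod_down(ct_xWz[[s2]], adj[[r]][[s2]]$level)))
        acc <- ct_sub(acc, ct_raw_mult(ct_mod_down(ct_B[[b]][[r]], D$level), D))
      }
    }
    ct_beta_star[[b]] <- ct_rescale(ct_relin(acc))

    m2 <- min(ct_detA$level, ct_B[[b]][[1]]$level)
    acc2 <- ct_raw_mult(ct_mod_down(ct_detA, m2), ct_mod_down(ct_B[[b]][[1]], m2))
    for (r in seq_len(k)) {
      for (s2 in seq_len(k)) {
        E <- ct_rescale(ct_mult(adj[[r]][[s2]],
                                ct_mod_down(ct_B[[b]][[s2]], adj[[r]][[s2]]$level)))
        acc2 <- ct_sub(acc2, ct_raw_mult(ct_mod_down(ct_B[[b]][[r]], E$level), E))
      }
    }
    ct_beta_dagger[[b]] <- ct_rescale(ct_relin(acc2))
  }
  trace$beta_star <- ct_beta_star[[1]]$level
  trace$beta_dagger <- ct_beta_dagger[[1]]$level

  out <- list(
    ct_beta_star = ct_beta_star,
    ct_beta_dagger = ct_beta_dagger,
    ct_detA = ct_detA,
    ct_beta_x = ct_beta,
    trace = as.list(trace)
  )
  if (keep_intermediates) {
    out$intermediates <- list(
      yhat_star = yhat_star, yhat = ct_yhat, p = ct_p, w = ct_w, Wz = ct_Wz,
      w_i = w_i, wz_i = wz_i, B = ct_B, sWz = ct_sWz, XoWz = XoWz,
      xWz = ct_xWz, adj = adj, xcolW = xcolW
    )
  }
  out
}

# pairwise product tree; odd counts padded with trivial encryptions of ones
product_tree <- function(ctx, cts) {
  while (length(cts) > 1) {
    if (length(cts) %% 2 == 1) {
      one <- ct_trivial(ctx, rep(1, ctx$N2), level = cts[[1]]$level)
      cts <- c(cts, list(one))
    }
    cts <- lapply(seq_len(length(cts) / 2), function(i) {
      ct_rescale(ct_mult(cts[[2 * i - 1]], cts[[2 * i]]))
    })
  }
  cts[[1]]
}

#' Decrypt circuit outputs and reconstruct statistics
#'
#' @param out result of [run_encrypted_gwas()].
#' @param enc the matching \code{encoded_dataset}.
#' @return a [reconstruct_gwas()] tibble over all SNPs.
#' @export
decrypt_gwas <- function(out, enc) {
  star <- numeric(0); dag <- numeric(0)
  for (b in seq_along(enc$blocks)) {
    nb <- length(enc$blocks[[b]])
    star <- c(star, ct_decrypt(out$ct_beta_star[[b]], n = nb))
    dag <- c(dag, ct_decrypt(out$ct_beta_dagger[[b]], n = nb))
  }
  det_a <- ct_decrypt(out$ct_detA, n = 1L)
  reconstruct_gwas(star, dag, det_a, snp_names = enc$snp_names)
}

#' Compare a realized level trace with the plan
#'
#' @param trace the \code{trace} component of [run_encrypted_gwas()] output.
#' @param plan a \code{hegwas_plan}.
#' @return tibble of name, planned, realized, match.
#' @export
check_level_trace <- function(trace, plan) {
  nm <- intersect(names(plan$levels), names(trace))
  tibble(
    name = nm,
    planned = unlist(plan$levels[nm]),
    realized = unlist(trace[nm]),
    match = unlist(plan$levels[nm]) == unlist(trace[nm])
  )
}
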