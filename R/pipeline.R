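#' End-to-end GWAS run
#'
#' Orchestrates simulate/load -> pad -> preprocess -> keygen -> encode ->
#' train -> evaluate -> decrypt -> reconstruct on the selected backend, or the
#' clear-text references (\code{"plain"} = plaintext semi-parallel,
#' \code{"full"} = per-SNP IRLS gold standard).  Backends share the dataset
#' preparation, so results are directly comparable.
#'
#' @param ds a \code{gwas_dataset} (raw; padding and preprocessing are applied
#'   here).
#' @param backend "emulator", "heaan", "plain" or "full".
#' @param preset parameter preset name for the encrypted backends.
#' @param num_iter,s,s_prime circuit plan knobs (defaults from the preset).
#' @param gamma GD step schedule.
#' @param seed key/encryption randomness seed.
#' @param keep_ciphertexts keep circuit ciphertexts in the return value.
#' @return list with \code{result} (per-SNP tibble), \code{plan},
#'   \code{trace} (encrypted backends), \code{backend}.
#' @export
run_gwas <- function(ds, backend = c("emulator", "heaan", "plain", "full"),
                     preset = "set2_small", num_iter = NULL, s = NULL,
                     s_prime = NULL, gamma = default_gd_step, seed = 1L,
                     keep_ciphertexts = FALSE) {
  backend <- match.arg(backend)
  prep <- preprocess_covariates(ds)
  if (backend == "full") {
    res <- fit_full_logistic(prep$X, prep$S, prep$y)
    return(list(result = res, backend = backend))
  }
  if (backend == "plain") {
    padded <- pad_dataset(prep)
    sp <- semi_parallel_plain(padded$X, padded$S, padded$y,
                              num_iter = num_iter %||% he_preset(preset)$num_iter,
                              gamma = gamma)
    return(list(result = sp$result, beta_x = sp$beta_x, backend = backend))
  }
  params <- he_preset(preset)
  plan <- level_plan(num_iter %||% params$num_iter, s %||% params$s,
                     s_prime %||% params$s_prime,
                     k = 2^ceiling(log2(ds$k)), params = params)
  ctx <- he_context(params, backend = if (backend == "heaan") "heaan" else "emulator")
  padded <- pad_dataset(prep)
  if (backend == "heaan") keygen(ctx, seed = seed)
  enc <- encode_dataset(padded, ctx, plan, seed = seed + 1000L)
  out <- run_encrypted_gwas(enc, gamma = gamma)
  res <- decrypt_gwas(out, enc)
  structure(list(
    result = res,
    plan = plan,
    trace = out$trace,
    trace_check = check_level_trace(out$trace, plan),
    backend = backend,
    ciphertexts = if (keep_ciphertexts) out else NULL
  ), class = "hegwas_run")
}

#' @export
print.hegwas_run <- function(x, ...) {
  cat("<hegwas_run> backend=", x$backend, "\n", sep = "")
  print(head(x$result))
  if (!is.null(x$trace_check) && !all(x$trace_check$match)) {
    cat("level trace deviates from plan!\n")
  }
  invisible(x)
}

#' Concordance scatter of two analyses
#'
#' Plots -log10 p-values of a test analysis against a reference (the standard
#' concordance diagnostic for the encrypted pipeline against its clear-text
#' oracle).  Requires ggplot2.
#'
#' @param p_test,p_reference p-value vectors.
#' @param cutoff optional cutoff drawn as reference lines.
#' @return a ggplot object.
#' @export
plot_concordance <- function(p_test, p_reference, cutoff = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- data.frame(ref = -log10(p_reference), test = -log10(p_test))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = ref, y = test)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "-log10 p (reference)", y = "-log10 p (test)")
  if (!is.null(cutoff)) {
    gg <- gg +
      ggplot2::geom_vline(xintercept = -log10(cutoff), linetype = 3) +
      ggplot2::geom_hline(yintercept = -log10(cutoff), linetype = 3)
  }
  gg
}
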