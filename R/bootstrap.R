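#' Subject-level bootstrap of a population fit
#'
#' Resamples subjects with replacement (to the original subject count),
#' refits the model to each resampled dataset (warm-started at the
#' original estimates), and reports empirical percentile 95% confidence
#' intervals of the converged replicates together with the convergence
#' rate.
#'
#' @param fit A `hemo_fit`.
#' @param n_boot Number of bootstrap datasets (default 500).
#' @param seed Integer seed.
#' @param control Optional overrides of the fit control (e.g. a smaller
#'   `iter.max` for the warm-started refits).
#' @return An object of class `hemo_boot`: list with `estimates` (matrix
#'   of converged replicate estimates), `ci` (data frame with
#'   `parameter`, `lo`, `hi`, `median`), `convergence_rate`, `n_boot`.
#' @export
bootstrap_hemo <- function(fit, n_boot = 500, seed = 1, control = list()) {
  stopifnot(inherits(fit, "hemo_fit"))
  n <- length(fit$subj_data)
  if (n < 10L) stop("invalid input: bootstrap needs >= 10 subjects")
  ctl <- utils::modifyList(fit$control, control)
  set.seed(seed)
  cf0 <- fit$coef
  est <- matrix(NA_real_, n_boot, length(fit$free),
                dimnames = list(NULL, fit$free))
  conv <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    ix <- sample.int(n, n, replace = TRUE)
    subj_b <- fit$subj_data[ix]
    res <- tryCatch(
      fit_core(subj_b, fit$config, cf0, fit$fixed, ctl),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$final$nll2) && res$final$nll2 < 1e9) {
      est[b, ] <- unlist(res$cf_hat[fit$free])
      conv[b] <- TRUE
    }
  }
  rate <- mean(conv)
  if (rate < 0.5)
    stop(sprintf("bootstrap failed: only %.0f%% of replicates converged",
                 100 * rate))
  ok <- est[conv, , drop = FALSE]
  # order-statistic percentiles: equivariant under monotone transforms
  ci <- data.frame(
    parameter = colnames(ok),
    lo = apply(ok, 2, stats::quantile, 0.025, type = 1),
    median = apply(ok, 2, stats::quantile, 0.5, type = 1),
    hi = apply(ok, 2, stats::quantile, 0.975, type = 1))
  rownames(ci) <- NULL
  structure(list(estimates = ok, ci = ci, convergence_rate = rate,
                 n_boot = n_boot), class = "hemo_boot")
}

#' @export
print.hemo_boot <- function(x, ...) {
  cat(sprintf("<hemo_boot> %d replicates, %.0f%% converged\n",
              x$n_boot, 100 * x$convergence_rate))
  print(transform(x$ci, lo = signif(lo, 4), median = signif(median, 4),
                  hi = signif(hi, 4)), row.names = FALSE)
  invisible(x)
}

#' Write bootstrap confidence intervals as CSV
#'
#' @param boot A `hemo_boot`.
#' @param path File path.
#' @export
write_bootstrap_csv <- function(boot, path) {
  utils::write.csv(boot$ci, path, row.names = FALSE)
  invisible(path)
}
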