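#' @export
print.hemo_fit <- function(x, ...) {
  cat("<hemo_fit> population turn-over model\n")
  cat(sprintf("  %d subjects, %d observations; -2LL = %.2f\n",
              x$n_subjects, x$n_obs, x$minus2LL))
  cat(sprintf("  %d free parameters (%d fixed); nlminb code %d\n",
              length(x$free), length(x$fixed), x$convergence$code))
  cat("  use summary() for the estimate table\n")
  invisible(x)
}

#' Summarize a population fit
#'
#' Prints the estimate table: fixed effects, inter-individual variability
#' as CV(%), the random-effect covariance, residual SDs, with relative
#' standard errors (if computed) and shrinkage.
#'
#' @param object A `hemo_fit`.
#' @param ... Unused.
#' @return A data frame (invisibly printed) with columns `parameter`,
#'   `estimate`, `rse_pct`, `shrinkage_pct`.
#' @export
summary.hemo_fit <- function(object, ...) {
  cf <- object$coef
  rows <- list(
    c("C50_propo (ug/mL)", cf[["C50_propo"]]),
    c("IIV C50_propo (%)", omega2_to_cv(cf[["omega2_C50_propo"]])),
    c("Emax_propo", cf[["Emax_propo"]]),
    c("C50_remi (ng/mL)", cf[["C50_remi"]]),
    c("IIV C50_remi (%)", omega2_to_cv(cf[["omega2_C50_remi"]])),
    c("Emax_remi_HR", cf[["Emax_remi"]]),
    c("gamma_remi", cf[["gamma_remi"]]),
    c("MAP0 (mmHg)", cf[["MAP0"]]),
    c("IIV MAP0 (%)", omega2_to_cv(cf[["omega2_MAP0"]])),
    c("HR0 (bpm)", cf[["HR0"]]),
    c("IIV HR0 (%)", omega2_to_cv(cf[["omega2_HR0"]])),
    c("kout (1/min)", cf[["kout"]]),
    c("IIV kout_MAP (%)", omega2_to_cv(cf[["omega2_kout_MAP"]])),
    c("IIV kout_HR (%)", omega2_to_cv(cf[["omega2_kout_HR"]])),
    c("FB_HR", cf[["FB_HR"]]),
    c("k_stim (1/min)", cf[["k_stim"]]),
    c("theta_stim", cf[["theta_stim"]]),
    c("cov(C50_propo, kout_MAP)",
      cf[["corr_c50p_kout"]] *
        sqrt(cf[["omega2_C50_propo"]] * cf[["omega2_kout_MAP"]])),
    c("sigma_MAP (mmHg)", cf[["sigma_MAP"]]),
    c("sigma_HR (bpm)", cf[["sigma_HR"]]))
  tab <- data.frame(parameter = vapply(rows, `[`, "", 1),
                    estimate = as.numeric(vapply(rows, `[`, "", 2)))
  shr_map <- c("IIV C50_propo (%)" = "C50_propo",
               "IIV C50_remi (%)" = "C50_remi",
               "IIV MAP0 (%)" = "MAP0", "IIV HR0 (%)" = "HR0",
               "IIV kout_MAP (%)" = "kout_MAP",
               "IIV kout_HR (%)" = "kout_HR")
  tab$shrinkage_pct <- NA_real_
  for (i in seq_len(nrow(tab))) {
    key <- shr_map[tab$parameter[i]]
    if (!is.na(key)) tab$shrinkage_pct[i] <- object$shrinkage[[key]]
  }
  rse_map <- c("C50_propo (ug/mL)" = "C50_propo", "Emax_propo" = "Emax_propo",
               "C50_remi (ng/mL)" = "C50_remi", "Emax_remi_HR" = "Emax_remi",
               "gamma_remi" = "gamma_remi", "MAP0 (mmHg)" = "MAP0",
               "HR0 (bpm)" = "HR0", "kout (1/min)" = "kout",
               "FB_HR" = "FB_HR", "k_stim (1/min)" = "k_stim",
               "theta_stim" = "theta_stim", "sigma_MAP (mmHg)" = "sigma_MAP",
               "sigma_HR (bpm)" = "sigma_HR")
  tab$rse_pct <- NA_real_
  if (!is.null(object$rse)) {
    for (i in seq_len(nrow(tab))) {
      key <- rse_map[tab$parameter[i]]
      if (!is.na(key) && key %in% names(object$rse))
        tab$rse_pct[i] <- object$rse[[key]]
    }
  }
  cat(sprintf("Population turn-over model fit: %d subjects, %d observations\n",
              object$n_subjects, object$n_obs))
  cat(sprintf("-2 log-likelihood (Laplace): %.2f\n\n", object$minus2LL))
  print(transform(tab, estimate = signif(estimate, 4),
                  rse_pct = signif(rse_pct, 3),
                  shrinkage_pct = signif(shrinkage_pct, 3)),
        row.names = FALSE)
  invisible(tab)
}

#' @export
coef.hemo_fit <- function(object, ...) object$coef

#' @export
logLik.hemo_fit <- function(object, ...) {
  structure(-object$minus2LL / 2, df = length(object$free),
            nobs = object$n_obs, class = "logLik")
}

# population parameters implied by the fit, for simulation/diagnostics
#' Population parameters from a fit
#'
#' Converts the estimates of a `hemo_fit` into a
#' [population_parameters()] object usable by [sample_individual()],
#' [pcvpc()] or [simulate_risk()].
#'
#' @param fit A `hemo_fit`.
#' @return A `pop_params` object.
#' @export
as_population <- function(fit) {
  stopifnot(inherits(fit, "hemo_fit"))
  cf <- fit$coef
  config <- fit$config
  typ <- hemo_params(
    MAP0 = cf[["MAP0"]], HR0 = cf[["HR0"]],
    kout_MAP = cf[["kout"]], kout_HR = cf[["kout"]],
    C50_propo = cf[["C50_propo"]], Emax_propo = cf[["Emax_propo"]],
    gamma_propo = if (config$gamma_propo) cf[["gamma_propo"]] else 1,
    C50_remi = cf[["C50_remi"]], Emax_remi = cf[["Emax_remi"]],
    gamma_remi = cf[["gamma_remi"]],
    C50_remi_MAP = if (config$remi_on_map) cf[["C50_remi_MAP"]] else 1,
    Emax_remi_MAP = if (config$remi_on_map) cf[["Emax_remi_MAP"]] else 0,
    FB_HR = cf[["FB_HR"]], FB_MAP = 0,
    theta_stim = cf[["theta_stim"]], k_stim = cf[["k_stim"]])
  population_parameters(
    typicals = typ,
    cv = list(C50_propo = omega2_to_cv(cf[["omega2_C50_propo"]]),
              C50_remi = omega2_to_cv(cf[["omega2_C50_remi"]]),
              MAP0 = omega2_to_cv(cf[["omega2_MAP0"]]),
              HR0 = omega2_to_cv(cf[["omega2_HR0"]]),
              kout_MAP = omega2_to_cv(cf[["omega2_kout_MAP"]]),
              kout_HR = omega2_to_cv(cf[["omega2_kout_HR"]]),
              k_stim = 100),
    cov_c50p_kout = cf[["corr_c50p_kout"]] *
      sqrt(cf[["omega2_C50_propo"]] * cf[["omega2_kout_MAP"]]),
    sigma_MAP = cf[["sigma_MAP"]], sigma_HR = cf[["sigma_HR"]])
}

# simulate one subject's responses from the fit machinery
subj_predict <- function(subj, typ, eta = rep(0, 7)) {
  p <- typ
  p[5] <- p[5] * exp(eta[1]); p[8] <- p[8] * exp(eta[2])
  p[1] <- p[1] * exp(eta[3]); p[2] <- p[2] * exp(eta[4])
  p[3] <- p[3] * exp(eta[5]); p[4] <- p[4] * exp(eta[6])
  p[17] <- p[17] * exp(eta[7])
  sim_turnover_final(subj$times, subj$cp_propo, subj$cp_remi, subj$stim, p)
}

#' Predictions from a population fit
#'
#' Population predictions (random effects at zero) and individual
#' predictions (at the empirical Bayes estimates) for every observation
#' record of the fitted dataset.
#'
#' @param object A `hemo_fit`.
#' @param ... Unused.
#' @return Data frame with `ID`, `TIME`, `DVID`, `DV`, `PRED`, `IPRED`.
#' @export
predict.hemo_fit <- function(object, ...) {
  m <- coef_to_model(as.list(object$coef), object$config)
  out <- lapply(seq_along(object$subj_data), function(i) {
    s <- object$subj_data[[i]]
    pred <- subj_predict(s, m$typ)
    ipred <- subj_predict(s, m$typ, object$eta[, i])
    data.frame(
      ID = s$id,
      TIME = c(s$times[s$i_map + 1L], s$times[s$i_hr + 1L]),
      DVID = rep(c(1L, 2L), c(length(s$i_map), length(s$i_hr))),
      DV = c(s$y_map, s$y_hr),
      PRED = c(pred[s$i_map + 1L, 1], pred[s$i_hr + 1L, 2]),
      IPRED = c(ipred[s$i_map + 1L, 1], ipred[s$i_hr + 1L, 2]))
  })
  do.call(rbind, out)
}

#' Residuals of a population fit
#'
#' @param object A `hemo_fit`.
#' @param type `"individual"` for individual weighted residuals
#'   (`(DV - IPRED)/sigma`), `"population"` for residual-SD-scaled
#'   population residuals (`(DV - PRED)/sigma`; no FOCE linearization).
#' @param ... Unused.
#' @return Numeric vector aligned with the rows of [predict.hemo_fit()].
#' @export
residuals.hemo_fit <- function(object, type = c("individual", "population"),
                               ...) {
  type <- match.arg(type)
  pr <- predict(object)
  sig <- ifelse(pr$DVID == 1L, object$coef[["sigma_MAP"]],
                object$coef[["sigma_HR"]])
  if (type == "individual") (pr$DV - pr$IPRED) / sig
  else (pr$DV - pr$PRED) / sig
}

#' Simulate datasets from a fit
#'
#' Draws new individuals (random effects from the estimated covariance)
#' and new residual errors for the original study design and dosing.
#'
#' @param object A `hemo_fit`.
#' @param nsim Number of simulated datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` data frames with `ID`, `TIME`, `DVID`, `DV`.
#' @export
simulate.hemo_fit <- function(object, nsim = 1, seed = NULL, ...) {
  m <- coef_to_model(as.list(object$coef), object$config)
  simulate_from_model(object$subj_data, m, nsim = nsim, seed = seed)
}

# shared simulation backend (also used by the VPC with bare pop_params)
simulate_from_model <- function(subj, m, nsim = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- eigen(m$Omega, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), 7)
  lapply(seq_len(nsim), function(k) {
    rows <- lapply(subj, function(s) {
      eta <- as.numeric(L %*% stats::rnorm(7))
      tr <- subj_predict(s, m$typ, eta)
      nm <- length(s$i_map); nh <- length(s$i_hr)
      data.frame(
        ID = s$id,
        TIME = c(s$times[s$i_map + 1L], s$times[s$i_hr + 1L]),
        DVID = rep(c(1L, 2L), c(nm, nh)),
        DV = c(tr[s$i_map + 1L, 1] + stats::rnorm(nm, 0, m$sigma_MAP),
               tr[s$i_hr + 1L, 2] + stats::rnorm(nh, 0, m$sigma_HR)))
    })
    do.call(rbind, rows)
  })
}

#' Diagnostic plots for a population fit
#'
#' Observations vs population and individual predictions, and individual
#' weighted residuals vs time.
#'
#' @param x A `hemo_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hemo_fit <- function(x, ...) {
  pr <- predict(x)
  iwres <- residuals(x, "individual")
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  cols <- ifelse(pr$DVID == 1L, "steelblue", "firebrick")
  graphics::plot(pr$PRED, pr$DV, col = cols, pch = 20, cex = 0.4,
                 xlab = "population prediction", ylab = "observation", ...)
  graphics::abline(0, 1)
  graphics::plot(pr$IPRED, pr$DV, col = cols, pch = 20, cex = 0.4,
                 xlab = "individual prediction", ylab = "observation", ...)
  graphics::abline(0, 1)
  graphics::plot(pr$TIME, iwres, col = cols, pch = 20, cex = 0.4,
                 xlab = "time (min)", ylab = "IWRES", ...)
  graphics::abline(h = 0)
  invisible(x)
}
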