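#' Build a fit object from known population parameters
#'
#' Constructs a `hemo_fit` without optimization, evaluating the Laplace
#' -2LL and (optionally) the empirical Bayes estimates at the supplied
#' population parameters.  Useful for goodness-of-fit and VPC checks
#' against generating ("true") values, and as a warm start.
#'
#' @param dataset A `hemo_dataset`.
#' @param pop A [population_parameters()] object.
#' @param config A [model_config()].
#' @param ebe Compute empirical Bayes estimates (otherwise all random
#'   effects are zero)?
#' @param thin Pharmacodynamic grid coarsening factor.
#' @param demographics Optional [patient_covariates()].
#' @return A `hemo_fit`.
#' @export
as_hemo_fit <- function(dataset, pop, config = final_model(), ebe = TRUE,
                        thin = 2L, demographics = NULL) {
  stopifnot(inherits(dataset, "hemo_dataset"), inherits(pop, "pop_params"))
  subj <- build_subject_data(dataset, demographics, thin = thin,
                             driver = if (config$effect_site_driver)
                               "effect_site" else "plasma")
  tp <- pop$typicals
  o2 <- pop$omega2
  rho <- if (o2[["C50_propo"]] > 0 && o2[["kout_MAP"]] > 0)
    pop$cov_c50p_kout / sqrt(o2[["C50_propo"]] * o2[["kout_MAP"]]) else 0
  cf <- c(MAP0 = tp$MAP0, HR0 = tp$HR0, kout = tp$kout_MAP,
          C50_propo = tp$C50_propo, Emax_propo = tp$Emax_propo,
          C50_remi = tp$C50_remi, Emax_remi = tp$Emax_remi,
          gamma_remi = tp$gamma_remi, FB_HR = tp$FB_HR,
          k_stim = tp$k_stim, theta_stim = tp$theta_stim,
          gamma_propo = tp$gamma_propo, C50_remi_MAP = tp$C50_remi_MAP,
          Emax_remi_MAP = tp$Emax_remi_MAP,
          gamma_remi_MAP = tp$gamma_remi_MAP,
          omega2_C50_propo = o2[["C50_propo"]],
          omega2_C50_remi = o2[["C50_remi"]],
          omega2_MAP0 = o2[["MAP0"]], omega2_HR0 = o2[["HR0"]],
          omega2_kout_MAP = o2[["kout_MAP"]],
          omega2_kout_HR = o2[["kout_HR"]],
          corr_c50p_kout = rho,
          sigma_MAP = pop$sigma_MAP, sigma_HR = pop$sigma_HR)
  m <- coef_to_model(as.list(cf), config)
  eta <- matrix(0, 7, length(subj),
                dimnames = list(eta_order,
                                vapply(subj, function(s) as.character(s$id), "")))
  nll2 <- NA_real_
  if (ebe && pop$sigma_MAP > 0 && pop$sigma_HR > 0) {
    res <- pop_nll2_cpp(m$typ, m$Omega, m$sigma_MAP, m$sigma_HR, subj, eta, 60L)
    eta[] <- res$eta
    nll2 <- res$nll2
  }
  omega2_hat <- c(o2[c("C50_propo", "C50_remi", "MAP0", "HR0", "kout_MAP",
                       "kout_HR")], k_stim = log(2))
  names(omega2_hat) <- eta_order
  structure(list(
    coef = cf, free = names(cf), fixed = list(), config = config,
    minus2LL = nll2, eta = eta,
    shrinkage = if (length(subj) >= 2) shrinkage(t(eta), omega2_hat) else NULL,
    se = NULL, rse = NULL,
    convergence = list(code = NA_integer_, message = "evaluated, not optimized",
                       iterations = 0L),
    n_subjects = length(subj), n_obs = sum(dataset$EVID == 0L),
    subj_data = subj, dataset = dataset,
    control = list(iter.max = 0, eval.max = 0, inner.maxit = 25, thin = thin),
    demographics = demographics %||% attr(dataset, "demographics") %||%
      typical_patient()),
    class = "hemo_fit")
}

#' Goodness-of-fit table
#'
#' Per-observation population and individual predictions with raw and
#' standardized residuals, for observations-vs-predictions and
#' residuals-vs-time displays.
#'
#' @param fit A `hemo_fit`.
#' @return Data frame with one row per observation: `ID`, `TIME`, `DVID`,
#'   `DV`, `PRED`, `IPRED`, `RES` (`DV - PRED`), `IRES` (`DV - IPRED`),
#'   `IWRES` (`IRES/sigma`), `PWRES` (`RES/sigma`).
#' @export
gof_tables <- function(fit) {
  stopifnot(inherits(fit, "hemo_fit"))
  pr <- predict(fit)
  sig <- ifelse(pr$DVID == 1L, fit$coef[["sigma_MAP"]],
                fit$coef[["sigma_HR"]])
  pr$RES <- pr$DV - pr$PRED
  pr$IRES <- pr$DV - pr$IPRED
  pr$IWRES <- pr$IRES / sig
  pr$PWRES <- pr$RES / sig
  pr
}
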