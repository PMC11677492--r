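# Nonlinear mixed-effects estimation for the turn-over model.
#
# Marginal likelihood: Laplace approximation around the per-subject
# penalized (MAP-Bayes) mode, with a Gauss-Newton Hessian -- a surrogate
# for first-order conditional estimation that is accurate here because the
# residual error is additive (no eta-epsilon interaction term).  The outer
# problem optimizes the fixed effects, random-effect (co)variances and
# residual SDs on transformed scales (log for positive parameters, logit
# for the Emax fractions, a scaled logit keeping the remifentanil Hill
# coefficient in [0.5, 5], atanh for the correlation).

eta_order <- c("C50_propo", "C50_remi", "MAP0", "HR0", "kout_MAP", "kout_HR",
               "k_stim")

# transform registry: natural -> optimizer scale and back
.tr <- list(
  log    = list(n2t = log, t2n = exp, dndt = function(n) n),
  logit  = list(n2t = function(p) log(p / (1 - p)),
                t2n = function(x) 1 / (1 + exp(-x)),
                dndt = function(n) n * (1 - n)),
  glogit = list(n2t = function(p) log((p - 0.5) / (5 - p)),
                t2n = function(x) 0.5 + 4.5 / (1 + exp(-x)),
                dndt = function(n) (n - 0.5) * (5 - n) / 4.5),
  atanh  = list(n2t = atanh, t2n = tanh, dndt = function(n) 1 - n^2)
)

fit_parameter_table <- function(config) {
  nm <- c("MAP0", "HR0", "kout", "C50_propo", "Emax_propo", "C50_remi",
          "Emax_remi", "gamma_remi", "FB_HR", "k_stim", "theta_stim")
  tr <- c("log", "log", "log", "log", "logit", "log", "logit", "glogit",
          "log", "log", "log")
  if (config$gamma_propo) { nm <- c(nm, "gamma_propo"); tr <- c(tr, "glogit") }
  if (config$remi_on_map) {
    nm <- c(nm, "C50_remi_MAP", "Emax_remi_MAP", "gamma_remi_MAP")
    tr <- c(tr, "log", "logit", "glogit")
  }
  nm <- c(nm, paste0("omega2_", c("C50_propo", "C50_remi", "MAP0", "HR0",
                                  "kout_MAP", "kout_HR")),
          "corr_c50p_kout", "sigma_MAP", "sigma_HR")
  tr <- c(tr, rep("log", 6), "atanh", "log", "log")
  data.frame(name = nm, trans = tr, stringsAsFactors = FALSE)
}

default_init <- function(dataset, config) {
  base_map <- base_hr <- NULL
  for (id in unique(dataset$ID)) {
    d <- dataset[dataset$ID == id, ]
    t_dose <- suppressWarnings(min(d$TIME[d$EVID == 1L & d$RATE > 0]))
    pre <- d$EVID == 0L & d$TIME < t_dose
    base_map <- c(base_map, d$DV[pre & d$DVID == 1L])
    base_hr <- c(base_hr, d$DV[pre & d$DVID == 2L])
  }
  init <- c(MAP0 = if (length(base_map)) mean(base_map) else 85,
            HR0 = if (length(base_hr)) mean(base_hr) else 75,
            kout = 0.1, C50_propo = 5, Emax_propo = 0.7,
            C50_remi = 5, Emax_remi = 0.5, gamma_remi = 1,
            FB_HR = 0.5, k_stim = 0.03, theta_stim = 0.2,
            gamma_propo = 1.5, C50_remi_MAP = 5, Emax_remi_MAP = 0.3,
            gamma_remi_MAP = 1,
            omega2_C50_propo = 0.5, omega2_C50_remi = 0.5,
            omega2_MAP0 = 0.02, omega2_HR0 = 0.02,
            omega2_kout_MAP = 0.5, omega2_kout_HR = 0.5,
            corr_c50p_kout = 0, sigma_MAP = 5, sigma_HR = 5)
  init
}

# Optimizer core shared by fit_hemodynamics() and the bootstrap: maximizes
# the Laplace marginal likelihood over the free parameters on transformed
# scales, warm-starting the per-subject modes across outer evaluations.
fit_core <- function(subj, config, cf0, fix, ctl, se = FALSE) {
  ptab <- fit_parameter_table(config)
  fix <- lapply(fix, as.numeric)
  free <- setdiff(ptab$name, names(fix))
  if (!length(free)) stop("invalid input: no free parameters")
  n_sub <- length(subj)

  trans_of <- stats::setNames(ptab$trans, ptab$name)
  n2t <- function(cf, nms) vapply(nms, function(nm)
    .tr[[trans_of[[nm]]]]$n2t(cf[[nm]]), numeric(1))
  t2n <- function(th) vapply(names(th), function(nm)
    .tr[[trans_of[[nm]]]]$t2n(th[[nm]]), numeric(1))
  full_cf <- function(th_nat) {
    cf <- as.list(cf0[ptab$name])
    cf[names(th_nat)] <- th_nat
    cf[names(fix)] <- unlist(fix)
    cf
  }

  env <- new.env(parent = emptyenv())
  env$eta <- matrix(0, 7, n_sub)
  env$n_eval <- 0L
  objective <- function(th) {
    names(th) <- free
    cf <- full_cf(t2n(th))
    m <- coef_to_model(cf, config)
    if (any(!is.finite(unlist(m))) || m$sigma_MAP <= 0 || m$sigma_HR <= 0)
      return(1e10)
    res <- pop_nll2_cpp(m$typ, m$Omega, m$sigma_MAP, m$sigma_HR, subj,
                        env$eta, ctl$inner.maxit)
    env$n_eval <- env$n_eval + 1L
    if (!is.finite(res$nll2)) return(1e10)
    env$eta <- res$eta
    res$nll2
  }

  # forward-difference gradient with a step large enough to dominate the
  # (tiny) noise left by the warm-started inner optimization
  grad <- function(th) {
    f0 <- objective(th)
    hstep <- 1e-3
    vapply(seq_along(th), function(j) {
      thj <- th; thj[j] <- thj[j] + hstep
      (objective(thj) - f0) / hstep
    }, numeric(1))
  }
  th0 <- n2t(as.list(cf0), free)
  opt <- stats::nlminb(th0, objective, gradient = grad,
                       control = list(iter.max = ctl$iter.max,
                                      eval.max = ctl$eval.max))
  th_hat <- stats::setNames(opt$par, free)
  cf_hat <- full_cf(t2n(th_hat))
  m_hat <- coef_to_model(cf_hat, config)
  # final inner pass at the optimum so the EBEs match the reported estimates
  final <- pop_nll2_cpp(m_hat$typ, m_hat$Omega, m_hat$sigma_MAP, m_hat$sigma_HR,
                        subj, env$eta, 60L)
  eta_hat <- final$eta
  rownames(eta_hat) <- eta_order
  colnames(eta_hat) <- vapply(subj, function(s) as.character(s$id), "")

  se_nat <- rse <- NULL
  if (se) {
    H <- stats::optimHess(opt$par, objective)
    V <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      se_t <- sqrt(pmax(diag(V), 0))
      deriv <- vapply(free, function(nm)
        .tr[[trans_of[[nm]]]]$dndt(cf_hat[[nm]]), numeric(1))
      se_nat <- stats::setNames(se_t * abs(deriv), free)
      rse <- 100 * se_nat / abs(unlist(cf_hat[free]))
    }
  }
  list(opt = opt, cf_hat = cf_hat, eta_hat = eta_hat, final = final,
       se_nat = se_nat, rse = rse, fix = fix, free = free)
}

# natural coefficient vector -> (typ 17-vector, Omega 7x7, sigmas)
coef_to_model <- function(cf, config) {
  typ <- c(cf[["MAP0"]], cf[["HR0"]], cf[["kout"]], cf[["kout"]],
           cf[["C50_propo"]], cf[["Emax_propo"]],
           if (config$gamma_propo) cf[["gamma_propo"]] else 1,
           cf[["C50_remi"]], cf[["Emax_remi"]], cf[["gamma_remi"]],
           if (config$remi_on_map) cf[["C50_remi_MAP"]] else 1,
           if (config$remi_on_map) cf[["Emax_remi_MAP"]] else 0,
           if (config$remi_on_map) cf[["gamma_remi_MAP"]] else 1,
           cf[["FB_HR"]], 0, cf[["theta_stim"]], cf[["k_stim"]])
  o2 <- c(cf[["omega2_C50_propo"]], cf[["omega2_C50_remi"]], cf[["omega2_MAP0"]],
          cf[["omega2_HR0"]], cf[["omega2_kout_MAP"]], cf[["omega2_kout_HR"]],
          log(2))
  O <- diag(o2, 7)
  dimnames(O) <- list(eta_order, eta_order)
  cv <- cf[["corr_c50p_kout"]] * sqrt(o2[1] * o2[5])
  O[1, 5] <- O[5, 1] <- cv
  list(typ = typ, Omega = O, sigma_MAP = cf[["sigma_MAP"]],
       sigma_HR = cf[["sigma_HR"]])
}

#' Fit the population turn-over model
#'
#' Estimates the fixed effects, random-effect variances (with the
#' C50-kout covariance) and residual SDs of the hemodynamic turn-over
#' model from a long-format dataset by maximizing the Laplace-approximate
#' marginal likelihood.  The random-effect variance of the
#' stimulus-dissipation rate is fixed at the value equivalent to a 100%
#' CV.  Empirical Bayes estimates of the per-subject random effects are
#' returned along with shrinkage.
#'
#' @param dataset A `hemo_dataset` (from [generate_dataset()] or
#'   [read_dataset()]).
#' @param config A [model_config()]; MAP-on-HR feedback (`fb_map`) cannot
#'   be estimated (the final model excludes it).
#' @param init Optional named vector of natural-scale initial values
#'   overriding the data-derived defaults.
#' @param fix Named list of parameters to fix (excluded from
#'   optimization), e.g. `list(Emax_remi = 0, C50_remi = 4.57,
#'   gamma_remi = 1, omega2_C50_remi = 1e-4)` for a no-remifentanil
#'   reduction.
#' @param se Compute standard errors (finite-difference Hessian of the
#'   marginal -2LL; adds noticeable runtime)?
#' @param control List: `iter.max`, `eval.max` passed to
#'   [stats::nlminb()]; `inner.maxit` Gauss-Newton iterations per subject;
#'   `thin` pharmacodynamic grid coarsening (2 = 20-s steps).
#' @param demographics [patient_covariates()] used to reconstruct the
#'   concentration profiles from the dosing records.
#' @return An object of class `hemo_fit`; see [summary.hemo_fit()],
#'   [coef.hemo_fit()], [predict.hemo_fit()], [residuals.hemo_fit()],
#'   [simulate.hemo_fit()].
#' @seealso [fit_individual()], [likelihood_ratio_test()], [shrinkage()]
#' @export
fit_hemodynamics <- function(dataset, config = final_model(), init = NULL,
                             fix = list(), se = FALSE, control = list(),
                             demographics = NULL) {
  stopifnot(inherits(dataset, "hemo_dataset"))
  if (config$fb_map)
    stop("configuration error: estimating MAP-on-HR feedback is not supported")
  ctl <- utils::modifyList(list(iter.max = 150, eval.max = 600,
                                inner.maxit = 25, thin = 2L), control)
  n_sub <- length(unique(dataset$ID))
  if (n_sub < 2L) stop("invalid input: need at least 2 subjects")

  subj <- build_subject_data(dataset, demographics, thin = ctl$thin,
                             driver = if (config$effect_site_driver)
                               "effect_site" else "plasma")
  cf0 <- default_init(dataset, config)
  if (!is.null(init)) cf0[names(init)] <- unlist(init)
  core <- fit_core(subj, config, cf0, fix, ctl, se = se)
  opt <- core$opt; cf_hat <- core$cf_hat
  eta_hat <- core$eta_hat; se_nat <- core$se_nat; rse <- core$rse
  final <- core$final
  fix <- core$fix; free <- core$free

  omega2_hat <- c(stats::setNames(
    unlist(cf_hat[paste0("omega2_", eta_order[1:6])]), eta_order[1:6]),
    k_stim = log(2))
  shr <- shrinkage(t(eta_hat), omega2_hat)

  fit <- structure(list(
    coef = unlist(cf_hat), free = free, fixed = fix, config = config,
    minus2LL = final$nll2, eta = eta_hat, shrinkage = shr,
    se = se_nat, rse = rse,
    convergence = list(code = opt$convergence, message = opt$message,
                       iterations = opt$iterations),
    n_subjects = n_sub,
    n_obs = sum(dataset$EVID == 0L),
    subj_data = subj, dataset = dataset,
    control = ctl,
    demographics = demographics %||% attr(dataset, "demographics") %||%
      typical_patient()),
    class = "hemo_fit")
  fit
}

#' @rdname fit_hemodynamics
#' @param ... Passed on to [fit_hemodynamics()].
#' @export
fit_population <- function(dataset, ...) fit_hemodynamics(dataset, ...)

#' Empirical Bayes fit of one subject
#'
#' Minimizes the penalized least-squares objective
#' `sum(residual^2/sigma^2) + eta' Omega^-1 eta` for a single subject's
#' random effects given population parameters (a MAP-Bayes fit).  With a
#' very diffuse prior (`flat = TRUE`) the penalty vanishes and the result
#' is the unpenalized nonlinear least-squares estimate.
#'
#' @param subject_records A `hemo_dataset` containing a single subject
#'   (at least one pre-dose and five post-dose observations).
#' @param pop_prior A [population_parameters()] object supplying typicals,
#'   random-effect covariance and residual SDs.
#' @param init Optional starting values for the 7 random effects.
#' @param flat Use an essentially flat prior (unpenalized fit)?
#' @param config A [model_config()].
#' @param thin Pharmacodynamic grid coarsening factor.
#' @return List with `eta` (named random effects), `params` (realized
#'   [hemo_params()]), `objective`, and `converged`.
#' @export
fit_individual <- function(subject_records, pop_prior, init = NULL,
                           flat = FALSE, config = final_model(), thin = 2L) {
  stopifnot(inherits(pop_prior, "pop_params"))
  ids <- unique(subject_records$ID)
  if (length(ids) != 1L) stop("invalid input: expected exactly one subject")
  d <- subject_records
  t_dose <- suppressWarnings(min(d$TIME[d$EVID == 1L & d$RATE > 0]))
  n_pre <- sum(d$EVID == 0L & d$TIME < t_dose)
  n_post <- sum(d$EVID == 0L & d$TIME >= t_dose)
  if (n_pre < 1L || n_post < 5L)
    stop("invalid input: need >= 1 baseline and >= 5 post-dose observations")
  subj <- build_subject_data(d, thin = thin,
                             driver = if (config$effect_site_driver)
                               "effect_site" else "plasma")[[1]]
  tp <- pop_prior$typicals
  typ <- params_vector(tp, config)
  O <- pop_omega_matrix(pop_prior)
  Oi <- if (flat) diag(1e-8, 7) else solve(O + diag(1e-10, 7))
  eta0 <- if (is.null(init)) rep(0, 7) else as.numeric(init)
  res <- gn_fit_eta_cpp(subj, typ, Oi, pop_prior$sigma_MAP, pop_prior$sigma_HR,
                        eta0, maxit = 60L)
  eta <- stats::setNames(as.numeric(res$eta), eta_order)
  params <- hemo_params(
    MAP0 = tp$MAP0 * exp(eta[["MAP0"]]), HR0 = tp$HR0 * exp(eta[["HR0"]]),
    kout_MAP = tp$kout_MAP * exp(eta[["kout_MAP"]]),
    kout_HR = tp$kout_HR * exp(eta[["kout_HR"]]),
    C50_propo = tp$C50_propo * exp(eta[["C50_propo"]]),
    Emax_propo = tp$Emax_propo, gamma_propo = tp$gamma_propo,
    C50_remi = tp$C50_remi * exp(eta[["C50_remi"]]),
    Emax_remi = tp$Emax_remi, gamma_remi = tp$gamma_remi,
    C50_remi_MAP = tp$C50_remi_MAP, Emax_remi_MAP = tp$Emax_remi_MAP,
    gamma_remi_MAP = tp$gamma_remi_MAP,
    FB_HR = tp$FB_HR, FB_MAP = tp$FB_MAP, theta_stim = tp$theta_stim,
    k_stim = tp$k_stim * exp(eta[["k_stim"]]))
  list(eta = eta, params = params, objective = res$objective,
       converged = is.finite(res$objective))
}

#' Random-effect shrinkage
#'
#' `100 * (1 - SD(eta_hat) / sqrt(omega2))` per parameter; high shrinkage
#' means the individual estimates are pulled to the population typical
#' value and carry little subject-level information.  May be negative.
#'
#' @param etas Matrix of empirical Bayes estimates, one row per subject,
#'   columns named by parameter.
#' @param omega2 Named vector of random-effect variances.
#' @return Named vector of shrinkage percentages (`NA` where
#'   `omega2 = 0`, with a warning).
#' @export
shrinkage <- function(etas, omega2) {
  etas <- as.matrix(etas)
  if (nrow(etas) < 2L) stop("invalid input: need >= 2 subjects")
  nms <- colnames(etas) %||% names(omega2)
  omega2 <- omega2[nms]
  out <- 100 * (1 - apply(etas, 2, stats::sd) / sqrt(omega2))
  if (any(omega2 == 0, na.rm = TRUE)) {
    warning("shrinkage undefined for zero-variance random effects")
    out[omega2 == 0] <- NA_real_
  }
  stats::setNames(out, nms)
}

#' Likelihood ratio test between nested fits
#'
#' Compares two fits of nested models by the chi-square approximation to
#' the drop in -2 log-likelihood; a drop of 3.84 (one parameter)
#' corresponds to p = 0.05 and 6.61 to p = 0.01.
#'
#' @param fit_full,fit_reduced `hemo_fit` objects (or bare -2LL values,
#'   in which case the caller asserts nesting); every free parameter of
#'   the reduced model must be free in the full model.
#' @param df Degrees of freedom (number of constrained parameters),
#'   `>= 1`.
#' @return List with `delta` (the -2LL difference, floored at 0), `df`,
#'   and `p.value`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced, df = NULL) {
  if (inherits(fit_full, "hemo_fit") && inherits(fit_reduced, "hemo_fit")) {
    if (!all(fit_reduced$free %in% fit_full$free))
      stop("models are not nested: reduced model frees parameters the full model fixes")
    if (is.null(df)) df <- length(fit_full$free) - length(fit_reduced$free)
    m2_full <- fit_full$minus2LL
    m2_red <- fit_reduced$minus2LL
  } else if (is.numeric(fit_full) && is.numeric(fit_reduced)) {
    m2_full <- fit_full
    m2_red <- fit_reduced
    if (is.null(df)) stop("invalid input: df required with bare -2LL values")
  } else stop("invalid input: supply two hemo_fit objects or two -2LL values")
  if (df < 1L) stop("models are not nested: df must be >= 1")
  delta <- max(0, m2_red - m2_full)
  list(delta = delta, df = df,
       p.value = 1 - stats::pchisq(delta, df))
}
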