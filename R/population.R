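#' Convert between coefficient of variation and log-normal variance
#'
#' Inter-individual variability of log-normally distributed parameters is
#' reported as CV(%) = sqrt(exp(omega^2) - 1) * 100; these helpers invert
#' that relation exactly.
#'
#' @param cv_percent CV in percent (`>= 0`).
#' @param omega2 Variance of the log-scale random effect (`>= 0`).
#' @return `cv_to_omega2` returns the variance; `omega2_to_cv` the CV(%).
#' @examples
#' cv_to_omega2(104)          # ~0.7335
#' omega2_to_cv(cv_to_omega2(104))
#' @export
cv_to_omega2 <- function(cv_percent) {
  if (any(!is.finite(cv_percent)) || any(cv_percent < 0))
    stop("invalid input: CV must be non-negative")
  log(1 + (cv_percent / 100)^2)
}

#' @rdname cv_to_omega2
#' @export
omega2_to_cv <- function(omega2) {
  if (any(!is.finite(omega2)) || any(omega2 < 0))
    stop("invalid input: omega2 must be non-negative")
  sqrt(exp(omega2) - 1) * 100
}

#' Population parameters
#'
#' Typical hemodynamic parameters plus the random-effect covariance
#' structure and residual error.  Random effects are log-normal
#' (multiplicative) for all dispersed parameters except the Emax
#' parameters, which use a logistic transform to stay in (0, 1); the
#' variance of the stimulus-dissipation random effect is fixed at the
#' value equivalent to a 100% CV.  A single covariance couples the
#' propofol C50 and MAP kout random effects.
#'
#' Defaults are the final-model population estimates.
#'
#' @param typicals A [hemo_params()] object of typical values.
#' @param cv Named list of inter-individual CVs (%) for `C50_propo`,
#'   `C50_remi`, `MAP0`, `HR0`, `kout_MAP`, `kout_HR`, `k_stim`.
#' @param cv_emax Named list of CVs (%) controlling the spread of the
#'   logit-scale random effects for `Emax_propo`, `Emax_remi` (default 0:
#'   no Emax variability was estimated).
#' @param cov_c50p_kout Covariance between the `C50_propo` and `kout_MAP`
#'   random effects (log scale).
#' @param sigma_MAP,sigma_HR Additive residual SDs (mmHg, bpm).
#' @return An object of class `pop_params`.
#' @examples
#' pop <- default_population()
#' sample_individual(pop, seed = 1)
#' @export
population_parameters <- function(typicals = hemo_params(),
                                  cv = list(C50_propo = 104.0, C50_remi = 103.7,
                                            MAP0 = 8.63, HR0 = 14.4,
                                            kout_MAP = 142.6, kout_HR = 130.2,
                                            k_stim = 100),
                                  cv_emax = list(Emax_propo = 0, Emax_remi = 0),
                                  cov_c50p_kout = 0.76,
                                  sigma_MAP = 5.53, sigma_HR = 4.30) {
  stopifnot(inherits(typicals, "hemo_params"))
  need <- c("C50_propo", "C50_remi", "MAP0", "HR0", "kout_MAP", "kout_HR",
            "k_stim")
  stopifnot(all(need %in% names(cv)))
  if (sigma_MAP < 0 || sigma_HR < 0)
    stop("invalid input: residual SDs must be non-negative")
  omega2 <- vapply(cv[need], cv_to_omega2, numeric(1))
  if (omega2[["C50_propo"]] > 0 && omega2[["kout_MAP"]] > 0) {
    rho <- cov_c50p_kout / sqrt(omega2[["C50_propo"]] * omega2[["kout_MAP"]])
    if (abs(rho) > 1)
      stop("configuration error: implied correlation outside [-1, 1]")
  } else if (cov_c50p_kout != 0) {
    stop("configuration error: covariance with a zero-variance random effect")
  }
  structure(list(typicals = typicals, omega2 = omega2,
                 omega2_emax = vapply(cv_emax, cv_to_omega2, numeric(1)),
                 cov_c50p_kout = cov_c50p_kout,
                 sigma_MAP = sigma_MAP, sigma_HR = sigma_HR),
            class = "pop_params")
}

#' @rdname population_parameters
#' @export
default_population <- function() population_parameters()

#' @export
print.pop_params <- function(x, ...) {
  cat("<pop_params>\n  typicals:\n")
  print(x$typicals)
  cat("  IIV CV(%):",
      paste(sprintf("%s %.1f", names(x$omega2), omega2_to_cv(x$omega2)),
            collapse = ", "), "\n")
  cat(sprintf("  cov(eta_C50_propo, eta_kout_MAP) %.2f\n", x$cov_c50p_kout))
  cat(sprintf("  residual SD: MAP %.2f mmHg, HR %.2f bpm\n",
              x$sigma_MAP, x$sigma_HR))
  invisible(x)
}

# 7x7 random-effect covariance matrix in the canonical eta order
# (C50_propo, C50_remi, MAP0, HR0, kout_MAP, kout_HR, k_stim)
pop_omega_matrix <- function(pop) {
  ord <- c("C50_propo", "C50_remi", "MAP0", "HR0", "kout_MAP", "kout_HR",
           "k_stim")
  O <- diag(pop$omega2[ord], 7)
  dimnames(O) <- list(ord, ord)
  O["C50_propo", "kout_MAP"] <- O["kout_MAP", "C50_propo"] <- pop$cov_c50p_kout
  ev <- eigen(O, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12)
    stop("configuration error: random-effect covariance matrix is not positive semi-definite")
  O
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Sample an individual from the population
#'
#' Draws the random effects (jointly normal on the log scale, with the
#' C50-kout covariance) and returns the realized individual parameters.
#' Log-normal parameters are `typical * exp(eta)`; Emax parameters are
#' `inv_logit(logit(typical) + eta)`.
#'
#' @param pop A [population_parameters()] object.
#' @param seed Integer seed; each subject of a study should use its own
#'   seed (see [generate_dataset()]).
#' @param id Subject identifier stored in the result.
#' @return An object of class `individual`: list with `id`, the
#'   random-effect vector `eta`, and `params` (a [hemo_params()]).
#' @export
sample_individual <- function(pop, seed = NULL, id = 1L) {
  stopifnot(inherits(pop, "pop_params"))
  if (!is.null(seed)) set.seed(seed)
  O <- pop_omega_matrix(pop)
  z <- stats::rnorm(7)
  # chol of a PSD matrix with possible zero variances: use eigen factor
  e <- eigen(O, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), 7)
  eta <- as.numeric(L %*% z)
  names(eta) <- colnames(O)
  eta_emax <- c(Emax_propo = 0, Emax_remi = 0)
  for (nm in names(eta_emax)) {
    o2 <- pop$omega2_emax[[nm]]
    if (!is.null(o2) && o2 > 0) eta_emax[nm] <- stats::rnorm(1, 0, sqrt(o2))
  }
  tp <- pop$typicals
  params <- hemo_params(
    MAP0 = tp$MAP0 * exp(eta[["MAP0"]]),
    HR0 = tp$HR0 * exp(eta[["HR0"]]),
    kout_MAP = tp$kout_MAP * exp(eta[["kout_MAP"]]),
    kout_HR = tp$kout_HR * exp(eta[["kout_HR"]]),
    C50_propo = tp$C50_propo * exp(eta[["C50_propo"]]),
    Emax_propo = inv_logit(logit(tp$Emax_propo) + eta_emax[["Emax_propo"]]),
    gamma_propo = tp$gamma_propo,
    C50_remi = tp$C50_remi * exp(eta[["C50_remi"]]),
    Emax_remi = inv_logit(logit(tp$Emax_remi) + eta_emax[["Emax_remi"]]),
    gamma_remi = tp$gamma_remi,
    C50_remi_MAP = tp$C50_remi_MAP, Emax_remi_MAP = tp$Emax_remi_MAP,
    gamma_remi_MAP = tp$gamma_remi_MAP,
    FB_HR = tp$FB_HR, FB_MAP = tp$FB_MAP,
    theta_stim = tp$theta_stim,
    k_stim = tp$k_stim * exp(eta[["k_stim"]]))
  structure(list(id = id, eta = c(eta, eta_emax), params = params),
            class = "individual")
}

#' @export
print.individual <- function(x, ...) {
  cat(sprintf("<individual> id %s\n", x$id))
  print(round(x$eta, 4))
  invisible(x)
}

#' Add additive residual error to a trajectory
#'
#' Observations are the noise-free predictions plus independent
#' homoscedastic Gaussian error on the natural scale (`sigma_MAP` mmHg,
#' `sigma_HR` bpm).
#'
#' @param trajectory A `hemo_trajectory` (columns `time`, `map`, `hr`)
#'   sampled at the observation times.
#' @param pop A [population_parameters()] object.
#' @param seed Integer seed for reproducibility.
#' @return A data frame like `trajectory` with noisy `map`, `hr`.
#' @export
add_residual_error <- function(trajectory, pop, seed = NULL) {
  stopifnot(inherits(pop, "pop_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trajectory)
  out <- trajectory
  out$map <- trajectory$map + stats::rnorm(n, 0, pop$sigma_MAP)
  out$hr <- trajectory$hr + stats::rnorm(n, 0, pop$sigma_HR)
  out
}
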