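#' Hemodynamic turn-over model parameters
#'
#' Parameters of the indirect-response (turn-over) model of mean arterial
#' pressure (MAP) and heart rate (HR).  MAP and HR are each maintained by a
#' zero-order input (`kin = kout * baseline`) and first-order loss
#' (`kout`); propofol inhibits the MAP input, remifentanil the HR input
#' (and, in the base model only, the MAP input directly); HR feeds back on
#' the MAP input as `(HR/HR0)^FB_HR`; a noxious stimulus transiently
#' multiplies the MAP input by `1 + theta_stim * exp(-k_stim (t - t_stim))`.
#'
#' Defaults are the final-model population estimates.
#'
#' @param MAP0 Baseline MAP (mmHg).
#' @param HR0 Baseline HR (bpm).
#' @param kout_MAP,kout_HR First-order loss rate constants (1/min); the
#'   typical value 0.123 is shared between the two responses.
#' @param C50_propo Propofol plasma concentration at half-maximal MAP
#'   inhibition (ug/mL).
#' @param Emax_propo Maximum fractional inhibition of the MAP input by
#'   propofol, in (0, 1).
#' @param gamma_propo Hill coefficient of the propofol effect (final model:
#'   fixed at 1).
#' @param C50_remi Remifentanil concentration at half-maximal HR inhibition
#'   (ng/mL).
#' @param Emax_remi Maximum fractional inhibition of the HR input by
#'   remifentanil, in (0, 1).
#' @param gamma_remi Hill coefficient of the remifentanil-on-HR effect.
#' @param C50_remi_MAP,Emax_remi_MAP,gamma_remi_MAP Direct
#'   remifentanil-on-MAP effect, present only in the base model
#'   (`Emax_remi_MAP = 0` removes it).
#' @param FB_HR Exponent of the HR-on-MAP feedback.
#' @param FB_MAP Exponent of the MAP-on-HR feedback (final model: 0).
#' @param theta_stim Fractional increase in the MAP input at stimulus onset.
#' @param k_stim First-order dissipation rate of the stimulus effect
#'   (1/min); `log(2)/k_stim` is the dissipation half-life.
#' @return An object of class `hemo_params`.
#' @examples
#' p <- hemo_params()
#' derive_kin(p)
#' @export
hemo_params <- function(MAP0 = 88.2, HR0 = 70.8,
                        kout_MAP = 0.123, kout_HR = 0.123,
                        C50_propo = 8.79, Emax_propo = 0.88, gamma_propo = 1,
                        C50_remi = 4.57, Emax_remi = 0.69, gamma_remi = 1.20,
                        C50_remi_MAP = 1, Emax_remi_MAP = 0, gamma_remi_MAP = 1,
                        FB_HR = 0.806, FB_MAP = 0,
                        theta_stim = 0.284, k_stim = 0.021) {
  p <- list(MAP0 = MAP0, HR0 = HR0, kout_MAP = kout_MAP, kout_HR = kout_HR,
            C50_propo = C50_propo, Emax_propo = Emax_propo,
            gamma_propo = gamma_propo,
            C50_remi = C50_remi, Emax_remi = Emax_remi,
            gamma_remi = gamma_remi,
            C50_remi_MAP = C50_remi_MAP, Emax_remi_MAP = Emax_remi_MAP,
            gamma_remi_MAP = gamma_remi_MAP,
            FB_HR = FB_HR, FB_MAP = FB_MAP,
            theta_stim = theta_stim, k_stim = k_stim)
  pos <- c("MAP0", "HR0", "kout_MAP", "kout_HR", "C50_propo", "C50_remi",
           "C50_remi_MAP", "k_stim")
  for (nm in pos) if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
    stop("invalid input: '", nm, "' must be positive")
  for (nm in c("Emax_propo", "Emax_remi"))
    if (p[[nm]] <= 0 || p[[nm]] >= 1)
      stop("invalid input: '", nm, "' must lie in (0, 1)")
  if (p$Emax_remi_MAP < 0 || p$Emax_remi_MAP >= 1)
    stop("invalid input: 'Emax_remi_MAP' must lie in [0, 1)")
  class(p) <- "hemo_params"
  p
}

#' @export
print.hemo_params <- function(x, ...) {
  cat("<hemo_params>\n")
  cat(sprintf("  MAP0 %.1f mmHg  HR0 %.1f bpm  kout %.3f/%.3f /min\n",
              x$MAP0, x$HR0, x$kout_MAP, x$kout_HR))
  cat(sprintf("  propofol: C50 %.2f ug/mL Emax %.2f gamma %.2f\n",
              x$C50_propo, x$Emax_propo, x$gamma_propo))
  cat(sprintf("  remifentanil (HR): C50 %.2f ng/mL Emax %.2f gamma %.2f\n",
              x$C50_remi, x$Emax_remi, x$gamma_remi))
  cat(sprintf("  FB_HR %.3f  FB_MAP %.3f  theta_stim %.3f  k_stim %.3f /min\n",
              x$FB_HR, x$FB_MAP, x$theta_stim, x$k_stim))
  invisible(x)
}

#' Model configuration
#'
#' Structural switches distinguishing the full base model from the reduced
#' final model.  The final-model preset (`final_model()`) disables the
#' direct remifentanil-on-MAP effect, the MAP-on-HR feedback, estimation of
#' the propofol Hill coefficient (fixed at 1) and the effect-site
#' pharmacodynamic driver (predicted plasma concentration drives the
#' effects).
#'
#' @param remi_on_map Include a direct remifentanil effect on MAP?
#' @param fb_map Include MAP-on-HR feedback?
#' @param gamma_propo Estimate/use a propofol Hill coefficient other than 1?
#' @param effect_site_driver Drive the pharmacodynamics with effect-site
#'   rather than plasma concentrations?
#' @return An object of class `hemo_config`.
#' @export
model_config <- function(remi_on_map = FALSE, fb_map = FALSE,
                         gamma_propo = FALSE, effect_site_driver = FALSE) {
  structure(list(remi_on_map = remi_on_map, fb_map = fb_map,
                 gamma_propo = gamma_propo,
                 effect_site_driver = effect_site_driver),
            class = "hemo_config")
}

#' @rdname model_config
#' @export
final_model <- function() model_config()

#' @export
print.hemo_config <- function(x, ...) {
  cat("<hemo_config>",
      if (!any(unlist(x))) "(final model)" else "", "\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, x[[nm]]))
  invisible(x)
}

# parameter vector in the layout shared with the C++ simulators
params_vector <- function(p, config = final_model()) {
  c(p$MAP0, p$HR0, p$kout_MAP, p$kout_HR,
    p$C50_propo, p$Emax_propo,
    if (config$gamma_propo) p$gamma_propo else 1,
    p$C50_remi, p$Emax_remi, p$gamma_remi,
    p$C50_remi_MAP,
    if (config$remi_on_map) p$Emax_remi_MAP else 0,
    p$gamma_remi_MAP,
    p$FB_HR,
    if (config$fb_map) p$FB_MAP else 0,
    p$theta_stim, p$k_stim)
}

#' Fractional drug effects
#'
#' Sigmoid maximum-effect (Hill) inhibition functions: propofol on the MAP
#' input and remifentanil on the HR (or, base model only, MAP) input.
#'
#' @param C Concentration (`>= 0`); ug/mL for propofol, ng/mL for
#'   remifentanil.
#' @param p A [hemo_params()] object.
#' @param response For remifentanil, which input is inhibited: `"HR"`
#'   (final model) or `"MAP"` (base model only).
#' @param config A [model_config()]; the `"MAP"` response requires
#'   `remi_on_map = TRUE`.
#' @return Fractional inhibition in `[0, Emax)`.
#' @examples
#' effect_propofol(8.79, hemo_params())   # half-maximum: 0.44
#' @export
effect_propofol <- function(C, p, config = final_model()) {
  if (any(C < 0)) stop("invalid input: negative concentration")
  g <- if (config$gamma_propo) p$gamma_propo else 1
  cg <- C^g
  ifelse(C == 0, 0, p$Emax_propo * cg / (cg + p$C50_propo^g))
}

#' @rdname effect_propofol
#' @export
effect_remifentanil <- function(C, p, response = c("HR", "MAP"),
                                config = final_model()) {
  response <- match.arg(response)
  if (any(C < 0)) stop("invalid input: negative concentration")
  if (response == "MAP") {
    if (!config$remi_on_map)
      stop("configuration error: remifentanil-on-MAP effect is disabled in this configuration")
    emax <- p$Emax_remi_MAP; c50 <- p$C50_remi_MAP; g <- p$gamma_remi_MAP
  } else {
    emax <- p$Emax_remi; c50 <- p$C50_remi; g <- p$gamma_remi
  }
  cg <- C^g
  ifelse(C == 0, 0, emax * cg / (cg + c50^g))
}

#' Noxious-stimulus factor
#'
#' Multiplicative factor on the MAP input rate: 1 before the stimulus
#' onset, `1 + theta_stim` at onset, decaying back to 1 with first-order
#' rate `k_stim`.  Multiple events compose multiplicatively.
#'
#' @param t Time (min), vectorized.
#' @param events A list of [stimulus_event()]s (or a single one).
#' @param p A [hemo_params()] object.
#' @param config A [model_config()]; under the final model only
#'   hysteroscopy events contribute.
#' @return Unitless factor `>= 1`.
#' @examples
#' ev <- stimulus_event("hysteroscopy", 20)
#' stimulus_factor(c(10, 20, 53), ev, hemo_params())
#' @export
stimulus_factor <- function(t, events, p, config = final_model()) {
  if (inherits(events, "stimulus_event")) events <- list(events)
  h <- rep(1, length(t))
  for (ev in events) {
    if (!active_stimulus(ev, config)) next
    on <- t >= ev$t_stim
    h[on] <- h[on] * (1 + p$theta_stim * exp(-p$k_stim * (t[on] - ev$t_stim)))
  }
  h
}

#' Stimulus event
#'
#' A timed noxious stimulus.  In the final model only hysteroscopy (the
#' surgical stimulus) has an identified hemodynamic effect; esophageal
#' instrumentation, laryngeal-mask insertion and tetanic stimulation are
#' carried as inert annotations.
#'
#' @param kind One of `"hysteroscopy"`, `"esophageal"`, `"LMA"`,
#'   `"tetanic"`.
#' @param t_stim Onset time (min, `>= 0`).
#' @return An object of class `stimulus_event`.
#' @export
stimulus_event <- function(kind = c("hysteroscopy", "esophageal", "LMA", "tetanic"),
                           t_stim) {
  kind <- match.arg(kind)
  if (!is.finite(t_stim) || t_stim < 0)
    stop("invalid input: 't_stim' must be non-negative")
  structure(list(kind = kind, t_stim = t_stim), class = "stimulus_event")
}

active_stimulus <- function(ev, config) {
  # only the surgical stimulus had an identifiable effect; the base/full
  # configuration carries the same restriction (the others were dropped
  # during model development)
  ev$kind == "hysteroscopy"
}

#' Feedback functions
#'
#' `feedback_hr_on_map` is `(HR/HR0)^FB_HR`, the HR feedback on the MAP
#' input; `feedback_map_on_hr` is `(MAP/MAP0)^(-FB_MAP)`, the MAP feedback
#' on the HR input (identically 1 in the final model, where `FB_MAP = 0`).
#'
#' @param HR,MAP Current response values (positive).
#' @param p A [hemo_params()] object.
#' @return Unitless multiplicative factor; equal to 1 at baseline.
#' @examples
#' feedback_hr_on_map(35.4, hemo_params())  # 0.5^0.806
#' @export
feedback_hr_on_map <- function(HR, p) {
  if (any(HR <= 0)) stop("invalid state: HR must be positive")
  (HR / p$HR0)^p$FB_HR
}

#' @rdname feedback_hr_on_map
#' @export
feedback_map_on_hr <- function(MAP, p) {
  if (any(MAP <= 0)) stop("invalid state: MAP must be positive")
  if (p$FB_MAP == 0) rep(1, length(MAP)) else (MAP / p$MAP0)^(-p$FB_MAP)
}

#' Derived zero-order input rates
#'
#' The steady-state constraint fixes `kin_MAP = kout_MAP * MAP0` and
#' `kin_HR = kout_HR * HR0`.
#'
#' @param p A [hemo_params()] object.
#' @return Named numeric vector `c(kin_MAP, kin_HR)` (mmHg/min, bpm/min).
#' @export
derive_kin <- function(p) {
  c(kin_MAP = p$kout_MAP * p$MAP0, kin_HR = p$kout_HR * p$HR0)
}

#' Simulate MAP and HR trajectories
#'
#' Integrates the turn-over system driven by propofol and remifentanil
#' concentration profiles and noxious-stimulus events, starting at the
#' baseline steady state.
#'
#' @param p A [hemo_params()] object.
#' @param propofol,remifentanil `conc_profile` objects from
#'   [simulate_concentrations()] covering `times`, or `NULL` for no drug.
#' @param events List of [stimulus_event()]s.
#' @param config A [model_config()].
#' @param times Uniform time grid (min); defaults to the profile grid.
#' @param nsub RK4 substeps per grid interval.
#' @param method `"rk4"` (reference integrator, any configuration) or
#'   `"exact"` (exponential-integrator cascade with node-interpolated
#'   sources, the discretization used inside the estimation core; only
#'   valid without MAP-on-HR feedback).
#' @return Data frame (class `hemo_trajectory`) with columns `time`,
#'   `map`, `hr`.
#' @examples
#' p <- hemo_params()
#' tr <- simulate_hemodynamics(p, times = seq(0, 60, by = 1/6),
#'                             events = list(stimulus_event("hysteroscopy", 10)))
#' @export
simulate_hemodynamics <- function(p, propofol = NULL, remifentanil = NULL,
                                  events = list(), config = final_model(),
                                  times = NULL, nsub = 4,
                                  method = c("rk4", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(p, "hemo_params"), inherits(config, "hemo_config"))
  if (inherits(events, "stimulus_event")) events <- list(events)
  if (is.null(times)) {
    times <- if (!is.null(propofol)) propofol$time
             else if (!is.null(remifentanil)) remifentanil$time
             else stop("invalid input: provide 'times' or a concentration profile")
  }
  col <- if (config$effect_site_driver) "ce" else "cp"
  grab <- function(prof) {
    if (is.null(prof)) return(numeric(length(times)))
    if (nrow(prof) != length(times) ||
        max(abs(prof$time - times)) > 1e-8)
      stop("invalid input: concentration profile grid does not match 'times'")
    prof[[col]]
  }
  cpp <- grab(propofol)
  cpr <- grab(remifentanil)
  onsets <- vapply(Filter(function(e) active_stimulus(e, config), events),
                   function(e) e$t_stim, numeric(1))
  pv <- params_vector(p, config)
  if (method == "exact") {
    if (pv[15] != 0)
      stop("configuration error: the exact cascade requires FB_MAP = 0")
    tr <- sim_turnover_final(times, cpp, cpr, onsets, pv)
  } else {
    tr <- sim_turnover_rk4(times, cpp, cpr, onsets, pv, nsub)
  }
  structure(data.frame(time = times, map = tr[, 1], hr = tr[, 2]),
            class = c("hemo_trajectory", "data.frame"))
}

#' Write a trajectory as CSV
#'
#' @param trajectory A `hemo_trajectory` from [simulate_hemodynamics()].
#' @param path File path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- data.frame(time_min = trajectory$time, map_mmHg = trajectory$map,
                   hr_bpm = trajectory$hr)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
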