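# Simulated general-anesthesia scenario and hypotension-risk curves.
#
# A 90-min procedure: LMA insertion at 5 min (no hemodynamic effect in
# the final model), surgical stimulation (hysteroscopy) from 20 to 70
# min, effect-site TCI targets switched from induction to maintenance
# levels at 10 min and zeroed at 80 min.  Three administration schemes
# pair decreasing propofol with increasing remifentanil targets at
# equivalent anti-nociceptive potential.

risk_schemes <- list(
  i   = list(propofol = c(induction = 4.0, maintenance = 2.5),
             remifentanil = c(induction = 3.0, maintenance = 2.0)),
  ii  = list(propofol = c(induction = 4.5, maintenance = 3.0),
             remifentanil = c(induction = 2.5, maintenance = 1.5)),
  iii = list(propofol = c(induction = 5.0, maintenance = 3.5),
             remifentanil = c(induction = 2.0, maintenance = 1.0))
)

#' Build the simulated anesthesia scenario
#'
#' @param scheme `"i"`, `"ii"` or `"iii"`: the administration scheme
#'   (induction/maintenance effect-site targets; see Details).
#' @details Scheme i: propofol 4.0/2.5 ug/mL with remifentanil 3.0/2.0
#'   ng/mL (induction/maintenance); scheme ii: 4.5/3.0 with 2.5/1.5;
#'   scheme iii: 5.0/3.5 with 2.0/1.0.  Induction targets hold until 10
#'   min, maintenance until 80 min, then zero.  The procedure lasts 90
#'   min with LMA insertion at 5 min and surgical stimulus from 20 to 70
#'   min.
#' @return An object of class `risk_scenario` with `scheme`, `duration`,
#'   `propofol_targets`/`remi_targets` (data frames `time`, `target`),
#'   `events`, `stim_onset`, `stim_end`.
#' @export
build_scenario <- function(scheme = c("i", "ii", "iii")) {
  if (is.character(scheme) && length(scheme) == 1L &&
      !scheme %in% names(risk_schemes))
    stop("invalid input: unknown scheme '", scheme, "'")
  scheme <- match.arg(scheme)
  s <- risk_schemes[[scheme]]
  tg <- function(v) data.frame(time = c(0, 10, 80),
                               target = c(v[["induction"]],
                                          v[["maintenance"]], 0))
  structure(list(scheme = scheme, duration = 90,
                 propofol_targets = tg(s$propofol),
                 remi_targets = tg(s$remifentanil),
                 events = list(stimulus_event("LMA", 5),
                               stimulus_event("hysteroscopy", 20)),
                 stim_onset = 20, stim_end = 70),
            class = "risk_scenario")
}

#' @export
print.risk_scenario <- function(x, ...) {
  cat(sprintf("<risk_scenario> scheme %s, %g min, stimulus %g-%g min\n",
              x$scheme, x$duration, x$stim_onset, x$stim_end))
  invisible(x)
}

#' Monte-Carlo hypotension risk curves
#'
#' Samples `n` individuals from the population, drives each with the
#' scenario's effect-site TCI concentrations, simulates the noise-free
#' MAP trajectory and evaluates, on a 1-min grid, the fraction of
#' replicates with (i) MAP below 60 mmHg and (ii) MAP at or below 80% of
#' the individual's model baseline.
#'
#' @param pop A [population_parameters()] object.
#' @param scenario A [build_scenario()] result.
#' @param n Number of simulated individuals (default 1000).
#' @param seed Integer seed.
#' @param demographics [patient_covariates()] for the pharmacokinetic
#'   models (default the typical study patient).
#' @param events Override the scenario stimulus events (e.g. `list()` to
#'   remove the stimulus).
#' @return An object of class `risk_curves`: data frame with `time`
#'   (min), `scheme`, `p_map_lt_60`, `p_drop_ge_20`; attribute
#'   `n_replicates`.
#' @export
simulate_risk <- function(pop, scenario, n = 1000, seed = 1,
                          demographics = typical_patient(), events = NULL) {
  stopifnot(inherits(pop, "pop_params"), inherits(scenario, "risk_scenario"),
            n >= 1)
  grid <- seq(0, scenario$duration, by = 1 / 6)
  profs <- list()
  for (drug in c("propofol", "remifentanil")) {
    tgts <- if (drug == "propofol") scenario$propofol_targets
            else scenario$remi_targets
    pk <- pk_parameters(drug, demographics)
    sch <- tci_schedule(pk, tgts, mode = "effect_site",
                        duration = scenario$duration)
    profs[[drug]] <- simulate_concentrations(pk, sch, grid)
  }
  events <- events %||% scenario$events
  obs_idx <- seq(1L, length(grid), by = 6L)  # 1-min marks
  times <- grid[obs_idx]
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lt60 <- drop20 <- matrix(FALSE, length(times), n)
  failures <- 0L
  for (k in seq_len(n)) {
    ind <- sample_individual(pop, seed = seeds[k], id = k)
    tr <- tryCatch(
      simulate_hemodynamics(ind$params, propofol = profs$propofol,
                            remifentanil = profs$remifentanil,
                            events = events, times = grid),
      error = function(e) NULL)
    if (is.null(tr)) { failures <- failures + 1L; next }
    map <- tr$map[obs_idx]
    lt60[, k] <- map < 60
    drop20[, k] <- map <= 0.8 * ind$params$MAP0
  }
  if (failures > 0.01 * n)
    stop(sprintf("integration failures in %d of %d replicates", failures, n))
  n_ok <- n - failures
  structure(data.frame(time = times, scheme = scenario$scheme,
                       p_map_lt_60 = rowSums(lt60) / n_ok,
                       p_drop_ge_20 = rowSums(drop20) / n_ok),
            n_replicates = n_ok, failures = failures,
            class = c("risk_curves", "data.frame"))
}

#' Per-window maxima of hypotension risk
#'
#' @param curves A `risk_curves` object (or a data frame with `time`,
#'   `p_map_lt_60`, `p_drop_ge_20`).
#' @param windows Named list of `c(lo, hi)` time windows (min),
#'   interpreted as half-open intervals `(lo, hi]`.  The defaults give
#'   the pre-surgery window (minutes 0-19) and the surgery-and-after
#'   window (strictly after the 20-min stimulus onset, whose first minute
#'   still reflects the pre-surgical state because the stimulus has had
#'   no time to act).
#' @return Data frame with `window`, `criterion`, `max_p`, `t_max`.
#' @export
summarize_max_risk <- function(curves,
                               windows = list(pre_surgery = c(-Inf, 19),
                                              surgery_and_after = c(20, Inf))) {
  stopifnot(all(c("time", "p_map_lt_60", "p_drop_ge_20") %in% names(curves)))
  out <- list()
  for (w in names(windows)) {
    lo <- windows[[w]][1]; hi <- windows[[w]][2]
    sel <- curves$time > lo & curves$time <= hi
    if (!any(sel)) stop("invalid input: empty window '", w, "'")
    for (cr in c("p_map_lt_60", "p_drop_ge_20")) {
      i <- which(sel)[which.max(curves[[cr]][sel])]
      out[[length(out) + 1L]] <- data.frame(
        window = w, criterion = cr, max_p = curves[[cr]][i],
        t_max = curves$time[i])
    }
  }
  do.call(rbind, out)
}

#' Write risk curves as CSV
#'
#' @param curves A `risk_curves`.
#' @param path File path.
#' @export
write_risk_csv <- function(curves, path) {
  utils::write.csv(as.data.frame(curves), path, row.names = FALSE)
  invisible(path)
}
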