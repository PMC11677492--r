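# Study designs: per-group stepwise effect-site target schedules.
#
# Times inside a design are measured from the start of the infusion: a
# 25-min step-up phase (five 5-min steps), a 15-min step-down phase (three
# 5-min steps), then a stable hold until the surgical stimulus and the end
# of observation.  Group A is propofol only, B remifentanil only, C stable
# propofol with varying remifentanil, D stable remifentanil with varying
# propofol.  The per-scheme target ladders span ~1-8 ug/mL (propofol) and
# ~1-8 ng/mL (remifentanil).

design_ladder <- function(peak) {
  data.frame(
    time = c(0, 5, 10, 15, 20, 25, 30, 35, 40),
    target = c(peak * (1:5) / 5, peak * c(0.55, 0.35, 0.2), peak * 0.2))
}

#' Generate a study-group design
#'
#' Builds the stepwise effect-site target schedules, stimulus events and
#' sampling cadences for one administration scheme of one study group.
#'
#' @param group `"A"` (propofol only), `"B"` (remifentanil only),
#'   `"C"` (stable propofol, varying remifentanil) or `"D"` (stable
#'   remifentanil, varying propofol).
#' @param scheme_index Which target ladder to use, `1..n_schemes`.
#' @param n_schemes Number of distinct ladders per group (default 8).
#' @param seed Unused (designs are deterministic); accepted for interface
#'   symmetry with the stochastic generators.
#' @return An object of class `study_design` with elements
#'   `propofol_targets` / `remi_targets` (data frames `time`, `target`),
#'   `events` (list of [stimulus_event()]), `duration` (min),
#'   `obs_interval` (1 min), `infusion_interval` (1/6 min), and the
#'   phase boundaries `step_up_end` (25) and `step_down_end` (40).
#' @examples
#' d <- generate_design("A", 1)
#' d$propofol_targets
#' @export
generate_design <- function(group, scheme_index = 1L, n_schemes = 8L,
                            seed = NULL) {
  if (!is.character(group) || !group %in% c("A", "B", "C", "D"))
    stop("invalid input: unknown group")
  s <- as.integer(scheme_index)
  if (is.na(s) || s < 1L || s > n_schemes)
    stop("invalid input: scheme_index out of range")
  peak_p <- seq(5, 8, length.out = n_schemes)[s]
  peak_r <- seq(5, 8, length.out = n_schemes)[s]
  flat <- function(level) data.frame(time = 0, target = level)
  zero <- data.frame(time = 0, target = 0)
  propofol <- switch(group,
    A = design_ladder(peak_p), B = zero, C = flat(3), D = design_ladder(peak_p))
  remi <- switch(group,
    A = zero, B = design_ladder(peak_r), C = design_ladder(peak_r), D = flat(2))
  stim <- if (group == "B") list() else list(
    stimulus_event("esophageal", 15),
    stimulus_event("tetanic", 35),
    stimulus_event("hysteroscopy", 45))
  duration <- if (group == "B") 45 else 65
  structure(list(group = group, scheme_index = s,
                 propofol_targets = propofol, remi_targets = remi,
                 events = stim, duration = duration,
                 obs_interval = 1, infusion_interval = 1 / 6,
                 step_up_end = 25, step_down_end = 40,
                 procedure = if (group == "B") "other" else "hysteroscopy"),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> group %s scheme %d, %g min, procedure %s\n",
              x$group, x$scheme_index, x$duration, x$procedure))
  invisible(x)
}
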