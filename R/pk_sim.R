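#' Infusion schedule
#'
#' A piecewise-constant infusion schedule plus optional bolus events, the
#' pump-side representation of a target-controlled infusion.  Rates are in
#' dose-mass per minute (mg/min for propofol, ug/min for remifentanil);
#' each rate holds from its start time until the next entry.
#'
#' @param drug `"propofol"` or `"remifentanil"`.
#' @param times Start times (min), non-decreasing.
#' @param rates Infusion rates (mass/min), `>= 0`, same length as `times`.
#' @param bolus_times Times of bolus doses (min).
#' @param bolus_amounts Bolus amounts (mass), `>= 0`.
#' @return An object of class `infusion_schedule`.
#' @examples
#' infusion_schedule("propofol", times = c(0, 10), rates = c(100, 0))
#' @export
infusion_schedule <- function(drug, times = numeric(), rates = numeric(),
                              bolus_times = numeric(), bolus_amounts = numeric()) {
  stopifnot(length(times) == length(rates),
            length(bolus_times) == length(bolus_amounts))
  if (is.unsorted(times)) stop("invalid input: schedule times must be non-decreasing")
  if (any(rates < 0)) stop("invalid input: rates must be non-negative")
  if (any(bolus_amounts < 0)) stop("invalid input: bolus amounts must be non-negative")
  structure(list(drug = drug, times = as.numeric(times),
                 rates = as.numeric(rates),
                 bolus_times = as.numeric(bolus_times),
                 bolus_amounts = as.numeric(bolus_amounts)),
            class = "infusion_schedule")
}

#' @export
print.infusion_schedule <- function(x, ...) {
  cat(sprintf("<infusion_schedule> %s: %d rate entries, %d boluses\n",
              x$drug, length(x$times), length(x$bolus_times)))
  invisible(x)
}

# rate in effect over [t_i, t_{i+1}) for every grid interval start
schedule_rates_on_grid <- function(schedule, grid) {
  if (length(schedule$times) == 0L) return(numeric(length(grid)))
  idx <- findInterval(grid + 1e-12, schedule$times)
  r <- ifelse(idx == 0L, 0, schedule$rates[pmax(idx, 1L)])
  as.numeric(r)
}

#' Simulate plasma and effect-site concentrations
#'
#' Propagates the three-compartment + effect-site system exactly over
#' piecewise-constant infusion rates using matrix exponentials (exact for
#' linear kinetics; no solver error beyond the matrix exponential itself).
#'
#' @param pk A [pk_parameters()] object.
#' @param schedule An [infusion_schedule()].
#' @param times Uniform time grid (min); step must not exceed 1/6 min (10 s)
#'   and every schedule change time must lie on the grid.
#' @return An object of class `conc_profile`: data frame with columns
#'   `time` (min), `cp` and `ce` (ug/mL for propofol, ng/mL for
#'   remifentanil), with the drug stored as an attribute.
#' @examples
#' pk <- pk_parameters("propofol", typical_patient())
#' sch <- infusion_schedule("propofol", times = c(0, 5), rates = c(120, 0))
#' prof <- simulate_concentrations(pk, sch, seq(0, 20, by = 1/6))
#' @export
simulate_concentrations <- function(pk, schedule, times) {
  stopifnot(inherits(pk, "pk_params"), inherits(schedule, "infusion_schedule"))
  n <- length(times)
  if (n < 2L) stop("invalid input: need at least two grid times")
  h <- diff(times)
  if (max(abs(h - h[1])) > 1e-9) stop("invalid input: grid must be uniform")
  h <- h[1]
  if (h > 1 / 6 + 1e-9) stop("resolution error: grid step exceeds 10 s")
  chg <- c(schedule$times, schedule$bolus_times)
  if (length(chg) && any(abs((chg - times[1]) / h -
                             round((chg - times[1]) / h)) > 1e-6))
    stop("resolution error: schedule change times must lie on the grid")
  sm <- pk_step_matrices(pk, h)
  rates <- schedule_rates_on_grid(schedule, times)
  x <- c(0, 0, 0, 0)
  cp <- ce <- numeric(n)
  bt <- schedule$bolus_times; ba <- schedule$bolus_amounts
  for (i in seq_len(n)) {
    if (length(bt)) {
      hit <- abs(bt - times[i]) < 1e-9
      if (any(hit)) x[1] <- x[1] + sum(ba[hit])
    }
    cp[i] <- x[1] / pk$V1
    ce[i] <- x[4]
    if (i < n) x <- sm$E %*% x + sm$f * rates[i]
  }
  structure(data.frame(time = times, cp = as.numeric(cp), ce = as.numeric(ce)),
            drug = pk$drug, class = c("conc_profile", "data.frame"))
}

#' Write / read an infusion schedule as CSV
#'
#' Boluses are stored as zero-duration rows with an `amount` column.
#'
#' @param schedule An [infusion_schedule()].
#' @param path File path.
#' @return `read_schedule_csv` returns an [infusion_schedule()].
#' @export
write_schedule_csv <- function(schedule, path) {
  df <- rbind(
    data.frame(drug = schedule$drug, time_min = schedule$times,
               rate = schedule$rates, amount = NA_real_),
    if (length(schedule$bolus_times))
      data.frame(drug = schedule$drug, time_min = schedule$bolus_times,
                 rate = NA_real_, amount = schedule$bolus_amounts)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("drug", "time_min", "rate", "amount") %in% names(df)))
  rate_rows <- !is.na(df$rate)
  infusion_schedule(df$drug[1],
                    times = df$time_min[rate_rows], rates = df$rate[rate_rows],
                    bolus_times = df$time_min[!rate_rows],
                    bolus_amounts = df$amount[!rate_rows])
}

#' Write a concentration profile as CSV
#'
#' @param profile A `conc_profile` from [simulate_concentrations()].
#' @param path File path.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(time_min = profile$time, cp = profile$cp, ce = profile$ce,
                   drug = attr(profile, "drug"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
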