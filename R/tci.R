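# Target-controlled infusion schedule generation.
#
# Plasma mode solves, at every pump update, the exact rate that lands the
# plasma concentration on the target at the end of the interval.
# Effect-site mode follows the standard pump logic: an initial "burst"
# overshoots the plasma concentration so that the predicted zero-input
# effect-site peak equals the target, then the pump coasts (rate 0) while
# the effect site rises, and finally holds plasma at the target once the
# effect site has reached it.  The burst rate is found by root-finding on
# the analytic (eigendecomposition) prediction of the future peak.

tci_eigen <- function(pk) {
  M <- pk_matrix(pk)
  e <- eigen(M)
  list(lambda = Re(e$values), V = Re(e$vectors),
       Vinv = Re(solve(e$vectors)))
}

# effect-site concentration t minutes ahead under zero input from state x
tci_ce_ahead <- function(eg, x, t) {
  z <- eg$Vinv %*% x
  as.numeric(eg$V[4, , drop = FALSE] %*% (exp(eg$lambda * t) * z))
}

tci_ce_peak <- function(eg, x, horizon = 20) {
  opt <- stats::optimize(function(t) tci_ce_ahead(eg, x, t),
                         interval = c(0, horizon), maximum = TRUE, tol = 1e-4)
  max(opt$objective, tci_ce_ahead(eg, x, 0), tci_ce_ahead(eg, x, horizon))
}

#' Generate a target-controlled infusion schedule
#'
#' Computes the discrete pump rates that track a stepwise plasma- or
#' effect-site concentration target for a given pharmacokinetic model.
#'
#' @param pk A [pk_parameters()] object.
#' @param targets Data frame with columns `time` (min, non-decreasing) and
#'   `target` (concentration, `>= 0`).  Each target holds from its time
#'   until the next row.
#' @param mode `"effect_site"` (default) or `"plasma"`.
#' @param update_interval Pump update interval in seconds (default 10).
#' @param duration Total schedule duration (min); defaults to the last
#'   target time.
#' @return An [infusion_schedule()] with one rate entry per update interval.
#' @examples
#' pk <- pk_parameters("remifentanil", typical_patient())
#' sch <- tci_schedule(pk, data.frame(time = 0, target = 3), duration = 10)
#' @export
tci_schedule <- function(pk, targets, mode = c("effect_site", "plasma"),
                         update_interval = 10, duration = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(pk, "pk_params"), is.data.frame(targets),
            all(c("time", "target") %in% names(targets)))
  if (any(targets$target < 0)) stop("invalid target: negative concentration")
  if (is.unsorted(targets$time)) stop("invalid target: times must be non-decreasing")
  h <- update_interval / 60
  if (is.null(duration)) duration <- max(targets$time)
  nstep <- ceiling(duration / h - 1e-9)
  t_grid <- (0:(nstep - 1)) * h
  sm <- pk_step_matrices(pk, h)
  eg <- tci_eigen(pk)
  x <- c(0, 0, 0, 0)
  rates <- numeric(nstep)

  maint_rate <- function(x, tgt) {
    # rate landing Cp on tgt at the end of the interval, floored at 0
    pred0 <- (sm$E %*% x)[1] / pk$V1
    max(0, (tgt - pred0) * pk$V1 / sm$f[1])
  }

  for (i in seq_len(nstep)) {
    tgt <- targets$target[findInterval(t_grid[i] + 1e-9, targets$time)]
    if (length(tgt) == 0L || is.na(tgt)) tgt <- 0
    R <- 0
    if (tgt > 0) {
      if (mode == "plasma") {
        R <- maint_rate(x, tgt)
      } else {
        ce <- x[4]
        if (ce >= tgt * (1 - 1e-3)) {
          R <- maint_rate(x, tgt)
        } else {
          peak0 <- tci_ce_peak(eg, x)
          if (peak0 < tgt * (1 - 1e-6)) {
            gfun <- function(R) {
              y <- sm$E %*% x + sm$f * R
              tci_ce_peak(eg, y) - tgt
            }
            if (gfun(0) < 0) {
              Rhi <- max(10, 2 * maint_rate(x, tgt))
              k <- 0
              while (gfun(Rhi) < 0 && k < 60) { Rhi <- Rhi * 2; k <- k + 1 }
              R <- stats::uniroot(gfun, c(0, Rhi), tol = 1e-6)$root
            }
          }
        }
      }
    }
    rates[i] <- R
    x <- sm$E %*% x + sm$f * R
  }
  infusion_schedule(pk$drug, times = t_grid, rates = rates)
}
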