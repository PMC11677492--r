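# Prediction-corrected visual predictive check.
#
# Observations and simulated values in each time bin are rescaled by
# median(PRED_bin)/PRED_ij, where PRED is the population prediction
# (random effects at zero); percentile bands of the corrected simulations
# are compared with the corrected observed percentiles.

#' Prediction correction
#'
#' Rescales values by `median(pred within bin) / pred`, the correction
#' applied to both observations and simulations in a pcVPC.  Records with
#' zero prediction are returned as `NA`.
#'
#' @param dv Observed or simulated values.
#' @param pred Population predictions (random effects at zero).
#' @param bin Bin index per record.
#' @return Corrected values, same length as `dv`.
#' @export
prediction_correct <- function(dv, pred, bin) {
  out <- rep(NA_real_, length(dv))
  for (b in unique(bin)) {
    ix <- bin == b & pred != 0
    out[ix] <- dv[ix] * stats::median(pred[bin == b]) / pred[ix]
  }
  out
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicate datasets with the design and dosing of
#' `dataset` from the population model, prediction-corrects observed and
#' simulated values by the binned median population prediction, and
#' returns observed percentiles with simulated 95% prediction bands,
#' separately for MAP and HR.
#'
#' @param dataset A `hemo_dataset`.
#' @param pop A [population_parameters()] object (e.g. [as_population()]
#'   of a fit, or the generating values for a calibration check).
#' @param config A [model_config()].
#' @param n_sim Number of simulated datasets (default 500).
#' @param bins Number of equal-count time bins per response (default 10).
#' @param seed Integer seed.
#' @param demographics Optional [patient_covariates()].
#' @param thin Pharmacodynamic grid coarsening factor.
#' @return An object of class `hemo_vpc`: a data frame with one row per
#'   response/bin/percentile: `dvid` (1 MAP, 2 HR), `bin`, `t_lo`,
#'   `t_mid`, `t_hi`, `percentile` (2.5, 50, 97.5), `observed`, `sim_lo`,
#'   `sim_hi` (95% prediction interval of that percentile across the
#'   simulations), plus attribute `n_sim`.
#' @export
pcvpc <- function(dataset, pop, config = final_model(), n_sim = 500,
                  bins = 10, seed = 1, demographics = NULL, thin = 2L) {
  stopifnot(inherits(dataset, "hemo_dataset"), inherits(pop, "pop_params"))
  subj <- build_subject_data(dataset, demographics, thin = thin,
                             driver = if (config$effect_site_driver)
                               "effect_site" else "plasma")
  typ <- params_vector(pop$typicals, config)
  m <- list(typ = typ, Omega = pop_omega_matrix(pop),
            sigma_MAP = pop$sigma_MAP, sigma_HR = pop$sigma_HR)

  obs <- do.call(rbind, lapply(subj, function(s) {
    pred <- subj_predict(s, typ)
    data.frame(
      ID = s$id,
      TIME = c(s$times[s$i_map + 1L], s$times[s$i_hr + 1L]),
      DVID = rep(c(1L, 2L), c(length(s$i_map), length(s$i_hr))),
      DV = c(s$y_map, s$y_hr),
      PRED = c(pred[s$i_map + 1L, 1], pred[s$i_hr + 1L, 2]))
  }))
  keep <- obs$PRED != 0
  if (any(!keep)) {
    warning(sum(!keep), " record(s) with zero population prediction excluded")
    obs <- obs[keep, ]
  }
  sims <- simulate_from_model(subj, m, nsim = n_sim, seed = seed)
  dv_sim <- vapply(sims, function(s) s$DV, numeric(length(keep)))[keep, ,
                                                                  drop = FALSE]
  qs <- c(0.025, 0.5, 0.975)
  res <- list()
  for (dvid in c(1L, 2L)) {
    sel <- obs$DVID == dvid
    o <- obs[sel, ]
    dvs <- dv_sim[sel, , drop = FALSE]
    br <- unique(stats::quantile(o$TIME, probs = seq(0, 1, length.out = bins + 1),
                                 names = FALSE))
    if (length(br) < 2L) next
    bin <- findInterval(o$TIME, br, all.inside = TRUE)
    for (b in sort(unique(bin))) {
      ix <- bin == b
      if (!any(ix)) next
      fac <- stats::median(o$PRED[ix]) / o$PRED[ix]
      pc_obs <- prediction_correct(o$DV[ix], o$PRED[ix], rep(1L, sum(ix)))
      pc_sim <- dvs[ix, , drop = FALSE] * fac
      obs_q <- stats::quantile(pc_obs, qs, names = FALSE)
      sim_q <- apply(pc_sim, 2, stats::quantile, probs = qs, names = FALSE)
      band <- apply(sim_q, 1, stats::quantile, probs = c(0.025, 0.975),
                    names = FALSE)
      res[[length(res) + 1L]] <- data.frame(
        dvid = dvid, bin = b, t_lo = br[b], t_hi = br[b + 1L],
        t_mid = stats::median(o$TIME[ix]),
        percentile = 100 * qs, observed = obs_q,
        sim_lo = band[1, ], sim_hi = band[2, ])
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (any(out$sim_lo > out$sim_hi) ||
      any(tapply(out$observed, list(out$dvid, out$bin), function(v)
        is.unsorted(v))))
    warning("inconsistent percentile ordering in VPC summary")
  structure(out, n_sim = n_sim, class = c("hemo_vpc", "data.frame"))
}

#' @export
print.hemo_vpc <- function(x, ...) {
  cat(sprintf("<hemo_vpc> %d bins x percentiles, %d simulations\n",
              nrow(x) / 3L, attr(x, "n_sim")))
  NextMethod()
}

#' Plot a prediction-corrected VPC
#'
#' Observed percentiles (lines/points) over the simulated 95% prediction
#' bands (shaded), one panel per response.
#'
#' @param x A `hemo_vpc`.
#' @param ... Unused.
#' @export
plot.hemo_vpc <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (dvid in unique(x$dvid)) {
    d <- x[x$dvid == dvid, ]
    ylim <- range(d$observed, d$sim_lo, d$sim_hi)
    graphics::plot(NA, xlim = range(d$t_lo, d$t_hi), ylim = ylim,
                   xlab = "time (min)",
                   ylab = if (dvid == 1) "pc MAP (mmHg)" else "pc HR (bpm)")
    for (p in unique(d$percentile)) {
      dp <- d[d$percentile == p, ]
      graphics::polygon(c(dp$t_mid, rev(dp$t_mid)),
                        c(dp$sim_lo, rev(dp$sim_hi)),
                        col = grDevices::adjustcolor("steelblue", 0.3),
                        border = NA)
      graphics::lines(dp$t_mid, dp$observed,
                      lty = if (p == 50) 1 else 2, lwd = 1.5)
    }
  }
  invisible(x)
}

#' Write VPC results as CSV
#'
#' @param vpc A `hemo_vpc`.
#' @param path File path.
#' @export
write_vpc_csv <- function(vpc, path) {
  utils::write.csv(as.data.frame(vpc), path, row.names = FALSE)
  invisible(path)
}
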