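# Long-format dataset I/O (NONMEM-style dialect).
# Columns: ID, TIME (min), EVID (0 observation / 1 infusion record /
# 2 stimulus annotation), DVID (1 = MAP, 2 = HR), DV, RATE, DRUG,
# STIM_KIND, STIM_TIME, PROC, GROUP, SCHEME.

#' Write a dataset to CSV
#'
#' @param dataset A `hemo_dataset` (see [generate_dataset()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(is.data.frame(dataset))
  miss <- setdiff(dataset_columns, names(dataset))
  if (length(miss)) stop("schema error: missing columns ",
                         paste(miss, collapse = ", "))
  utils::write.csv(dataset[, dataset_columns, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a dataset from CSV
#'
#' Validates the schema row by row: observation records (`EVID = 0`) must
#' carry a known `DVID` and a numeric `DV`.
#'
#' @param path CSV file path.
#' @return A `hemo_dataset` data frame.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("input not found: ", path)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  miss <- setdiff(dataset_columns, header)
  if (length(miss)) stop("schema error: missing columns ",
                         paste(miss, collapse = ", "))
  ds <- utils::read.csv(path, colClasses = c(
    ID = "integer", TIME = "numeric", EVID = "integer", DVID = "integer",
    DV = "numeric", RATE = "numeric", DRUG = "character",
    STIM_KIND = "character", STIM_TIME = "numeric", PROC = "character",
    GROUP = "character", SCHEME = "integer"))
  miss <- setdiff(dataset_columns, names(ds))
  if (length(miss)) stop("schema error: missing columns ",
                         paste(miss, collapse = ", "))
  obs <- ds$EVID == 0L
  bad_dvid <- obs & (is.na(ds$DVID) | !ds$DVID %in% c(1L, 2L))
  if (any(bad_dvid))
    stop("schema error: unknown or missing DVID on observation row(s) ",
         paste(utils::head(which(bad_dvid), 5L), collapse = ", "))
  bad_dv <- obs & is.na(ds$DV)
  if (any(bad_dv))
    stop("parse error: missing DV on observation row(s) ",
         paste(utils::head(which(bad_dv), 5L), collapse = ", "))
  structure(ds, class = c("hemo_dataset", "data.frame"))
}

#' @export
print.hemo_dataset <- function(x, ...) {
  ids <- unique(x$ID)
  cat(sprintf("<hemo_dataset> %d subjects, %d records (%d observations)\n",
              length(ids), nrow(x), sum(x$EVID == 0L)))
  invisible(x)
}

# Reconstruct per-subject simulation inputs (concentration profiles on a
# uniform grid, observation indices, stimulus onsets) from the dataset
# records, as consumed by the estimation core.  `thin` coarsens the
# pharmacodynamic grid (thin = 2 -> 20-s steps) while keeping the 1-min
# observation marks on-grid.
build_subject_data <- function(dataset, demographics = NULL, thin = 2L,
                               driver = c("plasma", "effect_site")) {
  driver <- match.arg(driver)
  col <- if (driver == "plasma") "cp" else "ce"
  demographics <- demographics %||% attr(dataset, "demographics") %||%
    typical_patient()
  pk <- list(propofol = pk_parameters("propofol", demographics),
             remifentanil = pk_parameters("remifentanil", demographics))
  ids <- unique(dataset$ID)
  lapply(ids, function(id) {
    d <- dataset[dataset$ID == id, , drop = FALSE]
    t_end <- max(d$TIME)
    fine <- seq(0, t_end, by = 1 / 6)
    profs <- lapply(pk, function(pkd) {
      rows <- d$EVID == 1L & d$DRUG == pkd$drug
      if (!any(rows)) return(numeric(length(fine)))
      sch <- infusion_schedule(pkd$drug, times = d$TIME[rows],
                               rates = d$RATE[rows])
      simulate_concentrations(pkd, sch, fine)[[col]]
    })
    keep <- seq(1L, length(fine), by = thin)
    grid <- fine[keep]
    h <- 1 / 6 * thin
    obs_idx <- function(dvid) {
      rows <- d$EVID == 0L & d$DVID == dvid
      ix <- round(d$TIME[rows] / h)
      if (any(abs(d$TIME[rows] / h - ix) > 1e-6))
        stop("schema error: observation times off the simulation grid")
      list(i = as.integer(ix), y = d$DV[rows])
    }
    m <- obs_idx(1L); hh <- obs_idx(2L)
    stim <- d$EVID == 2L & d$STIM_KIND == "hysteroscopy"
    list(id = id, times = grid,
         cp_propo = profs$propofol[keep], cp_remi = profs$remifentanil[keep],
         stim = as.numeric(d$STIM_TIME[stim]),
         i_map = m$i, y_map = m$y, i_hr = hh$i, y_hr = hh$y)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
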