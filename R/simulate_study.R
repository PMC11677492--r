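# Synthetic study datasets: compose TCI + pharmacokinetics + population
# sampling + turn-over dynamics + residual error into a long-format
# dataset with the study's sampling cadences (10-s infusion records,
# 1-min MAP/HR observations, baseline observations before the first dose).

dataset_columns <- c("ID", "TIME", "EVID", "DVID", "DV", "RATE", "DRUG",
                     "STIM_KIND", "STIM_TIME", "PROC", "GROUP", "SCHEME")

# TCI schedules and concentration profiles for one design (shared by all
# subjects on that design; the model carries no pharmacokinetic
# inter-individual variability)
design_profiles <- function(design, demographics) {
  grid <- seq(0, design$duration, by = design$infusion_interval)
  out <- list(grid = grid)
  for (drug in c("propofol", "remifentanil")) {
    tg <- if (drug == "propofol") design$propofol_targets else design$remi_targets
    if (all(tg$target == 0)) {
      out[[drug]] <- list(schedule = infusion_schedule(drug),
                          profile = NULL)
      next
    }
    pk <- pk_parameters(drug, demographics)
    sch <- tci_schedule(pk, tg, mode = "effect_site",
                        duration = design$duration)
    out[[drug]] <- list(schedule = sch,
                        profile = simulate_concentrations(pk, sch, grid))
  }
  out
}

#' Generate a synthetic study dataset
#'
#' Simulates a complete multi-subject study: subjects are allocated to the
#' four administration groups, individual parameters are sampled from the
#' population, drugs are given by effect-site target-controlled infusion
#' following the group design, MAP/HR are simulated with the turn-over
#' model and observed with additive noise every minute, and infusion rates
#' are recorded every 10 s.  Baseline observations precede the first dose
#' by `baseline_lead` minutes.
#'
#' @param pop A [population_parameters()] object.
#' @param n_subjects Number of subjects (default 77; groups A/C/D receive
#'   the hysteroscopy procedure, group B another procedure, emulating a
#'   56/21 train/test split at n = 77).
#' @param designs Optional list of [generate_design()] objects, one per
#'   subject; by default subjects are allocated round-robin to groups and
#'   schemes.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @param schemes_per_group Number of distinct target ladders cycled
#'   through within each group.
#' @param baseline_lead Minutes of pre-dose observation (default 2).
#' @param demographics A [patient_covariates()] used for the
#'   pharmacokinetic models (default [typical_patient()]).
#' @param sim_method Integrator passed to [simulate_hemodynamics()]
#'   (`"rk4"` or `"exact"`).
#' @return A long-format data frame of class `hemo_dataset` with columns
#'   `ID, TIME, EVID, DVID, DV, RATE, DRUG, STIM_KIND, STIM_TIME, PROC,
#'   GROUP, SCHEME` (`EVID` 0 = observation with `DVID` 1 MAP / 2 HR,
#'   1 = infusion-rate record, 2 = stimulus annotation).  Attributes:
#'   `subjects` (allocation table), `individuals` (sampled parameters and
#'   random effects), `truth` (noise-free predictions at observation
#'   times), `demographics`.
#' @examples
#' \donttest{
#' pop <- default_population()
#' ds <- generate_dataset(pop, n_subjects = 4, seed = 1)
#' }
#' @export
generate_dataset <- function(pop, n_subjects = 77, designs = NULL, seed = 1,
                             schemes_per_group = 4, baseline_lead = 2,
                             demographics = typical_patient(),
                             sim_method = "rk4") {
  stopifnot(inherits(pop, "pop_params"), n_subjects >= 1)
  n <- as.integer(n_subjects)
  if (is.null(designs)) {
    n_b <- round(n * 21 / 77)
    groups <- c(rep(c("A", "C", "D"), length.out = n - n_b), rep("B", n_b))
    designs <- lapply(seq_len(n), function(i)
      generate_design(groups[i],
                      scheme_index = ((i - 1L) %/% 3L) %% schemes_per_group + 1L,
                      n_schemes = max(schemes_per_group, 8L)))
  }
  stopifnot(length(designs) == n)
  set.seed(seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n)

  profile_cache <- new.env(parent = emptyenv())
  get_profiles <- function(design) {
    key <- paste(design$group, design$scheme_index, design$duration, sep = "_")
    if (!is.null(profile_cache[[key]])) return(profile_cache[[key]])
    profile_cache[[key]] <- design_profiles(design, demographics)
    profile_cache[[key]]
  }

  rec_list <- vector("list", n)
  truth_list <- vector("list", n)
  individuals <- vector("list", n)
  subjects <- data.frame(ID = seq_len(n),
                         GROUP = vapply(designs, function(d) d$group, ""),
                         SCHEME = vapply(designs, function(d) d$scheme_index, 1L),
                         PROC = vapply(designs, function(d) d$procedure, ""))

  for (i in seq_len(n)) {
    design <- designs[[i]]
    pr <- get_profiles(design)
    ind <- tryCatch(sample_individual(pop, seed = subj_seeds[i], id = i),
                    error = function(e)
                      stop("subject ", i, ": ", conditionMessage(e)))
    individuals[[i]] <- ind
    traj <- tryCatch(
      simulate_hemodynamics(ind$params,
                            propofol = pr$propofol$profile,
                            remifentanil = pr$remifentanil$profile,
                            events = design$events, times = pr$grid,
                            method = sim_method),
      error = function(e) stop("subject ", i, ": ", conditionMessage(e)))
    total <- baseline_lead + design$duration
    obs_t <- seq(0, floor(total), by = design$obs_interval)
    map_t <- hr_t <- numeric(length(obs_t))
    pre <- obs_t < baseline_lead
    map_t[pre] <- ind$params$MAP0
    hr_t[pre] <- ind$params$HR0
    idx <- round((obs_t[!pre] - baseline_lead) / design$infusion_interval) + 1L
    map_t[!pre] <- traj$map[idx]
    hr_t[!pre] <- traj$hr[idx]
    noisy <- add_residual_error(
      data.frame(time = obs_t, map = map_t, hr = hr_t), pop,
      seed = subj_seeds[i] + 1L)

    obs <- data.frame(
      ID = i, TIME = rep(obs_t, 2L), EVID = 0L,
      DVID = rep(c(1L, 2L), each = length(obs_t)),
      DV = round(c(noisy$map, noisy$hr), 4), RATE = NA_real_,
      DRUG = "", STIM_KIND = "", STIM_TIME = NA_real_)
    inf <- do.call(rbind, lapply(c("propofol", "remifentanil"), function(drug) {
      sch <- pr[[drug]]$schedule
      if (length(sch$times) == 0L) return(NULL)
      data.frame(ID = i, TIME = sch$times + baseline_lead, EVID = 1L,
                 DVID = NA_integer_, DV = NA_real_,
                 RATE = round(sch$rates, 6), DRUG = drug,
                 STIM_KIND = "", STIM_TIME = NA_real_)
    }))
    stim <- if (length(design$events)) do.call(rbind, lapply(design$events,
      function(ev) data.frame(
        ID = i, TIME = ev$t_stim + baseline_lead, EVID = 2L,
        DVID = NA_integer_, DV = NA_real_, RATE = NA_real_, DRUG = "",
        STIM_KIND = ev$kind, STIM_TIME = ev$t_stim + baseline_lead)))
      else NULL
    rec <- rbind(obs, inf, stim)
    rec <- rec[order(rec$TIME, rec$EVID, rec$DVID), ]
    rec$PROC <- design$procedure
    rec$GROUP <- design$group
    rec$SCHEME <- design$scheme_index
    rec_list[[i]] <- rec
    truth_list[[i]] <- data.frame(ID = i, TIME = obs_t, MAP = map_t, HR = hr_t)
  }
  ds <- do.call(rbind, rec_list)
  rownames(ds) <- NULL
  structure(ds, subjects = subjects, individuals = individuals,
            truth = do.call(rbind, truth_list), demographics = demographics,
            baseline_lead = baseline_lead,
            class = c("hemo_dataset", "data.frame"))
}

#' Split a dataset into training and test sets
#'
#' Partitions subjects by the annotated surgical procedure: subjects
#' undergoing hysteroscopy form the training set, all others the test set.
#'
#' @param dataset A `hemo_dataset`.
#' @param rule Splitting rule; only `"procedure"` is defined.
#' @return List with elements `train` and `test`, both `hemo_dataset`s.
#' @export
split_train_test <- function(dataset, rule = "procedure") {
  stopifnot(inherits(dataset, "hemo_dataset"), identical(rule, "procedure"))
  if (nrow(dataset) == 0L)
    return(list(train = dataset, test = dataset))
  if (any(is.na(dataset$PROC) | dataset$PROC == ""))
    stop("labeling error: missing procedure annotation")
  take <- function(keep) {
    out <- dataset[keep, , drop = FALSE]
    rownames(out) <- NULL
    ids <- unique(out$ID)
    for (a in c("subjects", "truth")) {
      v <- attr(dataset, a)
      if (!is.null(v)) attr(out, a) <- v[v$ID %in% ids, , drop = FALSE]
    }
    ind <- attr(dataset, "individuals")
    if (!is.null(ind))
      attr(out, "individuals") <- Filter(function(x) x$id %in% ids, ind)
    class(out) <- class(dataset)
    out
  }
  list(train = take(dataset$PROC == "hysteroscopy"),
       test = take(dataset$PROC != "hysteroscopy"))
}
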