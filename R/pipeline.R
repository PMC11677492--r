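# Config-driven stage runner tying the pipeline together:
# simulate -> fit -> vpc / bootstrap, plus the hypotension-risk study.
# Configs are plain lists or YAML files; every stochastic stage requires
# an explicit seed; outputs are written atomically (temp file + rename)
# and each run leaves a JSON log with the config echo and seed.

stage_defaults <- list(
  simulate = list(n_subjects = 10, schemes_per_group = 2, dataset = "dataset.csv"),
  fit = list(dataset = "dataset.csv", estimates = "estimates.json",
             summary = "fit_summary.csv", iter.max = 150),
  vpc = list(dataset = "dataset.csv", estimates = "estimates.json",
             n_sim = 200, bins = 8, vpc = "vpc.csv"),
  bootstrap = list(dataset = "dataset.csv", estimates = "estimates.json",
                   n_boot = 100, iter.max = 60, bootstrap = "bootstrap.csv"),
  hypotension = list(schemes = c("i", "ii", "iii"), n = 1000, risk = "risk.csv")
)

#' Run a pipeline stage
#'
#' Executes one stage of the simulation/estimation/diagnostics pipeline
#' from a validated config (a named list, or a path to a YAML file).
#' Required fields: `stage` (one of `simulate`, `fit`, `vpc`,
#' `bootstrap`, `hypotension`), `seed` (integer), `out_dir`.  Stage
#' options (all optional, with defaults): see the package vignette.
#' Identical config and inputs produce identical outputs; partial outputs
#' are removed on failure.
#'
#' @param config Named list or YAML file path.
#' @return Invisibly, a named list of written artifact paths.
#' @export
run_stage <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("input not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("schema violation: config must be a list")
  for (field in c("stage", "seed", "out_dir"))
    if (is.null(config[[field]]))
      stop("schema violation: config missing '", field, "'")
  stage <- config$stage
  if (!stage %in% names(stage_defaults))
    stop("schema violation: unknown stage '", stage, "'")
  seed <- as.integer(config$seed)
  if (is.na(seed)) stop("schema violation: seed must be an integer")
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  opts <- utils::modifyList(stage_defaults[[stage]],
                            config[setdiff(names(config),
                                           c("stage", "seed", "out_dir"))])

  tmp_of <- function(name) file.path(out_dir, paste0(".tmp_", name))
  final_of <- function(name) file.path(out_dir, name)
  written <- character()
  commit <- function(name) {
    file.rename(tmp_of(name), final_of(name))
    written <<- c(written, stats::setNames(final_of(name), name))
  }
  on.exit(unlink(file.path(out_dir, paste0(".tmp_", basename(unlist(opts)))),
                 force = TRUE), add = TRUE)

  in_path <- function(name) {
    p <- if (file.exists(name)) name else final_of(name)
    if (!file.exists(p)) stop("input not found: ", name)
    p
  }
  load_pop <- function() {
    p <- if (file.exists(opts$estimates)) opts$estimates
         else final_of(opts$estimates)
    if (file.exists(p)) {
      cf <- unlist(jsonlite::read_json(p, simplifyVector = TRUE)$coef)
      fit <- list(coef = cf, config = final_model())
      class(fit) <- "hemo_fit"
      as_population(fit)
    } else default_population()
  }

  if (stage == "simulate") {
    ds <- generate_dataset(default_population(),
                           n_subjects = opts$n_subjects, seed = seed,
                           schemes_per_group = opts$schemes_per_group)
    write_dataset(ds, tmp_of(opts$dataset)); commit(opts$dataset)
  } else if (stage == "fit") {
    ds <- read_dataset(in_path(opts$dataset))
    fit <- fit_hemodynamics(ds, control = list(iter.max = opts$iter.max))
    jsonlite::write_json(list(coef = as.list(fit$coef),
                              minus2LL = fit$minus2LL,
                              shrinkage = as.list(fit$shrinkage)),
                         tmp_of(opts$estimates), auto_unbox = TRUE,
                         digits = NA)
    commit(opts$estimates)
    tab <- utils::capture.output(summary(fit))
    st <- summary(fit)
    utils::write.csv(st, tmp_of(opts$summary), row.names = FALSE)
    commit(opts$summary)
  } else if (stage == "vpc") {
    ds <- read_dataset(in_path(opts$dataset))
    v <- pcvpc(ds, load_pop(), n_sim = opts$n_sim, bins = opts$bins,
               seed = seed)
    write_vpc_csv(v, tmp_of(opts$vpc)); commit(opts$vpc)
  } else if (stage == "bootstrap") {
    ds <- read_dataset(in_path(opts$dataset))
    fit <- fit_hemodynamics(ds, control = list(iter.max = opts$iter.max))
    bt <- bootstrap_hemo(fit, n_boot = opts$n_boot, seed = seed,
                         control = list(iter.max = opts$iter.max))
    write_bootstrap_csv(bt, tmp_of(opts$bootstrap)); commit(opts$bootstrap)
  } else if (stage == "hypotension") {
    pop <- default_population()
    curves <- do.call(rbind, lapply(opts$schemes, function(s)
      simulate_risk(pop, build_scenario(s), n = opts$n, seed = seed)))
    write_risk_csv(curves, tmp_of(opts$risk)); commit(opts$risk)
  }

  log <- list(stage = stage, seed = seed,
              package_version = as.character(utils::packageVersion("hemopd")),
              config = config,
              config_hash = sum(utf8ToInt(paste(
                deparse(config[order(names(config))]), collapse = ""))),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  log_name <- paste0("log_", stage, ".json")
  jsonlite::write_json(log, tmp_of(log_name), auto_unbox = TRUE)
  commit(log_name)
  invisible(as.list(written))
}
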