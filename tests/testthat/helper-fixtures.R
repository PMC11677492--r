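# Shared fixtures, memoized so expensive objects are built once per session.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

table2_truth <- c(MAP0 = 88.2, HR0 = 70.8, kout = 0.123, C50_propo = 8.79,
                  Emax_propo = 0.88, C50_remi = 4.57, Emax_remi = 0.69,
                  gamma_remi = 1.20, FB_HR = 0.806, k_stim = 0.021,
                  theta_stim = 0.284, sigma_MAP = 5.53, sigma_HR = 4.30)

fix_pop <- function() default_population()

# a noise-bearing 12-subject study used by several estimation/diagnostic tests
fix_small_dataset <- function() memo("small_ds", {
  generate_dataset(fix_pop(), n_subjects = 12, seed = 5)
})

fix_small_fit <- function() memo("small_fit", {
  fit_hemodynamics(fix_small_dataset())
})

# typical-profile concentration inputs on a uniform grid (propofol +
# remifentanil effect-site TCI), shared across tests
fix_profiles <- function() memo("profiles", {
  grid <- seq(0, 60, by = 1 / 6)
  pkp <- pk_parameters("propofol", typical_patient())
  pkr <- pk_parameters("remifentanil", typical_patient())
  list(
    grid = grid,
    propofol = simulate_concentrations(
      pkp, tci_schedule(pkp, data.frame(time = c(0, 40), target = c(4, 0)),
                        duration = 60), grid),
    remifentanil = simulate_concentrations(
      pkr, tci_schedule(pkr, data.frame(time = c(0, 40), target = c(3, 0)),
                        duration = 60), grid))
})

constant_profile <- function(drug, times, cp, ce = cp) {
  structure(data.frame(time = times, cp = rep_len(cp, length(times)),
                       ce = rep_len(ce, length(times))),
            drug = drug, class = c("conc_profile", "data.frame"))
}
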