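# Mixed-effects estimation: empirical Bayes fits, population fits,
# likelihood-ratio testing and shrinkage.

subset_dataset <- function(ds, ids) {
  out <- ds[ds$ID %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "demographics") <- attr(ds, "demographics")
  class(out) <- class(ds)
  out
}

test_that("empirical Bayes fit recovers eta = 0 from noise-free typical data", {
  pop0 <- population_parameters(sigma_MAP = 1e-6, sigma_HR = 1e-6)
  # noise-free data simulated at the typical parameters
  popgen <- population_parameters(
    cv = list(C50_propo = 0, C50_remi = 0, MAP0 = 0, HR0 = 0,
              kout_MAP = 0, kout_HR = 0, k_stim = 0),
    cov_c50p_kout = 0, sigma_MAP = 0, sigma_HR = 0)
  # the estimation core's own discretization generates the data so the
  # check isolates the estimator (no integrator mismatch)
  ds <- generate_dataset(popgen, n_subjects = 1,
                         designs = list(generate_design("C", 1)), seed = 2,
                         sim_method = "exact")
  res <- fit_individual(subset_dataset(ds, 1), default_population(),
                        thin = 1L)
  expect_true(res$converged)
  expect_lt(max(abs(res$eta)), 1e-4)
})

test_that("empirical Bayes fit recovers a known individual's baseline within 3%", {
  pop <- default_population()
  ds <- fix_small_dataset()   # sigma at the reported residual SDs
  ind <- attr(ds, "individuals")[[1]]
  n_obs <- sum(ds$EVID == 0 & ds$ID == 1)
  expect_gte(n_obs, 120)
  res <- fit_individual(subset_dataset(ds, 1), pop)
  expect_lt(abs(res$params$MAP0 - ind$params$MAP0) / ind$params$MAP0, 0.03)
})

test_that("a flat prior reduces the fit to unpenalized least squares", {
  pop <- default_population()
  ds <- fix_small_dataset()
  d1 <- subset_dataset(ds, 2)
  flat <- fit_individual(d1, pop, flat = TRUE)
  pen <- fit_individual(d1, pop)
  # the flat-prior objective is pure weighted RSS and can only be lower
  expect_lte(flat$objective, pen$objective + 1e-6)
  # penalized objective at the mode is no worse than at eta = 0
  subj <- hemopd:::build_subject_data(d1)[[1]]
  typ <- hemopd:::params_vector(pop$typicals, final_model())
  Oi <- solve(hemopd:::pop_omega_matrix(pop))
  at0 <- hemopd:::gn_fit_eta_cpp(subj, typ, Oi, pop$sigma_MAP, pop$sigma_HR,
                                 rep(0, 7), maxit = 0L)
  expect_lte(pen$objective, at0$objective)
  expect_error(fit_individual(subset_dataset(ds, c(1, 2)), pop),
               "exactly one subject")
})

test_that("likelihood ratio test reproduces the chi-square thresholds", {
  expect_equal(likelihood_ratio_test(100, 103.84, df = 1)$p.value, 0.05,
               tolerance = 0.015)
  expect_equal(likelihood_ratio_test(100, 106.61, df = 1)$p.value, 0.01,
               tolerance = 0.015)
  expect_equal(likelihood_ratio_test(100, 100, df = 1)$p.value, 1)
  # negative deltas are clamped to zero
  expect_equal(likelihood_ratio_test(100, 99, df = 2)$p.value, 1)
  expect_error(likelihood_ratio_test(100, 103, df = 0),
               "not nested")
  expect_error(likelihood_ratio_test(100, 103), "df required")
})

test_that("shrinkage behaves at its analytic anchors", {
  set.seed(31)
  omega2 <- c(MAP0 = 0.04, HR0 = 0.09)
  etas <- cbind(MAP0 = rnorm(5000, 0, 0.2), HR0 = rnorm(5000, 0, 0.3))
  s <- shrinkage(etas, omega2)
  expect_lt(max(abs(s)), 5)
  all0 <- shrinkage(matrix(0, 10, 2,
                           dimnames = list(NULL, c("MAP0", "HR0"))), omega2)
  expect_equal(unname(all0), c(100, 100))
  expect_warning(s0 <- shrinkage(etas, c(MAP0 = 0.04, HR0 = 0)),
                 "undefined")
  expect_true(is.na(s0[["HR0"]]))
  expect_error(shrinkage(etas[1, , drop = FALSE], omega2), ">= 2 subjects")
})

test_that("population fit improves on its start and is reproducible", {
  fit <- fix_small_fit()
  expect_true(is.finite(fit$minus2LL))
  expect_equal(fit$n_subjects, 12)
  # -2LL at the optimum is below the value at the default initials
  ds <- fix_small_dataset()
  subj <- hemopd:::build_subject_data(ds)
  cf0 <- hemopd:::default_init(ds, final_model())
  m0 <- hemopd:::coef_to_model(as.list(cf0), final_model())
  init_nll <- hemopd:::pop_nll2_cpp(m0$typ, m0$Omega, m0$sigma_MAP,
                                    m0$sigma_HR, subj,
                                    matrix(0, 7, 12), 25L)$nll2
  expect_lt(fit$minus2LL, init_nll)
  # reproducible: the same data and settings give the same optimum
  refit <- fit_hemodynamics(ds)
  expect_equal(refit$minus2LL, fit$minus2LL)
  expect_equal(refit$coef, fit$coef)
  # starting at the truth cannot end materially worse than the default start
  f_truth <- fit_hemodynamics(ds, init = as.list(table2_truth),
                              control = list(iter.max = 100))
  expect_lte(f_truth$minus2LL, fit$minus2LL + 3)
})

test_that("estimating MAP-on-HR feedback is rejected", {
  ds <- fix_small_dataset()
  expect_error(fit_hemodynamics(ds, config = model_config(fb_map = TRUE)),
               "configuration error")
})

test_that("the remifentanil effect is detected by LRT when present", {
  pop <- default_population()
  designs <- lapply(1:8, function(i) generate_design("C", 1))
  ds <- generate_dataset(pop, n_subjects = 8, designs = designs, seed = 41)
  fix_common <- list(C50_remi = 4.57, gamma_remi = 1.2,
                     omega2_C50_remi = cv_to_omega2(103.7))
  full <- fit_hemodynamics(ds, fix = fix_common,
                           control = list(iter.max = 60))
  red <- fit_hemodynamics(ds, fix = c(fix_common, list(Emax_remi = 0)),
                          control = list(iter.max = 60))
  lrt <- likelihood_ratio_test(full, red, df = 1)
  expect_gt(lrt$delta, 6.61)
  expect_lt(lrt$p.value, 0.01)
  # reversed nesting declaration is refused
  expect_error(likelihood_ratio_test(red, full, df = 1), "not nested")
})

test_that("LRT false-positive rate under the null is consistent with 5%", {
  # data carry remifentanil exposure but a negligible effect; the full
  # model frees Emax_remi, the reduced model pins it at zero.  Scale:
  # 20 replicate pairs of restricted fits (other parameters fixed at
  # truth), exact binomial consistency bound for p = 0.05.
  pop_null <- population_parameters(
    typicals = hemo_params(Emax_remi = 1e-6),
    cv = list(C50_propo = 104, C50_remi = 0, MAP0 = 8.63, HR0 = 14.4,
              kout_MAP = 142.6, kout_HR = 130.2, k_stim = 100))
  n_rep <- 20; per <- 5
  designs <- lapply(seq_len(n_rep * per), function(i) generate_design("C", 1))
  big <- generate_dataset(pop_null, n_subjects = n_rep * per,
                          designs = designs, seed = 57)
  fix_all <- list(MAP0 = 88.2, HR0 = 70.8, kout = 0.123, C50_propo = 8.79,
                  Emax_propo = 0.88, C50_remi = 4.57, gamma_remi = 1.2,
                  FB_HR = 0.806, k_stim = 0.021, theta_stim = 0.284,
                  omega2_C50_propo = cv_to_omega2(104),
                  omega2_C50_remi = 1e-4,
                  omega2_MAP0 = cv_to_omega2(8.63),
                  omega2_HR0 = cv_to_omega2(14.4),
                  omega2_kout_MAP = cv_to_omega2(142.6),
                  omega2_kout_HR = cv_to_omega2(130.2),
                  corr_c50p_kout = 0.63)
  hits <- 0L
  for (r in seq_len(n_rep)) {
    ids <- ((r - 1) * per + 1):(r * per)
    dsr <- subset_dataset(big, ids)
    full <- fit_hemodynamics(dsr, fix = fix_all,
                             init = list(Emax_remi = 0.1),
                             control = list(iter.max = 40))
    red <- fit_hemodynamics(dsr, fix = c(fix_all, list(Emax_remi = 1e-9)),
                            control = list(iter.max = 40))
    lrt <- likelihood_ratio_test(red$minus2LL, full$minus2LL, df = 1)
    if (lrt$delta > 3.84) hits <- hits + 1L
  }
  # P(X >= 5 | n = 20, p = 0.05) < 0.003: reject only a clearly broken rate
  expect_lte(hits, 4L)
})
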