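# Turn-over pharmacodynamics: effect functions, stimulus, feedback,
# trajectory simulation against closed forms and an independent solver.

test_that("drug effect functions hit their analytic anchors", {
  p <- hemo_params()
  expect_equal(effect_propofol(0, p), 0)
  expect_equal(effect_propofol(8.79, p), 0.44)             # half-maximum
  expect_lt(abs(effect_propofol(1e6, p) - 0.88), 1e-4)     # asymptote
  expect_true(all(diff(effect_propofol(seq(0, 50, 0.5), p)) >= 0))
  expect_error(effect_propofol(-1, p), "invalid input")

  expect_equal(effect_remifentanil(0, p), 0)
  expect_equal(effect_remifentanil(4.57, p), 0.345)        # half-maximum
  # gamma = 1.20 steepness at twice the C50, cross-checked in log domain
  log_dom <- exp(log(0.69) + 1.2 * log(2) - log(2^1.2 + 1))
  expect_equal(effect_remifentanil(2 * 4.57, p), 0.69 * 2^1.2 / (2^1.2 + 1))
  expect_equal(effect_remifentanil(2 * 4.57, p), log_dom, tolerance = 1e-12)
  expect_error(effect_remifentanil(2, p, response = "MAP"),
               "configuration error")
  pb <- hemo_params(Emax_remi_MAP = 0.3, C50_remi_MAP = 5)
  cfgb <- model_config(remi_on_map = TRUE)
  expect_equal(effect_remifentanil(5, pb, response = "MAP", config = cfgb),
               0.15)
})

test_that("stimulus factor is 1 before onset, peaks at onset, halves at ln2/k_stim", {
  p <- hemo_params()
  ev <- stimulus_event("hysteroscopy", 10)
  expect_equal(stimulus_factor(c(0, 9.99), ev, p), c(1, 1))
  expect_equal(stimulus_factor(10, ev, p), 1.284)
  t_half <- 10 + log(2) / 0.021
  expect_equal(stimulus_factor(t_half, ev, p), 1.142)
  expect_equal(log(2) / 0.021, 33.007, tolerance = 1e-3)
  # decays monotonically back to 1 and composes multiplicatively
  tt <- seq(10, 400, 1)
  expect_true(all(diff(stimulus_factor(tt, ev, p)) <= 0))
  expect_lt(stimulus_factor(400, ev, p) - 1, 1e-3)
  two <- list(stimulus_event("hysteroscopy", 10),
              stimulus_event("hysteroscopy", 20))
  expect_equal(stimulus_factor(25, two, p),
               stimulus_factor(25, two[[1]], p) *
                 stimulus_factor(25, two[[2]], p))
  # non-surgical stimuli are inert in the final model
  expect_equal(stimulus_factor(16, stimulus_event("tetanic", 15), p), 1)
})

test_that("feedback functions are 1 at baseline and follow the power laws", {
  p <- hemo_params()
  expect_equal(feedback_hr_on_map(70.8, p), 1)
  expect_equal(feedback_hr_on_map(70.8 / 2, p), 0.5^0.806)
  expect_equal(feedback_map_on_hr(123, p), 1)  # FB_MAP = 0 in final model
  pb <- hemo_params(FB_MAP = 0.4)
  expect_equal(feedback_map_on_hr(88.2, pb), 1)
  expect_equal(feedback_map_on_hr(44.1, pb), 0.5^-0.4)
  expect_error(feedback_hr_on_map(0, p), "invalid state")
  expect_error(feedback_map_on_hr(-5, p), "invalid state")
})

test_that("derived kin values reproduce the reported inputs", {
  p <- hemo_params()
  kin <- derive_kin(p)
  expect_equal(signif(kin[["kin_MAP"]], 3), 10.8)
  expect_equal(signif(kin[["kin_HR"]], 2), 8.7)
  p0 <- hemo_params()
  p0$kout_MAP <- 0; p0$kout_HR <- 0  # degenerate bound, bypassing validation
  expect_equal(unname(derive_kin(p0)), c(0, 0))
})

test_that("baseline equilibrium holds without perturbation for arbitrary parameters", {
  set.seed(42)
  for (i in 1:5) {
    p <- hemo_params(MAP0 = runif(1, 60, 110), HR0 = runif(1, 50, 100),
                     kout_MAP = runif(1, 0.02, 0.6),
                     kout_HR = runif(1, 0.02, 0.6),
                     FB_HR = runif(1, 0.1, 1.5))
    tr <- simulate_hemodynamics(p, times = seq(0, 120, by = 1 / 6))
    expect_lt(max(abs(tr$map - p$MAP0)), 1e-6)
    expect_lt(max(abs(tr$hr - p$HR0)), 1e-6)
  }
  # Table 2 typicals stay at 88.2 mmHg exactly
  tr <- simulate_hemodynamics(hemo_params(), times = seq(0, 120, by = 1 / 6))
  expect_lt(max(abs(tr$map - 88.2)), 1e-6)
})

test_that("steady states under sustained remifentanil match the closed form", {
  p <- hemo_params()
  tt <- seq(0, 240, by = 1 / 6)
  # saturating concentration: g -> Emax = 0.69
  prof <- constant_profile("remifentanil", tt, cp = 1e6)
  tr <- simulate_hemodynamics(p, remifentanil = prof, times = tt)
  expect_equal(tail(tr$hr, 1), 70.8 * (1 - 0.69), tolerance = 1e-4)
  expect_equal(tail(tr$map, 1), 88.2 * (1 - 0.69)^0.806, tolerance = 1e-4)
  # intermediate concentration
  g <- effect_remifentanil(3, p)
  prof2 <- constant_profile("remifentanil", tt, cp = 3)
  tr2 <- simulate_hemodynamics(p, remifentanil = prof2, times = tt)
  expect_equal(tail(tr2$hr, 1), 70.8 * (1 - g), tolerance = 1e-4)
  expect_equal(tail(tr2$map, 1), 88.2 * (1 - g)^0.806, tolerance = 1e-4)
})

test_that("drug-free stimulus dynamics match the linear-ODE closed form", {
  p <- hemo_params()
  tt <- seq(0, 120, by = 1 / 6)
  on <- 10
  tr <- simulate_hemodynamics(p, times = tt,
                              events = stimulus_event("hysteroscopy", on))
  kin <- 0.123 * 88.2; ko <- 0.123; ks <- 0.021; th <- 0.284
  el <- pmax(tt - on, 0)
  ana <- 88.2 + ifelse(tt >= on,
                       kin * th * (exp(-ks * el) - exp(-ko * el)) / (ko - ks), 0)
  expect_lt(max(abs(tr$map - ana) / ana), 1e-4)
  # analytic peak time ln(kout/k_stim)/(kout - k_stim)
  t_star <- on + log(ko / ks) / (ko - ks)
  expect_lt(abs(tr$time[which.max(tr$map)] - t_star), 0.1)
  expect_true(all(tr$hr == 70.8))  # stimulus affects MAP only
})

test_that("stimulus perturbation is transient", {
  p <- hemo_params()
  tt <- seq(0, 10 + 7 / 0.021 + 5, by = 1 / 6)
  tr <- simulate_hemodynamics(p, times = tt,
                              events = stimulus_event("hysteroscopy", 10))
  back <- tt >= 10 + 7 / 0.021
  expect_true(all(abs(tr$map[back] - 88.2) / 88.2 < 0.01))
})

test_that("steady-state MAP is non-increasing in propofol and HR in remifentanil", {
  p <- hemo_params()
  tt <- seq(0, 240, by = 1 / 6)
  map_ss <- vapply(c(0, 1, 2, 4, 8, 16), function(cp) {
    tail(simulate_hemodynamics(p, propofol = constant_profile("propofol", tt, cp),
                               times = tt)$map, 1)
  }, numeric(1))
  expect_true(all(diff(map_ss) < 0))
  hr_ss <- vapply(c(0, 1, 2, 4, 8, 16), function(cr) {
    tail(simulate_hemodynamics(p, remifentanil = constant_profile("remifentanil", tt, cr),
                               times = tt)$hr, 1)
  }, numeric(1))
  expect_true(all(diff(hr_ss) < 0))
})

test_that("final-model preset reproduces the neutralized base model bit-for-bit", {
  pr <- fix_profiles()
  pb <- hemo_params(gamma_propo = 1, Emax_remi_MAP = 0, FB_MAP = 0)
  cfg_base <- model_config(remi_on_map = TRUE, fb_map = TRUE,
                           gamma_propo = TRUE)
  ev <- list(stimulus_event("hysteroscopy", 45))
  a <- simulate_hemodynamics(pb, pr$propofol, pr$remifentanil, ev,
                             config = cfg_base, times = pr$grid)
  b <- simulate_hemodynamics(pb, pr$propofol, pr$remifentanil, ev,
                             config = final_model(), times = pr$grid)
  expect_identical(a$map, b$map)
  expect_identical(a$hr, b$hr)
})

test_that("base-model terms change the trajectories in the expected direction", {
  pr <- fix_profiles()
  pb <- hemo_params(Emax_remi_MAP = 0.3, C50_remi_MAP = 4, FB_MAP = 0.3,
                    gamma_propo = 2)
  cfg <- model_config(remi_on_map = TRUE, fb_map = TRUE, gamma_propo = TRUE)
  base <- simulate_hemodynamics(pb, pr$propofol, pr$remifentanil,
                                config = cfg, times = pr$grid)
  fin <- simulate_hemodynamics(pb, pr$propofol, pr$remifentanil,
                               config = final_model(), times = pr$grid)
  # direct remifentanil-on-MAP inhibition lowers MAP further
  expect_lt(min(base$map - fin$map), 0)
  expect_true(all(base$map > 0) && all(base$hr > 0))
})

test_that("trajectories agree with an independent adaptive solver", {
  skip_if_not_installed("deSolve")
  pr <- fix_profiles()
  p <- hemo_params()
  ev <- list(stimulus_event("hysteroscopy", 30))
  tr <- simulate_hemodynamics(p, pr$propofol, pr$remifentanil, ev,
                              times = pr$grid)
  cpf <- stats::approxfun(pr$grid, pr$propofol$cp, rule = 2)
  crf <- stats::approxfun(pr$grid, pr$remifentanil$cp, rule = 2)
  rhs <- function(t, y, parms) {
    f <- 0.88 * cpf(t) / (cpf(t) + 8.79)
    g <- 0.69 * crf(t)^1.2 / (crf(t)^1.2 + 4.57^1.2)
    h <- if (t >= 30) 1 + 0.284 * exp(-0.021 * (t - 30)) else 1
    list(c(0.123 * 88.2 * (1 - f) * (y[2] / 70.8)^0.806 * h - 0.123 * y[1],
           0.123 * 70.8 * (1 - g) - 0.123 * y[2]))
  }
  ref <- deSolve::lsoda(c(88.2, 70.8), pr$grid, rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  # lsoda smooths the stimulus-onset jump; compare away from the onset node
  sel <- abs(pr$grid - 30) > 0.5
  expect_lt(max(abs(tr$map[sel] - ref[sel, 2]) / ref[sel, 2]), 1e-3)
  expect_lt(max(abs(tr$hr[sel] - ref[sel, 3]) / ref[sel, 3]), 1e-3)
})

test_that("simulation input validation and export work", {
  p <- hemo_params()
  expect_error(simulate_hemodynamics(p), "invalid input")
  tt <- seq(0, 5, by = 1 / 6)
  prof <- constant_profile("propofol", seq(0, 4, by = 1 / 6), 2)
  expect_error(simulate_hemodynamics(p, propofol = prof, times = tt),
               "does not match")
  tr <- simulate_hemodynamics(p, times = tt)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  df <- read.csv(path)
  expect_equal(df$map_mmHg, tr$map)
  expect_error(hemo_params(MAP0 = -1), "invalid input")
  expect_error(hemo_params(Emax_propo = 1.2), "invalid input")
})
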