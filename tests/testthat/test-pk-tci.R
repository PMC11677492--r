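# Covariate-adjusted pharmacokinetics and target-controlled infusion.

test_that("covariate equations give the expected typical parameters", {
  cov <- typical_patient()  # female, 43 y, 62 kg, 161 cm
  pkp <- pk_parameters("propofol", cov)
  # hand-computed from the published coefficient sets (James LBM 44.3921 kg)
  expect_equal(pkp$V1, 4.27)
  expect_equal(pkp$V2, 22.81, tolerance = 1e-10)
  expect_equal(pkp$V3, 238)
  expect_equal(pkp$CL, 1.7783993, tolerance = 1e-6)
  expect_equal(pkp$Q2, 1.53, tolerance = 1e-10)
  expect_equal(pkp$ke0, 0.456)

  pkr <- pk_parameters("remifentanil", cov)
  expect_equal(pkr$V1, 4.2759299, tolerance = 1e-6)
  expect_equal(pkr$CL, 2.3487888, tolerance = 1e-6)
  expect_equal(pkr$ke0, 0.574, tolerance = 1e-10)
})

test_that("pk_parameters is deterministic, positive on a demographic grid, and validates input", {
  for (age in c(18, 45, 80)) for (wt in c(40, 70, 100))
    for (ht in c(140, 165, 190)) for (sex in c("female", "male")) {
      cov <- patient_covariates(age, wt, ht, sex)
      for (drug in c("propofol", "remifentanil")) {
        p <- pk_parameters(drug, cov)
        vals <- unlist(p[c("V1", "V2", "V3", "CL", "Q2", "Q3", "ke0")])
        expect_true(all(vals > 0))
        p2 <- pk_parameters(drug, cov)
        expect_identical(unclass(p)[1:8], unclass(p2)[1:8])
      }
    }
  expect_error(patient_covariates(-1, 60, 160), "invalid input")
  expect_error(patient_covariates(40, 0, 160), "invalid input")
  expect_error(pk_parameters("ketamine", typical_patient()), "unsupported drug")
})

test_that("simulated concentrations are zero without dosing and superpose linearly", {
  pk <- pk_parameters("propofol", typical_patient())
  grid <- seq(0, 30, by = 1 / 6)
  empty <- simulate_concentrations(pk, infusion_schedule("propofol"), grid)
  expect_true(all(empty$cp == 0) && all(empty$ce == 0))

  sch <- infusion_schedule("propofol", times = c(0, 2, 10),
                           rates = c(100, 30, 0))
  sch2 <- infusion_schedule("propofol", times = c(0, 2, 10),
                            rates = 2 * c(100, 30, 0))
  p1 <- simulate_concentrations(pk, sch, grid)
  p2 <- simulate_concentrations(pk, sch2, grid)
  expect_equal(p2$cp, 2 * p1$cp, tolerance = 1e-12)
  expect_equal(p2$ce, 2 * p1$ce, tolerance = 1e-12)
  expect_true(all(p1$cp >= 0) && all(p1$ce >= 0))
})

test_that("bolus kinetics match the analytic tri-exponential solution", {
  pk <- pk_parameters("propofol", typical_patient())
  dose <- 100
  sch <- infusion_schedule("propofol", bolus_times = 0, bolus_amounts = dose)
  prof <- simulate_concentrations(pk, sch, seq(0, 20, by = 1 / 6))
  # independent oracle: eigendecomposition of the 3-compartment system
  k10 <- pk$CL / pk$V1; k12 <- pk$Q2 / pk$V1; k21 <- pk$Q2 / pk$V2
  k13 <- pk$Q3 / pk$V1; k31 <- pk$Q3 / pk$V3
  M <- matrix(c(-(k10 + k12 + k13), k21, k31,
                k12, -k21, 0,
                k13, 0, -k31), 3, 3, byrow = TRUE)
  e <- eigen(M)
  cp_ana <- function(t) {
    z <- solve(e$vectors) %*% c(dose, 0, 0)
    Re(e$vectors[1, ] %*% (exp(e$values * t) * z)) / pk$V1
  }
  for (t in c(1, 5, 20)) {
    i <- which.min(abs(prof$time - t))
    expect_lt(abs(prof$cp[i] - cp_ana(t)) / cp_ana(t), 0.005)
  }
})

test_that("mass is conserved when elimination clearance is zero", {
  pk <- pk_parameters("propofol", typical_patient())
  pk$CL <- 0
  sm <- hemopd:::pk_step_matrices(pk, 1 / 6)
  x <- c(0, 0, 0, 0)
  for (i in 1:60) x <- sm$E %*% x + sm$f * 60  # 60 mg/min for 10 min
  expect_equal(sum(x[1:3]), 600, tolerance = 1e-9)
})

test_that("effect site equilibrates to constant plasma at rate ke0", {
  # freeze all distribution/elimination so a bolus gives constant Cp
  pk <- pk_parameters("propofol", typical_patient())
  pk$CL <- 0; pk$Q2 <- 0; pk$Q3 <- 0
  tt <- seq(0, 15, by = 1 / 6)
  dose <- 42.7
  prof <- simulate_concentrations(
    pk, infusion_schedule("propofol", bolus_times = 0, bolus_amounts = dose),
    tt)
  expect_equal(prof$cp, rep(dose / pk$V1, length(tt)), tolerance = 1e-12)
  expect_lt(max(abs(prof$ce / prof$cp - (1 - exp(-pk$ke0 * tt)))), 1e-6)
})

test_that("plasma-mode TCI tracks a constant target within 1% after 3 min", {
  pk <- pk_parameters("remifentanil", typical_patient())
  sch <- tci_schedule(pk, data.frame(time = 0, target = 3), mode = "plasma",
                      duration = 10)
  prof <- simulate_concentrations(pk, sch, seq(0, 10, by = 1 / 6))
  expect_lt(max(abs(prof$cp[prof$time > 3] - 3)) / 3, 0.01)
  expect_true(all(sch$rates >= 0))
})

test_that("effect-site TCI reaches target faster than plasma mode without sustained overshoot", {
  for (drug in c("propofol", "remifentanil")) {
    pk <- pk_parameters(drug, typical_patient())
    tgt <- if (drug == "propofol") 4 else 3
    grid <- seq(0, 15, by = 1 / 6)
    sche <- tci_schedule(pk, data.frame(time = 0, target = tgt),
                         mode = "effect_site", duration = 15)
    schp <- tci_schedule(pk, data.frame(time = 0, target = tgt),
                         mode = "plasma", duration = 15)
    pe <- simulate_concentrations(pk, sche, grid)
    pp <- simulate_concentrations(pk, schp, grid)
    over <- pe$ce > tgt * 1.05
    expect_lte(max(rle(over)$lengths[rle(over)$values], 0), 1)
    t90 <- function(pr) pr$time[which(pr$ce >= 0.9 * tgt)[1]]
    expect_lt(t90(pe), t90(pp))
    expect_true(all(sche$rates >= 0))
  }
})

test_that("zero target produces an all-zero schedule and invalid targets error", {
  pk <- pk_parameters("propofol", typical_patient())
  sch <- tci_schedule(pk, data.frame(time = 0, target = 0), duration = 5)
  expect_true(all(sch$rates == 0))
  expect_error(tci_schedule(pk, data.frame(time = 0, target = -1),
                            duration = 5), "invalid target")
})

test_that("grid and schedule validation raise resolution errors", {
  pk <- pk_parameters("propofol", typical_patient())
  sch <- infusion_schedule("propofol", times = 0.05, rates = 10)
  expect_error(simulate_concentrations(pk, sch, seq(0, 10, by = 1 / 6)),
               "resolution error")
  sch2 <- infusion_schedule("propofol", times = 0, rates = 10)
  expect_error(simulate_concentrations(pk, sch2, seq(0, 10, by = 0.5)),
               "resolution error")
})

test_that("schedules and profiles round-trip through CSV", {
  sch <- infusion_schedule("propofol", times = c(0, 1 / 6, 2),
                           rates = c(100, 50.5, 0),
                           bolus_times = 1, bolus_amounts = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(sch, path)
  sch2 <- read_schedule_csv(path)
  expect_equal(sch2$times, sch$times)
  expect_equal(sch2$rates, sch$rates)
  expect_equal(sch2$bolus_amounts, sch$bolus_amounts)
})
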