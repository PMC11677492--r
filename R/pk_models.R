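#' Patient covariates
#'
#' Constructor and validator for the demographic covariates entering the
#' Schnider (propofol) and Minto (remifentanil) pharmacokinetic models.
#'
#' @param age Age in years (> 0).
#' @param weight Body weight in kg (> 0).
#' @param height Height in cm (> 0).
#' @param sex `"female"` or `"male"`.
#' @return An object of class `patient_covariates`.
#' @examples
#' typical_patient()
#' patient_covariates(30, 70, 175, "male")
#' @export
patient_covariates <- function(age, weight, height, sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age) || age <= 0)
    stop("invalid input: 'age' must be a single positive number")
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) || weight <= 0)
    stop("invalid input: 'weight' must be a single positive number")
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) || height <= 0)
    stop("invalid input: 'height' must be a single positive number")
  structure(list(age = age, weight = weight, height = height, sex = sex),
            class = "patient_covariates")
}

#' Typical study patient
#'
#' The typical demographic profile of the study cohort (female, 43 years,
#' 62 kg, 161 cm), used as the default for simulations.
#'
#' @return A `patient_covariates` object.
#' @export
typical_patient <- function() patient_covariates(43, 62, 161, "female")

#' James lean body mass
#'
#' @param weight kg
#' @param height cm
#' @param sex `"female"` or `"male"`
#' @return Lean body mass in kg.
#' @keywords internal
james_lbm <- function(weight, height, sex) {
  if (sex == "male") 1.1 * weight - 128 * (weight / height)^2
  else 1.07 * weight - 148 * (weight / height)^2
}

#' Covariate-adjusted pharmacokinetic parameters
#'
#' Computes the three-compartment pharmacokinetic parameters for propofol
#' (Schnider model) or remifentanil (Minto model) from patient covariates,
#' including the effect-site equilibration rate constant `ke0`.  For
#' propofol, `ke0` is fixed at 0.456 min^-1, the value programmed in the
#' study's infusion pumps; for remifentanil the published age-adjusted
#' `ke0` is used.
#'
#' @param drug `"propofol"` or `"remifentanil"`.
#' @param cov A [patient_covariates()] object.
#' @return An object of class `pk_params`: list with `drug`, volumes
#'   `V1`, `V2`, `V3` (L), clearances `CL`, `Q2`, `Q3` (L/min) and
#'   `ke0` (1/min).  Concentration units are ug/mL for propofol and
#'   ng/mL for remifentanil (mg and ug dose units respectively).
#' @examples
#' pk_parameters("propofol", typical_patient())
#' @export
pk_parameters <- function(drug = c("propofol", "remifentanil"), cov) {
  if (is.character(drug) && length(drug) == 1L &&
      !drug %in% c("propofol", "remifentanil"))
    stop("unsupported drug: ", drug)
  drug <- match.arg(drug)
  stopifnot(inherits(cov, "patient_covariates"))
  lbm <- james_lbm(cov$weight, cov$height, cov$sex)
  age <- cov$age
  if (drug == "propofol") {
    # Schnider model; time in min, doses in mg, Cp in ug/mL
    p <- list(
      drug = drug,
      V1 = 4.27,
      V2 = 18.9 - 0.391 * (age - 53),
      V3 = 238,
      CL = 1.89 + 0.0456 * (cov$weight - 77) - 0.0681 * (lbm - 59) +
        0.0264 * (cov$height - 177),
      Q2 = 1.29 - 0.024 * (age - 53),
      Q3 = 0.836,
      ke0 = 0.456
    )
  } else {
    # Minto model; time in min, doses in ug, Cp in ng/mL
    p <- list(
      drug = drug,
      V1 = 5.1 - 0.0201 * (age - 40) + 0.072 * (lbm - 55),
      V2 = 9.82 - 0.0811 * (age - 40) + 0.108 * (lbm - 55),
      V3 = 5.42,
      CL = 2.6 - 0.0162 * (age - 40) + 0.0191 * (lbm - 55),
      Q2 = 2.05 - 0.0301 * (age - 40),
      Q3 = 0.076 - 0.00113 * (age - 40),
      ke0 = 0.595 - 0.007 * (age - 40)
    )
  }
  vals <- unlist(p[c("V1", "V2", "V3", "CL", "Q2", "Q3", "ke0")])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid input: covariates yield non-positive PK parameters")
  p$covariates <- cov
  class(p) <- "pk_params"
  p
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params> %s\n", x$drug))
  cat(sprintf("  V1 %.3f  V2 %.3f  V3 %.3f L\n", x$V1, x$V2, x$V3))
  cat(sprintf("  CL %.3f  Q2 %.3f  Q3 %.3f L/min   ke0 %.3f /min\n",
              x$CL, x$Q2, x$Q3, x$ke0))
  invisible(x)
}

# Micro rate constants and the 4-state system matrix (a1, a2, a3, ce),
# where a* are compartment amounts and ce is the effect-site concentration.
pk_matrix <- function(pk) {
  k10 <- pk$CL / pk$V1; k12 <- pk$Q2 / pk$V1; k21 <- pk$Q2 / pk$V2
  k13 <- pk$Q3 / pk$V1; k31 <- pk$Q3 / pk$V3
  matrix(c(
    -(k10 + k12 + k13), k21,  k31,  0,
    k12,               -k21,  0,    0,
    k13,                0,   -k31,  0,
    pk$ke0 / pk$V1,     0,    0,   -pk$ke0), 4, 4, byrow = TRUE)
}

# Exact propagation matrices over a step of length h for piecewise-constant
# infusion: x(t+h) = E x(t) + f * rate.  Uses the augmented-matrix
# exponential so the zero-clearance (singular) case is handled exactly.
pk_step_matrices <- function(pk, h) {
  M <- pk_matrix(pk)
  aug <- rbind(cbind(M, c(1, 0, 0, 0)), 0)
  E <- as.matrix(Matrix::expm(aug * h))
  list(E = E[1:4, 1:4, drop = FALSE], f = E[1:4, 5])
}
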