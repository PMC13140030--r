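# Deterministic clinical transforms: CKD-EPI eGFR, BMI, FIB-4 and the
# banding/flag definitions the score engines consume.

#' CKD-EPI (2009) estimated glomerular filtration rate
#'
#' Serum creatinine in umol/L is converted to mg/dL (/88.4) and the 2009
#' CKD-EPI piecewise power equation applied with the published constants:
#' females 144 x (Scr/0.7)^a x 0.993^age with a = -0.329 below the 0.7 mg/dL
#' knee and -1.209 above it; males 141 x (Scr/0.9)^a x 0.993^age with
#' a = -0.411 / -1.209 around the 0.9 mg/dL knee. The race coefficient is
#' omitted by default (French cohorts do not record race) and can be enabled.
#'
#' @param creatinine_umol Serum creatinine, umol/L (> 0).
#' @param sex `"male"` or `"female"`.
#' @param age Age in years.
#' @param black Apply the 1.159 race coefficient (default `FALSE`).
#' @return eGFR in mL/min/1.73m^2; `NA` inputs propagate.
#' @export
ckd_epi_egfr <- function(creatinine_umol, sex, age, black = FALSE) {
  if (any(!is.na(creatinine_umol) & creatinine_umol <= 0))
    stop("creatinine must be positive")
  sex <- rep_len(tolower(sex), length(creatinine_umol))
  scr <- creatinine_umol / 88.4
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  lead <- ifelse(female, 144, 141)
  alpha <- ifelse(female, -0.329, -0.411)
  ratio <- scr / kappa
  egfr <- lead * pmin(ratio, 1)^alpha * pmax(ratio, 1)^-1.209 * 0.993^age
  if (black) egfr <- egfr * 1.159
  egfr
}

#' Body mass index
#' @param weight_kg Weight in kg.
#' @param height_m Height in metres (> 0).
#' @return BMI in kg/m^2.
#' @export
body_mass_index <- function(weight_kg, height_m) {
  if (any(!is.na(height_m) & height_m <= 0)) stop("height must be positive")
  weight_kg / height_m^2
}

#' FIB-4 liver fibrosis index
#'
#' age x AST / (platelets x sqrt(ALT)), all inputs strictly positive.
#'
#' @param age Years.
#' @param ast,alt Transaminases, U/L.
#' @param platelets Platelet count, 10^3/uL.
#' @return Unitless FIB-4.
#' @export
fib4 <- function(age, ast, alt, platelets) {
  vals <- cbind(age, ast, alt, platelets)
  if (any(!is.na(vals) & vals <= 0)) stop("FIB-4 inputs must be positive")
  age * ast / (platelets * sqrt(alt))
}

#' Clinical flags and bands
#'
#' Anaemia is haemoglobin < 13 g/dL for males, < 12 g/dL for females; low BMI
#' is BMI < 18.5 kg/m^2; viral suppression is HIV-1 RNA <= 50 copies/mL. CD4
#' bands are half-open on the left: [0,200), [200,350), [350,500), [500,Inf);
#' eGFR bands [0,30), [30,60), [60,Inf). Missing inputs propagate `NA` flags.
#'
#' @param hemoglobin g/dL.
#' @param sex `"male"`/`"female"`.
#' @return `anemia_flag`: logical vector.
#' @export
anemia_flag <- function(hemoglobin, sex) {
  sex <- rep_len(tolower(sex), length(hemoglobin))
  threshold <- ifelse(sex == "male", 13, 12)
  hemoglobin < threshold
}

#' @rdname anemia_flag
#' @param bmi kg/m^2.
#' @export
low_bmi_flag <- function(bmi) bmi < 18.5

#' @rdname anemia_flag
#' @param hiv_rna copies/mL.
#' @export
rna_suppressed_flag <- function(hiv_rna) hiv_rna <= 50

#' @rdname anemia_flag
#' @param cd4 cells/mm^3.
#' @export
cd4_band <- function(cd4) {
  cut(cd4, breaks = c(0, 200, 350, 500, Inf), right = FALSE,
      labels = c("<200", "200-349", "350-499", ">=500"))
}

#' @rdname anemia_flag
#' @param egfr mL/min/1.73m^2.
#' @export
egfr_band <- function(egfr) {
  cut(egfr, breaks = c(0, 30, 60, Inf), right = FALSE,
      labels = c("<30", "30-59", ">=60"))
}

#' @rdname anemia_flag
#' @param age years.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(0, 70, 75, 85, Inf), right = FALSE,
      labels = c("<70", "70-74", "75-84", ">=85"))
}

#' Attach derived covariates to a resolved baseline table
#'
#' Computes eGFR (CKD-EPI), BMI, FIB-4, albumin in g/dL (input is g/L),
#' log10 HIV-RNA, and the flags/bands above from the resolved baseline
#' analytes. Pure and idempotent.
#'
#' @param base Data frame from [resolve_baseline()] (or with compatible
#'   columns: `sex`, `age`, `creatinine`, `weight`, `height`, `ast`, `alt`,
#'   `platelets`, `hemoglobin`, `hiv_rna`, `albumin`, `cd4`).
#' @return `base` with derived columns added.
#' @export
derive_covariates <- function(base) {
  base$egfr <- ckd_epi_egfr(base$creatinine, base$sex, base$age)
  base$bmi <- body_mass_index(base$weight, base$height)
  base$fib4 <- fib4(base$age, base$ast, base$alt, base$platelets)
  base$albumin_gdl <- base$albumin / 10
  base$log10_rna <- log10(pmax(base$hiv_rna, 1))
  base$anemia <- anemia_flag(base$hemoglobin, base$sex)
  base$low_bmi <- low_bmi_flag(base$bmi)
  base$rna_suppressed <- rna_suppressed_flag(base$hiv_rna)
  base$cd4_band <- cd4_band(base$cd4)
  base$egfr_band <- egfr_band(base$egfr)
  base$age_band <- age_band(base$age)
  base
}
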