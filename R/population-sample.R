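# Elementary covariate samplers and deterministic physiological relations.
# All stochastic draws take the current RNG state; callers control seeding.

#' Sample an age from a population's age range
#'
#' Default sampling is uniform over the per-sex age range; an empirical
#' age distribution (a numeric vector of observed ages, resampled with
#' replacement) can be plugged in instead.
#'
#' @param params a [population_params] object.
#' @param sex `"male"` or `"female"`.
#' @param empirical optional numeric vector of ages to resample from
#'   (values outside the age range are rejected).
#' @return age in years.
#' @export
sample_age <- function(params, sex = c("male", "female"), empirical = NULL) {
  sex <- match.arg(sex)
  rng <- params[[sex]]$age_range
  if (any(!is.finite(rng)) || rng[2] < rng[1])
    stop("invalid age range for ", sex)
  if (is.null(empirical)) {
    if (rng[2] == rng[1]) return(rng[1])
    return(stats::runif(1L, rng[1], rng[2]))
  }
  pool <- empirical[empirical >= rng[1] & empirical <= rng[2]]
  if (!length(pool)) stop("empirical age distribution has no values in range")
  pool[sample.int(length(pool), 1L)]
}

#' Height from age by the per-sex polynomial
#'
#' BH = c0 + c1*Age + c2*Age^2 plus a zero-mean Gaussian residual
#' (SD defaults to the parameter set's per-sex `height_sd`), truncated to
#' the physiological range 130-210 cm by resampling the residual.
#'
#' @param age years.
#' @param sex `"male"` or `"female"`.
#' @param params a [population_params] object.
#' @param residual_sd residual SD in cm; `NULL` uses the per-sex default,
#'   0 disables variability.
#' @param max_retries residual resampling bound before erroring.
#' @return height in cm.
#' @export
height_from_age <- function(age, sex = c("male", "female"), params,
                            residual_sd = NULL, max_retries = 50L) {
  sex <- match.arg(sex)
  co <- params[[sex]]$height_age
  if (is.null(residual_sd)) residual_sd <- params[[sex]]$height_sd
  mu <- co[1] + co[2] * age + co[3] * age^2
  if (residual_sd == 0) {
    if (mu <= 0) stop("height polynomial evaluates non-positive at age ", age)
    return(mu)
  }
  for (i in seq_len(max_retries)) {
    bh <- mu + stats::rnorm(1L, 0, residual_sd)
    if (bh >= 130 && bh <= 210) return(bh)
  }
  stop("could not draw a height in [130, 210] cm at age ", age)
}

#' Weight from height by the exponential relation
#'
#' BW = exp(a + b * BH_cm). An optional lognormal residual (geometric CV)
#' is off by default: weight inherits its population variability through
#' the height residual.
#'
#' @param height_cm height in cm.
#' @param sex `"male"` or `"female"`.
#' @param params a [population_params] object.
#' @param residual_cv lognormal residual CV (fraction), default 0.
#' @return weight in kg.
#' @export
weight_from_height <- function(height_cm, sex = c("male", "female"), params,
                               residual_cv = 0) {
  sex <- match.arg(sex)
  stopifnot(height_cm > 0)
  ab <- params[[sex]]$weight_height
  bw <- exp(ab[1] + ab[2] * height_cm)
  if (residual_cv > 0) bw <- bw * rlnorm_mean_cv(1L, 1, residual_cv)
  bw
}

#' Sample serum creatinine for an age and sex
#'
#' Draws from a lognormal distribution parameterized by the arithmetic mean
#' and CV of the age band covering (sex, age). Bands are left-closed,
#' right-open except the last, which is closed.
#'
#' @param age years; @param sex `"male"` or `"female"`.
#' @param params a [population_params] object.
#' @param n number of draws.
#' @return serum creatinine in umol/L.
#' @export
sample_serum_creatinine <- function(age, sex = c("male", "female"), params,
                                    n = 1L) {
  sex <- match.arg(sex)
  band <- scr_band_for(params, sex, age)
  rlnorm_mean_cv(n, band$mean, band$cv)
}

scr_band_for <- function(params, sex, age) {
  sb <- params[[sex]]$scr_bands
  last <- nrow(sb)
  for (i in seq_len(last)) {
    hit <- age >= sb$age_min[i] &&
      (age < sb$age_max[i] || (i == last && age <= sb$age_max[i]))
    if (hit) return(sb[i, ])
  }
  stop(sprintf(
    "no serum-creatinine band covers %s age %.3g (bands span %g-%g)",
    sex, age, min(sb$age_min), max(sb$age_max)), call. = FALSE)
}

# lognormal draws with a given arithmetic mean and CV; cv = 0 degenerates
# to the mean.
rlnorm_mean_cv <- function(n, mean, cv) {
  stopifnot(mean > 0, cv >= 0)
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Body surface area (DuBois-DuBois)
#'
#' BSA = 0.007184 * BW^0.425 * BH^0.725.
#'
#' @param weight_kg weight in kg; @param height_cm height in cm.
#' @return BSA in m^2.
#' @export
bsa_dubois <- function(weight_kg, height_cm) {
  stopifnot(all(weight_kg > 0), all(height_cm > 0))
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Cockcroft-Gault creatinine clearance / GFR
#'
#' CLcr (mL/min) = (140 - Age) * BW / (72 * SCr[mg/dL]), multiplied by 0.85
#' for females; the normalized value is CLcr * 1.73 / BSA in
#' mL/min/1.73 m^2. Creatinine clearance is used as the GFR estimate for
#' renal-function staging.
#'
#' @param age years (< 140); @param weight_kg kg; @param scr_mg_dL serum
#'   creatinine in mg/dL (umol/L / 88.42); @param sex `"male"`/`"female"`;
#'   @param bsa m^2.
#' @return list with `gfr_abs` (mL/min) and `gfr_norm` (mL/min/1.73 m^2).
#' @export
gfr_cockcroft_gault <- function(age, weight_kg, scr_mg_dL,
                                sex = c("male", "female"), bsa) {
  sex <- match.arg(sex)
  if (age >= 140) stop("age must be < 140 years")
  stopifnot(scr_mg_dL > 0, weight_kg > 0, bsa > 0)
  clcr <- (140 - age) * weight_kg / (72 * scr_mg_dL)
  if (sex == "female") clcr <- 0.85 * clcr
  list(gfr_abs = clcr, gfr_norm = clcr * 1.73 / bsa)
}

#' Sample hematocrit, AGP and HSA for an age and sex
#'
#' Hematocrit and alpha-1-acid glycoprotein are drawn lognormal with the
#' parameter set's arithmetic mean and CV. Serum albumin is deterministic
#' in age: HSA = C0 + C1*Age + C2*(Age/10)^2 (the decade-scaled quadratic
#' keeps albumin in the physiological 35-52 g/L range over the adult ages;
#' the coefficients are echoed in the result for provenance).
#'
#' @inheritParams sample_serum_creatinine
#' @return list with `hematocrit` (fraction), `agp` (g/L), `hsa` (g/L) and
#'   `hsa_coeffs`.
#' @export
sample_blood_params <- function(age, sex = c("male", "female"), params) {
  sex <- match.arg(sex)
  p <- params[[sex]]
  hct <- rlnorm_mean_cv(1L, p$hematocrit$mean, p$hematocrit$cv) / 100
  agp <- rlnorm_mean_cv(1L, p$agp$mean, p$agp$cv)
  hsa <- p$hsa[1] + p$hsa[2] * age + p$hsa[3] * (age / 10)^2
  list(hematocrit = hct, agp = agp, hsa = hsa, hsa_coeffs = p$hsa)
}

#' Kidney volume from body size
#'
#' V (mL) = baseline + bw_coeff * BW(kg) + bh_coeff * BH(m). The category-
#' specific coefficients encode the progressive loss of renal mass with
#' chronic kidney disease.
#'
#' @param weight_kg kg; @param height_cm cm.
#' @param params a [population_params] object.
#' @return volume of both kidneys, mL.
#' @export
kidney_volume <- function(weight_kg, height_cm, params) {
  k <- params$kidney
  v <- k$baseline + k$bw_coeff * weight_kg + k$bh_coeff * (height_cm / 100)
  if (any(v <= 0)) stop("non-positive kidney volume; check coefficients")
  v
}

#' Unit conversion for serum creatinine
#'
#' 1 mg/dL = 88.42 umol/L.
#' @param x value(s) to convert.
#' @return converted value(s).
#' @export
scr_umol_to_mg <- function(x) x / 88.42

#' @rdname scr_umol_to_mg
#' @export
scr_mg_to_umol <- function(x) x * 88.42
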