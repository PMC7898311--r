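#' Population parameter sets for virtual renal-impairment cohorts
#'
#' A `population_params` object holds, per renal-function category and per
#' sex, the coefficients of the demographic and physiological equations used
#' to sample virtual subjects: the height-age polynomial, the exponential
#' weight-height relation, age-banded serum-creatinine means and coefficients
#' of variation, hematocrit and alpha-1-acid glycoprotein (AGP) lognormal
#' parameters, the human serum albumin (HSA) age polynomial, and the kidney
#' volume regression.
#'
#' @param category one of `"healthy"`, `"mild"`, `"moderate"`, `"severe"`.
#' @param label free-text description of the parameter set.
#' @param sex_ratio_f fraction of females (F/total) in the target cohort.
#' @param gfr_band numeric length-2, the normalized GFR band
#'   (mL/min/1.73 m^2) enforced on generated subjects, or `NULL` for no
#'   enforcement (healthy reference sets).
#' @param male,female per-sex parameter lists, each with elements
#'   `age_range` (years), `height_age` (c0, c1, c2; BH in cm as a polynomial
#'   in age), `height_sd` (residual SD, cm), `weight_height` (a, b with
#'   BW = exp(a + b * BH_cm)), `scr_bands` (data.frame with columns
#'   `age_min`, `age_max`, `mean` in umol/L, `cv` as a fraction),
#'   `hematocrit` (list: mean %, cv), `agp` (list: mean g/L, cv),
#'   `hsa` (C0, C1, C2; HSA in g/L = C0 + C1*Age + C2*(Age/10)^2).
#' @param kidney list with `baseline`, `bw_coeff`, `bh_coeff` for the kidney
#'   volume relation V(mL) = baseline + bw_coeff*BW(kg) + bh_coeff*BH(m),
#'   and `density_g_L`.
#' @param meta optional list of provenance metadata carried along verbatim.
#'
#' @return an object of class `population_params`.
#' @seealso [chinese_ri_params()], [generate_population()],
#'   [read_population_params()]
#' @export
population_params <- function(category, label = category, sex_ratio_f,
                              gfr_band = NULL, male, female, kidney,
                              meta = list()) {
  category <- match.arg(category, c("healthy", "mild", "moderate", "severe"))
  stopifnot(is.numeric(sex_ratio_f), length(sex_ratio_f) == 1L,
            sex_ratio_f >= 0, sex_ratio_f <= 1)
  if (!is.null(gfr_band)) {
    stopifnot(is.numeric(gfr_band), length(gfr_band) == 2L,
              gfr_band[1] > 0, gfr_band[2] > gfr_band[1])
  }
  male <- validate_sex_params(male, "male")
  female <- validate_sex_params(female, "female")
  stopifnot(is.list(kidney),
            all(c("baseline", "bw_coeff", "bh_coeff") %in% names(kidney)))
  if (is.null(kidney$density_g_L)) kidney$density_g_L <- 1050
  obj <- structure(
    list(category = category, label = label, sex_ratio_f = sex_ratio_f,
         gfr_band = gfr_band, male = male, female = female, kidney = kidney,
         meta = meta),
    class = "population_params")
  table_1_counts_warning(obj)
  obj
}

validate_sex_params <- function(p, which) {
  need <- c("age_range", "height_age", "weight_height", "scr_bands",
            "hematocrit", "agp", "hsa")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop(sprintf("missing %s parameter(s): %s", which,
                 paste(miss, collapse = ", ")), call. = FALSE)
  stopifnot(length(p$age_range) == 2L, p$age_range[1] >= 18,
            p$age_range[2] >= p$age_range[1],
            length(p$height_age) == 3L, length(p$weight_height) == 2L,
            length(p$hsa) == 3L)
  if (is.null(p$height_sd)) p$height_sd <- 0
  stopifnot(p$height_sd >= 0)
  sb <- as.data.frame(p$scr_bands)
  stopifnot(all(c("age_min", "age_max", "mean", "cv") %in% names(sb)),
            all(sb$mean > 0), all(sb$cv >= 0), all(sb$cv < 1))
  sb <- sb[order(sb$age_min), , drop = FALSE]
  if (nrow(sb) > 1L && any(sb$age_max[-nrow(sb)] > sb$age_min[-1L] + 1e-9))
    stop("serum-creatinine age bands overlap for ", which, call. = FALSE)
  p$scr_bands <- sb
  for (nm in c("hematocrit", "agp")) {
    stopifnot(p[[nm]]$mean > 0, p[[nm]]$cv >= 0, p[[nm]]$cv < 1)
  }
  p
}

#' Built-in Chinese renal impairment population parameter sets
#'
#' Returns the recalibrated system-dependent parameter set for Chinese
#' patients with mild, moderate or severe chronic kidney disease:
#' per-sex height-age polynomials, exponential weight-height relations,
#' age-banded serum creatinine (arithmetic mean and CV, sampled lognormal),
#' hematocrit and AGP lognormal parameters, HSA age coefficients, and the
#' kidney-volume regression, together with the category's normalized-GFR
#' band (mild 60-89, moderate 30-59, severe 15-29 mL/min/1.73 m^2) and the
#' observed cohort sex ratio (F/total 0.22, 0.42, 0.42).
#'
#' The printed weight-height rows of the source data are algebraically
#' usable only as BW = exp(a + b * BH_cm); that interpretation is adopted
#' here (it reproduces the observed sex-specific mean weights within ~1%).
#'
#' @param category `"mild"`, `"moderate"` or `"severe"`.
#' @return a [population_params] object.
#' @examples
#' p <- chinese_ri_params("mild")
#' p$male$height_age  # height polynomial coefficients, cm
#' @export
chinese_ri_params <- function(category = c("mild", "moderate", "severe")) {
  category <- match.arg(category)
  path <- system.file("extdata", "populations",
                      paste0(category, "_cn.yaml"), package = "renalpbpk")
  if (!nzchar(path)) stop("bundled parameter file not found")
  read_population_params(path)
}

#' Built-in healthy reference population parameter sets
#'
#' Synthetic placeholder parameter sets for healthy Chinese and healthy
#' Caucasian adults, used as reference populations and as the template for
#' [derive_caucasian_mild()]. These are plausibility-level stand-ins, not
#' fitted to any proprietary population library; the bundled files mark
#' every value as user-replaceable.
#'
#' @param ethnicity `"chinese"` or `"caucasian"`.
#' @return a [population_params] object with `gfr_band = NULL` (no
#'   containment enforcement).
#' @export
healthy_params <- function(ethnicity = c("chinese", "caucasian")) {
  ethnicity <- match.arg(ethnicity)
  fn <- if (ethnicity == "chinese") "healthy_cn.yaml" else "healthy_caucasian.yaml"
  path <- system.file("extdata", "populations", fn, package = "renalpbpk")
  if (!nzchar(path)) stop("bundled parameter file not found")
  read_population_params(path)
}

#' Derive a mild renal-impairment population from a healthy template
#'
#' Implements the serum-creatinine scaling construction of a mild
#' renal-impairment population: every serum-creatinine band mean of the
#' healthy template is multiplied by 1.5 (the ratio of the healthy to the
#' mild lower GFR cutoff, 90 vs 60 mL/min/1.73 m^2) while every other
#' demographic and physiological parameter is kept unchanged.
#'
#' Applying the function twice scales creatinine by 2.25; a provenance flag
#' (`meta$scr_scaled`) records each application so accidental re-derivation
#' is visible.
#'
#' @param healthy a [population_params] object (typically [healthy_params()]).
#' @param factor creatinine scaling factor, default 1.5.
#' @return a [population_params] object with scaled creatinine bands.
#' @export
derive_caucasian_mild <- function(healthy, factor = 1.5) {
  stopifnot(inherits(healthy, "population_params"), factor > 0)
  out <- healthy
  for (sx in c("male", "female")) {
    out[[sx]]$scr_bands$mean <- out[[sx]]$scr_bands$mean * factor
  }
  prev <- out$meta$scr_scaled
  out$meta$scr_scaled <- c(prev, factor)
  if (!is.null(prev))
    warning("serum creatinine has now been scaled more than once (factors: ",
            paste(out$meta$scr_scaled, collapse = " x "), ")")
  out$label <- paste0(out$label, " + SCr x", factor, " (derived mild RI)")
  out
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population parameter set:", x$label, "\n")
  cat("  category:    ", x$category, "\n")
  cat("  sex ratio F: ", x$sex_ratio_f, "\n")
  if (!is.null(x$gfr_band))
    cat("  GFR band:    ", x$gfr_band[1], "-", x$gfr_band[2],
        "mL/min/1.73m2\n")
  else
    cat("  GFR band:     none enforced\n")
  for (sx in c("male", "female")) {
    p <- x[[sx]]
    cat(sprintf("  %-7s ages %g-%g, %d SCr band(s)\n", sx,
                p$age_range[1], p$age_range[2], nrow(p$scr_bands)))
  }
  invisible(x)
}
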