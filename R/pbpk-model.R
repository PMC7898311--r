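# Whole-body perfusion-limited PBPK model: reference physiology, subject
# scaling, and model compilation for one subject x drug.

# Reference adult physiology (70 kg, 170 cm male): organ volumes in L and
# blood flows as fractions of cardiac output. ICRP-style reference values;
# gut and spleen drain through the portal vein into the liver.
REF_WEIGHT <- 70
REF_HEIGHT <- 170
REF_CO_L_H <- 360   # 6.0 L/min

ref_volumes <- c(lung = 0.53, adipose = 14.0, bone = 8.5, brain = 1.45,
                 gut = 1.65, heart = 0.33, kidney = 0.31, liver = 1.80,
                 muscle = 28.0, skin = 2.60, spleen = 0.19, rest = 4.00,
                 venous = 3.60, arterial = 1.80)

ref_flow_frac <- c(adipose = 0.05, bone = 0.05, brain = 0.12, gut = 0.146,
                   heart = 0.04, kidney = 0.19, liver = 0.065,
                   muscle = 0.17, skin = 0.058, spleen = 0.017,
                   rest = 0.094)  # liver = hepatic artery only

#' Subject-scaled physiology
#'
#' Scales the reference organ volumes proportionally to body weight and
#' cardiac output proportionally to body surface area. The kidney volume is
#' overridden by the subject's covariate-regression value when present.
#' Flow fractions are renormalized so that organ inflows sum exactly to
#' cardiac output.
#'
#' @param subject one row of a `virtual_population`, or `NULL` for the
#'   70-kg reference adult (hematocrit 0.45).
#' @param co_ref cardiac output of the reference adult, L/h.
#' @return list with `volumes` (L, named; includes `venous`/`arterial`
#'   blood), `flows` (L/h, named by tissue; `liver` is the hepatic artery),
#'   `co` (L/h), `v_plasma` (L), `weight` (kg), `hematocrit`.
#' @export
subject_physiology <- function(subject = NULL, co_ref = REF_CO_L_H) {
  if (is.null(subject)) {
    subject <- list(weight = REF_WEIGHT, height = REF_HEIGHT,
                    bsa = bsa_dubois(REF_WEIGHT, REF_HEIGHT),
                    hematocrit = 0.45, kidney_volume = NULL)
  }
  wt <- subject$weight
  vol <- ref_volumes * wt / REF_WEIGHT
  if (!is.null(subject$kidney_volume))
    vol["kidney"] <- subject$kidney_volume / 1000
  bsa_ref <- bsa_dubois(REF_WEIGHT, REF_HEIGHT)
  co <- co_ref * subject$bsa / bsa_ref
  frac <- ref_flow_frac / sum(ref_flow_frac)  # exact conservation
  flows <- frac * co
  hct <- subject$hematocrit
  list(volumes = vol, flows = flows, co = co,
       v_plasma = unname((vol["venous"] + vol["arterial"]) * (1 - hct)),
       weight = wt, hematocrit = hct)
}

#' Compile a PBPK model for one subject and drug
#'
#' Builds the perfusion-limited whole-body model: subject-scaled volumes
#' and flows, tissue:plasma partition coefficients predicted for the
#' subject's unbound fraction and hematocrit (with the drug's fitted Kp
#' scalar), and clearances adjusted to the subject. The renal plasma
#' clearance is scaled by the subject's normalized GFR relative to the
#' drug's reference GFR; the non-renal route is unchanged. Each systemic
#' clearance is converted to an organ-intrinsic value through the
#' well-stirred relation `CLint_b = Q * CL_b / (Q - CL_b)` so that the
#' model's dose/AUC reproduces the assigned systemic clearance exactly for
#' a linear model (elimination is drawn from the kidney and liver
#' compartments at their venous-equilibrium concentrations).
#'
#' @param subject one row of a `virtual_population` (data.frame or list),
#'   or `NULL` for the reference adult.
#' @param drug a [drug_params] object.
#' @param composition tissue composition table.
#' @param adjust_binding recompute the unbound fraction from the subject's
#'   HSA/AGP level before Kp prediction (default `TRUE` when the subject
#'   carries protein concentrations).
#' @param kpset optional precomputed `kp_set` overriding prediction.
#' @return an object of class `pbpk_model`.
#' @export
build_pbpk_model <- function(subject = NULL, drug,
                             composition = tissue_composition(),
                             adjust_binding = TRUE, kpset = NULL) {
  stopifnot(inherits(drug, "drug_params"))
  phys <- subject_physiology(subject)
  has_proteins <- !is.null(subject) &&
    all(c("hsa", "agp") %in% names(subject))
  fu <- if (adjust_binding && has_proteins) adjust_fu(drug, subject)
        else drug$fu_plasma
  drug_s <- drug
  drug_s$fu_plasma <- fu
  if (is.null(kpset))
    kpset <- predict_kp(drug_s, composition,
                        hematocrit = phys$hematocrit)
  miss <- setdiff(pbpk_tissues(), names(kpset$kp))
  if (length(miss))
    stop("Kp set lacks tissue(s): ", paste(miss, collapse = ", "))

  gfr <- if (!is.null(subject) && !is.null(subject$gfr_norm))
    subject$gfr_norm else drug$gfr_ref
  cls <- scale_renal_clearance(drug$clr, gfr, drug$gfr_ref,
                               cl_ref = drug$cl_iv)
  clr <- cls$clr
  clnr <- cls$cl_total - clr
  bp <- drug$bp_ratio
  kpb <- kpset$kp / bp  # tissue:blood

  q_ki <- phys$flows[["kidney"]]
  q_li_tot <- phys$flows[["liver"]] + phys$flows[["gut"]] +
    phys$flows[["spleen"]]
  clint_r_b <- intrinsic_from_systemic(clr / bp, q_ki, "renal")
  clint_nr_b <- intrinsic_from_systemic(clnr / bp, q_li_tot, "non-renal")

  structure(list(
    volumes = phys$volumes, flows = phys$flows, co = phys$co,
    v_plasma = phys$v_plasma, weight = phys$weight,
    hematocrit = phys$hematocrit,
    kp = kpset$kp, kp_blood = kpb, kp_method = kpset$method,
    bp_ratio = bp, fu = fu,
    cl_total = cls$cl_total, clr = clr, clnr = clnr,
    clint_r_blood = clint_r_b, clint_nr_blood = clint_nr_b,
    q_liver_total = q_li_tot,
    drug = drug$name,
    subject_id = if (!is.null(subject$id)) subject$id else NA),
    class = "pbpk_model")
}

# well-stirred conversion of a systemic blood clearance to an
# organ-intrinsic blood clearance; requires CL_b < Q.
intrinsic_from_systemic <- function(cl_b, q, label) {
  if (cl_b < 0) stop("negative ", label, " clearance")
  if (cl_b == 0) return(0)
  if (cl_b >= 0.95 * q)
    stop(label, " blood clearance (", signif(cl_b, 3),
         " L/h) approaches or exceeds organ blood flow (", signif(q, 3),
         " L/h); perfusion-limited model invalid")
  q * cl_b / (q - cl_b)
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("PBPK model: %s in subject %s\n", x$drug,
              ifelse(is.na(x$subject_id), "(reference)", x$subject_id)))
  cat(sprintf("  weight %.1f kg, CO %.0f L/h, plasma %.2f L\n",
              x$weight, x$co, x$v_plasma))
  cat(sprintf("  CL %.3f L/h (renal %.3f, non-renal %.3f); fu %.3f; B:P %.2f\n",
              x$cl_total, x$clr, x$clnr, x$fu, x$bp_ratio))
  cat(sprintf("  Kp (%s): %s\n", x$kp_method,
              paste(sprintf("%s %.3g", names(x$kp), x$kp), collapse = ", ")))
  invisible(x)
}
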