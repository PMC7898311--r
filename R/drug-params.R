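#' Drug-dependent model parameters
#'
#' Container for the physicochemical, binding and clearance parameters of
#' one compound. Clearances are systemic plasma clearances from single-IV
#' studies in healthy reference (Caucasian) adults; the renal fraction is
#' scaled to each subject's GFR while the non-renal remainder is held
#' fixed.
#'
#' @param name compound name.
#' @param mw molecular weight, g/mol.
#' @param compound_class `"neutral"`, `"monoprotic_acid"`,
#'   `"monoprotic_base"` or `"zwitterion"`.
#' @param pka acid dissociation constant(s): one value for monoprotic
#'   acid/base, `c(acid = , base = )` for zwitterions, empty for neutrals.
#' @param logp octanol:water log partition coefficient of the neutral
#'   species.
#' @param fu_plasma fraction unbound in plasma, (0, 1].
#' @param bp_ratio blood:plasma concentration ratio.
#' @param vss_obs observed steady-state volume of distribution, L/kg.
#' @param cl_iv total plasma clearance, L/h (healthy reference).
#' @param clr renal plasma clearance, L/h (healthy reference); `clr <= cl_iv`.
#' @param kp_method `"poulin_theil"` or `"rodgers_rowland"`.
#' @param kp_scalar uniform multiplier applied to all predicted Kp values
#'   (fitted so predicted Vss matches `vss_obs`, see [fit_kp_scalar()]).
#' @param binding_protein principal plasma binding protein, `"hsa"` or
#'   `"agp"`, used for unbound-fraction scaling across subjects.
#' @param gfr_ref reference GFR (mL/min) to which `clr` corresponds;
#'   default 120 (typical healthy adult).
#' @param meta provenance metadata list.
#' @return an object of class `drug_params`.
#' @export
drug_params <- function(name, mw, compound_class, pka = numeric(), logp,
                        fu_plasma, bp_ratio, vss_obs, cl_iv, clr,
                        kp_method = c("poulin_theil", "rodgers_rowland"),
                        kp_scalar = 1, binding_protein = c("hsa", "agp"),
                        gfr_ref = 120, meta = list()) {
  compound_class <- match.arg(compound_class,
                              c("neutral", "monoprotic_acid",
                                "monoprotic_base", "zwitterion"))
  kp_method <- match.arg(kp_method)
  binding_protein <- match.arg(binding_protein)
  n_pka <- switch(compound_class, neutral = 0L, zwitterion = 2L, 1L)
  if (length(pka) != n_pka)
    stop(sprintf("%s: class '%s' needs %d pKa value(s), got %d",
                 name, compound_class, n_pka, length(pka)))
  stopifnot(mw > 0, fu_plasma > 0, fu_plasma <= 1, bp_ratio > 0,
            vss_obs > 0, cl_iv > 0, clr >= 0, kp_scalar > 0, gfr_ref > 0)
  if (clr > cl_iv + 1e-9)
    stop(name, ": renal clearance exceeds total clearance")
  structure(list(name = name, mw = mw, compound_class = compound_class,
                 pka = pka, logp = logp, fu_plasma = fu_plasma,
                 bp_ratio = bp_ratio, vss_obs = vss_obs, cl_iv = cl_iv,
                 clr = clr, kp_method = kp_method, kp_scalar = kp_scalar,
                 binding_protein = binding_protein, gfr_ref = gfr_ref,
                 meta = meta),
            class = "drug_params")
}

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf("Drug: %s (MW %.1f, %s, logP %.2f)\n", x$name, x$mw,
              gsub("_", " ", x$compound_class), x$logp))
  if (length(x$pka)) cat("  pKa:       ", paste(x$pka, collapse = ", "), "\n")
  cat(sprintf("  fu %.2f, B:P %.2f, Vss(obs) %.3f L/kg\n",
              x$fu_plasma, x$bp_ratio, x$vss_obs))
  cat(sprintf("  CL %.2f L/h (renal %.2f, non-renal %.2f) at GFR %g mL/min\n",
              x$cl_iv, x$clr, x$cl_iv - x$clr, x$gfr_ref))
  cat(sprintf("  Kp: %s, scalar %.4g\n", x$kp_method, x$kp_scalar))
  if (isTRUE(x$meta$approximate) || length(x$meta))
    cat("  provenance:", x$meta$source %||% "unspecified", "\n")
  invisible(x)
}

#' Adjust the unbound plasma fraction to a subject's binding-protein level
#'
#' Linear-binding scaling: with a single binding protein P,
#' `fu_s = 1 / (1 + ((1 - fu_ref)/fu_ref) * P_subject/P_ref)`. The result
#' is monotone decreasing in the protein concentration and bounded in
#' (0, 1].
#'
#' @param drug a [drug_params] object (its `binding_protein` selects HSA or
#'   AGP).
#' @param subject one row of a `virtual_population` (needs `hsa`/`agp`).
#' @param p_ref reference protein concentration (g/L) to which
#'   `drug$fu_plasma` corresponds; defaults: HSA 45 g/L, AGP 0.75 g/L.
#' @return subject-specific fraction unbound.
#' @export
adjust_fu <- function(drug, subject, p_ref = NULL) {
  stopifnot(inherits(drug, "drug_params"))
  prot <- drug$binding_protein
  if (is.null(p_ref)) p_ref <- if (prot == "hsa") 45 else 0.75
  if (p_ref <= 0) stop("reference protein concentration must be positive")
  p_subj <- subject[[prot]]
  stopifnot(is.numeric(p_subj), p_subj > 0)
  fu <- drug$fu_plasma
  1 / (1 + ((1 - fu) / fu) * (p_subj / p_ref))
}

#' Scale renal clearance to a subject's GFR
#'
#' The renal route scales proportionally with glomerular filtration while
#' the non-renal route is left untouched:
#' `CLr_s = CLr_ref * gfr_subject / gfr_ref`;
#' `CL_s = CLr_s + (CL_ref - CLr_ref)`.
#'
#' @param clr_ref reference renal plasma clearance, L/h.
#' @param gfr_subject subject GFR, mL/min (absolute or normalized — use the
#'   same convention as `gfr_ref`).
#' @param gfr_ref reference GFR, mL/min.
#' @param cl_ref optional reference total clearance; when given the scaled
#'   total is returned too.
#' @return list with `clr` and (when `cl_ref` given) `cl_total`.
#' @export
scale_renal_clearance <- function(clr_ref, gfr_subject, gfr_ref,
                                  cl_ref = NULL) {
  if (gfr_ref <= 0) stop("reference GFR must be positive")
  if (clr_ref < 0 || gfr_subject < 0) stop("negative clearance inputs")
  clr <- clr_ref * gfr_subject / gfr_ref
  out <- list(clr = clr)
  if (!is.null(cl_ref)) {
    if (cl_ref < clr_ref) stop("total clearance below renal clearance")
    out$cl_total <- clr + (cl_ref - clr_ref)
  }
  out
}
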