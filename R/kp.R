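# Tissue:plasma partition coefficient (Kp) prediction.
#
# Two standard lipid-partitioning methods are implemented from their
# published equations: Poulin-Theil (octanol/vegetable-oil surrogate
# partitioning with unbound-fraction correction) and Rodgers-Rowland
# (ionization-explicit; acidic-phospholipid binding for moderate-to-strong
# bases, albumin or lipoprotein binding for acids, neutrals and
# zwitterions). Kp values are plasma-referenced throughout.

# Henderson-Hasselbalch ionization factor X = total/un-ionized at a pH.
ionization_X <- function(drug, pH) {
  switch(drug$compound_class,
         neutral = 1,
         monoprotic_acid = 1 + 10^(pH - drug$pka[1]),
         monoprotic_base = 1 + 10^(drug$pka[1] - pH),
         zwitterion = {
           pk <- zwitter_pka(drug)
           1 + 10^(pH - pk["acid"]) + 10^(pk["base"] - pH)
         })
}

zwitter_pka <- function(drug) {
  pk <- drug$pka
  if (is.null(names(pk)) || !all(c("acid", "base") %in% names(pk))) {
    pk <- sort(pk)
    pk <- c(acid = pk[[1]], base = pk[[2]])
  }
  pk[c("acid", "base")]
}

# cationic ionization term (for acidic-phospholipid binding)
cationic_term <- function(drug, pH) {
  switch(drug$compound_class,
         monoprotic_base = 10^(drug$pka[1] - pH),
         zwitterion = 10^(zwitter_pka(drug)["base"] - pH),
         0)
}

# does the compound carry a moderate-to-strong basic group (pKa >= 7)?
is_strong_base <- function(drug) {
  switch(drug$compound_class,
         monoprotic_base = drug$pka[1] >= 7,
         zwitterion = zwitter_pka(drug)["base"] >= 7,
         FALSE)
}

#' Predict tissue:plasma partition coefficients
#'
#' @param drug a [drug_params] object.
#' @param composition tissue composition table from [tissue_composition()].
#' @param method `"poulin_theil"` or `"rodgers_rowland"`; defaults to the
#'   drug's `kp_method`.
#' @param hematocrit reference hematocrit used when back-calculating red
#'   blood cell binding from the blood:plasma ratio (Rodgers-Rowland
#'   bases), fraction.
#' @param apply_scalar multiply the predictions by the drug's `kp_scalar`
#'   (default `TRUE`).
#' @param tissues tissue names required; an error names any tissue missing
#'   from the composition table.
#' @return a `kp_set`: list with `kp` (named vector, tissue:plasma), the
#'   `method`, and the `scalar` applied.
#' @export
predict_kp <- function(drug, composition = tissue_composition(),
                       method = NULL, hematocrit = 0.45,
                       apply_scalar = TRUE,
                       tissues = pbpk_tissues()) {
  stopifnot(inherits(drug, "drug_params"))
  method <- match.arg(method %||% drug$kp_method,
                      c("poulin_theil", "rodgers_rowland"))
  miss <- setdiff(tissues, composition$tissue)
  if (length(miss))
    stop("composition table has no entry for tissue(s): ",
         paste(miss, collapse = ", "))
  comp <- composition[match(tissues, composition$tissue), ]
  plasma <- attr(composition, "plasma")
  kp <- switch(method,
               poulin_theil = kp_poulin_theil(drug, comp, plasma),
               rodgers_rowland = kp_rodgers_rowland(drug, comp, plasma,
                                                    attr(composition, "rbc"),
                                                    hematocrit))
  names(kp) <- tissues
  if (any(!is.finite(kp)) || any(kp <= 0))
    stop("non-positive or non-finite Kp predicted; check drug inputs")
  scalar <- if (apply_scalar) drug$kp_scalar else 1
  structure(list(kp = kp * scalar, method = method, scalar = scalar,
                 drug = drug$name),
            class = "kp_set")
}

kp_poulin_theil <- function(drug, comp, plasma) {
  P <- 10^drug$logp
  fu <- drug$fu_plasma
  fut <- 1 / (1 + 0.5 * (1 - fu) / fu)
  # vegetable-oil surrogate for adipose, from logD at plasma pH
  logd74 <- drug$logp - log10(ionization_X(drug, plasma$ph))
  Dvow <- 10^(1.115 * logd74 - 1.35)
  f_w_t <- comp$f_ew + comp$f_iw
  denom_P <- P * (plasma$f_nl + 0.3 * plasma$f_np) +
    (plasma$f_w + 0.7 * plasma$f_np)
  denom_D <- Dvow * (plasma$f_nl + 0.3 * plasma$f_np) +
    (plasma$f_w + 0.7 * plasma$f_np)
  kp <- (P * (comp$f_nl + 0.3 * comp$f_np) + (f_w_t + 0.7 * comp$f_np)) /
    denom_P * (fu / fut)
  ad <- comp$tissue == "adipose"
  if (any(ad)) {
    kp[ad] <- (Dvow * (comp$f_nl[ad] + 0.3 * comp$f_np[ad]) +
                 (f_w_t[ad] + 0.7 * comp$f_np[ad])) / denom_D * (fu / 1)
  }
  kp
}

kp_rodgers_rowland <- function(drug, comp, plasma, rbc, hematocrit) {
  P <- 10^drug$logp
  fu <- drug$fu_plasma
  X_p <- ionization_X(drug, plasma$ph)
  X_iw <- ionization_X(drug, comp$ph_iw)
  lipid_t <- P * comp$f_nl + (0.3 * P + 0.7) * comp$f_np
  lipid_p <- P * plasma$f_nl + (0.3 * P + 0.7) * plasma$f_np

  if (is_strong_base(drug)) {
    # acidic-phospholipid association constant back-calculated from the
    # blood:plasma ratio via the red blood cell partition
    kpu_bc <- (drug$bp_ratio - (1 - hematocrit)) / (hematocrit * fu)
    if (kpu_bc <= 0)
      stop("blood:plasma ratio inconsistent with hematocrit ",
           "(non-positive red-cell partition)")
    X_bc <- ionization_X(drug, rbc$ph)
    lipid_bc <- P * rbc$f_nl + (0.3 * P + 0.7) * rbc$f_np
    ka_ap <- (kpu_bc - (X_bc / X_p) * rbc$f_iw - lipid_bc / X_p) *
      X_p / (rbc$ap_mg_g * cationic_term(drug, rbc$ph))
    ka_ap <- max(ka_ap, 0)
    kpu <- comp$f_ew + (X_iw / X_p) * comp$f_iw + lipid_t / X_p +
      ka_ap * comp$ap_mg_g * cationic_term(drug, comp$ph_iw) / X_p
  } else {
    # acids, weak bases, neutrals, zwitterions without a strong base:
    # protein binding extrapolated from plasma (albumin for ionizable
    # species and zwitterions, lipoprotein for neutrals)
    ka_pr_p <- max(1 / fu - 1 - lipid_p / X_p, 0)
    ratio <- if (drug$compound_class == "neutral") comp$lr else comp$ar
    kpu <- comp$f_ew + (X_iw / X_p) * comp$f_iw + lipid_t / X_p +
      ratio * ka_pr_p
  }
  kpu * fu
}

#' Tissues of the whole-body model
#' @return character vector of the twelve perfusion-limited tissue names.
#' @export
pbpk_tissues <- function() {
  c("lung", "adipose", "bone", "brain", "gut", "heart", "kidney",
    "liver", "muscle", "skin", "spleen", "rest")
}

#' @export
print.kp_set <- function(x, ...) {
  cat(sprintf("Kp set for %s (%s, scalar %.4g)\n", x$drug, x$method,
              x$scalar))
  print(round(x$kp, 4))
  invisible(x)
}

#' Steady-state volume of distribution from a Kp set
#'
#' Vss (L/kg) = (V_plasma + sum_t Kp_t * V_t) / BW over the modelled
#' tissues.
#'
#' @param kpset a `kp_set` from [predict_kp()].
#' @param physiology a physiology list from [subject_physiology()] (or the
#'   70-kg reference when omitted).
#' @return Vss in L/kg.
#' @export
compute_vss <- function(kpset, physiology = subject_physiology()) {
  stopifnot(inherits(kpset, "kp_set"))
  vt <- physiology$volumes[names(kpset$kp)]
  if (any(is.na(vt)))
    stop("physiology lacks volumes for: ",
         paste(names(kpset$kp)[is.na(vt)], collapse = ", "))
  (physiology$v_plasma + sum(kpset$kp * vt)) / physiology$weight
}

#' Fit the uniform Kp scalar to an observed Vss
#'
#' Closed form from the linearity of Vss in the partition coefficients:
#' `scalar = (Vss_obs - Vp/BW) / (Vss_pred - Vp/BW)`. Applying the scalar
#' to the Kp set and recomputing Vss returns the observed value to
#' numerical precision.
#'
#' @param kpset unscaled `kp_set`.
#' @param vss_obs observed Vss, L/kg.
#' @param physiology as in [compute_vss()].
#' @return the scalar (single positive number).
#' @export
fit_kp_scalar <- function(kpset, vss_obs, physiology = subject_physiology()) {
  vp_kg <- physiology$v_plasma / physiology$weight
  vss_pred <- compute_vss(kpset, physiology)
  if (abs(vss_pred - vp_kg) < 1e-12)
    stop("predicted Vss equals plasma volume; scalar undefined")
  s <- (vss_obs - vp_kg) / (vss_pred - vp_kg)
  if (s <= 0)
    stop("observed Vss at or below plasma volume is unphysical ",
         "(scalar would be <= 0)")
  s
}

#' Apply a scalar to a Kp set
#' @param kpset a `kp_set`; @param scalar positive multiplier.
#' @return the rescaled `kp_set` (scalar recorded cumulatively).
#' @export
scale_kp <- function(kpset, scalar) {
  stopifnot(inherits(kpset, "kp_set"), scalar > 0)
  kpset$kp <- kpset$kp * scalar
  kpset$scalar <- kpset$scalar * scalar
  kpset
}
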