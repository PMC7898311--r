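#' Tissue composition table for partition-coefficient prediction
#'
#' Fractional tissue composition (extracellular and intracellular water,
#' neutral lipids, neutral phospholipids, acidic phospholipid content, and
#' tissue:plasma albumin / lipoprotein concentration ratios) for the twelve
#' modelled tissues, plus plasma and red-blood-cell composition constants.
#' The bundled table is a literature-informed approximation of the standard
#' published adult composition data used by lipid-partitioning Kp methods;
#' it is deliberately a plain CSV so users can substitute their own.
#'
#' @param path optional path to a user CSV with the same columns
#'   (`tissue, f_ew, f_iw, f_nl, f_np, ap_mg_g, ar, lr, ph_iw`).
#' @return data.frame, one row per tissue, with attributes `plasma` and
#'   `rbc` (named lists of plasma / red-cell composition constants).
#' @export
tissue_composition <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tissue_composition.csv",
                        package = "renalpbpk")
  comp <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("tissue", "f_ew", "f_iw", "f_nl", "f_np", "ap_mg_g",
            "ar", "lr", "ph_iw")
  miss <- setdiff(need, names(comp))
  if (length(miss)) stop("composition table missing columns: ",
                         paste(miss, collapse = ", "))
  frac <- comp[c("f_ew", "f_iw", "f_nl", "f_np")]
  if (any(frac < 0) || any(frac > 1) ||
      any(rowSums(frac) > 1 + 1e-9))
    stop("tissue fractional volumes must lie in [0,1] and sum to <= 1")
  # plasma and erythrocyte constants (same provenance as the table)
  attr(comp, "plasma") <- list(f_w = 0.945, f_nl = 0.0023, f_np = 0.0013,
                               ph = 7.4)
  attr(comp, "rbc") <- list(f_iw = 0.603, f_nl = 0.0017, f_np = 0.0029,
                            ap_mg_g = 0.5, ph = 7.22)
  comp
}
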