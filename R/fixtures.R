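#' Regenerate the shipped drug and observed-data fixtures
#'
#' Writes the four drug parameter files (ceftazidime, cefodizime,
#' vancomycin, cefuroxime) and a synthetic "observed" PK table to `dir`.
#' The observed table is generated by simulating one typical subject per
#' drug and renal category with the package itself and perturbing the
#' noiseless NCA parameters with lognormal noise of CV 20%; it exists so
#' the evaluation path is exercisable without external clinical data and
#' must never be mistaken for clinical observations (the file header says
#' so).
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; regeneration with the same seed is
#'   byte-identical.
#' @param categories renal categories to include.
#' @param noise_cv lognormal noise CV for the synthetic observations.
#' @return character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L,
                          categories = c("mild", "moderate", "severe"),
                          noise_cv = 0.2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drugs <- c("ceftazidime", "cefodizime", "vancomycin", "cefuroxime")
  files <- character()
  for (d in drugs) {
    p <- file.path(dir, paste0(d, ".yaml"))
    write_drug_params(bundled_drug(d), p)
    files <- c(files, p)
  }
  set.seed(as.integer(seed))
  comp <- tissue_composition()
  rows <- list()
  for (cat in categories) {
    pop <- chinese_ri_params(cat)
    subj <- suppressWarnings(
      generate_population(pop, n = 1L, seed = seed + match(cat, categories)))
    for (d in drugs) {
      drug <- bundled_drug(d)
      model <- build_pbpk_model(subj[1, ], drug, composition = comp)
      prof <- simulate(model, doses = dose_events(500, 0, 0.5), t_end = 48,
                       dt_out = 0.1)
      pk <- nca(prof, schedule = c(0, 0.5, 1, 2, 4, 6, 8, 12, 24, 36, 48))
      for (p in c("auc_inf", "cmax", "clr")) {
        truth <- pk[[p]]
        if (is.na(truth)) next
        rows[[length(rows) + 1L]] <- data.frame(
          drug = d, category = cat, parameter = p,
          pred_noiseless = truth,
          obs = truth * rlnorm_mean_cv(1L, 1, noise_cv),
          units = switch(p, auc_inf = "mg*h/L", cmax = "mg/L", "L/h"))
      }
    }
  }
  obs <- do.call(rbind, rows)
  obs_path <- file.path(dir, "synthetic_observed_pk.csv")
  write_csv_meta(obs, obs_path,
                 meta = list(seed = seed, noise_cv = noise_cv,
                             note = paste("SYNTHETIC observations: simulator",
                                          "output perturbed with lognormal",
                                          "noise; not clinical data")))
  invisible(c(files, obs_path))
}
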