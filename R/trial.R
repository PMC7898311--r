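#' Virtual trial design
#'
#' Describes a simulated clinical study: the population to draw from, the
#' trial structure (e.g. 10 trials of 10 subjects), the IV regimen, and
#' the sampling schedule for non-compartmental analysis.
#'
#' @param population a [population_params] object.
#' @param drug a [drug_params] object.
#' @param doses a `dose_events` object ([dose_events()] / [regimen()]).
#' @param n_trials,n_per_trial trial structure (both >= 1).
#' @param sex_ratio_f optional override of the population's female ratio.
#' @param age_range optional `c(min, max)` override applied to both sexes.
#' @param schedule sampling times, h post first dose; default
#'   `c(0, 0.25, 0.5, 1, 2, 4, 6, 8, 12, 24)` (typical rich sampling for
#'   short-half-life IV antibacterials).
#' @param t_end simulation horizon, h; default covers the schedule.
#' @return a `trial_design` object.
#' @export
trial_design <- function(population, drug, doses,
                         n_trials = 10L, n_per_trial = 10L,
                         sex_ratio_f = NULL, age_range = NULL,
                         schedule = c(0, 0.25, 0.5, 1, 2, 4, 6, 8, 12, 24),
                         t_end = NULL) {
  stopifnot(inherits(population, "population_params"),
            inherits(drug, "drug_params"), inherits(doses, "dose_events"),
            n_trials >= 1, n_per_trial >= 1)
  if (!is.null(age_range)) {
    stopifnot(length(age_range) == 2L, age_range[1] <= age_range[2])
    population$male$age_range <- age_range
    population$female$age_range <- age_range
  }
  if (is.null(t_end)) t_end <- max(max(schedule),
                                   max(doses$time + doses$duration))
  structure(list(population = population, drug = drug, doses = doses,
                 n_trials = as.integer(n_trials),
                 n_per_trial = as.integer(n_per_trial),
                 sex_ratio_f = sex_ratio_f, schedule = sort(schedule),
                 t_end = t_end),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Trial design: %s in '%s'\n", x$drug$name,
              x$population$label))
  cat(sprintf("  %d trial(s) x %d subject(s); %d dose event(s); ",
              x$n_trials, x$n_per_trial, nrow(x$doses)))
  cat(sprintf("sampling to %g h\n", max(x$schedule)))
  invisible(x)
}

#' Run a virtual trial
#'
#' Generates `n_trials * n_per_trial` virtual subjects, compiles and
#' simulates the PBPK model for each, and computes per-subject NCA
#' parameters plus per-trial and overall summaries. Fully reproducible
#' given `seed`; the overall central tendency is by construction identical
#' whether the subjects are grouped as n trials of m subjects or as one
#' trial of n*m.
#'
#' @param design a [trial_design] object.
#' @param seed integer seed.
#' @param keep_profiles keep the simulated profiles in the result
#'   (default `FALSE` to save memory).
#' @param dt_out simulation output spacing, h.
#' @return a `trial_result`: list with `subjects` (the population),
#'   `pk` (per-subject NCA data.frame with `trial` column), `by_trial` and
#'   `overall` summary data.frames, and optionally `profiles`.
#' @export
run_trial <- function(design, seed = 1L, keep_profiles = FALSE,
                      dt_out = 0.05) {
  stopifnot(inherits(design, "trial_design"))
  n_tot <- design$n_trials * design$n_per_trial
  subjects <- generate_population(design$population, n = n_tot,
                                  sex_ratio_f = design$sex_ratio_f,
                                  seed = seed)
  comp <- tissue_composition()
  profiles <- if (keep_profiles) vector("list", n_tot) else NULL
  rows <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    subj <- subjects[i, ]
    model <- tryCatch(
      build_pbpk_model(subj, design$drug, composition = comp),
      error = function(e) stop("subject ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    prof <- simulate(model, doses = design$doses, t_end = design$t_end,
                     dt_out = dt_out)
    if (keep_profiles) profiles[[i]] <- prof
    row <- nca(prof, schedule = design$schedule)
    row$id <- subj$id
    row$trial <- ((i - 1L) %/% design$n_per_trial) + 1L
    rows[[i]] <- row
  }
  pk <- do.call(rbind, rows)
  params <- c("auc_inf", "auc_last", "cmax", "cl", "clr", "t_half")
  summarize <- function(df) {
    do.call(rbind, lapply(params, function(p) {
      x <- df[[p]]; x <- x[!is.na(x)]
      data.frame(parameter = p, n = length(x), mean = mean(x),
                 sd = stats::sd(x),
                 geomean = if (all(x > 0)) exp(mean(log(x))) else NA_real_,
                 p5 = unname(stats::quantile(x, 0.05)),
                 p95 = unname(stats::quantile(x, 0.95)))
    }))
  }
  by_trial <- do.call(rbind, lapply(split(pk, pk$trial), function(df) {
    s <- summarize(df); s$trial <- df$trial[1]; s
  }))
  rownames(by_trial) <- NULL
  structure(list(subjects = subjects, pk = pk, by_trial = by_trial,
                 overall = summarize(pk), profiles = profiles,
                 design = design, seed = seed),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  d <- x$design
  cat(sprintf("Trial result: %s, %d x %d subjects (seed %s)\n",
              d$drug$name, d$n_trials, d$n_per_trial, x$seed))
  print(x$overall, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.trial_result <- function(object, ...) object$overall
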