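# Structured-text I/O: YAML parameter files and CSV tables with
# metadata-comment headers. All files are plain UTF-8 text, '.' decimal.

#' Read a population parameter file
#'
#' Parses a `renalpbpk-population/1` YAML file (see the files under
#' `system.file("extdata", "populations", package = "renalpbpk")` for the
#' schema) into a [population_params] object.
#'
#' @param path file path.
#' @return a [population_params] object.
#' @export
read_population_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  if (!identical(y$schema, "renalpbpk-population/1"))
    stop(path, ": expected schema 'renalpbpk-population/1', got '",
         y$schema %||% "<none>", "'")
  sex_list <- function(p) {
    p$age_range <- as.numeric(unlist(p$age_range))
    p$height_age <- as.numeric(unlist(p$height_age))
    p$weight_height <- as.numeric(unlist(p$weight_height))
    p$hsa <- as.numeric(unlist(p$hsa))
    p$scr_bands <- do.call(rbind, lapply(p$scr_bands, as.data.frame))
    p
  }
  population_params(
    category = y$category, label = y$label %||% y$category,
    sex_ratio_f = y$sex_ratio_f,
    gfr_band = if (!is.null(y$gfr_band)) as.numeric(unlist(y$gfr_band)),
    male = sex_list(y$male), female = sex_list(y$female),
    kidney = y$kidney, meta = y$meta %||% list())
}

#' Write a population parameter file
#'
#' @param params a [population_params] object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_population_params <- function(params, path) {
  stopifnot(inherits(params, "population_params"))
  sex_out <- function(p) {
    p$scr_bands <- lapply(seq_len(nrow(p$scr_bands)),
                          function(i) as.list(p$scr_bands[i, ]))
    p
  }
  y <- list(schema = "renalpbpk-population/1",
            category = params$category, label = params$label,
            sex_ratio_f = params$sex_ratio_f, gfr_band = params$gfr_band,
            kidney = params$kidney,
            male = sex_out(params$male), female = sex_out(params$female),
            meta = params$meta)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read / write drug parameter files
#'
#' Drug files use the `renalpbpk-drug/1` YAML schema; see the bundled
#' fixtures under `system.file("extdata", "drugs", package = "renalpbpk")`.
#' The fixtures carry a `provenance` block marking every value as a
#' literature-informed approximation.
#'
#' @param path file path.
#' @return [read_drug_params()] returns a [drug_params] object.
#' @export
read_drug_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  if (!identical(y$schema, "renalpbpk-drug/1"))
    stop(path, ": expected schema 'renalpbpk-drug/1'")
  drug_params(
    name = y$name, mw = y$mw, compound_class = y$compound_class,
    pka = as.numeric(unlist(y$pka %||% numeric())), logp = y$logp,
    fu_plasma = y$fu_plasma, bp_ratio = y$bp_ratio, vss_obs = y$vss_obs,
    cl_iv = y$cl_iv, clr = y$clr, kp_method = y$kp_method,
    kp_scalar = y$kp_scalar %||% 1,
    binding_protein = y$binding_protein %||% "hsa",
    gfr_ref = y$gfr_ref %||% 120,
    meta = y$provenance %||% list())
}

#' @rdname read_drug_params
#' @param drug a [drug_params] object.
#' @export
write_drug_params <- function(drug, path) {
  stopifnot(inherits(drug, "drug_params"))
  y <- list(schema = "renalpbpk-drug/1", name = drug$name, mw = drug$mw,
            compound_class = drug$compound_class,
            pka = as.list(drug$pka), logp = drug$logp,
            fu_plasma = drug$fu_plasma, bp_ratio = drug$bp_ratio,
            vss_obs = drug$vss_obs, cl_iv = drug$cl_iv, clr = drug$clr,
            kp_method = drug$kp_method, kp_scalar = drug$kp_scalar,
            binding_protein = drug$binding_protein, gfr_ref = drug$gfr_ref,
            provenance = drug$meta)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Load a bundled drug parameter fixture
#'
#' @param name one of `"ceftazidime"`, `"cefodizime"`, `"vancomycin"`,
#'   `"cefuroxime"`.
#' @return a [drug_params] object.
#' @export
bundled_drug <- function(name = c("ceftazidime", "cefodizime",
                                  "vancomycin", "cefuroxime")) {
  name <- match.arg(name)
  path <- system.file("extdata", "drugs", paste0(name, ".yaml"),
                      package = "renalpbpk")
  if (!nzchar(path)) stop("bundled drug file not found: ", name)
  read_drug_params(path)
}

#' Write a data.frame as CSV with a metadata comment header
#'
#' Lines starting with `#` carry tool version, seed, and caller-supplied
#' metadata; the table follows in plain CSV.
#'
#' @param x data.frame.
#' @param path destination.
#' @param meta named list written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_csv_meta <- function(x, path, meta = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("renalpbpk"))
  writeLines(sprintf("# renalpbpk %s", ver), con)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(meta[[nm]]), collapse = " ")), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_csv_meta()]
#'
#' @param path file path.
#' @return data.frame with attribute `meta` (character vector of header
#'   lines, `#` stripped).
#' @export
read_csv_meta <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines)
  meta <- sub("^#\\s*", "", lines[hdr])
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                     collapse = "\n"),
                        stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
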