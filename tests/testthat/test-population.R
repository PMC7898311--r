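# Population module: covariate samplers, physiological relations, cohort
# generation and validation.

test_that("age sampling respects the range and the uniform mean", {
  p <- mild_params()
  set.seed(1)
  ages <- replicate(500, sample_age(p, "male"))
  expect_true(all(ages >= 18 & ages <= 69))

  # degenerate range is a point mass
  p40 <- p
  p40$male$age_range <- c(40, 40)
  expect_identical(sample_age(p40, "male"), 40)

  # closed-form uniform mean (18+69)/2 = 43.5
  set.seed(2)
  big <- stats::runif(1e5, 18, 69)
  expect_equal(mean(big), 43.5, tolerance = 0.2 / 43.5)

  # empirical plug-in distribution resamples the supplied pool
  expect_true(sample_age(p, "male", empirical = c(25, 25, 25)) == 25)
  expect_error(sample_age(p, "male", empirical = c(5, 10)), "no values")
})

test_that("height polynomial reproduces hand-evaluated values", {
  p <- mild_params()
  expect_equal(height_from_age(41.96, "male", p, residual_sd = 0),
               166.9716848, tolerance = 1e-9)
  expect_equal(height_from_age(42.76, "female", p, residual_sd = 0),
               157.9761398, tolerance = 1e-9)

  # constant polynomial when c1 = c2 = 0
  pc <- p
  pc$male$height_age <- c(170, 0, 0)
  for (a in c(20, 45, 68))
    expect_equal(height_from_age(a, "male", pc, residual_sd = 0), 170)

  # residual draws stay inside the truncation window
  set.seed(3)
  h <- replicate(200, height_from_age(40, "male", p))
  expect_true(all(h >= 130 & h <= 210))
})

test_that("exponential weight-height relation matches observed means", {
  p <- mild_params()
  # evaluated at the observed sex-specific mean heights
  expect_equal(weight_from_height(167.06, "male", p),
               exp(2.13 + 0.0128 * 167.06), tolerance = 1e-9)
  expect_equal(weight_from_height(167.06, "male", p), 71.07,
               tolerance = 0.01)   # within 1% of the observed male mean
  expect_equal(weight_from_height(157.67, "female", p), 58.38,
               tolerance = 0.016)  # female mean within ~2%
  # b = 0 makes weight height-independent
  pb <- p
  pb$male$weight_height <- c(log(65), 0)
  expect_equal(weight_from_height(150, "male", pb), 65)
  expect_equal(weight_from_height(190, "male", pb), 65)
})

test_that("serum creatinine bands select by age and recover their means", {
  p <- mild_params()
  # band switching at the female 50-year boundary
  set.seed(4)
  young <- mean(sample_serum_creatinine(45, "female", p, n = 2e4))
  old <- mean(sample_serum_creatinine(55, "female", p, n = 2e4))
  expect_equal(young, 93, tolerance = 0.02)
  expect_equal(old, 78, tolerance = 0.02)

  # male < 60 band arithmetic-mean recovery at 1e5 draws
  set.seed(5)
  draws <- sample_serum_creatinine(45, "male", p, n = 1e5)
  expect_equal(mean(draws), 118, tolerance = 1 / 118)
  expect_true(all(draws > 0))

  # zero CV degenerates to the band mean
  p0 <- p
  p0$male$scr_bands$cv <- 0
  expect_equal(unique(sample_serum_creatinine(30, "male", p0, n = 10)), 118)

  # out-of-band age names the gap
  p18 <- p
  p18$male$scr_bands <- p18$male$scr_bands[1, ]
  expect_error(sample_serum_creatinine(68, "male", p18),
               "no serum-creatinine band")
})

test_that("DuBois BSA and its power-law scaling", {
  expect_equal(bsa_dubois(70, 170), 1.809, tolerance = 5e-4)
  expect_equal(bsa_dubois(71.07, 167.06), 1.80, tolerance = 3e-3)
  expect_equal(bsa_dubois(140, 340) / bsa_dubois(70, 170), 2^1.15,
               tolerance = 1e-12)
})

test_that("Cockcroft-Gault clearance and normalization", {
  g <- gfr_cockcroft_gault(41.96, 71.07, 116.03 / 88.42, "male",
                           bsa = bsa_dubois(71.07, 167.06))
  expect_equal(g$gfr_abs, 73.74, tolerance = 1e-3)
  expect_gt(g$gfr_norm, 60); expect_lt(g$gfr_norm, 89)

  # inverse proportionality in creatinine; 0.85 female factor
  g2 <- gfr_cockcroft_gault(50, 70, 2, "male", bsa = 1.8)
  g3 <- gfr_cockcroft_gault(50, 70, 1, "male", bsa = 1.8)
  expect_equal(g3$gfr_abs / g2$gfr_abs, 2)
  gf <- gfr_cockcroft_gault(50, 70, 1, "female", bsa = 1.8)
  expect_equal(gf$gfr_abs, 0.85 * g3$gfr_abs)
  expect_error(gfr_cockcroft_gault(141, 70, 1, "male", bsa = 1.8), "140")
})

test_that("creatinine unit conversion round-trips to 1e-9 relative", {
  x <- c(50, 109.31, 323.34, 500)
  expect_equal(scr_mg_to_umol(scr_umol_to_mg(x)), x, tolerance = 1e-9)
  expect_equal(scr_umol_to_mg(88.42), 1)
})

test_that("blood parameters: lognormal recovery and deterministic HSA", {
  sev <- suppressWarnings(chinese_ri_params("severe"))
  set.seed(6)
  hcts <- replicate(1e4, sample_blood_params(50, "male", sev)$hematocrit)
  expect_equal(mean(hcts) * 100, 33.2, tolerance = 0.3 / 33.2)

  p0 <- mild_params()
  p0$female$agp$cv <- 0
  expect_equal(sample_blood_params(40, "female", p0)$agp, 0.575)

  # HSA constant when C1 = C2 = 0; coefficients echoed
  ph <- mild_params()
  ph$male$hsa <- c(47, 0, 0)
  b <- sample_blood_params(63, "male", ph)
  expect_equal(b$hsa, 47)
  expect_equal(b$hsa_coeffs, c(47, 0, 0))
})

test_that("kidney volume regression and its category monotonicity", {
  mi <- mild_params()
  sev <- suppressWarnings(chinese_ri_params("severe"))
  mo <- suppressWarnings(chinese_ri_params("moderate"))
  expect_equal(kidney_volume(68.05, 164.82, mi), 239.59876,
               tolerance = 1e-9)
  expect_equal(kidney_volume(62.04, 163.01, sev), 118.7986,
               tolerance = 1e-6)
  # fixed covariates: volume strictly decreases with disease severity
  v <- vapply(list(mi, mo, sev), kidney_volume,
              numeric(1), weight_kg = 65, height_cm = 165)
  expect_true(all(diff(v) < 0))
  # baseline-only coefficients
  pb <- mi; pb$kidney[c("bw_coeff", "bh_coeff")] <- list(0, 0)
  expect_equal(kidney_volume(80, 180, pb), 15.4)
})

test_that("generated cohorts satisfy their GFR band and are reproducible", {
  p <- mild_params()
  pop <- generate_population(p, n = 120, seed = 11)
  expect_equal(nrow(pop), 120)
  expect_true(all(pop$gfr_norm >= 60 & pop$gfr_norm <= 89))
  expect_true(all(pop$scr_umol_L > 0 & pop$height > 0 & pop$weight > 0))
  expect_true(all(pop$bsa > 1.0 & pop$bsa < 3.0))
  expect_equal(pop$scr_mg_dL, pop$scr_umol_L / 88.42, tolerance = 1e-12)

  # byte-identical reproducibility, and per-subject streams independent of n
  pop2 <- generate_population(p, n = 120, seed = 11)
  expect_identical(pop, pop2)
  pop3 <- generate_population(p, n = 40, seed = 11)
  for (col in c("age", "height", "weight", "scr_umol_L", "gfr_norm"))
    expect_identical(pop3[[col]], pop[[col]][1:40])

  # single subject determinism
  s1 <- generate_population(p, n = 1, seed = 7)
  s2 <- generate_population(p, n = 1, seed = 7)
  expect_identical(s1, s2)
})

test_that("category ordering of creatinine, hematocrit and AGP", {
  pops <- lapply(c("mild", "moderate", "severe"), function(ct)
    generate_population(suppressWarnings(chinese_ri_params(ct)),
                        n = 300, seed = 21))
  scr <- vapply(pops, function(x) mean(x$scr_umol_L), numeric(1))
  hct <- vapply(pops, function(x) mean(x$hematocrit), numeric(1))
  agp <- vapply(pops, function(x) mean(x$agp), numeric(1))
  expect_true(all(diff(scr) > 0))  # creatinine rises with severity
  expect_true(all(diff(hct) < 0))  # anemia of CKD
  expect_true(all(diff(agp) > 0))  # acute-phase protein rises
})

test_that("creatinine scaling derives a mild population from healthy", {
  h <- healthy_params("chinese")
  d <- derive_caucasian_mild(h)
  expect_equal(d$male$scr_bands$mean, h$male$scr_bands$mean * 1.5)
  expect_equal(d$male$scr_bands$cv, h$male$scr_bands$cv)     # CVs untouched
  expect_equal(d$male$height_age, h$male$height_age)         # rest untouched
  expect_equal(d$meta$scr_scaled, 1.5)
  # double application compounds and warns via the provenance flag
  expect_warning(dd <- derive_caucasian_mild(d), "more than once")
  expect_equal(dd$male$scr_bands$mean, h$male$scr_bands$mean * 2.25)
})

test_that("covariate validation envelopes cover same-model observations", {
  p <- mild_params()
  pop <- generate_population(p, n = 2000, seed = 31)
  # observed points drawn from the same generative model
  obs_pop <- generate_population(p, n = 400, seed = 32)
  obs <- do.call(rbind, lapply(c("height", "weight", "scr_umol_L"),
                               function(v)
                                 data.frame(age = obs_pop$age,
                                            sex = obs_pop$sex, variable = v,
                                            value = obs_pop[[v]])))
  rep <- validate_population(pop, obs)
  expect_true(all(rep$coverage[c("height", "weight", "scr_umol_L")] > 0.8))
  expect_true(all(rep$coverage[c("height", "weight", "scr_umol_L")] <= 1))
  # envelope sanity: lower <= mean <= upper in every age bin
  for (env in rep$envelopes)
    expect_true(all(env$lower <= env$mean + 1e-9 &
                      env$mean <= env$upper + 1e-9))
  # a single observation at the simulated mean lies inside
  env_h <- rep$envelopes$height
  one <- data.frame(age = env_h$age_mid[3], sex = "male",
                    variable = "height", value = env_h$mean[3])
  expect_equal(unname(validate_population(pop, one)$coverage["height"]), 1)
  # empty observed table: envelopes produced, coverage flagged NA
  rep0 <- validate_population(pop, NULL)
  expect_true(all(is.na(rep0$coverage)))
  expect_gt(nrow(rep0$envelopes$height), 0)
  # unknown covariate errors with the available names
  bad <- data.frame(age = 40, sex = "male", variable = "shoe_size",
                    value = 42)
  expect_error(validate_population(pop, bad), "shoe_size")
})
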