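# Drug model: partition-coefficient prediction, Vss, Kp scalar fitting,
# binding adjustment and clearance scaling.

test_that("drug parameter validation enforces class/pKa consistency", {
  expect_error(drug_params("x", mw = 300, compound_class = "neutral",
                           pka = 4, logp = 1, fu_plasma = 1, bp_ratio = 1,
                           vss_obs = 0.5, cl_iv = 2, clr = 1),
               "0 pKa")
  expect_error(drug_params("x", mw = 300,
                           compound_class = "monoprotic_acid", pka = 4,
                           logp = 1, fu_plasma = 1, bp_ratio = 1,
                           vss_obs = 0.5, cl_iv = 2, clr = 3),
               "exceeds total")
})

test_that("water-only partitioning limit: Kp tends to the water ratio", {
  # logP -> -inf, fu = 1: only aqueous terms survive
  d <- toy_neutral(logp = -12, fu = 1)
  comp <- tissue_composition()
  kp <- predict_kp(d, comp, method = "poulin_theil")
  f_w_t <- comp$f_ew + comp$f_iw
  expected <- f_w_t / attr(comp, "plasma")$f_w
  expect_equal(unname(kp$kp[comp$tissue]), expected, tolerance = 0.01)
  # same limit under the ionization-explicit method, which references the
  # unbound plasma concentration rather than plasma water (within ~6%)
  kp2 <- predict_kp(d, comp, method = "rodgers_rowland")
  expect_equal(unname(kp2$kp[comp$tissue]),
               f_w_t + 0.7 * comp$f_np,   # phospholipid water-equivalent
               tolerance = 1e-3)
  expect_equal(unname(kp2$kp[comp$tissue]), expected, tolerance = 0.08)
})

test_that("Henderson-Hasselbalch ionized fraction for an acid at pH 7.4", {
  d <- toy_acid(pka = 3)
  X <- renalpbpk:::ionization_X(d, 7.4)
  ionized <- (X - 1) / X
  expect_equal(ionized, 1 / (1 + 10^(3 - 7.4)), tolerance = 1e-9)
  expect_equal(ionized, 0.99996, tolerance = 1e-5)
})

test_that("the two Kp methods agree within twofold for a hydrophilic neutral unbound drug", {
  # hydrophilic: for lipophilic compounds the two methods use different
  # adipose surrogates (vegetable oil vs octanol) and diverge there
  d <- toy_neutral(logp = -2, fu = 1)
  kp_pt <- predict_kp(d, method = "poulin_theil")
  kp_rr <- predict_kp(d, method = "rodgers_rowland")
  ratio <- kp_pt$kp / kp_rr$kp
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("Kp predictions are positive for randomized valid drugs", {
  set.seed(41)
  for (i in 1:25) {
    cls <- sample(c("neutral", "monoprotic_acid", "monoprotic_base",
                    "zwitterion"), 1)
    pka <- switch(cls, neutral = numeric(),
                  monoprotic_acid = runif(1, 2, 6),
                  monoprotic_base = runif(1, 5, 10),
                  zwitterion = c(acid = runif(1, 2, 5),
                                 base = runif(1, 6, 10)))
    d <- drug_params("rand", mw = runif(1, 150, 1500),
                     compound_class = cls, pka = pka,
                     logp = runif(1, -4, 4),
                     fu_plasma = runif(1, 0.05, 1),
                     bp_ratio = runif(1, 0.6, 1.5), vss_obs = 0.5,
                     cl_iv = 5, clr = 4,
                     kp_method = sample(c("poulin_theil",
                                          "rodgers_rowland"), 1))
    kp <- predict_kp(d)
    expect_true(all(is.finite(kp$kp)) && all(kp$kp > 0))
  }
})

test_that("Vss is the Kp-weighted tissue volume sum and is linear in Kp", {
  phys <- subject_physiology()
  kp1 <- structure(list(kp = setNames(rep(1, 12), pbpk_tissues()),
                        method = "poulin_theil", scalar = 1, drug = "t"),
                   class = "kp_set")
  vtot <- (phys$v_plasma + sum(phys$volumes[pbpk_tissues()])) / phys$weight
  expect_equal(compute_vss(kp1, phys), vtot, tolerance = 1e-12)
  # doubling every Kp doubles the non-plasma part
  kp2 <- scale_kp(kp1, 2)
  vp <- phys$v_plasma / phys$weight
  expect_equal(compute_vss(kp2, phys) - vp,
               2 * (compute_vss(kp1, phys) - vp), tolerance = 1e-12)
})

test_that("fixture cephalosporin Vss lands in the class-typical range", {
  d <- bundled_drug("ceftazidime")
  kp <- predict_kp(d)  # fitted scalar applied
  vss <- compute_vss(kp)
  expect_gt(vss, 0.15); expect_lt(vss, 0.35)
})

test_that("Kp scalar: closed form and round-trip recovery", {
  # arithmetic identity on constructed numbers
  phys <- subject_physiology()
  vp <- phys$v_plasma / phys$weight
  expect_equal((0.1715 - 0.043) / (0.30 - 0.043), 0.5)

  set.seed(42)
  for (i in 1:10) {
    kp <- structure(list(kp = setNames(runif(12, 0.05, 5), pbpk_tissues()),
                         method = "poulin_theil", scalar = 1, drug = "r"),
                    class = "kp_set")
    vss_obs <- runif(1, vp + 0.02, 2)
    s <- fit_kp_scalar(kp, vss_obs, phys)
    expect_equal(compute_vss(scale_kp(kp, s), phys), vss_obs,
                 tolerance = 1e-6)
  }
  # observed Vss = predicted Vss gives scalar 1
  kp <- predict_kp(toy_neutral())
  expect_equal(fit_kp_scalar(kp, compute_vss(kp, phys), phys), 1,
               tolerance = 1e-12)
  # unphysical observed Vss (below plasma) errors
  expect_error(fit_kp_scalar(kp, vp * 0.5, phys), "unphysical")
})

test_that("unbound-fraction adjustment is bounded and monotone", {
  d <- bundled_drug("cefodizime")  # highly bound, HSA
  ref <- list(hsa = 45, agp = 0.75)
  expect_equal(adjust_fu(d, ref), d$fu_plasma, tolerance = 1e-12)
  # halved protein: fu_ref 0.5 -> 2/3 analog; check the closed form
  d5 <- d; d5$fu_plasma <- 0.5
  expect_equal(adjust_fu(d5, list(hsa = 22.5, agp = 0.75)), 2 / 3,
               tolerance = 1e-12)
  # fu_ref = 1 stays 1 whatever the protein level
  d1 <- d; d1$fu_plasma <- 1
  expect_equal(adjust_fu(d1, list(hsa = 10, agp = 0.75)), 1)
  # monotone decreasing in protein concentration, always in (0, 1]
  fus <- vapply(seq(20, 60, by = 5), function(p)
    adjust_fu(d, list(hsa = p, agp = 0.75)), numeric(1))
  expect_true(all(diff(fus) < 0))
  expect_true(all(fus > 0 & fus <= 1))
})

test_that("renal clearance scales with GFR, non-renal untouched", {
  expect_equal(scale_renal_clearance(6, 120, 120)$clr, 6)
  s <- scale_renal_clearance(6, 60, 120, cl_ref = 7)
  expect_equal(s$clr, 3)
  expect_equal(s$cl_total - s$clr, 1)  # CLnr invariant
  # fixture drug in a severe subject: CL falls to (20/120)*CLr + CLnr
  d <- bundled_drug("ceftazidime")
  s2 <- scale_renal_clearance(d$clr, 20, 120, cl_ref = d$cl_iv)
  expect_equal(s2$cl_total, (20 / 120) * d$clr + (d$cl_iv - d$clr),
               tolerance = 1e-12)
  # linearity in GFR
  g <- seq(10, 120, by = 10)
  clr <- vapply(g, function(x) scale_renal_clearance(6, x, 120)$clr,
                numeric(1))
  expect_equal(clr, 6 * g / 120, tolerance = 1e-12)
  expect_error(scale_renal_clearance(6, 60, 0), "positive")
  expect_error(scale_renal_clearance(-1, 60, 120), "negative")
})
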