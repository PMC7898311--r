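# Test fixtures built in code: tiny parameter sets with controllable
# variability, toy drugs, and hand-constructed models.

# mild-category parameters with every stochastic CV/SD forced to zero,
# so covariates are deterministic functions of (sex, age)
mild_deterministic <- function() {
  p <- suppressWarnings(chinese_ri_params("mild"))
  for (sx in c("male", "female")) {
    p[[sx]]$height_sd <- 0
    p[[sx]]$scr_bands$cv <- 0
    p[[sx]]$hematocrit$cv <- 0
    p[[sx]]$agp$cv <- 0
  }
  p
}

mild_params <- function() suppressWarnings(chinese_ri_params("mild"))

# neutral, fully unbound toy compound; useful for closed-form limits
toy_neutral <- function(logp = 1, fu = 1, bp = 1, cl = 3, clr = 2.4,
                        vss = 0.6) {
  drug_params(name = "toydrug", mw = 300, compound_class = "neutral",
              logp = logp, fu_plasma = fu, bp_ratio = bp, vss_obs = vss,
              cl_iv = cl, clr = clr, kp_method = "poulin_theil")
}

toy_acid <- function(pka = 3, logp = -1, fu = 0.8, bp = 0.6) {
  drug_params(name = "toyacid", mw = 400,
              compound_class = "monoprotic_acid", pka = pka, logp = logp,
              fu_plasma = fu, bp_ratio = bp, vss_obs = 0.25, cl_iv = 5,
              clr = 4.5, kp_method = "poulin_theil")
}

# model with all tissue:plasma Kp = 1, B:P = 1 and flows inflated so the
# body behaves as one well-stirred compartment
one_compartment_model <- function(cl = 2, flow_factor = 200) {
  drug <- toy_neutral(cl = cl, clr = cl, bp = 1, fu = 1)
  kp1 <- structure(list(kp = stats::setNames(rep(1, length(pbpk_tissues())),
                                             pbpk_tissues()),
                        method = "poulin_theil", scalar = 1,
                        drug = drug$name), class = "kp_set")
  m <- build_pbpk_model(NULL, drug, kpset = kp1)
  m$flows <- m$flows * flow_factor
  m$co <- m$co * flow_factor
  m$q_liver_total <- m$q_liver_total * flow_factor
  # re-derive intrinsic clearances for the inflated flows
  q_ki <- m$flows[["kidney"]]
  m$clint_r_blood <- q_ki * m$clr / (q_ki - m$clr)
  m$clint_nr_blood <- 0
  m
}

# analytic mono-exponential profile as a bare data.frame
monoexp_profile <- function(c0 = 10, k = 0.1, t = seq(0, 72, by = 0.05)) {
  data.frame(time = t, conc = c0 * exp(-k * t))
}
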