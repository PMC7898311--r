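#' Non-compartmental analysis of a concentration-time profile
#'
#' Computes AUC by the linear-up/log-down trapezoidal rule, the terminal
#' rate constant by unweighted log-linear regression over the terminal
#' points (the window, at least 3 points excluding Cmax, is chosen by the
#' best adjusted R-squared), and the derived parameters AUC_inf, half-life,
#' clearance and renal clearance.
#'
#' @param profile a `pbpk_profile` or data.frame with columns `time` and a
#'   concentration column (`conc_plasma` or `conc`), optionally `ae_renal`.
#' @param schedule optional sampling times (h); the profile is linearly
#'   interpolated onto it, emulating sparse clinical sampling. `NULL` uses
#'   every profile point.
#' @param dose dose amount for clearance, mg; taken from the profile
#'   attribute when present.
#' @param min_points minimum number of terminal points for the lambda-z
#'   fit.
#' @param lambda_window optional fixed vector of times to use for the
#'   lambda-z fit instead of the adjusted-R-squared search.
#' @param max_window largest trailing window size considered by the
#'   adjusted-R-squared search (keeps the search linear on dense grids).
#' @return one-row data.frame: `auc_last`, `auc_inf` (mg*h/L), `cmax`
#'   (mg/L), `tmax`, `lambda_z` (1/h), `t_half` (h), `extrap_frac`, `cl`
#'   (L/h), `clr` (L/h, NA without renal amounts), `ae_renal`; plus
#'   `lambda_z_n`, the number of points used. When no positive lambda-z
#'   can be estimated the row is flagged (`lambda_z = NA`) and
#'   extrapolation-dependent values are NA.
#' @export
nca <- function(profile, schedule = NULL, dose = NULL, min_points = 3L,
                lambda_window = NULL, max_window = 20L) {
  conc_col <- intersect(c("conc_plasma", "conc"), names(profile))[1]
  if (is.na(conc_col)) stop("profile has no concentration column")
  if (is.null(dose)) dose <- attr(profile, "dose_total")
  t_all <- profile$time
  c_all <- profile[[conc_col]]
  if (!is.null(schedule)) {
    schedule <- sort(unique(schedule))
    if (max(schedule) > max(t_all) + 1e-9)
      stop("schedule extends beyond the simulated profile")
    cs <- stats::approx(t_all, c_all, xout = schedule)$y
    t <- schedule; cc <- cs
  } else {
    t <- t_all; cc <- c_all
  }
  ae_r <- if ("ae_renal" %in% names(profile))
    profile$ae_renal[length(profile$ae_renal)] else NA_real_

  cmax <- max(cc); tmax <- t[which.max(cc)]
  auc_last <- auc_lin_log(t, cc)

  lz <- fit_lambda_z(t, cc, min_points = min_points,
                     window = lambda_window, max_window = max_window)
  clast <- rev(cc[cc > 0])[1]
  if (is.na(lz$lambda_z)) {
    auc_inf <- NA_real_; t_half <- NA_real_; extrap <- NA_real_
  } else {
    auc_inf <- auc_last + clast / lz$lambda_z
    t_half <- log(2) / lz$lambda_z
    extrap <- (auc_inf - auc_last) / auc_inf
  }
  cl <- if (!is.null(dose) && !is.na(auc_inf)) dose / auc_inf else NA_real_
  clr <- if (!is.na(ae_r) && !is.na(auc_inf)) ae_r / auc_inf else NA_real_
  data.frame(auc_last = auc_last, auc_inf = auc_inf, cmax = cmax,
             tmax = tmax, lambda_z = lz$lambda_z, t_half = t_half,
             extrap_frac = extrap, cl = cl, clr = clr, ae_renal = ae_r,
             lambda_z_n = lz$n)
}

# linear-up / log-down trapezoid
auc_lin_log <- function(t, c) {
  a <- 0
  for (i in seq_len(length(t) - 1L)) {
    dt <- t[i + 1L] - t[i]
    c1 <- c[i]; c2 <- c[i + 1L]
    a <- a + if (c2 < c1 && c2 > 0 && c1 > 0)
      dt * (c1 - c2) / log(c1 / c2)
    else dt * (c1 + c2) / 2
  }
  a
}

# terminal slope by best adjusted R^2 over trailing windows, excluding the
# Cmax point; returns lambda_z = -slope.
fit_lambda_z <- function(t, c, min_points = 3L, window = NULL,
                         max_window = 20L) {
  pos <- c > 0
  imax <- which.max(c)
  cand <- which(pos & seq_along(t) > imax)
  if (!is.null(window)) {
    idx <- which(t %in% window & pos)
    if (length(idx) < 2L) return(list(lambda_z = NA_real_, n = 0L))
    fit <- stats::lm.fit(cbind(1, t[idx]), log(c[idx]))
    lam <- -fit$coefficients[2L]
    return(list(lambda_z = if (isTRUE(lam > 0)) unname(lam) else NA_real_,
                n = length(idx)))
  }
  if (length(cand) < min_points) return(list(lambda_z = NA_real_, n = 0L))
  best <- list(lambda_z = NA_real_, n = 0L, adj_r2 = -Inf)
  for (k in seq(min_points, min(length(cand), max_window))) {
    idx <- utils::tail(cand, k)
    x <- t[idx]; y <- log(c[idx])
    fit <- stats::lm.fit(cbind(1, x), y)
    res <- fit$residuals
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    lam <- -unname(fit$coefficients[2L])
    if (is.finite(adj) && adj > best$adj_r2 && isTRUE(lam > 0))
      best <- list(lambda_z = lam, n = k, adj_r2 = adj)
  }
  best[c("lambda_z", "n")]
}
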