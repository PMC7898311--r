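# Predictive-performance metrics: fold errors with twofold / 1.25-fold
# classification, mean absolute prediction error (MAPE), and cross-model
# comparison tables.

#' Fold error of a prediction
#'
#' Ratio predicted/observed with inclusive classification flags for the
#' standard acceptance windows: within twofold (0.5 <= ratio <= 2) and
#' within 1.25-fold (0.8 <= ratio <= 1.25). Both windows are symmetric on
#' the log scale, so the classification is invariant to swapping predicted
#' and observed.
#'
#' @param pred,obs positive numeric vectors (recycled).
#' @return data.frame with `ratio`, `within_2fold`, `within_125`.
#' @export
fold_error <- function(pred, obs) {
  if (any(obs <= 0)) stop("observed values must be positive")
  if (any(pred <= 0)) stop("predicted values must be positive")
  r <- pred / obs
  data.frame(ratio = r,
             within_2fold = r >= 0.5 & r <= 2,
             within_125 = r >= 0.8 & r <= 1.25)
}

#' Mean absolute prediction error (percent)
#'
#' MAPE(%) = (1/n) * sum_i |pred_i - obs_i| * 100 / obs_i.
#'
#' @param pred,obs equal-length numeric vectors; all `obs` > 0.
#' @return MAPE in percent.
#' @export
mape <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop("pred and obs must have equal length")
  if (!length(pred)) stop("need at least one prediction")
  if (any(obs <= 0)) stop("observed values must be positive")
  mean(abs(pred - obs) * 100 / obs)
}

#' Compare predictive performance across population models
#'
#' Aggregates prediction records per population model: MAPE, fraction of
#' predictions within twofold, and fraction within 0.8-1.25-fold, sorted by
#' increasing MAPE (best model first).
#'
#' @param records data.frame with columns `model`, `pred`, `obs`
#'   (optionally `drug`, `parameter` carried through counts).
#' @return data.frame, one row per model, sorted by MAPE.
#' @export
compare_models <- function(records) {
  need <- c("model", "pred", "obs")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (length(unique(records$model)) < 2L)
    stop("need at least two population models to compare")
  out <- do.call(rbind, lapply(split(records, records$model), function(df) {
    fe <- fold_error(df$pred, df$obs)
    data.frame(model = df$model[1], n = nrow(df),
               mape = mape(df$pred, df$obs),
               frac_within_2fold = mean(fe$within_2fold),
               frac_within_125 = mean(fe$within_125))
  }))
  out <- out[order(out$mape), , drop = FALSE]
  rownames(out) <- NULL
  out
}
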