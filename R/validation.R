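# Validation rules: target-vs-observed PK parameter comparison at the 20%
# acceptance bound, and bias/imprecision metrics for whole profiles.

#' Compare observed PK parameters against their targets
#'
#' Builds the validation report used to accept or reject a rig setup:
#' percent bias `100 * (observed - target) / target` for concentrations,
#' AUCs and half-life, and absolute bias in hours for peak-time
#' (`tmax`-named) parameters, which are grid/sampling-quantized and thus
#' not meaningfully expressed in percent. A parameter passes when its
#' percent bias is within `tolerance_pct`; `tmax` rows carry the absolute
#' bias and are flagged (`pass = NA`) for the analyst's judgement.
#'
#' @param target Named numeric vector of target PK parameters.
#' @param observed Named numeric vector with matching names.
#' @param tolerance_pct Acceptance bound on |percent bias|; default 20.
#' @return A data frame of class `comparison_report` with columns
#'   `parameter`, `target`, `observed`, `bias`, `bias_type`, `pass`, plus
#'   attributes `mpe` (mean percent error over percent-type rows) and
#'   `rmse` (root mean square of those percent errors).
#' @examples
#' compare_to_target(c(auc_tau_ss = 66.9), c(auc_tau_ss = 67.1))
#' @export
compare_to_target <- function(target, observed, tolerance_pct = 20) {
  if (is.null(names(target)) || is.null(names(observed)))
    stop("target and observed must be named")
  common <- intersect(names(target), names(observed))
  if (length(common) == 0L) stop("no matching parameter names")
  target <- target[common]; observed <- observed[common]
  is_tmax <- grepl("^tmax", common, ignore.case = TRUE)
  bias <- numeric(length(common)); type <- character(length(common))
  pass <- rep(NA, length(common))
  for (k in seq_along(common)) {
    if (is_tmax[k]) {
      bias[k] <- observed[k] - target[k]
      type[k] <- "absolute_h"
    } else if (target[k] == 0) {
      bias[k] <- NA_real_
      type[k] <- "undefined_target_zero"
    } else {
      bias[k] <- 100 * (observed[k] - target[k]) / target[k]
      type[k] <- "percent"
      pass[k] <- abs(bias[k]) <= tolerance_pct
    }
  }
  out <- data.frame(parameter = common, target = unname(target),
                    observed = unname(observed), bias = bias,
                    bias_type = type, pass = pass)
  pct <- bias[type == "percent"]
  attr(out, "mpe") <- if (length(pct)) mean(pct) else NA_real_
  attr(out, "rmse") <- if (length(pct)) sqrt(mean(pct^2)) else NA_real_
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  df <- x
  df$target <- signif(df$target, 3)
  df$observed <- signif(df$observed, 3)
  df$bias <- signif(df$bias, 3)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("  overall MPE %.3g%% | RMSE %.3g%%\n",
              attr(x, "mpe"), attr(x, "rmse")))
  invisible(x)
}

#' Bias and imprecision of an expected profile against its target
#'
#' Mean percentage error (bias) and root mean squared error (imprecision,
#' in concentration units) of an expected concentration profile relative to
#' a target profile. The target is interpolated linearly onto the expected
#' time grid when the grids differ; points where the target is zero are
#' excluded from the MPE and counted.
#'
#' @param expected A [concentration_series()] (single group).
#' @param target A [concentration_series()] (single group).
#' @return List with `mpe` (percent), `rmse` (mg/L), `n` and `n_excluded`.
#' @export
profile_bias_metrics <- function(expected, target) {
  expected <- validate_concentration_series(expected)
  target <- validate_concentration_series(target)
  tgt <- approx(target$time_h, target$conc_mg_L, xout = expected$time_h,
                rule = 1)$y
  ok <- !is.na(tgt)
  e <- expected$conc_mg_L[ok]; g <- tgt[ok]
  nz <- g != 0
  list(mpe = mean(100 * (e[nz] - g[nz]) / g[nz]),
       rmse = sqrt(mean((e - g)^2)),
       n = sum(nz), n_excluded = sum(!nz) + sum(!ok))
}
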