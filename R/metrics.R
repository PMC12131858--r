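# Non-compartmental metrics computed from a sampled concentration-time
# series: per-dose Cmax/Tmax/Cmin, AUC over the dosing interval and the
# terminal half-life.

# Linear-up / log-down trapezoid over one interval of a sampled curve.
# The log rule is used on strictly decreasing segments with both ends > 0.
.auc_linlog <- function(t, c) {
  dt <- diff(t); c0 <- head(c, -1); c1 <- tail(c, -1)
  logdown <- c1 < c0 & c1 > 0 & c0 > 0
  seg <- ifelse(logdown,
                dt * (c0 - c1) / log(c0 / c1),
                dt * (c0 + c1) / 2)
  sum(seg)
}

#' Per-dose PK metrics from a sampled concentration-time series
#'
#' Computes, for each dosing interval, the maximal concentration (`cmax`),
#' its time (`tmax`, absolute, read on the sampling grid; `tmax_rel` relative
#' to the dose time), the trough at the end of the interval (`cmin`), and
#' the area under the curve over the interval (`auc_tau`, linear-up/log-down
#' trapezoid). The terminal half-life is estimated by log-linear regression
#' over all positive-concentration points after the last within-interval
#' peak (at least 3 points required) and attached as attribute
#' `"t_half"`.
#'
#' Intervals whose peak falls on the last grid point (no post-peak points)
#' have their metrics flagged in the `flag` column rather than silently
#' zeroed.
#'
#' @param series A [concentration_series()]; must contain a single
#'   compartment/replicate combination (filter first if needed).
#' @param dose_times Administration times (h).
#' @param tau Dosing interval (h).
#' @return A data frame with one row per dose and attribute `t_half`.
#' @export
pk_metrics_from_series <- function(series, dose_times, tau) {
  series <- validate_concentration_series(series)
  if (length(unique(paste(series$compartment, series$replicate))) != 1L)
    stop("series must contain exactly one (compartment, replicate) group")
  if (any(diff(dose_times) <= 0)) stop("dose_times must be increasing")
  t <- series$time_h; c <- series$conc_mg_L
  out <- lapply(seq_along(dose_times), function(j) {
    a <- dose_times[j]; b <- a + tau
    w <- t >= a & t <= b
    if (sum(w) < 2L)
      return(data.frame(dose = j, cmax = NA_real_, tmax = NA_real_,
                        tmax_rel = NA_real_, cmin = NA_real_,
                        auc_tau = NA_real_, flag = "too_few_points"))
    tt <- t[w]; cc <- c[w]
    i_max <- which.max(cc)
    flag <- if (i_max == length(cc)) "no_post_peak" else ""
    data.frame(dose = j, cmax = cc[i_max], tmax = tt[i_max],
               tmax_rel = tt[i_max] - a, cmin = cc[length(cc)],
               auc_tau = .auc_linlog(tt, cc), flag = flag)
  })
  out <- do.call(rbind, out)
  # terminal half-life from the final interval
  a <- dose_times[length(dose_times)]
  w <- t >= a & t <= a + tau
  th <- NA_real_
  if (sum(w) >= 2L) {
    tt <- t[w]; cc <- c[w]
    i_max <- which.max(cc)
    post <- seq_along(tt) > i_max & cc > 0
    if (sum(post) >= 3L) {
      fit <- lm(log(cc[post]) ~ tt[post])
      slope <- coef(fit)[2L]
      if (is.finite(slope) && slope < 0) th <- log(2) / (-slope)
    }
  }
  attr(out, "t_half") <- unname(th)
  out
}

#' Summary PK parameters in the table convention of HFIM validation reports
#'
#' Convenience wrapper extracting the first-dose and steady-state parameters
#' (`cmax_1`, `tmax_1`, `auc_tau_1`, `cmax_ss`, `tmax_ss`, `auc_tau_ss`,
#' `cmin_ss`, `t_half`) from the per-dose metrics of a series. The final
#' dosing interval is taken as steady state.
#'
#' @inheritParams pk_metrics_from_series
#' @return A named numeric vector.
#' @export
pk_summary_from_series <- function(series, dose_times, tau) {
  m <- pk_metrics_from_series(series, dose_times, tau)
  n <- nrow(m)
  c(cmax_1 = m$cmax[1L], tmax_1 = m$tmax[1L], auc_tau_1 = m$auc_tau[1L],
    cmax_ss = m$cmax[n], tmax_ss = m$tmax[n], auc_tau_ss = m$auc_tau[n],
    cmin_ss = m$cmin[n], t_half = attr(m, "t_half"))
}
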