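# Closed-form mono-compartmental PK: IV infusion and first-order absorption,
# multi-dose superposition, and the secondary parameters derived from a
# target profile.

#' Define a target PK profile for the hollow-fiber rig
#'
#' A target profile is a mono-compartmental approximation of the clinical
#' concentration-time curve to be reproduced in the rig: either an
#' intravenous zero-order infusion (`mode = "iv"`, e.g. unbound plasma) or a
#' first-order absorption profile (`mode = "absorption"`, e.g. CSF, where the
#' rise is slow and delayed).
#'
#' @param cmax1 Peak concentration after the first dose (mg/L).
#' @param ke First-order elimination rate constant (1/h).
#' @param tau Dosing interval (h).
#' @param mode `"absorption"` or `"iv"`.
#' @param ka First-order absorption rate constant (1/h); required in
#'   absorption mode. `ka == ke` is allowed (the equal-rate limit is handled
#'   explicitly).
#' @param t_infusion Infusion duration (h); required in iv mode.
#' @param n_doses Total number of doses administered.
#' @return An object of class `target_pk`.
#' @examples
#' # CSF profile of 600 mg q12h linezolid
#' target_pk(cmax1 = 4.25, ka = 0.300, ke = 0.230, tau = 12,
#'           mode = "absorption")
#' @export
target_pk <- function(cmax1, ke, tau, mode = c("absorption", "iv"),
                      ka = NULL, t_infusion = NULL, n_doses = 8L) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(cmax1), length(cmax1) == 1L, is.finite(cmax1))
  if (cmax1 <= 0) stop("cmax1 must be > 0")
  if (!is.numeric(ke) || length(ke) != 1L || ke <= 0) stop("ke must be > 0")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) stop("tau must be > 0")
  if (n_doses < 1L) stop("n_doses must be >= 1")
  if (mode == "absorption") {
    if (is.null(ka)) stop("ka is required in absorption mode")
    if (!is.numeric(ka) || length(ka) != 1L || ka <= 0) stop("ka must be > 0")
  } else {
    if (is.null(t_infusion) || t_infusion <= 0)
      stop("t_infusion (> 0) is required in iv mode")
  }
  structure(
    list(cmax1 = cmax1, ka = ka, ke = ke, tau = tau,
         t_infusion = t_infusion, n_doses = as.integer(n_doses), mode = mode),
    class = "target_pk")
}

#' @export
print.target_pk <- function(x, ...) {
  cat(sprintf("<target_pk: %s mode>\n", x$mode))
  cat(sprintf("  Cmax,1 %.3g mg/L | ke %.3g 1/h | tau %g h | %d doses\n",
              x$cmax1, x$ke, x$tau, x$n_doses))
  if (x$mode == "absorption") cat(sprintf("  ka %.3g 1/h\n", x$ka))
  else cat(sprintf("  t_infusion %g h\n", x$t_infusion))
  invisible(x)
}

# relative tolerance below which ka and ke are treated as equal
.EQUAL_RATE_RTOL <- 1e-8

#' Time of the first-dose peak of a first-order absorption model
#'
#' For a one-compartment model with first-order absorption (rate `ka`) and
#' elimination (rate `ke`), the first-dose peak occurs at
#' `tmax = ln(ka/ke) / (ka - ke)`. The removable singularity at `ka == ke`
#' is evaluated as its limit `1/ke`.
#'
#' @param ka Absorption rate constant (1/h).
#' @param ke Elimination rate constant (1/h).
#' @return Time of the peak (h).
#' @examples
#' tmax_first_dose(0.300, 0.230) # 3.80 h to 3 s.f.
#' @export
tmax_first_dose <- function(ka, ke) {
  if (!is.numeric(ka) || any(ka <= 0)) stop("ka must be > 0")
  if (!is.numeric(ke) || any(ke <= 0)) stop("ke must be > 0")
  ifelse(abs(ka - ke) < .EQUAL_RATE_RTOL * ke, 1 / ke, log(ka / ke) / (ka - ke))
}

#' Terminal half-life from the elimination rate constant
#'
#' @param ke Elimination rate constant (1/h).
#' @return `log(2) / ke` (h).
#' @examples
#' half_life(0.230) # 3.01 h
#' @export
half_life <- function(ke) {
  if (!is.numeric(ke) || any(ke <= 0)) stop("ke must be > 0")
  log(2) / ke
}

#' Number of doses needed to reach (90% of) steady state
#'
#' Uses the convention that 3.3 half-lives bring a first-order system to 90%
#' of steady state: the smallest integer `N >= 1` such that
#' `N * tau >= 3.3 * t_half`.
#'
#' @param t_half Terminal half-life (h).
#' @param tau Dosing interval (h).
#' @return Integer number of doses.
#' @examples
#' n_doses_to_steady_state(3.01, 12) # 1
#' n_doses_to_steady_state(3.65, 8)  # 2
#' @export
n_doses_to_steady_state <- function(t_half, tau) {
  if (!is.numeric(t_half) || any(t_half <= 0)) stop("t_half must be > 0")
  if (!is.numeric(tau) || any(tau <= 0)) stop("tau must be > 0")
  # small slack so an exact multiple is not pushed up by representation error
  pmax(1L, as.integer(ceiling(3.3 * t_half / tau - 1e-9)))
}

#' Accumulation ratio for repeated identical doses
#'
#' Ratio of the steady-state peak to the first-dose peak for a linear
#' one-compartment model under repeated identical administrations,
#' `Rac = 1 / (1 - exp(-ke * tau))`.
#'
#' @param ke Elimination rate constant (1/h).
#' @param tau Dosing interval (h).
#' @return Dimensionless ratio `>= 1`.
#' @examples
#' accumulation_ratio_iv(0.230, 8)  # 1.19
#' accumulation_ratio_iv(0.230, 12) # 1.07
#' @export
accumulation_ratio_iv <- function(ke, tau) {
  if (!is.numeric(ke) || any(ke <= 0)) stop("ke must be > 0")
  if (!is.numeric(tau) || any(tau <= 0)) stop("tau must be > 0")
  1 / (1 - exp(-ke * tau))
}

# Single-dose unit profile at time t >= 0 since that dose, scaled so the
# first-dose peak equals cmax1.
.single_dose_conc <- function(t, target) {
  t <- pmax(t, 0)
  if (target$mode == "absorption") {
    ka <- target$ka; ke <- target$ke
    if (abs(ka - ke) < .EQUAL_RATE_RTOL * ke) {
      # limit shape t * exp(-ke t), peak exp(-1)/ke at t = 1/ke
      target$cmax1 * t * exp(-ke * t) / (exp(-1) / ke)
    } else {
      tmax <- tmax_first_dose(ka, ke)
      scale <- target$cmax1 / (exp(-ke * tmax) - exp(-ka * tmax))
      scale * (exp(-ke * t) - exp(-ka * t))
    }
  } else {
    ke <- target$ke; tinf <- target$t_infusion
    rise <- (1 - exp(-ke * pmin(t, tinf))) / (1 - exp(-ke * tinf))
    target$cmax1 * rise * exp(-ke * pmax(t - tinf, 0))
  }
}

#' Simulate the multi-dose mono-compartmental target profile
#'
#' Superposes the closed-form single-dose solution (zero-order infusion in iv
#' mode, first-order input in absorption mode) over `target$n_doses`
#' administrations spaced `tau` apart. The single-dose curve is scaled so the
#' first-dose peak equals `cmax1`.
#'
#' @param target A [target_pk()] object.
#' @param grid Numeric vector of times (h) at which to evaluate the profile.
#' @return A [concentration_series()] with compartment `"lumped"`.
#' @examples
#' tp <- target_pk(4.25, ke = 0.230, tau = 12, ka = 0.300, n_doses = 4)
#' prof <- simulate_mono_profile(tp, seq(0, 48, by = 0.01))
#' max(prof$conc_mg_L)
#' @export
simulate_mono_profile <- function(target, grid) {
  stopifnot(inherits(target, "target_pk"))
  if (length(grid) == 0L) stop("grid is empty")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  conc <- numeric(length(grid))
  for (j in seq_len(target$n_doses)) {
    t0 <- (j - 1) * target$tau
    on <- grid >= t0
    conc[on] <- conc[on] + .single_dose_conc(grid[on] - t0, target)
  }
  concentration_series(time_h = grid, conc_mg_L = conc,
                       compartment = "lumped", replicate = "sim")
}

#' Secondary (derived) PK parameters of a target profile
#'
#' Computes the half-life, first-dose peak time, number of doses to steady
#' state, accumulation ratio and the steady-state peak/trough of the target
#' model. Steady-state quantities are read off a dense simulation of the
#' multi-dose superposition continued to at least `3.3` half-lives.
#'
#' @param target A [target_pk()] object.
#' @param grid_step Simulation step (h) used for the steady-state read-off.
#' @return A list of class `derived_pk` with elements `t_half`, `tmax1`,
#'   `n_dose_to_ss`, `rac`, `cmax_ss`, `cmin_ss`, `tmax_ss`.
#' @export
derived_pk <- function(target, grid_step = 0.01) {
  stopifnot(inherits(target, "target_pk"))
  t_half <- half_life(target$ke)
  tmax1 <- if (target$mode == "absorption")
    tmax_first_dose(target$ka, target$ke) else target$t_infusion
  n_ss <- n_doses_to_steady_state(t_half, target$tau)
  # simulate far past steady state so the last interval is converged
  n_sim <- max(target$n_doses, 10L * n_ss)
  sim_target <- target; sim_target$n_doses <- n_sim
  grid <- seq(0, n_sim * target$tau, by = grid_step)
  prof <- simulate_mono_profile(sim_target, grid)
  last <- prof$time_h >= (n_sim - 1L) * target$tau
  cmax_ss <- max(prof$conc_mg_L[last])
  tmax_ss <- prof$time_h[last][which.max(prof$conc_mg_L[last])] -
    (n_sim - 1L) * target$tau
  cmin_ss <- prof$conc_mg_L[length(prof$time_h)]
  structure(list(t_half = t_half, tmax1 = tmax1, n_dose_to_ss = n_ss,
                 rac = cmax_ss / target$cmax1, cmax_ss = cmax_ss,
                 cmin_ss = cmin_ss, tmax_ss = tmax_ss),
            class = "derived_pk")
}

#' @export
print.derived_pk <- function(x, ...) {
  cat("<derived_pk>\n")
  cat(sprintf("  t1/2 %.3g h | Tmax,1 %.3g h | N_dose %d | Rac %.3g\n",
              x$t_half, x$tmax1, x$n_dose_to_ss, x$rac))
  cat(sprintf("  Cmax,ss %.3g mg/L | Cmin,ss %.3g mg/L | Tmax,ss %.3g h\n",
              x$cmax_ss, x$cmin_ss, x$tmax_ss))
  invisible(x)
}

#' Concentration-time series container
#'
#' A plain data frame (columns `time_h`, `conc_mg_L`, `compartment`,
#' `replicate`) carrying observed or simulated concentration-time data.
#' Times must be strictly increasing within each (compartment, replicate)
#' group and concentrations non-negative.
#'
#' @param time_h Sampling times (h).
#' @param conc_mg_L Concentrations (mg/L).
#' @param compartment Compartment label: `"central"`, `"ICS"`, `"ECS"` or
#'   `"lumped"` (recycled).
#' @param replicate Replicate identifier (recycled).
#' @return A data frame of class `concentration_series`.
#' @export
concentration_series <- function(time_h, conc_mg_L,
                                 compartment = "lumped", replicate = "r1") {
  df <- data.frame(time_h = as.numeric(time_h),
                   conc_mg_L = as.numeric(conc_mg_L),
                   compartment = as.character(compartment),
                   replicate = as.character(replicate),
                   stringsAsFactors = FALSE)
  validate_concentration_series(df)
}

validate_concentration_series <- function(df) {
  need <- c("time_h", "conc_mg_L", "compartment", "replicate")
  if (!all(need %in% names(df)))
    stop("concentration series needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$time_h))) stop("non-finite times")
  if (any(df$conc_mg_L < 0)) stop("negative concentrations")
  by_grp <- split(df$time_h, paste(df$compartment, df$replicate, sep = "\r"))
  ok <- vapply(by_grp, function(tt) !is.unsorted(tt, strictly = TRUE), logical(1))
  if (!all(ok))
    stop("times must be strictly increasing within each (compartment, replicate)")
  class(df) <- c("concentration_series", "data.frame")
  df
}
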