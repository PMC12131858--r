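# Convert a first-order-absorption target into a quantized ambulatory-pump
# program (a series of piecewise-constant infusions delivering equal
# amounts), size the dilution pump that mimics elimination, and design the
# short-infusion setup for IV-profile mode.

#' Round half-up to a resolution
#'
#' Plain `round()` uses round-half-to-even; pump programming uses the
#' commercial half-up rule. `x` is rounded to the nearest multiple of
#' `resolution`, ties away from zero.
#'
#' @param x Numeric vector.
#' @param resolution Positive grid size.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, resolution = 1) {
  if (resolution <= 0) stop("resolution must be > 0")
  floor(x / resolution + 0.5 + 1e-12) * resolution
}

# Stepwise (digit-by-digit) half-up rounding: the value is first rounded to
# two decimal sub-divisions of the resolution, then one, then to the
# resolution itself. Successive display-precision rounding of this kind is
# what pump-program worksheets effectively apply, and it is the rule that
# reproduces published whole-minute programs (e.g. 18.468 min -> 18.47 ->
# 18.5 -> 19).
round_stepwise <- function(x, resolution = 1) {
  for (f in c(100, 10, 1)) x <- round_half_up(x, resolution / f)
  x
}

#' Dose that achieves a given first-dose peak under first-order absorption
#'
#' Inverts the one-compartment first-order absorption model: the dose (mg)
#' such that the first-dose peak concentration in a well-mixed volume
#' `v_total` equals `cmax1`,
#' `Dose = cmax1 * v_total * (ka - ke) / (F * ka * (exp(-ke*tmax) - exp(-ka*tmax)))`
#' with `tmax` from [tmax_first_dose()]. The equal-rate limit gives
#' `Dose = cmax1 * v_total * e / F`.
#'
#' @param cmax1 Target first-dose peak (mg/L).
#' @param ka,ke Absorption and elimination rate constants (1/h).
#' @param v_total Well-mixed distribution volume of the rig (L); by design
#'   the central reservoir plus the cartridge ECS.
#' @param F Bioavailability fraction in (0, 1]; the rig delivers the full
#'   dose so the default is 1.
#' @return Dose in mg.
#' @examples
#' compute_dose(4.25, 0.300, 0.230, 0.360) # ~3.66 mg
#' @export
compute_dose <- function(cmax1, ka, ke, v_total, F = 1) {
  if (!is.numeric(F) || F <= 0 || F > 1) stop("F must be in (0, 1]")
  if (ka <= 0 || ke <= 0) stop("rates must be > 0")
  if (v_total <= 0) stop("v_total must be > 0")
  if (cmax1 < 0) stop("cmax1 must be >= 0")
  if (abs(ka - ke) < .EQUAL_RATE_RTOL * ke)
    return(cmax1 * v_total * exp(1) / F)
  tmax <- tmax_first_dose(ka, ke)
  cmax1 * v_total * (ka - ke) / (F * ka * (exp(-ke * tmax) - exp(-ka * tmax)))
}

#' Fraction of the dose delivered by the end of the last sub-interval
#'
#' The sub-interval scheme truncates the exponentially decaying absorption
#' input at `t_n`, so only `f_dose = 1 - exp(-ka * t_n)` of the nominal dose
#' is ever infused; the remainder is the price of finishing the program
#' within the dosing interval.
#'
#' @param ka Absorption rate constant (1/h).
#' @param t_n End time of the last sub-interval (h).
#' @return Fraction in (0, 1).
#' @examples
#' floor(100 * compute_fdose(0.300, 12)) # 97 (%)
#' floor(100 * compute_fdose(0.300, 8))  # 90 (%)
#' @export
compute_fdose <- function(ka, t_n) {
  if (ka <= 0 || t_n <= 0) stop("ka and t_n must be > 0")
  1 - exp(-ka * t_n)
}

#' Raw (unquantized) sub-interval infusion schedule
#'
#' Splits the first-order absorption input into `n` consecutive constant-rate
#' infusions that each deliver the same amount `Dose * f_dose / n`. Their end
#' times are `t_i = -log(1 - f_dose * i / n) / ka`, so the cumulative amount
#' delivered by `t_i` equals the cumulative absorption
#' `Dose * (1 - exp(-ka * t_i))` exactly; rates follow as amount over
#' duration. Durations grow strictly with the sub-interval index.
#'
#' @param dose Nominal dose (mg), usually from [compute_dose()].
#' @param ka Absorption rate constant (1/h).
#' @param n Number of sub-intervals (>= 2).
#' @param t_n End time of the last sub-interval (h), normally the dosing
#'   interval.
#' @return A data frame (class `hfim_schedule`) with columns `index`,
#'   `t_start`, `t_end`, `duration_h`, `rate_mg_h`, `amount_mg` and
#'   attributes `f_dose`, `dose`, `ka`, `t_n`.
#' @export
build_schedule <- function(dose, ka, n, t_n) {
  if (n < 2L) stop("n must be >= 2")
  if (dose <= 0) stop("dose must be > 0")
  f_dose <- compute_fdose(ka, t_n)
  i <- 0:n
  t_i <- -log(1 - f_dose * i / n) / ka
  t_i[n + 1L] <- t_n  # exact by construction; avoid rounding drift
  amounts_left <- dose * exp(-ka * t_i)       # A_i
  per <- dose * f_dose / n
  dur <- diff(t_i)
  rate <- -diff(amounts_left) / dur           # S_i
  out <- data.frame(index = 1:n, t_start = head(t_i, -1), t_end = tail(t_i, -1),
                    duration_h = dur, rate_mg_h = rate, amount_mg = per)
  attr(out, "f_dose") <- f_dose
  attr(out, "dose") <- dose
  attr(out, "ka") <- ka
  attr(out, "t_n") <- t_n
  class(out) <- c("hfim_schedule", "data.frame")
  out
}

#' Infusion-solution concentration for a target per-sub-interval volume
#'
#' The infusion solution is prepared so that the volume pushed during each
#' sub-interval is as close as possible to `target_volume` (the smallest
#' volume the ambulatory pump injects with good precision), i.e.
#' `c_infusion = amount per sub-interval / target_volume`.
#'
#' @param schedule A schedule from [build_schedule()].
#' @param target_volume Per-sub-interval volume (mL); default 2 mL.
#' @return Concentration in mg/mL.
#' @export
select_infusion_concentration <- function(schedule, target_volume = 2) {
  if (target_volume <= 0) stop("target_volume must be > 0")
  amt <- schedule$amount_mg[1L]
  if (!is.finite(amt) || amt <= 0) stop("schedule has non-positive amounts")
  amt / target_volume
}

#' Quantize a raw schedule to the pump's programmable grid
#'
#' Flow rates `S_i / c_infusion` are rounded half-up to `flow_resolution`;
#' durations (in minutes) are rounded to `duration_resolution` either in a
#' single step (`duration_rounding = "single"`) or digit-by-digit
#' (`"stepwise"`, the default: 0.01 min, then 0.1 min, then the resolution).
#' Stepwise rounding mirrors successive display-precision rounding in
#' program worksheets and reproduces published whole-minute pump programs
#' whose centiminute values sit just below the half-way point.
#'
#' The nominal per-sub-interval amount is kept in `amount_mg`; the amount
#' the quantized program actually delivers (`flow * duration * c_infusion`)
#' is reported separately in `amount_delivered_mg`. Sub-intervals whose
#' positive rate quantizes to zero flow are flagged.
#'
#' @param schedule A schedule from [build_schedule()].
#' @param c_infusion Infusion-solution concentration (mg/mL).
#' @param flow_resolution Pump flow grid (mL/h); default 0.1.
#' @param duration_resolution Pump duration grid (min); default 1.
#' @param duration_rounding `"stepwise"` or `"single"`.
#' @return A `pump_program` object: a data frame with columns
#'   `sub_interval`, `duration_min`, `flow_mL_h`, `amount_mg`,
#'   `amount_delivered_mg`, `zero_flow_flag`, plus attributes
#'   `c_infusion`, `f_dose`, `dose`, `t_n`.
#' @export
quantize_program <- function(schedule, c_infusion,
                             flow_resolution = 0.1, duration_resolution = 1,
                             duration_rounding = c("stepwise", "single")) {
  duration_rounding <- match.arg(duration_rounding)
  if (flow_resolution <= 0 || duration_resolution <= 0)
    stop("resolutions must be > 0")
  flow_raw <- schedule$rate_mg_h / c_infusion
  flow <- round_half_up(flow_raw, flow_resolution)
  dur_min <- schedule$duration_h * 60
  dur <- switch(duration_rounding,
                stepwise = round_stepwise(dur_min, duration_resolution),
                single = round_half_up(dur_min, duration_resolution))
  delivered <- flow * (dur / 60) * c_infusion
  zero <- flow == 0 & schedule$rate_mg_h > 0
  if (any(zero))
    warning("sub-interval(s) with positive rate quantized to zero flow: ",
            paste(schedule$index[zero], collapse = ", "))
  out <- data.frame(sub_interval = schedule$index,
                    duration_min = dur,
                    flow_mL_h = flow,
                    amount_mg = schedule$amount_mg,
                    amount_delivered_mg = delivered,
                    zero_flow_flag = zero)
  attr(out, "c_infusion") <- c_infusion
  attr(out, "f_dose") <- attr(schedule, "f_dose")
  attr(out, "dose") <- attr(schedule, "dose")
  attr(out, "ka") <- attr(schedule, "ka")
  attr(out, "t_n") <- attr(schedule, "t_n")
  attr(out, "schedule") <- schedule
  class(out) <- c("pump_program", "data.frame")
  out
}

#' @export
print.pump_program <- function(x, ...) {
  cat(sprintf("<pump_program: %d sub-intervals, c_infusion %.4g mg/mL, f_dose %.3f>\n",
              nrow(x), attr(x, "c_infusion"), attr(x, "f_dose")))
  print.data.frame(x[, c("sub_interval", "duration_min", "flow_mL_h", "amount_mg")],
                   row.names = FALSE, ...)
  invisible(x)
}

#' Dilution-pump setup mimicking first-order elimination
#'
#' In the rig, elimination is mimicked by a peristaltic pump flushing
#' drug-free medium through the central reservoir at
#' `CL_elim = ke * v_total`; the diluent volume to prepare for the whole
#' experiment is `CL_elim * exp_duration`.
#'
#' @param ke Elimination rate constant (1/h).
#' @param v_total Well-mixed volume of the rig (L).
#' @param exp_duration Experiment duration (h).
#' @return List with `cl_elim` (L/h) and `v_diluent` (L).
#' @examples
#' elimination_setup(0.230, 0.360, 96) # CL 0.0828 L/h, 7.95 L of diluent
#' @export
elimination_setup <- function(ke, v_total, exp_duration) {
  if (ke < 0 || v_total <= 0 || exp_duration <= 0)
    stop("ke must be >= 0; v_total and exp_duration > 0")
  cl <- ke * v_total
  list(cl_elim = cl, v_diluent = cl * exp_duration)
}

#' Design the full absorption-mode pump program for a target profile
#'
#' End-to-end design: dose from [compute_dose()], raw schedule from
#' [build_schedule()], infusion concentration from
#' [select_infusion_concentration()], pump quantization from
#' [quantize_program()] and the dilution-pump setup from
#' [elimination_setup()]. The same program is repeated every `tau`; the
#' undelivered `1 - f_dose` fraction is not carried over, which matches the
#' systematic slight under-exposure of the physical setup.
#'
#' @param target A [target_pk()] in absorption mode.
#' @param rig A [rig_config()]; supplies `v_total` (central + ECS volume)
#'   and the experiment duration.
#' @param n_sub Number of sub-intervals.
#' @param t_n End time of the last sub-interval (h); defaults to `tau`.
#' @param target_volume Per-sub-interval infusion volume (mL).
#' @param flow_resolution,duration_resolution,duration_rounding Passed to
#'   [quantize_program()].
#' @return A `pump_program` with additional attributes `cl_elim`,
#'   `v_diluent`, `tau`, `n_doses`.
#' @examples
#' tp <- target_pk(4.25, ke = 0.230, tau = 12, ka = 0.300)
#' design_absorption(tp, rig_config(), n_sub = 12)
#' @export
design_absorption <- function(target, rig = rig_config(), n_sub = 12L,
                              t_n = target$tau, target_volume = 2,
                              flow_resolution = 0.1, duration_resolution = 1,
                              duration_rounding = "stepwise") {
  stopifnot(inherits(target, "target_pk"))
  if (target$mode != "absorption") stop("target must be in absorption mode")
  v_tot <- v_total(rig)
  dose <- compute_dose(target$cmax1, target$ka, target$ke, v_tot)
  sched <- build_schedule(dose, target$ka, n_sub, t_n)
  c_inf <- select_infusion_concentration(sched, target_volume)
  prog <- quantize_program(sched, c_inf, flow_resolution, duration_resolution,
                           duration_rounding)
  elim <- elimination_setup(target$ke, v_tot, rig$exp_duration)
  attr(prog, "cl_elim") <- elim$cl_elim
  attr(prog, "v_diluent") <- elim$v_diluent
  attr(prog, "tau") <- target$tau
  attr(prog, "n_doses") <- target$n_doses
  prog
}

#' Design the short-infusion (IV-profile) setup
#'
#' Sizes the dose so that the concentration at the end of the first
#' zero-order infusion equals `cmax1` in the well-mixed rig volume,
#' correcting for elimination during the infusion:
#' `Dose = cmax1 * v_total * (ke * t_inf) / (1 - exp(-ke * t_inf))`.
#' Without the correction a 30-min infusion would undershoot the peak by
#' roughly `ke * t_inf / 2`.
#'
#' @param target A [target_pk()] in iv mode.
#' @param rig A [rig_config()].
#' @param infusion_volume Volume pushed per dose (mL); default 5 mL.
#' @return List of class `iv_design` with `dose` (mg), `c_infusion`
#'   (mg/mL), `flow_mL_h` (pump rate), `t_infusion` (h), `cl_elim` (L/h)
#'   and `v_diluent` (L).
#' @export
design_iv <- function(target, rig = rig_config(), infusion_volume = 5) {
  stopifnot(inherits(target, "target_pk"))
  if (target$mode != "iv") stop("target must be in iv mode")
  if (infusion_volume <= 0) stop("infusion_volume must be > 0")
  v_tot <- v_total(rig)
  ke <- target$ke; tinf <- target$t_infusion
  dose <- target$cmax1 * v_tot * (ke * tinf) / (1 - exp(-ke * tinf))
  elim <- elimination_setup(ke, v_tot, rig$exp_duration)
  structure(list(dose = dose,
                 c_infusion = dose / infusion_volume,
                 flow_mL_h = infusion_volume / tinf,
                 t_infusion = tinf,
                 tau = target$tau, n_doses = target$n_doses,
                 cl_elim = elim$cl_elim, v_diluent = elim$v_diluent),
            class = "iv_design")
}

#' @export
print.iv_design <- function(x, ...) {
  cat(sprintf("<iv_design: %.4g mg over %g h, c_infusion %.4g mg/mL, flow %.3g mL/h>\n",
              x$dose, x$t_infusion, x$c_infusion, x$flow_mL_h))
  cat(sprintf("  CL_elim %.4g L/h | diluent %.4g L\n", x$cl_elim, x$v_diluent))
  invisible(x)
}
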