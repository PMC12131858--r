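# File formats: study configuration (YAML), pump-program CSV (the pump
# worksheet), and concentration-time CSV.

.rig_keys <- c(v_central_L = "v_central", v_cartridge_L = "v_cartridge",
               f_ics = "f_ics", q_cartridge_L_h = "q_cartridge",
               cl_elim_L_h = "cl_elim", q_diffusion_L_h = "q_diffusion",
               exp_duration_h = "exp_duration")

.regimen_keys <- c("label", "mode", "cmax1_mg_L", "ka_1_h", "ke_1_h",
                   "tau_h", "t_infusion_h", "n_doses", "n_sub_intervals")

.top_keys <- c("seed", "grid_step", "flow_resolution", "duration_resolution",
               "target_volume_mL", "rig", "regimens")

.fail_unknown <- function(keys, allowed, where) {
  bad <- setdiff(keys, allowed)
  if (length(bad))
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
}

#' Load and validate a study configuration file
#'
#' A study configuration is a YAML file with optional global settings
#' (`seed`, `grid_step` in h, `flow_resolution` in mL/h,
#' `duration_resolution` in min, `target_volume_mL`), a `rig` block
#' (`v_central_L`, `v_cartridge_L`, `f_ics`, `q_cartridge_L_h`,
#' `cl_elim_L_h`, `q_diffusion_L_h`, `exp_duration_h`) and a list of
#' `regimens`, each with `label`, `mode` (`absorption`/`iv`), `cmax1_mg_L`,
#' `ke_1_h`, `tau_h`, and mode-specific fields (`ka_1_h` and
#' `n_sub_intervals`, or `t_infusion_h`). Unknown keys are a hard error so
#' typos never pass silently; all defaults applied are echoed via
#' `message()`.
#'
#' @param path Path to the YAML file.
#' @param quiet Suppress the resolved-configuration echo.
#' @return A list of class `study_config` with elements `rig`
#'   ([rig_config()]), `regimens` (named list; each has `target`
#'   ([target_pk()]) and `n_sub`), and the global settings.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  .fail_unknown(names(raw), .top_keys, "config")
  defaults <- list(seed = 1L, grid_step = 0.01, flow_resolution = 0.1,
                   duration_resolution = 1, target_volume_mL = 2)
  filled <- character(0)
  for (k in names(defaults)) if (is.null(raw[[k]])) {
    raw[[k]] <- defaults[[k]]; filled <- c(filled, k)
  }
  rig_raw <- raw$rig %||% list()
  .fail_unknown(names(rig_raw), names(.rig_keys), "rig block")
  rig_args <- setNames(rig_raw, .rig_keys[names(rig_raw)])
  rig <- do.call(rig_config, rig_args)
  regs <- list()
  for (rg in raw$regimens %||% list()) {
    .fail_unknown(names(rg), .regimen_keys, "regimen")
    for (k in c("label", "mode", "cmax1_mg_L", "ke_1_h", "tau_h"))
      if (is.null(rg[[k]])) stop("regimen is missing required field: ", k)
    if (rg$label %in% names(regs)) stop("duplicate regimen label: ", rg$label)
    tp <- target_pk(cmax1 = rg$cmax1_mg_L, ke = rg$ke_1_h, tau = rg$tau_h,
                    mode = rg$mode, ka = rg$ka_1_h,
                    t_infusion = rg$t_infusion_h,
                    n_doses = rg$n_doses %||% 8L)
    regs[[rg$label]] <- list(label = rg$label, target = tp,
                             n_sub = rg$n_sub_intervals %||% 12L)
  }
  cfg <- structure(list(rig = rig, regimens = regs, seed = raw$seed,
                        grid_step = raw$grid_step,
                        flow_resolution = raw$flow_resolution,
                        duration_resolution = raw$duration_resolution,
                        target_volume_mL = raw$target_volume_mL),
                   class = "study_config")
  if (!quiet) {
    if (length(filled))
      message("defaults filled: ", paste(filled, collapse = ", "))
    message(sprintf(
      "config: %d regimen(s); grid %g h; flow res %g mL/h; duration res %g min; seed %s",
      length(regs), cfg$grid_step, cfg$flow_resolution,
      cfg$duration_resolution, cfg$seed))
  }
  cfg
}

#' Export / import a pump program as a worksheet CSV
#'
#' The worksheet has a commented header block (`# key: value` lines for
#' `c_infusion_mg_mL`, `tau_h`, `n_doses`, `cl_elim_L_h`, `v_diluent_L`,
#' `f_dose`, `dose_mg`, `ka_1_h`, `t_n_h`) followed by the program table
#' with columns `sub_interval`, `duration_min`, `flow_mL_h`, `amount_mg`.
#' Writing then reading then writing again is byte-identical.
#'
#' @param program A `pump_program` (see [quantize_program()]).
#' @param path Output path.
#' @return `export_pump_program()` returns `path` invisibly;
#'   `read_pump_program()` returns a `pump_program`.
#' @export
export_pump_program <- function(program, path) {
  stopifnot(inherits(program, "pump_program"))
  num <- function(x) if (is.null(x)) "NA" else format(x, digits = 15)
  hdr <- c(c_infusion_mg_mL = num(attr(program, "c_infusion")),
           tau_h = num(attr(program, "tau")),
           n_doses = num(attr(program, "n_doses")),
           cl_elim_L_h = num(attr(program, "cl_elim")),
           v_diluent_L = num(attr(program, "v_diluent")),
           f_dose = num(attr(program, "f_dose")),
           dose_mg = num(attr(program, "dose")),
           ka_1_h = num(attr(program, "ka")),
           t_n_h = num(attr(program, "t_n")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(hdr), hdr), con)
  df <- program[, c("sub_interval", "duration_min", "flow_mL_h", "amount_mg")]
  df$amount_mg <- format(df$amount_mg, digits = 15)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_pump_program
#' @export
read_pump_program <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr_lines, regexec("^# *([^:]+): *(.*)$", hdr_lines))
  hdr <- setNames(vapply(kv, function(m) m[3L], character(1)),
                  vapply(kv, function(m) m[2L], character(1)))
  num <- function(k) {
    v <- suppressWarnings(as.numeric(hdr[[k]]))
    if (length(v) == 0 || is.na(v)) NULL else v
  }
  df <- read.csv(textConnection(lines[!grepl("^#", lines)]))
  need <- c("sub_interval", "duration_min", "flow_mL_h", "amount_mg")
  if (!all(need %in% names(df)))
    stop("pump program file needs columns: ", paste(need, collapse = ", "))
  c_inf <- num("c_infusion_mg_mL")
  if (is.null(c_inf)) stop("header is missing c_infusion_mg_mL")
  out <- data.frame(sub_interval = df$sub_interval,
                    duration_min = df$duration_min,
                    flow_mL_h = df$flow_mL_h,
                    amount_mg = df$amount_mg,
                    amount_delivered_mg = df$flow_mL_h * df$duration_min / 60 * c_inf,
                    zero_flow_flag = df$flow_mL_h == 0 & df$amount_mg > 0)
  attr(out, "c_infusion") <- c_inf
  attr(out, "tau") <- num("tau_h")
  attr(out, "n_doses") <- num("n_doses")
  attr(out, "cl_elim") <- num("cl_elim_L_h")
  attr(out, "v_diluent") <- num("v_diluent_L")
  attr(out, "f_dose") <- num("f_dose")
  attr(out, "dose") <- num("dose_mg")
  attr(out, "ka") <- num("ka_1_h")
  attr(out, "t_n") <- num("t_n_h")
  class(out) <- c("pump_program", "data.frame")
  out
}

#' Read / write concentration-time series CSV
#'
#' The dialect is a comma-separated file with mandatory header
#' `time_h,conc_mg_L,compartment,replicate` and decimal points. Malformed
#' rows are reported with their line numbers. An empty file (header only)
#' yields an empty series with a warning.
#'
#' @param path File path.
#' @param series A [concentration_series()].
#' @return `read_concentrations()` returns a [concentration_series()];
#'   `write_concentrations()` returns `path` invisibly.
#' @export
read_concentrations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "conc_mg_L", "compartment", "replicate")
  if (!all(need %in% names(df)))
    stop("concentration file needs header: ", paste(need, collapse = ","))
  if (nrow(df) == 0L) {
    warning("empty concentration file: ", path)
    return(concentration_series(numeric(0), numeric(0),
                                character(0), character(0)))
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$time_h))) |
               !is.finite(suppressWarnings(as.numeric(df$conc_mg_L))))
  if (length(bad))
    stop("malformed row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "), " in ", path)
  validate_concentration_series(df)
}

#' @rdname read_concentrations
#' @export
write_concentrations <- function(series, path) {
  series <- validate_concentration_series(series)
  df <- as.data.frame(series)
  df$time_h <- format(df$time_h, digits = 15)
  df$conc_mg_L <- format(df$conc_mg_L, digits = 15)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
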