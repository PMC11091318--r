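# File formats: observation-series CSV, mass-balance CSV, trajectory export,
# and run configuration (JSON/YAML). CSV files use '.' decimals, UTF-8, and
# '#'-prefixed comment lines; writers embed the package version and seed.

file_header <- function(seed = NULL) {
  h <- sprintf("# bsflux %s",
               as.character(utils::packageVersion("bsflux")))
  if (!is.null(seed)) h <- paste0(h, sprintf("; seed=%d", as.integer(seed)))
  h
}

#' Read an observation series from CSV
#'
#' Required columns: `t_d` (age, days) and `x_dw_mg` (dry weight, mg).
#' Optional: `rco2_mgco2_d` (CO2 production, mg CO2 day^-1) and `ltot_mg`
#' (total lipid, mg). Time must be strictly increasing and masses
#' non-negative; violations are reported with their line numbers. The CO2
#' column is additionally converted to a carbon rate (x 12/44) in
#' `r_co2_c`.
#'
#' @param path Path to a CSV file (comment lines start with `#`).
#'
#' @return An `observation_series` data.frame with columns `t`, `x_dw` and,
#'   when present, `r_co2`, `r_co2_c`, `l_tot`.
#' @export
read_observations <- function(path) {
  if (!file.exists(path))
    stop("read_observations: no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("t_d", "x_dw_mg")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("read_observations: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  # data line numbers (1-based over data rows, excluding header/comments)
  bad_t <- which(!is.finite(raw$t_d))
  if (length(bad_t))
    stop("read_observations: non-numeric time at data row(s) ",
         paste(bad_t, collapse = ", "), call. = FALSE)
  nd <- which(diff(raw$t_d) <= 0)
  if (length(nd))
    stop("read_observations: time not strictly increasing at data row(s) ",
         paste(nd + 1, collapse = ", "),
         " (duplicated or decreasing t_d)", call. = FALSE)
  for (col in intersect(c("x_dw_mg", "ltot_mg"), names(raw))) {
    neg <- which(raw[[col]] < 0)
    if (length(neg))
      stop("read_observations: negative mass in ", col, " at data row(s) ",
           paste(neg, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(t = raw$t_d, x_dw = raw$x_dw_mg)
  if ("rco2_mgco2_d" %in% names(raw)) {
    out$r_co2 <- raw$rco2_mgco2_d
    out$r_co2_c <- raw$rco2_mgco2_d * 12 / 44
  }
  if ("ltot_mg" %in% names(raw)) out$l_tot <- raw$ltot_mg
  class(out) <- c("observation_series", "data.frame")
  out
}

#' Write an observation series to CSV
#'
#' Inverse of [read_observations()]; numeric columns are written with 15
#' significant digits so that a write/read round trip is lossless to 1e-12.
#'
#' @param obs A data.frame with columns `t`, `x_dw` and optionally `r_co2`,
#'   `l_tot`.
#' @param path Output path.
#' @param seed Optional seed recorded in the comment header.
#' @export
write_observations <- function(obs, path, seed = NULL) {
  stopifnot(is.data.frame(obs), all(c("t", "x_dw") %in% names(obs)))
  df <- data.frame(t_d = obs$t, x_dw_mg = obs$x_dw)
  if ("r_co2" %in% names(obs)) df$rco2_mgco2_d <- obs$r_co2
  if ("l_tot" %in% names(obs)) df$ltot_mg <- obs$l_tot
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(file_header(seed), con)
  utils::write.table(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read mass-balance ledgers from CSV
#'
#' Expects columns `x_dw0`, `x_dw`, `w_dw0`, `w_dw_res` (one ledger per row).
#'
#' @param path Path to a CSV file.
#' @return A list of [mass_balance_ledger()] objects.
#' @export
read_mass_balance <- function(path) {
  if (!file.exists(path))
    stop("read_mass_balance: no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("x_dw0", "x_dw", "w_dw0", "w_dw_res")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("read_mass_balance: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(raw)), function(i)
    mass_balance_ledger(raw$x_dw0[i], raw$x_dw[i],
                        raw$w_dw0[i], raw$w_dw_res[i]))
}

#' Export a simulated trajectory to CSV (and optional JSON summary)
#'
#' Writes the observable trajectory (columns `t_d`, `B_mgC`, `L_mgC`,
#' `X_DW_mg`, `rCO2_mgCO2_per_d`, `L_tot_mg`, `delta_lipid`, `delta_DW`,
#' `stage`) and, if `summary_path` is given, a JSON summary with `t_pp`,
#' `A_cum`, `CO2_cum` and `nge_avg`.
#'
#' @param traj A [simulate_deb()] trajectory.
#' @param path Output CSV path.
#' @param summary_path Optional JSON summary path.
#' @param seed Optional seed recorded in the header/summary.
#' @export
write_trajectory <- function(traj, path, summary_path = NULL, seed = NULL) {
  stopifnot(inherits(traj, "deb_trajectory"))
  obs <- predict_observables(traj)
  df <- data.frame(t_d = traj$t, B_mgC = traj$B, L_mgC = traj$L,
                   X_DW_mg = obs$x_dw, rCO2_mgCO2_per_d = obs$r_co2,
                   L_tot_mg = obs$l_tot, delta_lipid = obs$delta_lipid,
                   delta_DW = obs$delta_dw, stage = traj$stage)
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(file_header(seed), con)
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  if (!is.null(summary_path)) {
    nge <- tryCatch(nge_average(traj), error = function(e) NULL)
    summ <- list(package = "bsflux",
                 version = as.character(utils::packageVersion("bsflux")),
                 seed = seed,
                 t_pp = attr(traj, "t_pp"),
                 t_harvest = attr(traj, "t_harvest"),
                 A_cum = traj$A_cum[nrow(traj)],
                 CO2_cum = traj$CO2_cum[nrow(traj)],
                 nge_avg = if (is.null(nge)) NA else nge$nge_avg)
    jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

.config_keys <- c("model", "params", "scenario", "noise", "seed",
                  "output_dir", "verbosity")

#' Read and validate a run configuration (JSON or YAML)
#'
#' Recognized top-level keys: `model` (`"logistic"` or `"deb"`), `params`,
#' `scenario`, `noise`, `seed`, `output_dir`, `verbosity`. Unknown keys are
#' rejected. Parameter and scenario blocks are validated through their
#' constructors.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#'
#' @return A list of class `run_config` with validated components: `model`,
#'   `params` (a [deb_params()] or [logistic_params()]), `scenario`, `noise`,
#'   `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("read_run_config: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("read_run_config: unsupported extension '.", ext,
                     "', use .json/.yaml/.yml", call. = FALSE))
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("read_run_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  model <- cfg$model %||% "deb"
  if (!model %in% c("logistic", "deb"))
    stop("read_run_config: model must be 'logistic' or 'deb'", call. = FALSE)
  params <- if (model == "deb") do.call(deb_params, cfg$params %||% list())
            else do.call(logistic_params, cfg$params)
  scenario <- do.call(deb_scenario, cfg$scenario %||% list())
  noise <- if (is.null(cfg$noise)) NULL else do.call(noise_model, cfg$noise)
  structure(list(model = model, params = params, scenario = scenario,
                 noise = noise, seed = cfg$seed,
                 output_dir = cfg$output_dir, verbosity = cfg$verbosity),
            class = "run_config")
}
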