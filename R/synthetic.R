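# Seeded synthetic-data generators: noisy larval observation series and whole
# rearing-experiment mass balances with a lumped microbial consumption term.

#' Observation noise model
#'
#' Multiplicative lognormal noise (mean-one, coefficient of variation
#' `cv_weight`) on dry weight and lipid, additive Gaussian noise
#' (sd `sd_co2`, truncated at zero) on the CO2 production rate.
#'
#' @param cv_weight CV of the weight/lipid noise, >= 0.
#' @param sd_co2 SD of the CO2-rate noise, mg CO2 day^-1, >= 0.
#' @param seed Integer seed, or `NULL` for noise-free/deterministic use.
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv_weight = 0.05, sd_co2 = 0, seed = 1L) {
  if (cv_weight < 0 || sd_co2 < 0)
    stop("noise_model: cv_weight and sd_co2 must be >= 0", call. = FALSE)
  structure(list(cv_weight = cv_weight, sd_co2 = sd_co2, seed = seed),
            class = "noise_model")
}

# default sampling design: every 2 days from t0 to t_pp + 4 (or trajectory end)
#' Default observation times for a trajectory
#'
#' Every 2 days from the trajectory start until 4 days after prepupation
#' (or the trajectory end if prepupation was not reached), emulating a
#' typical rearing-study sampling design.
#'
#' @param traj A [simulate_deb()] trajectory.
#' @return Numeric vector of days.
#' @export
default_observation_times <- function(traj) {
  stopifnot(inherits(traj, "deb_trajectory"))
  t0 <- traj$t[1]
  tpp <- attr(traj, "t_pp")
  tend <- if (is.na(tpp)) traj$t[nrow(traj)] else
    min(tpp + 4, traj$t[nrow(traj)])
  seq(t0, tend, by = 2)
}

#' Generate a noisy larval observation series
#'
#' Simulates the dynamic model, predicts the observables at the requested
#' times, and applies the noise model. With zero noise the output equals the
#' noise-free prediction exactly; with a seed the output is a pure function
#' of (parameters, scenario, times, noise).
#'
#' @param p A [deb_params()] object.
#' @param scenario A [deb_scenario()] object.
#' @param times Observation times (days) within the scenario span; default
#'   every 2 days from `t0` until 4 days past prepupation.
#' @param noise A [noise_model()].
#'
#' @return An `observation_series` data.frame (`t`, `x_dw`, `r_co2`, `l_tot`,
#'   `delta_lipid`, `delta_dw`, `stage`) with attributes `noise` and
#'   `truth` (the noise-free series).
#' @export
#' @examples
#' obs <- generate_observations(deb_params(), deb_scenario(),
#'                              noise = noise_model(0.05, 1, seed = 7))
#' head(obs)
generate_observations <- function(p, scenario, times = NULL,
                                  noise = noise_model(0, 0, seed = NULL)) {
  stopifnot(inherits(p, "deb_params"), inherits(scenario, "deb_scenario"),
            inherits(noise, "noise_model"))
  if (is.null(times)) {
    times <- default_observation_times(simulate_deb(p, scenario))
  }
  times <- sort(unique(as.numeric(times)))
  if (times[1] < scenario$t0 || times[length(times)] > scenario$t_end)
    stop("generate_observations: times outside the scenario span", call. = FALSE)
  traj <- simulate_deb(p, scenario, times = times)
  pred <- predict_observables(traj, p)
  idx <- vapply(times, function(tt) which.min(abs(pred$t - tt)), 0L)
  clean <- pred[idx, , drop = FALSE]
  rownames(clean) <- NULL

  out <- clean
  if (noise$cv_weight > 0 || noise$sd_co2 > 0) {
    n <- nrow(out)
    draws <- local_seed(noise$seed, {
      sdlog <- sqrt(log(1 + noise$cv_weight^2))
      list(w = stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog),
           l = stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog),
           c = stats::rnorm(n, 0, noise$sd_co2))
    })
    if (noise$cv_weight > 0) {
      out$x_dw <- out$x_dw * draws$w
      out$l_tot <- out$l_tot * draws$l
    }
    if (noise$sd_co2 > 0) out$r_co2 <- pmax(out$r_co2 + draws$c, 0)
    out$delta_lipid <- out$l_tot / out$x_dw
  }
  attr(out, "noise") <- noise
  attr(out, "truth") <- clean
  class(out) <- c("observation_series", "data.frame")
  out
}

#' Rearing-experiment scenario
#'
#' A whole-cohort experiment: `n_larvae` average larvae following the dynamic
#' model, a supplied substrate pool, a larval digestion efficiency `AD`
#' (fraction of ingested feed that is assimilated; the rest is egested as
#' frass into the residue), and a lumped first-order microbial substrate
#' consumption `mu_mic` competing with the larvae.
#'
#' @param p A [deb_params()] object.
#' @param scenario A [deb_scenario()] object (per-capita trajectory).
#' @param n_larvae Cohort size. Default 100.
#' @param W_DW0 Supplied substrate dry weight, mg. Default 40000.
#' @param AD Digestion efficiency, in (0, 1]. Default 0.8.
#' @param mu_mic Microbial specific consumption of remaining substrate,
#'   day^-1, >= 0. Default 0.02.
#'
#' @return An object of class `rearing_scenario`.
#' @export
rearing_scenario <- function(p = deb_params(), scenario = deb_scenario(),
                             n_larvae = 100, W_DW0 = 40000,
                             AD = 0.8, mu_mic = 0.02) {
  stopifnot(inherits(p, "deb_params"), inherits(scenario, "deb_scenario"))
  if (AD <= 0 || AD > 1)
    stop("rearing_scenario: AD must lie in (0, 1]", call. = FALSE)
  if (mu_mic < 0) stop("rearing_scenario: mu_mic must be >= 0", call. = FALSE)
  if (n_larvae < 1 || W_DW0 <= 0)
    stop("rearing_scenario: need n_larvae >= 1 and W_DW0 > 0", call. = FALSE)
  structure(list(p = p, scenario = scenario, n_larvae = n_larvae,
                 W_DW0 = W_DW0, AD = AD, mu_mic = mu_mic),
            class = "rearing_scenario")
}

#' Generate a whole rearing experiment with its mass-balance ledger
#'
#' Runs the per-capita dynamic model, scales to the cohort, and integrates
#' the substrate pool: removal is the sum of larval ingestion
#' (assimilation / AD) and first-order microbial consumption. Residue at
#' harvest is unconsumed substrate plus frass (ingested x (1 - AD)). Ledger
#' closure (supplied = remaining + ingested + microbially consumed) holds to
#' integrator precision before any noise. Because the frass and digestion
#' terms cancel between ingestion and residue, the ledger SCE equals
#' NGE*_avg x assimilated / (assimilated + microbial), so SCE <= NGE*_avg
#' with equality exactly when microbial consumption is zero.
#'
#' @param rs A [rearing_scenario()].
#' @param noise A [noise_model()] applied to the returned per-capita
#'   observation series (the ledger itself is noise-free).
#'
#' @return A list of class `rearing_experiment` with elements `ledger`
#'   (a [mass_balance_ledger()], mg DW), `obs` (per-capita
#'   `observation_series`), and `truth` (list: generating parameters,
#'   `t_harvest`, `nge_avg`, `assimilated_dw`, `ingested_dw`, `frass_dw`,
#'   `microbial_dw`, `remaining_dw`, `truncated` flag).
#' @export
#' @examples
#' ex <- generate_rearing_experiment(rearing_scenario())
#' indicators_from_ledger(ex$ledger)
#' ex$truth$nge_avg
generate_rearing_experiment <- function(rs, noise = noise_model(0, 0, seed = NULL)) {
  stopifnot(inherits(rs, "rearing_scenario"))
  p <- rs$p; sc <- rs$scenario
  traj <- simulate_deb(p, sc)
  t_h <- attr(traj, "t_harvest")

  # substrate pool: dW/dt = -ingestion(t) - mu_mic * W
  ing_rate <- stats::approxfun(traj$t, rs$n_larvae * traj$r_A / (rs$AD * p$f_C),
                               rule = 2)
  rhs_W <- function(t, y, parms)
    list(c(-ing_rate(t) - rs$mu_mic * y[1], rs$mu_mic * y[1], ing_rate(t)))
  root_W <- function(t, y, parms) y[1]
  wt <- traj$t[traj$t <= t_h + 1e-12]
  if (wt[length(wt)] < t_h) wt <- c(wt, t_h)
  outW <- deSolve::lsodar(c(W = rs$W_DW0, M = 0, I = 0), wt, rhs_W,
                          parms = NULL, rootfunc = root_W,
                          rtol = 1e-10, atol = 1e-8)
  truncated <- !is.null(attr(outW, "troot")) && length(attr(outW, "troot")) > 0
  t_stop <- if (truncated) attr(outW, "troot")[1] else t_h
  if (truncated)
    warning("generate_rearing_experiment: substrate exhausted at t = ",
            signif(t_stop, 4), " d, before harvest (truncated experiment)",
            call. = FALSE)

  W_rem <- max(unname(outW[nrow(outW), "W"]), 0)
  microbial <- unname(outW[nrow(outW), "M"])
  ingested <- unname(outW[nrow(outW), "I"])
  X_h <- interp_col(traj, "X", t_stop)
  assimilated <- ingested * rs$AD
  frass <- ingested * (1 - rs$AD)

  ledger <- mass_balance_ledger(
    x_dw0 = rs$n_larvae * sc$X0 / p$f_C,
    x_dw = rs$n_larvae * X_h / p$f_C,
    w_dw0 = rs$W_DW0,
    w_dw_res = W_rem + frass)

  nge <- nge_average(traj, t0 = sc$t0, t_harvest = t_stop)
  obs <- generate_observations(p, sc, noise = noise)

  structure(list(
    ledger = ledger, obs = obs,
    truth = list(params = p, scenario = sc, n_larvae = rs$n_larvae,
                 AD = rs$AD, mu_mic = rs$mu_mic,
                 t_harvest = t_stop, nge_avg = nge$nge_avg,
                 assimilated_dw = assimilated, ingested_dw = ingested,
                 frass_dw = frass, microbial_dw = unname(microbial),
                 remaining_dw = unname(W_rem), truncated = truncated)),
    class = "rearing_experiment")
}

#' @export
print.rearing_experiment <- function(x, ...) {
  tr <- x$truth
  cat(sprintf("Synthetic rearing experiment: %d larvae, harvest at t = %.4g d%s\n",
              tr$n_larvae, tr$t_harvest,
              if (tr$truncated) " (TRUNCATED: substrate exhausted)" else ""))
  cat(sprintf("  true NGE*_avg = %.4f; microbial share of removal = %.3f\n",
              tr$nge_avg,
              tr$microbial_dw / (tr$microbial_dw + tr$assimilated_dw)))
  print(indicators_from_ledger(x$ledger))
  invisible(x)
}
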