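# Dynamic two-compartment energy-budget model.
#
# State: structural biomass B and storage lipid L (mg C), total X = B + L.
# Two rate-limiting flows, both declining logistically in x = X/Xmax:
#   supply   r_A = a(x) * X,      a(x) = a_max / (1 + exp(k_A (x - x_A)))
#   demand   d   = s_max * B / (1 + exp(k_B (x - x5)))
# Allocation priority: maintenance (m*X) first, then structural synthesis at
# cost Y, then overflow into lipid at cost Y_L. In the prepupal phase feeding
# stops and maintenance is paid from lipid.

# relative margin of net assimilation over maintenance below which the larva
# is considered to have entered the prepupal stage (see simulate_deb)
.PP_EPS <- 0.01

#' Specific feed assimilation rate
#'
#' Logistic decline of the specific assimilation rate with relative larval
#' mass x = X/Xmax: a(x) = a_max / (1 + exp(k_A (x - x_A))). Highest in newly
#' hatched larvae, effectively zero in the prepupa.
#'
#' @param x Relative larval mass X/Xmax (vectorized), typically in `[0, 1.05]`.
#' @param p A [deb_params()] object.
#'
#' @return Specific assimilation rate, day^-1; decreasing in `x`, equal to
#'   `a_max/2` at `x = x_A`.
#' @export
specific_assimilation <- function(x, p) {
  stopifnot(inherits(p, "deb_params"), is.numeric(x))
  p$a_max / (1 + exp(p$k_A * (x - p$x_A)))
}

#' Structural growth demand
#'
#' Maximal rate at which structural biomass can be synthesized,
#' demand = s_max * B / (1 + exp(k_B (x - x5))). Nearly `s_max * B` while
#' x << x5 (constant early specific growth), declining to zero as the larva
#' approaches its maximal weight — the instar-5 growth-rate break.
#'
#' @param x Relative larval mass X/Xmax (vectorized).
#' @param B Structural biomass, mg C, > 0.
#' @param p A [deb_params()] object.
#'
#' @return Demand rate, mg C day^-1.
#' @export
structural_demand <- function(x, B, p) {
  stopifnot(inherits(p, "deb_params"), is.numeric(x), is.numeric(B))
  if (any(B <= 0)) stop("structural_demand: B must be > 0", call. = FALSE)
  p$s_max * B / (1 + exp(p$k_B * (x - p$x5)))
}

# Fast unvalidated flux kernel for the larval phase; returns the six flows.
# Carbon closure r_A = r_B + r_L + r_CO2_B + r_CO2_L + r_CO2_m is exact by
# construction in both the fed and the starvation branch.
larval_fluxes_ <- function(B, L, p, Xmax) {
  L <- max(L, 0)
  X <- B + L
  x <- X / Xmax
  r_A <- p$a_max / (1 + exp(p$k_A * (x - p$x_A))) * X
  r_m <- p$m * X
  if (r_A >= r_m) {
    avail <- r_A - r_m
    demand <- p$s_max * B / (1 + exp(p$k_B * (x - p$x5)))
    r_B <- min(demand, avail / (1 + p$Y))
    r_CO2_B <- p$Y * r_B
    E <- avail - (1 + p$Y) * r_B
    r_L <- E / (1 + p$Y_L)
    r_CO2_L <- p$Y_L * r_L
    starv <- FALSE
  } else {
    # assimilation below maintenance: deficit drawn from lipid
    r_B <- 0; r_CO2_B <- 0
    r_L <- -(r_m - r_A); r_CO2_L <- 0
    starv <- TRUE
  }
  list(r_A = r_A, r_B = r_B, r_L = r_L,
       r_CO2_B = r_CO2_B, r_CO2_L = r_CO2_L, r_CO2_m = r_m,
       starvation = starv)
}

#' Partition assimilated carbon into the six metabolic flows (larval phase)
#'
#' Given a larval state, computes assimilation supply and allocates it with
#' priority maintenance -> structural synthesis -> lipid overflow. Lipid
#' synthesis carries its own respiratory cost `Y_L` (redox balancing). If
#' supply falls below maintenance, growth stops and the deficit is drawn from
#' lipid (`r_L < 0`) with a starvation flag.
#'
#' @param state List (or row) with elements `B` (> 0) and `L` (>= 0), mg C.
#' @param p A [deb_params()] object.
#' @param scenario A [deb_scenario()] object (provides `Xmax`).
#'
#' @return An object of class `flux_record`: list with `r_A`, `r_B`, `r_L`,
#'   `r_CO2_B`, `r_CO2_L`, `r_CO2_m` (mg C day^-1) and logical `starvation`.
#'   Carbon closure `r_A = r_B + r_L + sum(r_CO2_*)` holds exactly.
#' @export
#' @examples
#' st <- list(B = 10, L = 0)
#' partition_fluxes(st, deb_params(), deb_scenario(Xmax = 30))
partition_fluxes <- function(state, p, scenario) {
  stopifnot(inherits(p, "deb_params"), inherits(scenario, "deb_scenario"))
  B <- state$B; L <- state$L
  if (!is.finite(B) || B <= 0) stop("partition_fluxes: B must be > 0", call. = FALSE)
  if (!is.finite(L) || L < 0) stop("partition_fluxes: L must be >= 0", call. = FALSE)
  f <- larval_fluxes_(B, L, p, scenario$Xmax)
  structure(f, class = "flux_record")
}

#' Metabolic flows in the prepupal phase
#'
#' After prepupation feeding stops (`r_A = 0`), structural biomass is
#' conserved, and maintenance `m * X` is covered entirely by remobilizing
#' storage lipid, so the prepupa loses weight.
#'
#' @param state List with elements `B` (> 0) and `L` (> 0), mg C.
#' @param p A [deb_params()] object.
#'
#' @return A `flux_record` with `r_A = r_B = 0`, `r_L = -m*X`,
#'   `r_CO2_m = m*X`.
#' @export
prepupal_step <- function(state, p) {
  stopifnot(inherits(p, "deb_params"))
  B <- state$B; L <- state$L
  if (!is.finite(B) || B <= 0) stop("prepupal_step: B must be > 0", call. = FALSE)
  if (!is.finite(L) || L <= 0)
    stop("prepupal_step: storage lipid exhausted (L <= 0)", call. = FALSE)
  X <- B + L
  structure(list(r_A = 0, r_B = 0, r_L = -p$m * X,
                 r_CO2_B = 0, r_CO2_L = 0, r_CO2_m = p$m * X,
                 starvation = FALSE),
            class = "flux_record")
}

#' Simulate the dynamic energy-budget model
#'
#' Integrates dB/dt = r_B, dL/dt = r_L from `t0` (with B0 = X0, L0 = 0 by
#' default) through the larval feeding phase and, after the prepupation event,
#' through the lipid-catabolizing prepupal phase until `t_end` or lipid
#' depletion. Cumulative assimilation and CO2 are carried as additional
#' integrator states, so carbon closure holds to integrator precision.
#'
#' The prepupation event fires when net specific assimilation is effectively
#' exhausted: a(x) - m <= eps * (a_max - m) with eps = 0.01. For m = 0 this is
#' exactly "assimilation below 1% of its maximum"; for m > 0 it is the same
#' 1% criterion applied to the margin over maintenance, which is the quantity
#' that actually reaches zero in this model (a(x) equilibrates with m instead
#' of reaching zero; see the methods vignette).
#'
#' @param p A [deb_params()] object.
#' @param scenario A [deb_scenario()] object.
#' @param L0 Initial storage lipid, mg C. Default 0 (young larvae are lean).
#' @param dt Output grid spacing, days. Default 0.02. Ignored if `times` given.
#' @param times Optional explicit output times (days, strictly increasing,
#'   within `[t0, t_end]`). Event times are always added to the grid.
#' @param rtol,atol Integrator tolerances (deSolve `lsodar`).
#'
#' @return An object of class `deb_trajectory`: a data.frame with columns
#'   `t`, `stage` ("larva"/"prepupa"), `B`, `L`, `X`, `A_cum`, `CO2_cum` and
#'   the six flux columns, plus attributes `t_pp` (prepupation time, `NA` if
#'   not reached), `t_harvest` (per the scenario's harvest rule), `params`,
#'   `scenario`, and logical flags `starvation`, `lipid_depleted`.
#' @seealso [predict_observables()], [nge_average()]
#' @export
#' @examples
#' traj <- simulate_deb(deb_params(), deb_scenario())
#' attr(traj, "t_pp")
#' nge_average(traj)$nge_avg
simulate_deb <- function(p, scenario, L0 = 0, dt = 0.02, times = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "deb_params"), inherits(scenario, "deb_scenario"))
  if (L0 < 0) stop("simulate_deb: L0 must be >= 0", call. = FALSE)
  t0 <- scenario$t0; t_end <- scenario$t_end; Xmax <- scenario$Xmax

  if (is.null(times)) {
    times <- unique(c(seq(t0, t_end, by = dt), t_end))
  } else {
    times <- sort(unique(as.numeric(times)))
    if (times[1] < t0 || times[length(times)] > t_end)
      stop("simulate_deb: times must lie within [t0, t_end]", call. = FALSE)
    times <- unique(c(t0, times))
  }

  rhs_larva <- function(t, y, parms) {
    f <- larval_fluxes_(y[1], y[2], p, Xmax)
    list(c(f$r_B, f$r_L, f$r_A, f$r_CO2_B + f$r_CO2_L + f$r_CO2_m))
  }
  # net specific assimilation margin; prepupation at 1% of its maximum
  root_pp <- function(t, y, parms) {
    x <- (y[1] + max(y[2], 0)) / Xmax
    a <- p$a_max / (1 + exp(p$k_A * (x - p$x_A)))
    (a - p$m) - .PP_EPS * (p$a_max - p$m)
  }
  y0 <- c(B = scenario$X0 - L0, L = L0, A = 0, C = 0)
  if (y0[1] <= 0) stop("simulate_deb: L0 must be < X0", call. = FALSE)

  out1 <- deSolve::lsodar(y0, times, rhs_larva, parms = NULL,
                          rootfunc = root_pp, rtol = rtol, atol = atol)
  if (attr(out1, "istate")[1] < 0)
    stop("simulate_deb: integrator failure in larval phase at t = ",
         out1[nrow(out1), 1], call. = FALSE)
  troot <- attr(out1, "troot")
  t_pp <- if (!is.null(troot) && length(troot) >= 1) troot[1] else NA_real_
  # root at the initial point means the scenario starts past prepupation
  if (!is.na(t_pp) && t_pp <= t0) t_pp <- t0

  df1 <- as.data.frame(out1)
  names(df1) <- c("t", "B", "L", "A_cum", "CO2_cum")
  df1$stage <- "larva"

  lipid_depleted <- FALSE
  df2 <- NULL
  if (!is.na(t_pp) && t_pp < t_end) {
    yst <- unlist(df1[nrow(df1), c("B", "L", "A_cum", "CO2_cum")])
    times2 <- unique(c(t_pp, times[times > t_pp], t_end))
    if (yst[["L"]] <= atol) {
      lipid_depleted <- TRUE
    } else {
      rhs_pp <- function(t, y, parms) {
        X <- y[1] + max(y[2], 0)
        list(c(0, -p$m * X, 0, p$m * X))
      }
      root_lipid <- function(t, y, parms) y[2]
      out2 <- deSolve::lsodar(c(B = yst[["B"]], L = yst[["L"]],
                                A = yst[["A_cum"]], C = yst[["CO2_cum"]]),
                              times2, rhs_pp, parms = NULL,
                              rootfunc = root_lipid, rtol = rtol, atol = atol)
      if (attr(out2, "istate")[1] < 0)
        stop("simulate_deb: integrator failure in prepupal phase at t = ",
             out2[nrow(out2), 1], call. = FALSE)
      if (!is.null(attr(out2, "troot")) && length(attr(out2, "troot")))
        lipid_depleted <- TRUE
      df2 <- as.data.frame(out2)
      names(df2) <- c("t", "B", "L", "A_cum", "CO2_cum")
      df2$stage <- "prepupa"
      df2 <- df2[-1, , drop = FALSE]  # t_pp row already in df1
    }
  }

  traj <- rbind(df1, df2)
  traj$L <- pmax(traj$L, 0)
  traj$X <- traj$B + traj$L

  # per-row fluxes, recomputed from the state with the same kernels
  n <- nrow(traj)
  fx <- matrix(0, n, 6,
               dimnames = list(NULL, c("r_A", "r_B", "r_L",
                                       "r_CO2_B", "r_CO2_L", "r_CO2_m")))
  starv <- FALSE
  for (i in seq_len(n)) {
    if (traj$stage[i] == "larva") {
      f <- larval_fluxes_(traj$B[i], traj$L[i], p, Xmax)
      starv <- starv || f$starvation
    } else {
      X <- traj$X[i]
      f <- list(r_A = 0, r_B = 0, r_L = -p$m * X,
                r_CO2_B = 0, r_CO2_L = 0, r_CO2_m = p$m * X)
    }
    fx[i, ] <- c(f$r_A, f$r_B, f$r_L, f$r_CO2_B, f$r_CO2_L, f$r_CO2_m)
  }
  traj <- cbind(traj[c("t", "stage", "B", "L", "X", "A_cum", "CO2_cum")],
                as.data.frame(fx))

  t_harvest <- if (scenario$harvest_rule == "at-prepupation" && !is.na(t_pp))
    t_pp else t_end

  structure(traj,
            class = c("deb_trajectory", "data.frame"),
            t_pp = t_pp, t_harvest = t_harvest,
            params = p, scenario = scenario,
            starvation = starv, lipid_depleted = lipid_depleted)
}

#' Predict measurable observables from a simulated trajectory
#'
#' Converts the internal carbon-equivalent trajectory into the quantities a
#' rearing study measures: dry weight `x_dw = (B+L)/f_C` (mg), CO2 production
#' rate `r_co2` in mg CO2 day^-1 (carbon rate scaled by 44/12), total lipid
#' `l_tot = L/f_C` (mg), relative lipid content `delta_lipid = l_tot/x_dw`,
#' and dry-matter content `delta_dw = x_dw / (x_dw + h*B/f_C)` under the
#' assumption that water is bound to structural mass only (so `delta_dw`
#' rises as lipid accumulates; an out-of-fit coherence observable).
#'
#' @param traj A [simulate_deb()] trajectory.
#' @param p A [deb_params()] object; defaults to the trajectory's own.
#'
#' @return A data.frame of class `observation_series` with columns `t`,
#'   `x_dw`, `r_co2`, `l_tot`, `delta_lipid`, `delta_dw`, `stage`.
#' @export
predict_observables <- function(traj, p = attr(traj, "params")) {
  stopifnot(inherits(traj, "deb_trajectory"), inherits(p, "deb_params"))
  if (nrow(traj) == 0) stop("predict_observables: empty trajectory", call. = FALSE)
  x_dw <- traj$X / p$f_C
  l_tot <- traj$L / p$f_C
  out <- data.frame(
    t = traj$t,
    x_dw = x_dw,
    r_co2 = (traj$r_CO2_B + traj$r_CO2_L + traj$r_CO2_m) * (44 / 12),
    l_tot = l_tot,
    delta_lipid = l_tot / x_dw,
    delta_dw = x_dw / (x_dw + p$h * traj$B / p$f_C),
    stage = traj$stage
  )
  class(out) <- c("observation_series", "data.frame")
  out
}

# subsetting a trajectory drops the trajectory-level attributes, so return a
# plain data.frame rather than a half-valid trajectory object
#' @export
`[.deb_trajectory` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.deb_trajectory <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("DEB trajectory: %d points over t = [%.3g, %.3g] d\n",
              nrow(x), x$t[1], x$t[nrow(x)]))
  tpp <- attr(x, "t_pp")
  if (!is.null(tpp) && !is.na(tpp))
    cat(sprintf("  prepupation at t_pp = %.4g d\n", tpp))
  cat(sprintf("  final X = %.4g mg C (x = %.3g of Xmax), lipid fraction %.3g\n",
              x$X[nrow(x)], x$X[nrow(x)] / sc$Xmax, x$L[nrow(x)] / x$X[nrow(x)]))
  if (attr(x, "starvation")) cat("  note: starvation occurred in larval phase\n")
  if (attr(x, "lipid_depleted")) cat("  note: lipid depleted in prepupal phase\n")
  invisible(x)
}
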