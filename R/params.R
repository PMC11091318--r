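#' Parameters of the Verhulst logistic growth model
#'
#' Container for the three constants of the logistic (Verhulst) growth curve
#' used for BSF larval mass in carbon equivalents.
#'
#' @param mu Maximal specific growth rate, day^-1. Must be > 0.
#' @param X0 Initial larval mass, mg C. Must satisfy 0 < X0 < Xmax.
#' @param Xmax Asymptotic larval mass, mg C.
#'
#' @return An object of class `logistic_params`.
#' @seealso [verhulst_weight()], [fit_verhulst()]
#' @export
#' @examples
#' logistic_params(mu = 0.5, X0 = 1, Xmax = 100)
logistic_params <- function(mu, X0, Xmax) {
  stopifnot(is.numeric(mu), is.numeric(X0), is.numeric(Xmax),
            length(mu) == 1, length(X0) == 1, length(Xmax) == 1)
  if (!is.finite(mu) || !is.finite(X0) || !is.finite(Xmax))
    stop("logistic_params: all parameters must be finite", call. = FALSE)
  if (mu <= 0) stop("logistic_params: mu must be > 0", call. = FALSE)
  if (X0 <= 0 || X0 >= Xmax)
    stop("logistic_params: need 0 < X0 < Xmax", call. = FALSE)
  structure(list(mu = mu, X0 = X0, Xmax = Xmax), class = "logistic_params")
}

#' Pirt-type respiration parameters
#'
#' Cost of growth and maintenance coefficient of the kinetic model. `Y` is a
#' cost ratio: mg C respired as CO2 per mg C incorporated into new tissue
#' (so the maintenance-free growth yield on assimilate is 1/(1+Y)). `m` is
#' mg C respired per mg C larva per day for life-sustaining functions not
#' associated with growth.
#'
#' @param Y Cost of growth, dimensionless, >= 0. Default 0.44 (chicken feed).
#' @param m Maintenance coefficient, day^-1, >= 0. Default 0.08 (chicken feed).
#'
#' @return An object of class `pirt_params`.
#' @export
pirt_params <- function(Y = 0.44, m = 0.08) {
  stopifnot(is.numeric(Y), is.numeric(m), length(Y) == 1, length(m) == 1)
  if (!is.finite(Y) || !is.finite(m) || Y < 0 || m < 0)
    stop("pirt_params: Y and m must be finite and >= 0", call. = FALSE)
  structure(list(Y = Y, m = m), class = "pirt_params")
}

#' Parameters of the dynamic two-compartment energy-budget model
#'
#' Constants of the dynamic model in which feed assimilation and structural
#' growth are the two rate-limiting metabolic flows. The three measurable
#' constants (`a_max`, `Y`, `m`) default to the chicken-feed values; the
#' remaining constants parameterize the two logistic rate declines and the
#' observable reconstruction and are fixed design constants of the model
#' formulation (see the methods vignette).
#'
#' @param a_max Maximal specific feed assimilation rate, day^-1 (mg C
#'   assimilated per mg C larva per day). Default 1.2.
#' @param Y Cost of structural growth, dimensionless (mg C respired per mg C
#'   incorporated). Default 0.44.
#' @param m Maintenance coefficient, day^-1. Default 0.08.
#' @param s_max Maximal specific structural growth rate, day^-1. Default
#'   1.56, set so that structural demand crosses assimilation supply exactly
#'   at the instar-5 midpoint `x5` under the chicken-feed constants
#'   (`s_max = 2 (a_max - m)/(1 + Y)`): early growth is then supply-limited
#'   with a near-constant specific growth rate, and lipid overflow begins
#'   only in the second half of the lifespan.
#' @param x5 Fraction of `Xmax` at which the structural growth-rate decline is
#'   centred (instar-5 break), in (0, 1]. Default 0.5.
#' @param k_B Steepness of the structural growth decline. Default 10.
#' @param x_A Fraction of `Xmax` at which the assimilation decline is centred,
#'   in (0, 1]. Default 0.85.
#' @param k_A Steepness of the assimilation decline. Default 15.
#' @param Y_L Cost of lipid synthesis, dimensionless (mg C respired per mg C
#'   stored as lipid); the default 0.38 follows from the electron balance of
#'   converting average feed (degree of reduction ~4.2) into lipid (~5.8).
#' @param f_C Carbon fraction of dry weight, shared by feed and larvae.
#'   Default 0.49.
#' @param h Water mass bound per unit structural dry mass, used to predict the
#'   dry-matter content. Default 2.33.
#'
#' @return An object of class `deb_params`.
#' @seealso [simulate_deb()], [deb_scenario()]
#' @export
#' @examples
#' deb_params()                       # chicken-feed defaults
#' deb_params(a_max = 1.5, m = 0.13)  # brewery-waste-like mixture
deb_params <- function(a_max = 1.2, Y = 0.44, m = 0.08,
                       s_max = 1.56, x5 = 0.5, k_B = 10,
                       x_A = 0.85, k_A = 15, Y_L = 0.38,
                       f_C = 0.49, h = 2.33) {
  p <- list(a_max = a_max, Y = Y, m = m, s_max = s_max, x5 = x5, k_B = k_B,
            x_A = x_A, k_A = k_A, Y_L = Y_L, f_C = f_C, h = h)
  bad <- !vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                 logical(1))
  if (any(bad))
    stop("deb_params: non-finite or non-scalar parameter(s): ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  if (a_max <= 0) stop("deb_params: a_max must be > 0", call. = FALSE)
  if (Y < 0 || Y_L < 0) stop("deb_params: Y and Y_L must be >= 0", call. = FALSE)
  if (m < 0) stop("deb_params: m must be >= 0", call. = FALSE)
  if (s_max <= 0) stop("deb_params: s_max must be > 0", call. = FALSE)
  if (x5 <= 0 || x5 > 1 || x_A <= 0 || x_A > 1)
    stop("deb_params: x5 and x_A must lie in (0, 1]", call. = FALSE)
  if (k_A <= 0 || k_B <= 0) stop("deb_params: k_A, k_B must be > 0", call. = FALSE)
  if (f_C <= 0 || f_C >= 1) stop("deb_params: f_C must lie in (0, 1)", call. = FALSE)
  if (h < 0) stop("deb_params: h must be >= 0", call. = FALSE)
  structure(p, class = "deb_params")
}

#' Rearing scenario for the dynamic model
#'
#' Defines the scale and time window of a simulation. `Xmax` sets the carbon
#' mass scale (the model dynamics depend on larval mass only through
#' x = X/Xmax, so efficiency results are invariant to `Xmax` at fixed
#' `X0/Xmax`). Larvae are introduced at age `t0` a few days after hatching,
#' as is usual in rearing studies.
#'
#' @param Xmax Asymptotic larval mass scale, mg C. Default 30 (about 61 mg
#'   dry weight at the default carbon fraction).
#' @param X0 Larval mass at `t0`, mg C. Default `0.002 * Xmax`.
#' @param t0 Start age, days. Default 1.
#' @param t_end Simulation horizon, days. Default 60.
#' @param harvest_rule `"at-prepupation"` (harvest when the prepupation event
#'   fires) or `"fixed-time"` (harvest at `t_end`).
#'
#' @return An object of class `deb_scenario`.
#' @export
deb_scenario <- function(Xmax = 30, X0 = 0.002 * Xmax, t0 = 1, t_end = 60,
                         harvest_rule = c("at-prepupation", "fixed-time")) {
  harvest_rule <- match.arg(harvest_rule)
  stopifnot(is.numeric(Xmax), is.numeric(X0), is.numeric(t0), is.numeric(t_end))
  if (!all(is.finite(c(Xmax, X0, t0, t_end))))
    stop("deb_scenario: all fields must be finite", call. = FALSE)
  if (X0 <= 0 || X0 >= Xmax)
    stop("deb_scenario: need 0 < X0 < Xmax", call. = FALSE)
  if (t0 >= t_end) stop("deb_scenario: need t0 < t_end", call. = FALSE)
  structure(list(Xmax = Xmax, X0 = X0, t0 = t0, t_end = t_end,
                 harvest_rule = harvest_rule),
            class = "deb_scenario")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("Verhulst logistic parameters: mu = %.4g /d, X0 = %.4g mg C, Xmax = %.4g mg C\n",
              x$mu, x$X0, x$Xmax))
  invisible(x)
}

#' @export
print.deb_params <- function(x, ...) {
  cat("Dynamic energy-budget parameters\n")
  cat(sprintf("  a_max = %.4g /d, Y = %.4g, m = %.4g /d\n", x$a_max, x$Y, x$m))
  cat(sprintf("  s_max = %.4g /d, x5 = %.3g, k_B = %.3g, x_A = %.3g, k_A = %.3g\n",
              x$s_max, x$x5, x$k_B, x$x_A, x$k_A))
  cat(sprintf("  Y_L = %.4g, f_C = %.3g, h = %.3g\n", x$Y_L, x$f_C, x$h))
  invisible(x)
}

#' @export
print.deb_scenario <- function(x, ...) {
  cat(sprintf("Scenario: X0 = %.4g mg C, Xmax = %.4g mg C, t = [%.3g, %.3g] d, harvest %s\n",
              x$X0, x$Xmax, x$t0, x$t_end, x$harvest_rule))
  invisible(x)
}

# shared: update a deb_params object from a named numeric vector (used by fitting)
set_params <- function(p, theta) {
  for (nm in names(theta)) p[[nm]] <- unname(theta[[nm]])
  class(p) <- "deb_params"
  p
}
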