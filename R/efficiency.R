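# Net growth efficiency and mass-balance performance indicators.

#' Instantaneous net growth efficiency
#'
#' NGE = r_X / r_A: the rate of carbon built into larval biomass relative to
#' the rate of carbon assimilated. For the dynamic model r_X means
#' r_B + r_L (structure plus lipid).
#'
#' @param r_X Growth rate, mg C day^-1 (vectorized).
#' @param r_A Assimilation rate, mg C day^-1; must be nonzero.
#'
#' @return NGE fraction(s).
#' @export
nge_instantaneous <- function(r_X, r_A) {
  if (!is.numeric(r_X) || !is.numeric(r_A))
    stop("nge_instantaneous: inputs must be numeric", call. = FALSE)
  if (any(r_A == 0))
    stop("nge_instantaneous: undefined ratio, r_A = 0", call. = FALSE)
  r_X / r_A
}

#' Lifetime-average net growth efficiency of a trajectory
#'
#' NGE*_avg = (X(t_harvest) - X(t0)) / (A(t_harvest) - A(t0)), both in carbon
#' equivalents; the integrated form of the instantaneous NGE. The asterisk
#' marks that the underlying model has an unbalanced composition (structure
#' and lipid carry different synthesis costs), so carbon and energy are not
#' conserved with the same efficiency.
#'
#' @param traj A [simulate_deb()] trajectory.
#' @param t0 Start of the integration window, days. Defaults to the
#'   trajectory start.
#' @param t_harvest End of the window, days. Defaults to the trajectory's
#'   harvest time (prepupation under the default harvest rule).
#'
#' @return An object of class `efficiency_result`: list with `nge_avg`, `t0`,
#'   `t_harvest`, and `nge_series` (data.frame `t`, `nge` of instantaneous
#'   values where `r_A > 0`). Values outside (0, 1) are reported with a
#'   warning, not clamped.
#' @export
nge_average <- function(traj, t0 = NULL, t_harvest = NULL) {
  stopifnot(inherits(traj, "deb_trajectory"))
  t0 <- t0 %||% traj$t[1]
  t_harvest <- t_harvest %||% attr(traj, "t_harvest")
  tspan <- range(traj$t)
  if (t0 >= t_harvest || t0 < tspan[1] - 1e-9 || t_harvest > tspan[2] + 1e-9)
    stop("nge_average: need t0 < t_harvest within the trajectory span",
         call. = FALSE)
  dX <- interp_col(traj, "X", t_harvest) - interp_col(traj, "X", t0)
  dA <- interp_col(traj, "A_cum", t_harvest) - interp_col(traj, "A_cum", t0)
  if (dA <= 0)
    stop("nge_average: undefined ratio, no assimilation in window", call. = FALSE)
  nge_avg <- dX / dA
  if (nge_avg <= 0 || nge_avg >= 1)
    warning("nge_average: NGE*_avg = ", signif(nge_avg, 4),
            " lies outside (0, 1)", call. = FALSE)
  ok <- traj$r_A > 0
  structure(list(nge_avg = nge_avg, t0 = t0, t_harvest = t_harvest,
                 nge_series = data.frame(
                   t = traj$t[ok],
                   nge = (traj$r_B[ok] + traj$r_L[ok]) / traj$r_A[ok])),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("NGE*_avg = %.4f over t = [%.3g, %.4g] d\n",
              x$nge_avg, x$t0, x$t_harvest))
  invisible(x)
}

#' Mass-balance ledger of a rearing experiment
#'
#' The four dry weights from which all performance indicators derive:
#' larvae at start and harvest, substrate supplied, and residue (unconsumed
#' substrate plus frass) at harvest. Units must be consistent (mg or g).
#'
#' @param x_dw0 Initial total larval dry weight, >= 0.
#' @param x_dw Harvested total larval dry weight, >= 0.
#' @param w_dw0 Supplied substrate dry weight, > 0.
#' @param w_dw_res Residual substrate + frass dry weight at harvest, >= 0.
#'
#' @return An object of class `mass_balance_ledger`.
#' @export
mass_balance_ledger <- function(x_dw0, x_dw, w_dw0, w_dw_res) {
  v <- c(x_dw0 = x_dw0, x_dw = x_dw, w_dw0 = w_dw0, w_dw_res = w_dw_res)
  if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
    stop("mass_balance_ledger: all masses must be finite and >= 0", call. = FALSE)
  if (w_dw0 <= 0)
    stop("mass_balance_ledger: w_dw0 must be > 0", call. = FALSE)
  structure(as.list(v), class = "mass_balance_ledger")
}

#' Performance indicators
#'
#' Light container for the four indicators; `NA` marks an absent value.
#' Provenance records, per field, whether the value was measured/supplied or
#' derived from the algebraic identities (`SCE = 1/SCR = BR/SRR`).
#'
#' @param br Bioconversion rate, larval weight gain / substrate supplied.
#' @param sce Substrate conversion efficiency, weight gain / substrate removed.
#' @param scr Substrate conversion ratio, 1/SCE.
#' @param srr Substrate reduction rate, substrate removed / supplied.
#' @param provenance Named character vector over `br`, `sce`, `scr`, `srr`.
#' @param flags Character vector of diagnostic flags.
#'
#' @return An object of class `bsf_indicators`.
#' @export
indicators <- function(br = NA_real_, sce = NA_real_, scr = NA_real_,
                       srr = NA_real_,
                       provenance = NULL, flags = character()) {
  vals <- c(br = br, sce = sce, scr = scr, srr = srr)
  if (is.null(provenance))
    provenance <- ifelse(is.na(vals), NA_character_, "measured")
  names(provenance) <- names(vals)
  structure(list(br = br, sce = sce, scr = scr, srr = srr,
                 provenance = provenance, flags = flags),
            class = "bsf_indicators")
}

#' Performance indicators from a mass-balance ledger
#'
#' BR = dX/W0, SCE = dX/(-dW), SCR = (-dW)/dX, SRR = (-dW)/W0, where
#' dX = x_dw - x_dw0 and -dW = w_dw0 - w_dw_res (substrate removed). The
#' identity BR = SCE * SRR holds exactly by construction.
#'
#' @param ledger A [mass_balance_ledger()].
#'
#' @return A [indicators()] object; undefined ratios (no growth, or no
#'   substrate removed) are `NA` with a flag.
#' @export
#' @examples
#' led <- mass_balance_ledger(0, 18, 100, 56)   # dX = 18, -dW = 44
#' indicators_from_ledger(led)                  # BR 0.18, SCE ~0.41
indicators_from_ledger <- function(ledger) {
  stopifnot(inherits(ledger, "mass_balance_ledger"))
  dX <- ledger$x_dw - ledger$x_dw0
  rem <- ledger$w_dw0 - ledger$w_dw_res   # -dW, substrate removed
  flags <- character()
  br <- dX / ledger$w_dw0
  srr <- rem / ledger$w_dw0
  if (rem <= 0) {
    sce <- NA_real_; scr <- NA_real_
    flags <- c(flags, "sce_scr_undefined_no_substrate_removed")
    if (dX == 0) sce <- NA_real_
  } else {
    sce <- dX / rem
    if (dX <= 0) {
      scr <- NA_real_
      flags <- c(flags, "scr_undefined_no_growth")
      if (dX == 0) sce <- 0
    } else {
      scr <- rem / dX
    }
  }
  indicators(br = br, sce = sce, scr = scr, srr = srr, flags = flags)
}

#' Complete a partial indicator set from the algebraic identities
#'
#' Fills missing indicators using SCE = 1/SCR and SCE = BR/SRR (and their
#' inverses). When several routes to SCE are available and disagree by more
#' than `tol` (absolute), an inconsistency flag is raised. Filled fields are
#' marked `"derived-from-identity"`. Idempotent on complete sets.
#'
#' @param partial A [indicators()] object with at least one of: `sce`; `scr`;
#'   or both `br` and `srr`.
#' @param tol Absolute agreement tolerance between routes, matched to
#'   2-decimal literature values. Default 0.02.
#'
#' @return A completed [indicators()] object.
#' @export
#' @examples
#' complete_indicators(indicators(scr = 3.75))$sce           # 0.267
#' complete_indicators(indicators(br = 0.13, srr = 0.85))$sce # 0.153
complete_indicators <- function(partial, tol = 0.02) {
  stopifnot(inherits(partial, "bsf_indicators"))
  br <- partial$br; sce <- partial$sce; scr <- partial$scr; srr <- partial$srr
  prov <- partial$provenance
  flags <- partial$flags

  sce_routes <- c(direct = sce,
                  from_scr = if (!is.na(scr) && scr != 0) 1 / scr else NA_real_,
                  from_br_srr = if (!is.na(br) && !is.na(srr) && srr != 0)
                    br / srr else NA_real_)
  have <- sce_routes[!is.na(sce_routes)]
  if (length(have) == 0)
    stop("complete_indicators: cannot complete, need sce, scr, or br+srr",
         call. = FALSE)
  if (length(have) > 1 && diff(range(have)) > tol)
    flags <- c(flags, "sce_routes_inconsistent")

  if (is.na(sce)) {
    sce <- unname(have[1]); prov["sce"] <- "derived-from-identity"
  }
  if (is.na(scr) && sce != 0) {
    scr <- 1 / sce; prov["scr"] <- "derived-from-identity"
  }
  if (is.na(br) && !is.na(srr)) {
    br <- sce * srr; prov["br"] <- "derived-from-identity"
  }
  if (is.na(srr) && !is.na(br) && sce != 0) {
    srr <- br / sce; prov["srr"] <- "derived-from-identity"
  }
  indicators(br = br, sce = sce, scr = scr, srr = srr,
             provenance = prov, flags = unique(flags))
}

#' Summarize indicators across studies
#'
#' Per-indicator minimum, maximum and count of available values across a
#' collection of indicator sets (e.g. the packaged chicken-feed literature
#' table, [bsf_table1()]).
#'
#' @param rows A non-empty list of [indicators()] objects, or a data.frame
#'   with (some of the) columns `br`, `sce`, `scr`, `srr`.
#'
#' @return A data.frame with rows `br`, `sce`, `scr`, `srr` and columns
#'   `min`, `max`, `n`; indicators absent everywhere have `n = 0` and `NA`
#'   bounds.
#' @export
indicator_summary <- function(rows) {
  if (inherits(rows, "bsf_indicators")) rows <- list(rows)
  if (is.data.frame(rows)) {
    df <- rows
  } else {
    if (!is.list(rows) || length(rows) == 0)
      stop("indicator_summary: need a non-empty list of indicators", call. = FALSE)
    df <- do.call(rbind, lapply(rows, function(r)
      data.frame(br = r$br, sce = r$sce, scr = r$scr, srr = r$srr)))
  }
  if (nrow(df) == 0) stop("indicator_summary: empty input", call. = FALSE)
  out <- data.frame(indicator = c("br", "sce", "scr", "srr"),
                    min = NA_real_, max = NA_real_, n = 0L)
  for (i in seq_len(nrow(out))) {
    nm <- out$indicator[i]
    v <- if (nm %in% names(df)) df[[nm]][!is.na(df[[nm]])] else numeric()
    out$n[i] <- length(v)
    if (length(v)) { out$min[i] <- min(v); out$max[i] <- max(v) }
  }
  out
}

#' Literature performance indicators on chicken-feed-type substrates
#'
#' The packaged table of published mass-balance performance indicators of BSF
#' larvae reared on chicken feed or similar feeds (12 studies): maximal wet
#' and dry weights where reported, BR, SCE, SCR, SRR, and whether a value was
#' read from a graph or derived from the identities (`derived` column).
#'
#' @return A data.frame with one row per study.
#' @export
#' @examples
#' indicator_summary(bsf_table1())   # SCE ranges 0.14-0.48
bsf_table1 <- function() {
  path <- system.file("extdata", "chicken_feed_indicators.csv",
                      package = "bsflux", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @export
print.bsf_indicators <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.3g", v)
  cat(sprintf("Indicators: BR = %s, SCE = %s, SCR = %s, SRR = %s\n",
              fmt(x$br), fmt(x$sce), fmt(x$scr), fmt(x$srr)))
  der <- names(x$provenance)[!is.na(x$provenance) &
                               x$provenance == "derived-from-identity"]
  if (length(der)) cat("  derived from identity:", paste(der, collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
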