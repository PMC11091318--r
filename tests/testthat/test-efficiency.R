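# Net growth efficiency and the four mass-balance performance indicators.

test_that("instantaneous NGE is the growth fraction of assimilation", {
  expect_equal(nge_instantaneous(1.0, 1.0), 1.0)
  expect_equal(nge_instantaneous(0.5, 1.0), 0.5)
  expect_error(nge_instantaneous(0.2317, 0), "r_A = 0")
})

test_that("lifetime NGE agrees with a trapezoid oracle on the flux series", {
  traj <- chicken_traj()
  res <- nge_average(traj)
  tpp <- attr(traj, "t_pp")
  expect_equal(res$t_harvest, tpp)
  # independent oracle: trapezoid integration of r_B + r_L and r_A
  pre <- traj[traj$t <= tpp, ]
  trap <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
  oracle <- trap(pre$t, pre$r_B + pre$r_L) / trap(pre$t, pre$r_A)
  expect_equal(res$nge_avg, oracle, tolerance = 1e-4)
})

test_that("constant instantaneous NGE integrates to the same average", {
  # m = 0 and permanently supply-limited growth: NGE = 1/(1+Y) at all times
  p <- deb_params(m = 0, s_max = 1000, x5 = 1)
  traj <- simulate_deb(p, deb_scenario())
  res <- nge_average(traj)
  inst <- res$nge_series$nge
  expect_lt(max(abs(inst - 1 / (1 + p$Y))), 1e-9)
  expect_equal(res$nge_avg, 1 / (1 + p$Y), tolerance = 1e-6)
})

test_that("harvest past prepupation strictly lowers the average NGE", {
  traj <- chicken_traj()
  tpp <- attr(traj, "t_pp")
  tmax <- traj$t[nrow(traj)]
  delays <- seq(0, min(5, tmax - tpp - 0.1), length.out = 4)
  nges <- vapply(delays, function(d)
    nge_average(traj, t_harvest = tpp + d)$nge_avg, 0.0)
  expect_true(all(diff(nges) < 0))
})

test_that("indicators from a ledger reproduce the mass-balance formulas", {
  led <- mass_balance_ledger(x_dw0 = 0, x_dw = 18, w_dw0 = 100, w_dw_res = 56)
  ind <- indicators_from_ledger(led)
  expect_equal(ind$br, 0.18)
  expect_equal(ind$srr, 0.44)
  expect_equal(round(ind$sce, 2), 0.41)
  expect_equal(round(ind$scr, 1), 2.4)
  # BR = SCE * SRR holds exactly for any ledger
  for (w_res in c(10, 40, 80)) {
    i <- indicators_from_ledger(mass_balance_ledger(2, 21, 100, w_res))
    expect_equal(i$br, i$sce * i$srr, tolerance = 1e-12)
  }
})

test_that("degenerate ledgers are flagged, not silently computed", {
  nogrow <- indicators_from_ledger(mass_balance_ledger(5, 5, 100, 60))
  expect_equal(nogrow$br, 0)
  expect_equal(nogrow$sce, 0)
  expect_true(is.na(nogrow$scr))
  expect_true(any(grepl("no_growth", nogrow$flags)))
  noremove <- indicators_from_ledger(mass_balance_ledger(5, 20, 100, 100))
  expect_true(is.na(noremove$sce))
  expect_true(any(grepl("no_substrate_removed", noremove$flags)))
  # all substrate consumed: SRR = 1 and SCE = BR
  allgone <- indicators_from_ledger(mass_balance_ledger(0, 18, 100, 0))
  expect_equal(allgone$srr, 1)
  expect_equal(allgone$sce, allgone$br)
})

test_that("identity completion fills missing indicators and is idempotent", {
  a <- complete_indicators(indicators(scr = 3.75))
  expect_equal(round(a$sce, 2), 0.27)
  expect_equal(a$provenance[["sce"]], "derived-from-identity")
  b <- complete_indicators(indicators(br = 0.13, srr = 0.85))
  expect_equal(round(b$sce, 2), 0.15)
  d <- complete_indicators(indicators(sce = 0.5))
  expect_equal(d$scr, 2.0)
  d2 <- complete_indicators(d)
  expect_equal(unlist(d[c("br", "sce", "scr", "srr")]),
               unlist(d2[c("br", "sce", "scr", "srr")]))
  expect_error(complete_indicators(indicators(br = 0.2)), "cannot complete")
  # disagreeing routes raise the inconsistency flag
  e <- complete_indicators(indicators(sce = 0.30, scr = 2.0))
  expect_true("sce_routes_inconsistent" %in% e$flags)
})

test_that("ledger route and identity route give identical SCE", {
  led <- mass_balance_ledger(1, 19, 100, 56)
  direct <- indicators_from_ledger(led)
  via_id <- complete_indicators(indicators(br = direct$br, srr = direct$srr))
  expect_equal(via_id$sce, direct$sce, tolerance = 1e-12)
})

test_that("the packaged literature table summarizes as published", {
  tab <- bsf_table1()
  expect_equal(nrow(tab), 12)
  s <- indicator_summary(tab)
  expect_equal(s$min[s$indicator == "sce"], 0.14)
  expect_equal(s$max[s$indicator == "sce"], 0.48)
  expect_equal(s$n[s$indicator == "sce"], 12)
  one <- indicator_summary(tab[1, ])
  expect_equal(one$min[one$indicator == "sce"],
               one$max[one$indicator == "sce"])
  empty_sce <- indicator_summary(data.frame(br = c(0.1, 0.2)))
  expect_equal(empty_sce$n[empty_sce$indicator == "sce"], 0)
  expect_true(is.na(empty_sce$min[empty_sce$indicator == "sce"]))
  expect_error(indicator_summary(list()), "non-empty")
})
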