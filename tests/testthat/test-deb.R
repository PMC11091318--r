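# Dynamic two-compartment energy-budget model: rate laws, flux partition,
# prepupal catabolism, simulation invariants, observables.

test_that("specific assimilation is a falling logistic in relative mass", {
  p <- deb_params()
  expect_equal(specific_assimilation(p$x_A, p), p$a_max / 2)
  expect_equal(specific_assimilation(0, p),
               1.2 / (1 + exp(-12.75)), tolerance = 1e-12)
  expect_equal(specific_assimilation(0, p), p$a_max, tolerance = 1e-5)
  expect_gt(specific_assimilation(0.2, p), specific_assimilation(0.8, p))
  expect_lt(specific_assimilation(1, p), 0.15 * p$a_max)
})

test_that("structural demand is near-maximal early and collapses near Xmax", {
  p <- deb_params()   # k_B = 10, x5 = 0.5
  B <- 7
  expect_equal(structural_demand(p$x5, B, p), p$s_max * B / 2)
  expect_equal(structural_demand(0.05, B, p), p$s_max * B,
               tolerance = 0.02)
  expect_lt(structural_demand(0.95, B, p), 0.02 * p$s_max * B)
  expect_error(structural_demand(0.5, 0, p), "B must be > 0")
})

test_that("flux partition follows maintenance -> structure -> lipid priority", {
  sc <- deb_scenario(Xmax = 30)
  # supply-limited: huge demand, everything after maintenance goes to structure
  p_hi <- deb_params(s_max = 1000, x5 = 1)
  st <- list(B = 10, L = 0)
  f <- partition_fluxes(st, p_hi, sc)
  avail <- f$r_A - p_hi$m * 10
  expect_equal(f$r_CO2_m, p_hi$m * 10)
  expect_equal(f$r_B, avail / (1 + p_hi$Y), tolerance = 1e-12)
  expect_equal(f$r_CO2_B, p_hi$Y * f$r_B, tolerance = 1e-12)
  expect_equal(f$r_L, 0)
  expect_equal(f$r_CO2_L, 0)

  # demand-limited: small s_max, excess assimilate overflows to lipid
  p_lo <- deb_params(s_max = 0.05)
  g <- partition_fluxes(st, p_lo, sc)
  dem <- structural_demand(10 / 30, 10, p_lo)
  expect_equal(g$r_B, dem, tolerance = 1e-12)
  E <- g$r_A - p_lo$m * 10 - (1 + p_lo$Y) * g$r_B
  expect_equal(g$r_L, E / (1 + p_lo$Y_L), tolerance = 1e-12)
  expect_equal(g$r_CO2_L, p_lo$Y_L * g$r_L, tolerance = 1e-12)
  expect_gt(g$r_L, 0)

  # carbon closure is exact in both branches
  for (fl in list(f, g))
    expect_equal(fl$r_A,
                 fl$r_B + fl$r_L + fl$r_CO2_B + fl$r_CO2_L + fl$r_CO2_m,
                 tolerance = 1e-12)
})

test_that("supply below maintenance stops growth and draws on lipid", {
  sc <- deb_scenario(Xmax = 30)
  # near-prepupal larva: assimilation far below maintenance
  p <- deb_params(m = 0.3)
  st <- list(B = 15, L = 14.9)   # x close to 1, a(x) small
  f <- partition_fluxes(st, p, sc)
  X <- st$B + st$L
  expect_lt(f$r_A, p$m * X)
  expect_true(f$starvation)
  expect_equal(f$r_B, 0)
  expect_equal(f$r_L, -(p$m * X - f$r_A), tolerance = 1e-12)
  expect_equal(f$r_CO2_L, 0)
  expect_equal(f$r_A, f$r_B + f$r_L + f$r_CO2_B + f$r_CO2_L + f$r_CO2_m,
               tolerance = 1e-12)
})

test_that("prepupal catabolism pays maintenance from lipid only", {
  p <- deb_params()
  f <- prepupal_step(list(B = 30, L = 30), p)
  expect_equal(f$r_A, 0)
  expect_equal(f$r_B, 0)
  expect_equal(f$r_L, -0.08 * 60)      # dX/dt = -4.8 mg C/d, all from lipid
  expect_equal(f$r_CO2_m, 4.8)
  expect_error(prepupal_step(list(B = 30, L = 0), p), "exhausted")
})

test_that("simulated trajectory conserves carbon and loses weight after t_pp", {
  traj <- chicken_traj()
  n <- nrow(traj)
  # cumulative closure at integrator precision
  expect_lt(abs(traj$A_cum[n] - (traj$X[n] - traj$X[1]) - traj$CO2_cum[n]) /
              traj$A_cum[n], 1e-6)
  # per-row flux closure (exact by construction)
  res <- traj$r_A - (traj$r_B + traj$r_L + traj$r_CO2_B + traj$r_CO2_L +
                       traj$r_CO2_m)
  expect_lt(max(abs(res)), 1e-9 * max(traj$r_A))
  tpp <- attr(traj, "t_pp")
  expect_false(is.na(tpp))
  expect_true(all(diff(traj$X[traj$t <= tpp]) > 0))       # growing larva
  post <- traj$X[traj$t > tpp]
  expect_true(all(diff(post) < 0))                        # shrinking prepupa
  expect_true(all(traj$B[traj$t > tpp] == traj$B[traj$t > tpp][1]))
})

test_that("dry-weight trajectory is sigmoidal with one inflection before t_pp", {
  traj <- chicken_traj()
  pre <- traj[traj$t <= attr(traj, "t_pp"), ]
  d2 <- diff(diff(pre$X))
  d2[abs(d2) < 1e-8 * max(abs(d2))] <- 0
  sgn <- sign(d2[d2 != 0])
  expect_equal(sum(diff(sgn) != 0), 1)
})

test_that("efficiency is invariant to the carbon mass scale", {
  p <- deb_params()
  n1 <- nge_average(simulate_deb(p, deb_scenario(Xmax = 30)))$nge_avg
  n2 <- nge_average(simulate_deb(p, deb_scenario(Xmax = 300)))$nge_avg
  expect_equal(n1, n2, tolerance = 1e-7)
})

test_that("observables reconstruct dry weight, CO2, lipid and water content", {
  traj <- chicken_traj()
  p <- deb_params()
  obs <- predict_observables(traj)
  expect_equal(obs$x_dw, traj$X / p$f_C)
  expect_equal(obs$r_co2,
               (traj$r_CO2_B + traj$r_CO2_L + traj$r_CO2_m) * 44 / 12)
  # lean larva: no lipid signal, dry-matter content 1/(1+h)
  i0 <- which(traj$L < 1e-12)[1]
  expect_equal(obs$delta_lipid[i0], 0)
  expect_equal(obs$delta_dw[i0], 1 / (1 + p$h), tolerance = 1e-9)
  # anhydrous-lipid limit: delta_dw rises monotonically with L at fixed B
  fake <- traj[rep(i0, 5), ]
  fake$L <- c(0, 1, 5, 20, 100)
  fake$X <- fake$B + fake$L
  attr(fake, "params") <- p
  class(fake) <- class(traj)
  dd <- predict_observables(fake, p)$delta_dw
  expect_true(all(diff(dd) > 0))
  expect_lt(1 - dd[5] / 1, 0.3)
  # relative lipid content accumulates through the larval phase (monotone up
  # to a sliver of numerical give just before t_pp, where the dwindling
  # overflow is shared with structural growth)
  lar <- obs$delta_lipid[traj$t <= attr(traj, "t_pp")]
  expect_true(all(diff(lar) > -1e-4 * max(lar)))
  expect_gt(lar[length(lar)], 0.9 * max(lar))
})

test_that("simulation stops with a flag when prepupal lipid runs out", {
  traj <- simulate_deb(deb_params(), deb_scenario(t_end = 60))
  expect_true(attr(traj, "lipid_depleted"))
  expect_lt(traj$t[nrow(traj)], 60)
  expect_lt(traj$L[nrow(traj)], 1e-6)
})
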