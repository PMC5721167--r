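test_that("nodal stiffness, wall displacement and the tube law are mutually consistent", {
  A0 <- 8.042e-4                      # 32 mm vessel
  C_A <- 1e-8
  K <- nodal_stiffness(C_A, A0)
  expect_equal(K, 2 * sqrt(pi * A0) / C_A, tolerance = 1e-12)
  expect_equal(K, 1.0053e7, tolerance = 1e-4)
  expect_identical(nodal_stiffness(0, A0), Inf)
  expect_equal(nodal_stiffness(C_A / 2, A0), 2 * K, tolerance = 1e-12)

  p_ext <- 76 * MMHG_TO_PA
  expect_identical(wall_displacement(p_ext, p_ext, K), 0)
  d <- wall_displacement(p_ext + 68 * MMHG_TO_PA, p_ext, K)
  expect_equal(d, 9.066e3 / 1.0053e7, tolerance = 1e-3)
  expect_equal(wall_displacement(p_ext + 500, p_ext, K),
               -wall_displacement(p_ext - 500, p_ext, K))

  expect_equal(area_from_pressure(A0, K, p_ext, p_ext), A0)
  A <- area_from_pressure(A0, K, p_ext + 9066, p_ext)
  expect_equal(A, pi * (sqrt(A0 / pi) + 9066 / K)^2, tolerance = 1e-12)
  expect_equal(A, 8.975e-4, tolerance = 1e-3)
  # linearization: dA/dp at p_ext equals C_A to 0.01%
  h <- 1e-3
  slope <- (area_from_pressure(A0, K, p_ext + h, p_ext) -
              area_from_pressure(A0, K, p_ext - h, p_ext)) / (2 * h)
  expect_equal(slope, C_A, tolerance = 1e-4)
  expect_error(area_from_pressure(A0, K, p_ext - 2 * K * sqrt(A0 / pi), p_ext),
               "collapse")
})

test_that("Carreau-Yasuda viscosity spans its limits and matches a dual formula", {
  rheo <- rheology_params()
  expect_equal(cy_viscosity(0, rheo), rheo$mu_0)
  expect_equal(cy_viscosity(1e9, rheo), rheo$mu_inf, tolerance = 1e-3)
  g <- 1 / rheo$lambda                 # midpoint lambda*gamma = 1
  ref <- rheo$mu_inf + (rheo$mu_0 - rheo$mu_inf) *
    2^((rheo$n_cy - 1) / rheo$a_cy)    # independent evaluation
  expect_equal(cy_viscosity(g, rheo), ref, tolerance = 1e-12)
  gg <- c(0.1, 1, 10, 100, 1000)
  expect_true(all(diff(cy_viscosity(gg, rheo)) < 0))
  expect_error(cy_viscosity(-1, rheo), ">= 0")
})

test_that("wall shear follows the Poiseuille closed form and is odd in Q", {
  rheo <- newtonian_rheology(4e-3)
  Q <- 1.345e-4; r <- 0.016
  tw <- wall_shear(Q, pi * r^2, rheo)
  expect_equal(tw, 4 * 4e-3 * Q / (pi * r^3), tolerance = 1e-12)
  expect_equal(tw, 0.167, tolerance = 2e-3)
  expect_identical(wall_shear(0, pi * r^2, rheo), 0)
  expect_equal(wall_shear(-Q, pi * r^2), -wall_shear(Q, pi * r^2))
})

test_that("tear orifice flow is odd and matches the direct evaluation", {
  tear <- tear_orifice()               # 18.5 mm^2, Cd = 0.6
  expect_identical(tear_flow(0, tear), 0)
  Q <- tear_flow(30 * MMHG_TO_PA, tear, 1056)
  expect_equal(Q, 3.055e-5, tolerance = 1e-3)
  expect_equal(tear_flow(-30 * MMHG_TO_PA, tear), -Q)
  expect_error(tear_orifice(Cd = 1.5), "Cd")
})

test_that("steady flow through a compliant tube matches Poiseuille and the WK3 load", {
  # narrow tube so the viscous gradient is well above solver noise
  geom <- single_tube(length = 0.3, n = 16, diameter = 0.010, D = 1.7e-5,
                      R_tot = 4, C = 0.3)
  wf <- const_flow(20)
  res <- solve_pulsewave(geom, list(inlet = wf), n_cycles = 20,
                         rheo = newtonian_rheology(4e-3), tol_cycle = 1e-4)
  p0 <- result_probe(res, "tube", 0)$P
  p1 <- result_probe(res, "tube", 1)$P
  A_op <- mean(result_probe(res, "tube", 0.5)$A$v)
  dP_pois <- 8 * pi * 4e-3 * 0.3 * 20e-6 / A_op^2
  expect_equal(mean(p0$v) - mean(p1$v), dP_pois, tolerance = 0.01 * dP_pois)
  expect_equal(mean(p1$v) / MMHG_TO_PA, 4 * 20, tolerance = 0.01 * 80)
  expect_equal(mean(result_probe(res, "tube", 1)$Q$v) * 1e6, 20, tolerance = 0.01 * 20)
})

test_that("a narrow pulse travels at the Bramwell-Hill wave speed", {
  rho <- 1056; D <- 1.18e-5
  geom <- single_tube(length = 0.6, n = 64, diameter = 0.032, D = D,
                      R_tot = 0.8, C = 1.0)
  Tp <- 0.8; t <- seq(0, Tp - 1e-3, by = 1e-3)
  wf <- waveform(t, 20 + 150 * exp(-((t - 0.1) / 0.015)^2), Tp)
  res <- suppressWarnings(solve_pulsewave(geom, list(inlet = wf), n_cycles = 6))
  pa <- result_probe(res, "tube", 0.1)$P
  pb <- result_probe(res, "tube", 0.9)$P
  pwv <- foot_to_foot_pwv(pa, pb, 0.8 * 0.6)
  expect_equal(pwv, 1 / sqrt(rho * D), tolerance = 0.05)
})

test_that("grid refinement leaves outlet waveforms unchanged within 2%", {
  run <- function(n) {
    geom <- single_tube(length = 0.5, n = n, diameter = 0.025, D = 1.2e-5,
                        R_tot = 1.0, C = 1.0)
    solve_pulsewave(geom, list(inlet = synth_inflow(inflow_spec())),
                    n_cycles = 12, tol_cycle = 3e-3)
  }
  p16 <- result_probe(run(16), "tube", 1)$P$v
  p32 <- result_probe(run(32), "tube", 1)$P$v
  pulse <- max(p16) - min(p16)
  expect_lt(max(abs(p16 - p32)) / pulse, 0.02)
})

test_that("the full compliant fixture conserves volume per cycle", {
  rep <- fixture_pipeline()
  sim <- rep$simulation
  expect_true(sim$converged)
  expect_lt(sim$balance$relative_error, 0.005)
})

test_that("rigid two-lumen model has exactly zero false-lumen flow", {
  rig <- fixture_rigid_result()
  expect_identical(max(abs(rig$segments$fl$Q)), 0)
  # rigid network: instantaneous balance, inflow = sum of outflows
  q_in <- inlet_flow_ml(rig, fixture_pipeline()$geometry)
  outs <- outlet_flows_ml(rig, fixture_pipeline()$geometry)
  tot_out <- Reduce(`+`, lapply(outs, function(w) w$v))
  expect_lt(max(abs(q_in$v - tot_out)) / max(q_in$v), 0.02)
})

test_that("compliance attenuates systolic and augments diastolic lumen flow", {
  rep <- fixture_pipeline()
  sim <- rep$simulation
  rig <- fixture_rigid_result()
  sw <- systole_window(synth_inflow(inflow_spec()))
  rel <- (sim$t - sw[1L]) %% sim$T
  sys <- rel <= (sw[2L] - sw[1L])
  qc <- result_probe(sim, "tl", 0.5)$Q$v * 1e6
  qr <- result_probe(rig, "tl", 0.5)$Q$v * 1e6
  expect_lt(mean(qc[sys]), mean(qr[sys]))     # lower TL flow in systole
  expect_gt(mean(qc[!sys]), mean(qr[!sys]))   # higher TL flow in diastole
  expect_lt(max(qc), max(qr))                 # attenuated peak
  # cycle means agree (compliance redistributes, it does not add flow)
  expect_equal(mean(qc), mean(qr), tolerance = 0.05 * mean(qr))
})

test_that("systolic storage matches the compliance bookkeeping within 15%", {
  rep <- fixture_pipeline()
  sim <- rep$simulation
  geom <- rep$geometry
  outs <- outlet_flows_ml(sim, geom)
  qin <- inlet_flow_ml(sim, geom)
  net <- qin$v - Reduce(`+`, lapply(outs, function(w) w$v))
  stored_max <- diff(range(cumsum(net) * sim$dt))
  pred <- 0
  for (s in names(geom$segments)) {
    seg <- geom$segments[[s]]
    pm <- result_probe(sim, s, 0.5)$P$v
    pred <- pred + mean(seg$C_A) * seg$length * diff(range(pm)) * 1e6
  }
  expect_equal(stored_max, pred, tolerance = 0.15 * pred)
  expect_gt(stored_max, 0)
})

test_that("CFL violations and missing terminal parameters are explicit errors", {
  geom <- single_tube()
  geom$boundaries$out$params <- NULL
  expect_error(solve_pulsewave(geom, list(inlet = const_flow(50))),
               "without parameters")
  g2 <- single_tube()
  expect_error(solve_pulsewave(g2, list(inlet = const_flow(50)), dt = 0.3),
               "dt must divide|CFL")
})

test_that("geometry validation enforces the dissection topology", {
  cfg <- fixture_config(n_nodes = 8)
  geom <- idealized_dissected_aorta(cfg)
  expect_setequal(
    names(Filter(function(b) b$type == "wk3", geom$boundaries)),
    c("RSA", "LSA", "CT", "SMA", "RRA", "LRA", "AbAo"))
  expect_setequal(
    names(Filter(function(b) b$type %in% c("q_in", "q_out"), geom$boundaries)),
    c("inlet", "RCC", "LCC"))
  # single-lumen variant drops the FL and its junctions stay consistent
  g1 <- idealized_dissected_aorta(fixture_config(n_nodes = 8, dissected = FALSE))
  expect_null(g1$dissection)
  expect_false("fl" %in% names(g1$segments))
  # a dangling end is rejected
  segs <- list(a = vessel_segment("a", 0.1, 8, A0 = 1e-4, C_A = 1e-9))
  expect_error(network_geometry(segs, list(), list(
    inlet = list(seg = "a", end = "proximal", type = "q_in"))), "unconnected")
})
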