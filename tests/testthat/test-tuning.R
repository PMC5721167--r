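test_that("fit_system_wk3 hits the pressure targets and rejects degenerate input", {
  wf <- synth_inflow(inflow_spec())
  tg <- tuning_targets()
  fit <- fit_system_wk3(wf, tg)
  expect_lt(abs(fit$P_sys - 150), 0.5)
  expect_lt(abs(fit$P_dia - 80), 0.5)
  # mean pressure identity of the periodic WK3: Pbar = R_tot * Qbar
  expect_equal(fit$P_mean, fit$R_tot * cycle_mean(wf), tolerance = 1e-3)
  expect_error(fit_system_wk3(const_flow(134.5), tg), "unidentifiable")
  expect_error(tuning_targets(P_sys = 80, P_dia = 80), "P_sys > P_dia")
})

test_that("fit_system_wk3 matches a closed-form square-wave oracle within 1%", {
  Tp <- 0.8; dt <- 1e-4
  a <- Tp / 3                    # ON duration
  t <- seq(0, Tp - dt, by = dt)
  Qh <- 300
  wf <- waveform(t, ifelse(t < a, Qh, 0), Tp)
  tg <- tuning_targets(P_sys = 150, P_dia = 80)
  fit <- fit_system_wk3(wf, tg, dt = dt)

  # oracle: piecewise-exponential periodic solution of the WK3 ODE.
  # Capacitor pressure Pc = P - R1 Q is continuous; P jumps by R1*dQ.
  f <- tg$r1_fraction
  b <- Tp - a
  extremes <- function(R_tot, C) {
    R1 <- f * R_tot; R2 <- (1 - f) * R_tot
    tau <- R2 * C
    ea <- exp(-a / tau); eb <- exp(-b / tau)
    # periodic fixed point: Pc at ON start
    Pc0 <- R2 * Qh * (1 - ea) * eb / (1 - ea * eb)
    Pc_a <- R2 * Qh + (Pc0 - R2 * Qh) * ea
    c(sys = Pc_a + R1 * Qh, dia = Pc0)   # max at ON end, min at OFF end
  }
  C_star <- NA
  R_tot <- 110 / cycle_mean(wf)
  for (i in 1:80) {
    lo <- 1e-3; hi <- 50
    for (k in 1:60) {
      C_star <- sqrt(lo * hi)
      ex <- extremes(R_tot, C_star)
      if (ex["sys"] - ex["dia"] > 70) lo <- C_star else hi <- C_star
    }
    ex <- extremes(R_tot, C_star)
    if (abs(ex["sys"] - 150) < 0.01 && abs(ex["dia"] - 80) < 0.01) break
    R_tot <- unname(R_tot + (150 - ex["sys"]) / cycle_mean(wf))
  }
  expect_equal(fit$C_sys, C_star, tolerance = 0.01)
})

test_that("fit_system_wk3 is invariant to time-shifting the inflow", {
  wf <- synth_inflow(inflow_spec())
  wf2 <- waveform(wf$t, wf_interp(wf, wf$t - 0.25), wf$T)
  f1 <- fit_system_wk3(wf, tuning_targets())
  f2 <- fit_system_wk3(wf2, tuning_targets())
  expect_equal(f1$C_sys, f2$C_sys, tolerance = 1e-6)
  expect_equal(f1$R_tot, f2$R_tot, tolerance = 1e-6)
})

test_that("distribute_outlet_params: symmetry, flow targets, series bookkeeping", {
  # two identical terminals on a symmetric network get identical parameters
  wf <- synth_inflow(inflow_spec())
  net <- lumped_network(
    data.frame(name = c("a", "b"), from = c("n0", "n0"), to = c("ta", "tb"),
               L = c(1e-4, 1e-4), R = c(0.01, 0.01)),
    list(ta = wk3_params(0.1, 1, 0.5), tb = wk3_params(0.1, 1, 0.5)),
    list(n0 = wf))
  tg <- tuning_targets(mean_flows = c(ta = 67.25, tb = 67.25))
  d <- distribute_outlet_params(1.0, tg, net, P_mean_init = 110)
  expect_true(d$converged)
  expect_equal(d$params$ta$R1, d$params$tb$R1, tolerance = 1e-10)
  expect_equal(d$params$ta$C, d$params$tb$C, tolerance = 1e-10)
  expect_equal(unname(d$params$ta$C + d$params$tb$C), 1.0, tolerance = 1e-10)
  expect_lt(max(abs(d$achieved / c(67.25, 67.25) - 1)), 0.01)

  # degenerate single outlet: recovered R_tot = system R_tot - series R
  fit <- fit_system_wk3(wf, tuning_targets())
  R_ser <- 0.05
  net1 <- lumped_network(
    data.frame(name = "s", from = "n0", to = "t1", L = 1e-4, R = R_ser),
    list(t1 = fit$params), list(n0 = wf))
  tg1 <- tuning_targets(mean_flows = c(t1 = cycle_mean(wf)))
  d1 <- distribute_outlet_params(fit$C_sys, tg1, net1, P_mean_init = fit$P_mean)
  R_rec <- d1$params$t1$R1 + d1$params$t1$R2
  expect_equal(R_rec, fit$R_tot - R_ser, tolerance = 0.01 * fit$R_tot)
})

test_that("distribute_outlet_params achieves the branch-flow table on the fixture", {
  rep <- fixture_pipeline()
  tgt <- table1_mean_flows()
  expect_true(rep$step2$converged)
  expect_lt(max(abs(rep$step2$achieved[names(tgt)] / tgt - 1)), 0.01)
})

test_that("normalized area variation and the distensibility estimators", {
  t <- seq(0, 0.799, by = 1e-3)
  # constant area -> identically zero
  expect_true(all(normalized_area_variation(const_flow(500))$v == 0))
  # min 500, max 555 mm^2 -> peak 11.0%
  A <- waveform(t, 527.5 - 27.5 * cos(2 * pi * t / 0.8), 0.8)
  expect_equal(max(normalized_area_variation(A)$v), 55 / 500, tolerance = 1e-6)
  # sinusoid 100 + 10 sin -> peak 20/90
  A2 <- waveform(t, 100 + 10 * sin(2 * pi * t / 0.8), 0.8)
  expect_equal(max(normalized_area_variation(A2)$v), 20 / 90, tolerance = 1e-6)
  expect_error(normalized_area_variation(waveform(t, sin(t), 0.8)), "positive")

  # D = dA*/dP
  expect_equal(estimate_distensibility(0.110, 70 * MMHG_TO_PA), 1.179e-5,
               tolerance = 1e-3, ignore_attr = TRUE)
  D0 <- estimate_distensibility(0, 1000)
  expect_identical(as.numeric(D0), 0)
  expect_true(attr(D0, "degenerate"))
  expect_error(estimate_distensibility(0.1, 0), "deltaP")
})

test_that("distensibility round-trips through synthetic area data", {
  t <- seq(0, 0.799, by = 1e-3)
  P <- waveform(t, (100 + 30 * sin(2 * pi * t / 0.8)) * MMHG_TO_PA, 0.8)
  D_true <- 1.18e-5
  A <- synth_area_waveform(P, D_true, 8.04e-4)
  dAs <- max(normalized_area_variation(A)$v)
  dP <- max(P$v) - min(P$v)
  expect_equal(as.numeric(estimate_distensibility(dAs, dP)), D_true,
               tolerance = 1e-3)
  expect_equal(as.numeric(fit_distensibility(A, P)), D_true, tolerance = 1e-6)
})

test_that("the PWV-diameter law and Bramwell-Hill relation", {
  expect_identical(pwv_from_diameter(1), 13.3)
  expect_equal(pwv_from_diameter(25), 13.3 / 25^0.3, tolerance = 1e-12)
  d <- sort(runif(20, 1, 40))
  expect_true(all(diff(pwv_from_diameter(d)) < 0))
  expect_error(pwv_from_diameter(0), "> 0")

  expect_equal(distensibility_from_pwv(5.063, 1056), 3.694e-5, tolerance = 1e-3)
  expect_equal(distensibility_from_pwv(10) / distensibility_from_pwv(20), 4,
               tolerance = 1e-12)
  # algebraic inverse: d -> PWV -> D -> 1/sqrt(rho D) recovers PWV
  pwv <- pwv_from_diameter(18)
  expect_equal(1 / sqrt(1056 * distensibility_from_pwv(pwv, 1056)), pwv,
               tolerance = 1e-12)
})

test_that("aortic compliance integration is additive and unit-correct", {
  seg <- vessel_segment("u", 0.3, 16, A0 = 8e-4, C_A = 1e-8)
  C1 <- integrate_aortic_compliance(list(seg))
  expect_equal(C1, 3e-9 * M3_PER_PA_TO_ML_PER_MMHG, tolerance = 1e-12)
  expect_equal(C1, 0.39997, tolerance = 1e-4)
  halves <- list(vessel_segment("a", 0.15, 16, A0 = 8e-4, C_A = 1e-8),
                 vessel_segment("b", 0.15, 16, A0 = 8e-4, C_A = 1e-8))
  expect_equal(integrate_aortic_compliance(halves), C1, tolerance = 1e-12)
  expect_error(integrate_aortic_compliance(list()), "empty")
})

test_that("step-4 re-tuning preserves R_tot and reproduces the printed compliance split", {
  tgt <- table1_mean_flows()
  # step-2-like parameters: R_tot per outlet from a 113 mmHg mean
  rigid <- lapply(tgt, function(q) {
    Rt <- 113 / q
    wk3_params(0.056 * Rt, (1 - 0.056) * Rt, 0.99 * q / sum(tgt))
  })
  props <- list(
    RSA = list(PWV = pwv_from_diameter(9), A0 = pi * 0.0045^2),
    LSA = list(PWV = pwv_from_diameter(9), A0 = pi * 0.0045^2),
    CT = list(PWV = pwv_from_diameter(8), A0 = pi * 0.004^2),
    SMA = list(PWV = pwv_from_diameter(7), A0 = pi * 0.0035^2),
    RRA = list(PWV = pwv_from_diameter(6), A0 = pi * 0.003^2),
    LRA = list(PWV = pwv_from_diameter(6), A0 = pi * 0.003^2),
    AbAo = list(PWV = pwv_from_diameter(16), A0 = pi * 0.008^2))
  budget <- compliance_budget(C_sys = 0.99, C_aorta = 0.41)
  out <- retune_for_compliant(budget, rigid, props, tgt)
  # compliances sum to C_per and the AbAo share matches the printed 0.157
  expect_equal(sum(vapply(out, function(p) p$C, numeric(1))), 0.58,
               tolerance = 1e-12)
  expect_equal(out$AbAo$C, 0.58 * 30.5 / sum(tgt), tolerance = 1e-12)
  expect_equal(out$AbAo$C, 0.157, tolerance = 0.01)
  # R1 + R2 = R_tot exactly, R1 = rho PWV / A0
  for (o in names(out)) {
    expect_equal(out[[o]]$R1 + out[[o]]$R2, rigid[[o]]$R1 + rigid[[o]]$R2,
                 tolerance = 1e-12)
    Z <- 1056 * props[[o]]$PWV / props[[o]]$A0 / (MMHG_TO_PA * 1e6)
    expect_equal(out[[o]]$R1, Z, tolerance = 1e-12)
  }
  # degenerate budget: C_aorta = 0 keeps the step-2 compliances
  out0 <- retune_for_compliant(compliance_budget(0.99, 0), rigid, props, tgt)
  for (o in names(out0)) expect_equal(out0[[o]]$C, rigid[[o]]$C)
  # characteristic impedance >= R_tot is an explicit error naming the outlet
  rigid$RRA <- wk3_params(0.01, 0.05, 0.07)
  expect_error(retune_for_compliant(budget, rigid, props, tgt), "RRA")
})

test_that("the tuning pipeline closes its compliance budget and reports deviations", {
  rep <- fixture_pipeline()
  expect_equal(rep$budget$C_per, rep$budget$C_sys - rep$budget$C_aorta,
               tolerance = 1e-14)
  expect_equal(sum(vapply(rep$params, function(p) p$C, numeric(1))),
               rep$budget$C_per, tolerance = 1e-12)
  # rigid-only mode reproduces step 2 verbatim
  geom <- idealized_dissected_aorta(fixture_config())
  r0 <- tune_pipeline(geom, synth_inflow(inflow_spec()), tuning_targets(),
                      rigid_only = TRUE)
  for (o in names(r0$params)) {
    expect_equal(r0$params[[o]]$R1, rep$step2$params[[o]]$R1, tolerance = 1e-9)
    expect_equal(r0$params[[o]]$C, rep$step2$params[[o]]$C, tolerance = 1e-9)
  }
  expect_true(is.finite(rep$max_deviation_pct))
})
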