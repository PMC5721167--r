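test_that("wk3_step reaches the analytic steady state (R1+R2)*Q", {
  p <- wk3_params(R1 = 0.115, R2 = 3.608, C = 0.157)  # abdominal outlet values
  st <- wk3_state(P = 0, Q_prev = 30.5)
  for (i in 1:20000) st <- wk3_step(st, 30.5, p, 1e-3)
  expect_equal(st$P, (0.115 + 3.608) * 30.5, tolerance = 1e-6)
})

test_that("wk3_step decays exponentially with Q = 0 and converges first order", {
  p <- wk3_params(R1 = 0.115, R2 = 3.608, C = 0.157)
  tau <- 3.608 * 0.157
  errs <- sapply(c(1e-3, 5e-4, 2.5e-4), function(dt) {
    st <- wk3_state(P = 100, Q_prev = 0)
    n <- round(tau / dt)
    for (i in seq_len(n)) st <- wk3_step(st, 0, p, dt)
    abs(st$P - 100 * exp(-1))
  })
  expect_equal(errs[1], 0, tolerance = 0.1)       # near 36.79 at dt = 1 ms
  expect_gt(errs[1] / errs[2], 1.8)               # first-order in dt
  expect_gt(errs[2] / errs[3], 1.8)
  # zero fixed point
  st <- wk3_state(P = 0, Q_prev = 0)
  for (i in 1:100) st <- wk3_step(st, 0, p, 1e-3)
  expect_identical(st$P, 0)
})

test_that("wk3_step rejects bad inputs", {
  p <- wk3_params(0.1, 1, 0.5)
  expect_error(wk3_step(wk3_state(), 10, p, 0), "dt")
  expect_error(wk3_step(wk3_state(), NaN, p, 1e-3), "non-finite")
  expect_error(wk3_params(-0.1, 1, 0.5), "R1")
  expect_error(wk3_params(0.1, 0, 0.5), "R2")
})

test_that("lr_step has the Ohmic steady state and analytic decay", {
  b <- lr_block(L = 0.01, R = 2)
  Q <- 0
  for (i in 1:5000) Q <- lr_step(Q, 10, 0, b, 1e-4)
  expect_equal(Q, 5, tolerance = 1e-9)
  # decay with time constant L/R
  b2 <- lr_block(L = 0.01, R = 1)
  Q <- 8
  dt <- 1e-4
  for (i in seq_len(round(0.01 / dt))) Q <- lr_step(Q, 50, 50, b2, dt)
  expect_equal(Q, 8 * exp(-1), tolerance = 0.02 * 8)
  expect_error(lr_block(L = 0, R = 1), "L")
})

test_that("lr_step tracks the analytic step response, first order in dt", {
  # rise 0 -> 5 ml/s under a 10 mmHg head, R = 2, tau = L/R
  b <- lr_block(L = 0.02, R = 2)
  tau <- b$L / b$R
  err_at <- function(dt) {
    n <- round(5 * tau / dt)
    Q <- 0; e <- 0
    for (i in seq_len(n)) {
      Q <- lr_step(Q, 10, 0, b, dt)
      e <- max(e, abs(Q - 5 * (1 - exp(-i * dt / tau))))
    }
    e / 5
  }
  e1 <- err_at(0.02 * tau)
  expect_lt(e1, 0.01)
  expect_gt(err_at(0.04 * tau) / e1, 1.8)
})

test_that("solve_lumped on a direct source-terminal node matches the WK3 oracle", {
  p <- wk3_params(0.115, 3.608, 0.05)  # short time constant
  wf <- synth_inflow(inflow_spec())
  net <- lumped_network(
    data.frame(name = "stub", from = "n0", to = "nt", L = 1e-6, R = 0),
    list(nt = p), list(n0 = wf))
  sol <- solve_lumped(net, dt = 1e-3, n_cycles = 60, tol = 1e-10)
  m <- 800
  Q <- wf_interp(wf, seq(1e-3, by = 1e-3, length.out = m))
  P_oracle <- pulsead:::wk3_periodic(Q, p, 1e-3)
  expect_lt(max(abs(sol$pressures$nt$v - P_oracle)) / max(P_oracle), 1e-7)
})

test_that("zero-inertance, zero-compliance limit acts as a resistive divider", {
  wf <- const_flow(100)
  # two terminals, tiny L and C: flows split as 1/R_tot
  net <- lumped_network(
    data.frame(name = c("a", "b"), from = c("n0", "n0"), to = c("ta", "tb"),
               L = c(1e-8, 1e-8), R = c(0, 0)),
    list(ta = wk3_params(0, 2, 1e-6), tb = wk3_params(0, 6, 1e-6)),
    list(n0 = wf))
  sol <- suppressWarnings(solve_lumped(net, dt = 1e-3, n_cycles = 30, tol = 1e-8))
  qa <- cycle_mean(sol$terminal_flows$ta)
  qb <- cycle_mean(sol$terminal_flows$tb)
  expect_equal(qa / qb, 6 / 2, tolerance = 1e-3)
  expect_equal(qa + qb, 100, tolerance = 1e-3)
})

test_that("periodic steady state conserves charge and capacitor balance", {
  rep <- fixture_pipeline()
  geom <- idealized_dissected_aorta(fixture_config())
  lump <- geometry_to_lumped(geom, fixture_sources(),
                             terminal_params = rep$step2$params)
  sol <- solve_lumped(lump$net, dt = 1e-3, n_cycles = 40, tol = 1e-7)
  q_in <- sum(vapply(lump$net$sources, cycle_mean, numeric(1)))
  q_out <- sum(vapply(sol$terminal_flows, cycle_mean, numeric(1)))
  expect_lt(abs(q_in - q_out) / q_in, 1e-3)
  # per-cycle capacitor volume: cycle mean of (Q_t - Pc/R2) vanishes at
  # periodic steady state (Pc = P_node - R1 * Q_t)
  for (nm in names(sol$terminal_flows)) {
    p <- rep$step2$params[[nm]]
    Qt <- sol$terminal_flows[[nm]]$v
    Pc <- sol$pressures[[nm]]$v - p$R1 * Qt
    q_cap <- mean(Qt - Pc / p$R2)
    expect_lt(abs(q_cap), 1e-3 * mean(Qt))
  }
})

test_that("series chain matches the analytic input impedance for sinusoidal forcing", {
  Tp <- 0.8; dt <- Tp / 4000
  t <- seq(0, Tp - dt, by = dt)
  om <- 2 * pi / Tp
  Qm <- 80; qa <- 30
  wf <- waveform(t, Qm + qa * sin(om * t), Tp)
  L <- 5e-4; R <- 0.05
  p <- wk3_params(0.1, 0.9, 1.2)
  net <- lumped_network(
    data.frame(name = "seg", from = "n0", to = "nt", L = L, R = R),
    list(nt = p), list(n0 = wf))
  sol <- solve_lumped(net, dt = dt, n_cycles = 40, tol = 1e-9)
  P <- sol$pressures$n0$v
  # analytic: Z(om) = R + i om L + R1 + R2/(1 + i om R2 C)
  Z <- complex(real = R + p$R1, imaginary = om * L) +
    p$R2 / complex(real = 1, imaginary = om * p$R2 * p$C)
  ph <- exp(-1i * om * t)
  P1 <- 2 * mean(P * ph)          # fundamental (complex amplitude)
  Q1 <- 2 * mean(wf$v * ph)
  H <- P1 / Q1
  expect_equal(Mod(H), Mod(Z), tolerance = 0.01)
  expect_lt(abs(Arg(H) - Arg(Z)), 0.01)
  # DC component
  expect_equal(mean(P), Qm * (R + p$R1 + p$R2), tolerance = 0.01)
})
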