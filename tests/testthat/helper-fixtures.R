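# shared builders and a one-shot cache for the expensive fixture runs

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# uniform compliant tube with a WK3 termination; R1 matched to the
# characteristic impedance unless overridden
single_tube <- function(length = 0.3, n = 16, diameter = 0.032,
                        D = 1.18e-5, R_tot = 0.8, C = 1.0, R1 = NULL,
                        rho = 1056) {
  A0 <- pi * (diameter / 2)^2
  if (is.null(R1)) R1 <- rho / sqrt(rho * D) / A0 / (MMHG_TO_PA * 1e6)
  seg <- vessel_segment("tube", length, n, A0 = A0, C_A = D * A0)
  network_geometry(
    segments = list(tube = seg), junctions = list(),
    boundaries = list(
      inlet = list(seg = "tube", end = "proximal", type = "q_in"),
      out = list(seg = "tube", end = "distal", type = "wk3",
                 params = wk3_params(R1, R_tot - R1, C))))
}

const_flow <- function(Q = 100, Tp = 0.8, dt = 1e-3) {
  t <- seq(0, Tp - dt, by = dt)
  waveform(t, rep(Q, length(t)), Tp)
}

# the tuned fixture pipeline, run once for the whole suite
fixture_pipeline <- function() {
  cached("pipeline", {
    geom <- idealized_dissected_aorta(fixture_config())
    inflow <- synth_inflow(inflow_spec())
    tune_pipeline(geom, inflow, tuning_targets(), dt = 1e-3, n_cycles = 12)
  })
}

fixture_sources <- function() {
  cached("sources", {
    c(list(inlet = synth_inflow(inflow_spec())), synth_branch_flows())
  })
}

fixture_rigid_result <- function() {
  cached("rigid", {
    rep <- fixture_pipeline()
    solve_pulsewave(rep$geometry, fixture_sources(), dt = 1e-3, rigid = TRUE)
  })
}

# outflow waveforms (ml/s) at all outlet boundaries of a sim result
outlet_flows_ml <- function(res, geom) {
  nms <- names(Filter(function(b) b$type %in% c("q_out", "wk3"),
                      geom$boundaries))
  out <- lapply(nms, function(nm) {
    b <- geom$boundaries[[nm]]
    pr <- result_probe(res, b$seg, if (b$end == "distal") 1 else 0)$Q
    waveform(pr$t, pr$v * 1e6, pr$T)
  })
  names(out) <- nms
  out
}

inlet_flow_ml <- function(res, geom) {
  b <- geom$boundaries[[names(Filter(function(x) x$type == "q_in",
                                     geom$boundaries))]]
  pr <- result_probe(res, b$seg, if (b$end == "proximal") 0 else 1)$Q
  waveform(pr$t, pr$v * 1e6, pr$T)
}
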