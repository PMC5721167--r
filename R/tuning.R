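#' Tuning targets for the Windkessel parameter pipeline
#'
#' Brachial systolic/diastolic pressure targets at the inlet, mean-flow
#' targets per WK3 outlet, and the R1-to-Rtot ratio used to seed steps
#' 1-2 of the tuning procedure (step 4 replaces R1 by the characteristic
#' impedance of the coupled vessel).
#'
#' @param P_sys,P_dia systolic and diastolic pressure targets (mmHg),
#'   `P_sys > P_dia > 0`.
#' @param mean_flows named numeric vector of target cycle-mean flows
#'   (ml/s) per WK3 outlet, all `> 0`.
#' @param r1_fraction ratio R1/Rtot in (0, 1), default 0.056.
#' @return object of class `tuning_targets`.
#' @export
tuning_targets <- function(P_sys = 150, P_dia = 80,
                           mean_flows = table1_mean_flows(),
                           r1_fraction = 0.056) {
  stopifnot_finite(c(P_sys, P_dia, mean_flows, r1_fraction), "tuning_targets")
  if (!(P_sys > P_dia && P_dia > 0)) stop("need P_sys > P_dia > 0", call. = FALSE)
  if (any(mean_flows <= 0)) stop("all mean-flow targets must be > 0", call. = FALSE)
  if (is.null(names(mean_flows)) || any(!nzchar(names(mean_flows)))) {
    stop("mean_flows must be named by outlet", call. = FALSE)
  }
  if (r1_fraction <= 0 || r1_fraction >= 1) stop("r1_fraction must be in (0,1)", call. = FALSE)
  structure(list(P_sys = P_sys, P_dia = P_dia, mean_flows = mean_flows,
                 r1_fraction = r1_fraction), class = "tuning_targets")
}

#' Fit a whole-system WK3 to inflow and pressure targets (tuning step 1)
#'
#' A single three-element Windkessel stands in for the entire systemic
#' circulation. Its total resistance and compliance are iterated until the
#' periodic pressure response to the inflow waveform matches the systolic
#' and diastolic targets: an inner bisection on `C` matches the pulse
#' pressure, an outer update of `R_tot` (driven by the mean/systolic
#' pressure residual over the mean inflow) matches the level. The fitted
#' `C` is the total systemic compliance `C_sys`.
#'
#' @param inflow aortic inflow [waveform] (ml/s) with positive cycle mean
#'   and a pulse (max > mean).
#' @param targets a [tuning_targets].
#' @param dt integration step (s), default 1 ms.
#' @param tol_P pressure tolerance (mmHg), default 0.05 (well inside the
#'   0.5 mmHg contract).
#' @return list with `params` ([wk3_params]), `C_sys` (ml/mmHg), `R_tot`
#'   (mmHg s/ml), `P_sys`, `P_dia`, `P_mean` achieved (mmHg), `pressure`
#'   (the fitted periodic pressure [waveform]) and `iterations`.
#' @export
fit_system_wk3 <- function(inflow, targets, dt = 1e-3, tol_P = 0.05) {
  stopifnot(is_waveform(inflow), inherits(targets, "tuning_targets"))
  Qbar <- cycle_mean(inflow)
  if (Qbar <= 0) stop("inflow must have positive cycle mean", call. = FALSE)
  if (max(inflow$v) <= Qbar * (1 + 1e-9)) {
    stop("inflow has no pulse (max <= mean): compliance is unidentifiable",
         call. = FALSE)
  }
  m <- round(inflow$T / dt)
  Q <- wf_resample(inflow, m)$v
  f <- targets$r1_fraction
  PP_t <- targets$P_sys - targets$P_dia

  sim <- function(R_tot, C) {
    wk3_periodic(Q, wk3_params(f * R_tot, (1 - f) * R_tot, C), dt)
  }
  R_tot <- ((targets$P_sys + 2 * targets$P_dia) / 3) / Qbar
  C <- NA_real_
  for (it in 1:60) {
    lo <- 1e-4; hi <- 100
    for (k in 1:64) {
      C <- sqrt(lo * hi)
      P <- sim(R_tot, C)
      if (max(P) - min(P) > PP_t) lo <- C else hi <- C
      if (hi / lo < 1 + 1e-10) break
    }
    P <- sim(R_tot, C)
    if (abs(max(P) - targets$P_sys) < tol_P &&
        abs(min(P) - targets$P_dia) < tol_P) break
    R_tot <- R_tot + (targets$P_sys - max(P)) / Qbar
    if (R_tot <= 0) stop("infeasible pressure targets for this inflow", call. = FALSE)
  }
  t_grid <- seq(0, by = dt, length.out = m)
  list(params = wk3_params(f * R_tot, (1 - f) * R_tot, C),
       C_sys = C, R_tot = R_tot,
       P_sys = max(P), P_dia = min(P), P_mean = mean(P),
       pressure = waveform(t_grid, P, inflow$T), iterations = it)
}

#' Distribute WK3 parameters over the outlets (tuning step 2)
#'
#' The total systemic compliance is split among the WK3 outlets in
#' proportion to their target mean flows. Each outlet's total resistance
#' is initialized as (mean terminal pressure)/(target mean flow) with a
#' venous reference of 0 mmHg, then iterated under repeated solves of the
#' lumped 0D network until the achieved cycle-mean flows match the
#' targets.
#'
#' @param C_sys total systemic compliance (ml/mmHg).
#' @param targets a [tuning_targets]; `mean_flows` must name every WK3
#'   terminal of `net`.
#' @param net a [lumped_network] (Windkessel parameters on its terminals
#'   are replaced during the iteration).
#' @param P_mean_init target mean inlet pressure (mmHg), normally step
#'   1's fitted mean; it seeds the resistances and anchors the level of
#'   the 0D solution (so that network series resistances are correctly
#'   discounted from the terminal totals).
#' @param tol relative tolerance on achieved mean flows (default 1%).
#' @param max_iter iteration cap (default 50); non-convergence is reported
#'   with the final residuals.
#' @param dt,n_cycles passed to [solve_lumped].
#' @return list with `params` (named list of [wk3_params]), `achieved`
#'   (mean flows ml/s), `P_mean` (mean terminal pressures mmHg),
#'   `converged`, `iterations`, `residual`, and `solution` (the final
#'   [solve_lumped] output).
#' @export
distribute_outlet_params <- function(C_sys, targets, net, P_mean_init = 100,
                                     tol = 0.01, max_iter = 50L,
                                     dt = 1e-3, n_cycles = 30L) {
  stopifnot(inherits(targets, "tuning_targets"), inherits(net, "lumped_network"))
  outlets <- names(net$terminals)
  missing <- setdiff(outlets, names(targets$mean_flows))
  if (length(missing)) {
    stop("mean-flow targets missing for terminal(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  Qt <- targets$mean_flows[outlets]
  inlet_mean <- sum(vapply(net$sources, cycle_mean, numeric(1)))
  if (sum(Qt) > inlet_mean * (1 + 1e-6)) {
    stop("sum of outlet flow targets exceeds the net source inflow", call. = FALSE)
  }
  f <- targets$r1_fraction
  Ci <- C_sys * Qt / sum(Qt)
  Rt <- P_mean_init / Qt
  # the source with the largest mean flow is the aortic inlet; its mean
  # pressure is anchored at P_mean_init when rescaling resistances
  src_means <- vapply(net$sources, cycle_mean, numeric(1))
  inlet_node <- names(src_means)[which.max(src_means)]
  converged <- FALSE; resid <- NA_real_; sol <- NULL; Qa <- NULL; Pm <- NULL
  for (it in seq_len(max_iter)) {
    params <- lapply(outlets, function(o) {
      wk3_params(f * Rt[[o]], (1 - f) * Rt[[o]], Ci[[o]])
    })
    names(params) <- outlets
    net2 <- lumped_network(net$blocks, params, net$sources)
    sol <- suppressWarnings(solve_lumped(net2, dt = dt, n_cycles = n_cycles,
                                         P0 = P_mean_init))
    Qa <- vapply(sol$terminal_flows[outlets], cycle_mean, numeric(1))
    Pm <- vapply(sol$pressures[outlets], cycle_mean, numeric(1))
    P_in <- cycle_mean(sol$pressures[[inlet_node]])
    Rt_new <- (Pm + (P_mean_init - P_in)) / Qt
    resid <- max(abs(Qa / Qt - 1))
    if (resid < tol && max(abs(Rt_new / Rt - 1)) < tol) {
      converged <- TRUE
      break
    }
    Rt <- Rt_new
  }
  if (!converged) {
    warning(sprintf("flow-matching loop: residual %.3g after %d iterations; final flows: %s",
                    resid, max_iter,
                    paste(sprintf("%s=%.2f", outlets, Qa), collapse = ", ")),
            call. = FALSE)
  }
  params <- lapply(outlets, function(o) {
    wk3_params(f * Rt[[o]], (1 - f) * Rt[[o]], Ci[[o]])
  })
  names(params) <- outlets
  list(params = params, achieved = Qa, P_mean = Pm, converged = converged,
       iterations = it, residual = resid, solution = sol)
}

#' Normalized cross-sectional area variation
#'
#' `dA*(t) = (A(t) - A_min)/A_min`, where `A_min` is the smallest area
#' over the cardiac cycle; the minimum of the output is exactly 0.
#'
#' @param A lumen-area [waveform] (any positive unit).
#' @return dimensionless [waveform].
#' @export
normalized_area_variation <- function(A) {
  stopifnot(is_waveform(A))
  if (any(A$v <= 0)) stop("area samples must be positive", call. = FALSE)
  A0 <- min(A$v)
  waveform(A$t, (A$v - A0) / A0, A$T)
}

#' Distensibility from normalized area variation and pulse pressure
#'
#' `D = dA*_peak / dP` (1/Pa), the estimator applied to cine-MRI area
#' data with the systolic-diastolic pressure variation taken from the
#' rigid simulation.
#'
#' @param deltaA_star_peak peak normalized area variation (dimensionless).
#' @param deltaP systolic-diastolic pressure variation (Pa), `> 0`.
#' @return distensibility (1/Pa); 0 is allowed and flagged as a rigid
#'   (degenerate) segment via attribute `degenerate`.
#' @export
estimate_distensibility <- function(deltaA_star_peak, deltaP) {
  stopifnot_finite(c(deltaA_star_peak, deltaP), "estimate_distensibility")
  if (deltaP <= 0) stop("deltaP must be > 0", call. = FALSE)
  if (deltaA_star_peak < 0) stop("deltaA* must be >= 0", call. = FALSE)
  D <- deltaA_star_peak / deltaP
  attr(D, "degenerate") <- (D == 0)
  D
}

#' Empirical pulse-wave velocity from vessel diameter
#'
#' Population-based law `PWV = a / d^b` with `a = 13.3`, `b = 0.3`
#' (PWV in m/s, diameter in mm); monotonically decreasing in `d`.
#'
#' @param d vessel diameter (mm), `> 0` (vectorized).
#' @param a,b law coefficients.
#' @return pulse-wave velocity (m/s).
#' @export
pwv_from_diameter <- function(d, a = 13.3, b = 0.3) {
  if (any(d <= 0)) stop("diameter must be > 0", call. = FALSE)
  a / d^b
}

#' Fit distensibility from paired area and pressure waveforms
#'
#' Projects the lumen-area signal onto the pressure waveform through the
#' linear distension law `A = A0 (1 + D (P - min P))` by least squares,
#' then returns `D` together with the implied peak normalized area
#' variation. For noise-free data this equals the peak-ratio estimator
#' [estimate_distensibility] to rounding; for noisy area data the
#' regression is unbiased where the max/min ratio is not.
#'
#' @param A lumen-area [waveform].
#' @param P pressure [waveform] (Pa) on the same time base.
#' @return distensibility `D` (1/Pa) with attribute `deltaA_star_peak`.
#' @export
fit_distensibility <- function(A, P) {
  stopifnot(is_waveform(A), is_waveform(P))
  if (length(A$v) != length(P$v)) {
    stop("A and P must share one time base", call. = FALSE)
  }
  x <- P$v - min(P$v)
  fit <- stats::lm.fit(cbind(1, x), A$v)
  a <- fit$coefficients[[1L]]; b <- fit$coefficients[[2L]]
  if (a <= 0) stop("degenerate area fit (non-positive baseline)", call. = FALSE)
  D <- max(b / a, 0)
  attr(D, "deltaA_star_peak") <- D * (max(P$v) - min(P$v))
  D
}

#' Distensibility from pulse-wave velocity (Bramwell-Hill)
#'
#' `D = 1 / (rho PWV^2)`.
#'
#' @param PWV pulse-wave velocity (m/s), `> 0`.
#' @param rho blood density (kg/m^3), `> 0`.
#' @return distensibility (1/Pa).
#' @export
distensibility_from_pwv <- function(PWV, rho = 1056) {
  if (any(PWV <= 0) || rho <= 0) stop("PWV and rho must be > 0", call. = FALSE)
  1 / (rho * PWV^2)
}

#' Integrate area compliance along the modelled vessels (tuning step 3)
#'
#' `C_aorta = sum over segments of int C_A(x) dx` (trapezoidal), converted
#' from m^3/Pa to ml/mmHg.
#'
#' @param segments list of [vessel_segment]s with `C_A` set.
#' @return compliance of the modelled vasculature (ml/mmHg).
#' @export
integrate_aortic_compliance <- function(segments) {
  if (length(segments) == 0L) stop("empty geometry", call. = FALSE)
  tot <- 0
  for (s in segments) {
    stopifnot(inherits(s, "vessel_segment"))
    tot <- tot + sum(diff(s$x) * (s$C_A[-1L] + s$C_A[-s$n]) / 2)
  }
  tot * M3_PER_PA_TO_ML_PER_MMHG
}

#' Compliance budget of the multi-scale model
#'
#' @param C_sys total systemic compliance (ml/mmHg).
#' @param C_aorta compliance of the modelled (3D/1D) aorta (ml/mmHg).
#' @return object of class `compliance_budget` with `C_per = C_sys -
#'   C_aorta` (must be `>= 0`).
#' @export
compliance_budget <- function(C_sys, C_aorta) {
  stopifnot_finite(c(C_sys, C_aorta), "compliance_budget")
  if (C_sys < 0 || C_aorta < 0) stop("compliances must be >= 0", call. = FALSE)
  if (C_aorta > C_sys) stop("C_aorta exceeds C_sys: nothing left for the periphery",
                            call. = FALSE)
  structure(list(C_sys = C_sys, C_aorta = C_aorta, C_per = C_sys - C_aorta),
            class = "compliance_budget")
}

#' Re-tune WK3 outlets for the compliant model (tuning step 4)
#'
#' Only the peripheral compliance `C_per = C_sys - C_aorta` is distributed
#' over the outlets (again by target-flow weights). Each outlet's total
#' resistance is kept from step 2, but `R1` is replaced by the
#' characteristic impedance of the coupled vessel, `rho PWV / A0`, to
#' minimize non-physiological wave reflections; `R2` takes the remainder.
#'
#' @param budget a [compliance_budget].
#' @param rigid_params named list of step-2 [wk3_params] per outlet.
#' @param outlet_props named list per outlet: `list(PWV = m/s, A0 = m^2)`.
#' @param mean_flows named target mean flows (ml/s) supplying the
#'   compliance weights.
#' @param rho blood density (kg/m^3).
#' @return named list of [wk3_params]; errors if any characteristic
#'   impedance reaches `R_tot`.
#' @export
retune_for_compliant <- function(budget, rigid_params, outlet_props,
                                 mean_flows, rho = 1056) {
  stopifnot(inherits(budget, "compliance_budget"))
  outlets <- names(rigid_params)
  Qw <- mean_flows[outlets]
  out <- lapply(outlets, function(o) {
    p <- rigid_params[[o]]
    R_tot <- p$R1 + p$R2
    pr <- outlet_props[[o]]
    Z <- rho * pr$PWV / pr$A0 / MMHG_S_ML_TO_SI
    if (Z >= R_tot) {
      stop(sprintf("characteristic impedance of outlet %s (%.3g) reaches R_tot (%.3g)",
                   o, Z, R_tot), call. = FALSE)
    }
    C_i <- if (budget$C_aorta == 0) p$C else budget$C_per * Qw[[o]] / sum(Qw)
    wk3_params(R1 = Z, R2 = R_tot - Z, C = C_i)
  })
  names(out) <- outlets
  out
}

#' Run the full 4-step Windkessel tuning pipeline
#'
#' Orchestrates: (1) whole-system WK3 fit on the inflow; (2) distribution
#' of resistances and compliance over the outlets via the lumped 0D
#' analogue of the geometry; (3) a rigid run of the network, whose
#' segmental systolic-diastolic pressure variations are combined with
#' (synthetic) area waveforms to estimate aortic distensibility and hence
#' the aortic compliance `C_aorta` (branch distensibility comes from the
#' diameter-PWV law); (4) impedance-matched re-tuning against the
#' peripheral compliance budget. Optionally finishes with the compliant
#' pulse-wave simulation and reports achieved versus target values.
#'
#' @param geometry a [network_geometry] whose `meta` carries per-segment
#'   `distensibility` (the synthetic imaging truth) and per-outlet
#'   `diameter_mm`.
#' @param inflow inlet flow [waveform] (ml/s).
#' @param targets a [tuning_targets].
#' @param prescribed named list of prescribed branch flow [waveform]s
#'   (ml/s) for the `q_out` boundaries (default: generated carotid-like
#'   shapes from `geometry$meta$prescribed_means`).
#' @param rigid_only logical; stop after step 2 (rigid parameter set).
#' @param simulate logical; run the final compliant simulation (default
#'   TRUE; the deviation report needs it).
#' @param dt time step (s).
#' @param rheo a [rheology_params].
#' @param n_cycles cycle cap for the final simulation.
#' @return object of class `tuning_report`: per-outlet parameters and
#'   achieved values, the compliance budget, the fitted system WK3, the
#'   maximum relative deviation from targets, and convergence logs.
#' @export
tune_pipeline <- function(geometry, inflow, targets,
                          prescribed = NULL, rigid_only = FALSE,
                          simulate = TRUE, dt = 1e-3,
                          rheo = rheology_params(), n_cycles = 8L) {
  stopifnot(inherits(geometry, "network_geometry"),
            inherits(targets, "tuning_targets"))
  wk3_names <- names(Filter(function(b) b$type == "wk3", geometry$boundaries))
  missing <- setdiff(wk3_names, names(targets$mean_flows))
  if (length(missing)) {
    stop("step 2: geometry terminals lack flow targets: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(prescribed)) {
    pm <- geometry$meta$prescribed_means
    if (is.null(pm)) stop("no prescribed branch flows and no meta$prescribed_means",
                          call. = FALSE)
    prescribed <- synth_branch_flows(pm, HR = 60 / inflow$T,
                                     n_samples = length(inflow$t))
  }
  sources <- c(stats::setNames(list(inflow), grep_boundary(geometry, "q_in")),
               prescribed)

  # step 1: whole-system WK3
  step1 <- fit_system_wk3(inflow, targets, dt = dt)

  # step 2: distribute over outlets through the 0D analogue
  lump <- geometry_to_lumped(
    geometry, sources, rho = rheo$rho,
    terminal_params = stats::setNames(rep(list(step1$params), length(wk3_names)),
                                      wk3_names))
  step2 <- distribute_outlet_params(step1$C_sys, targets, lump$net,
                                    P_mean_init = step1$P_mean, dt = dt)
  geometry <- set_terminal_params(geometry, step2$params)
  if (rigid_only) {
    return(structure(list(step1 = step1, step2 = step2, params = step2$params,
                          rigid_only = TRUE, targets = targets),
                     class = "tuning_report"))
  }

  # step 3: rigid network run -> segmental pulse pressures -> C_A, C_aorta
  rigid_res <- solve_pulsewave(geometry, sources, dt = dt, rigid = TRUE,
                               rheo = rheo)
  dis <- geometry$dissection
  Dmeta <- geometry$meta$distensibility
  C_A <- list(); D_hat <- list()
  for (s in names(geometry$segments)) {
    seg <- geometry$segments[[s]]
    pr <- result_probe(rigid_res, s, 0.5)$P
    if (!is.null(Dmeta[[s]])) {
      # aortic segment: synthesize the cine-MRI-like area signal and invert it
      A_seg <- if (!is.null(dis) && s %in% c(dis$tl, dis$fl)) {
        # dissected region: TL and FL areas are considered jointly
        tlp <- result_probe(rigid_res, dis$tl, 0.5)$P
        A0c <- mean(geometry$segments[[dis$tl]]$A0) +
          mean(geometry$segments[[dis$fl]]$A0)
        synth_area_waveform(tlp, Dmeta[[s]], A0c)
      } else {
        synth_area_waveform(pr, Dmeta[[s]], mean(seg$A0))
      }
      p_src <- if (!is.null(dis) && s %in% c(dis$tl, dis$fl)) {
        result_probe(rigid_res, dis$tl, 0.5)$P
      } else pr
      dP <- max(p_src$v) - min(p_src$v)
      dAs <- attr(fit_distensibility(A_seg, p_src), "deltaA_star_peak")
      D_hat[[s]] <- estimate_distensibility(dAs, dP)
    } else {
      dmm <- geometry$meta$diameter_mm[[s]]
      if (is.null(dmm)) dmm <- 2 * sqrt(mean(seg$A0) / pi) * 1e3
      D_hat[[s]] <- distensibility_from_pwv(pwv_from_diameter(dmm), rheo$rho)
    }
    C_A[[s]] <- D_hat[[s]] * mean(seg$A0)
  }
  if (!is.null(dis)) {
    # split the combined external-wall compliance by reference area
    A_tl <- mean(geometry$segments[[dis$tl]]$A0)
    A_fl <- mean(geometry$segments[[dis$fl]]$A0)
    C_comb <- D_hat[[dis$tl]] * (A_tl + A_fl)
    C_A[[dis$tl]] <- C_comb * A_tl / (A_tl + A_fl)
    C_A[[dis$fl]] <- C_comb * A_fl / (A_tl + A_fl)
  }
  geometry <- set_segment_compliance(geometry, C_A)
  C_aorta <- integrate_aortic_compliance(geometry$segments)
  budget <- compliance_budget(step1$C_sys, C_aorta)

  # step 4: impedance-matched re-tune on the peripheral budget
  outlet_props <- lapply(wk3_names, function(o) {
    seg <- geometry$segments[[geometry$boundaries[[o]]$seg]]
    dmm <- geometry$meta$diameter_mm[[geometry$boundaries[[o]]$seg]]
    if (is.null(dmm)) dmm <- 2 * sqrt(mean(seg$A0) / pi) * 1e3
    list(PWV = pwv_from_diameter(dmm), A0 = mean(seg$A0))
  })
  names(outlet_props) <- wk3_names
  params4 <- retune_for_compliant(budget, step2$params, outlet_props,
                                  targets$mean_flows, rho = rheo$rho)
  geometry <- set_terminal_params(geometry, params4)

  report <- list(step1 = step1, step2 = step2, budget = budget,
                 C_A = C_A, D_hat = D_hat, params = params4,
                 geometry = geometry, targets = targets, rigid_only = FALSE)

  if (simulate) {
    sim <- solve_pulsewave(geometry, sources, dt = dt, n_cycles = n_cycles,
                           rheo = rheo)
    achieved_Q <- vapply(wk3_names, function(o) {
      b <- geometry$boundaries[[o]]
      pr <- result_probe(sim, b$seg, if (b$end == "distal") 1 else 0)
      cycle_mean(pr$Q) * 1e6
    }, numeric(1))
    inlet_b <- geometry$boundaries[[grep_boundary(geometry, "q_in")]]
    pin <- result_probe(sim, inlet_b$seg, if (inlet_b$end == "proximal") 0 else 1)$P
    achieved <- c(achieved_Q,
                  P_sys = max(pin$v) / MMHG_TO_PA,
                  P_dia = min(pin$v) / MMHG_TO_PA)
    target_vec <- c(targets$mean_flows[wk3_names],
                    P_sys = targets$P_sys, P_dia = targets$P_dia)
    dev <- abs(achieved / target_vec - 1)
    report$simulation <- sim
    report$achieved <- achieved
    report$target_vec <- target_vec
    report$deviation <- dev
    report$max_deviation_pct <- 100 * max(dev)
  }
  structure(report, class = "tuning_report")
}

grep_boundary <- function(geometry, type) {
  nm <- names(Filter(function(b) b$type == type, geometry$boundaries))
  if (length(nm) != 1L && type == "q_in") {
    stop("geometry must have exactly one inflow boundary", call. = FALSE)
  }
  nm
}

#' @export
print.tuning_report <- function(x, ...) {
  cat("<tuning_report>\n")
  cat(sprintf("  step 1: C_sys = %.3f ml/mmHg, R_tot = %.3f mmHg s/ml (P %0.1f/%0.1f)\n",
              x$step1$C_sys, x$step1$R_tot, x$step1$P_sys, x$step1$P_dia))
  if (!is.null(x$budget)) {
    cat(sprintf("  budget: C_sys = %.3f, C_aorta = %.3f, C_per = %.3f ml/mmHg\n",
                x$budget$C_sys, x$budget$C_aorta, x$budget$C_per))
  }
  if (!is.null(x$max_deviation_pct)) {
    cat(sprintf("  max |achieved/target - 1| = %.2f%%\n", x$max_deviation_pct))
  }
  invisible(x)
}
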