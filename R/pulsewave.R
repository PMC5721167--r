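#' Carreau-Yasuda blood rheology parameters
#'
#' Shear-thinning viscosity
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
#'   [1 + (\lambda\dot\gamma)^a]^{(n-1)/a}.}
#' Defaults follow the whole-blood fit of Gijsen and co-workers; density
#' 1056 kg/m^3.
#'
#' @param rho blood density (kg/m^3).
#' @param mu_0,mu_inf low- and high-shear viscosities (Pa s), `mu_0 >= mu_inf > 0`.
#' @param lambda relaxation time (s), `> 0`.
#' @param a_cy,n_cy Carreau-Yasuda exponents.
#' @return object of class `rheology_params`.
#' @export
rheology_params <- function(rho = 1056, mu_0 = 22e-3, mu_inf = 2.2e-3,
                            lambda = 0.110, a_cy = 0.644, n_cy = 0.392) {
  stopifnot_finite(c(rho, mu_0, mu_inf, lambda, a_cy, n_cy), "rheology_params")
  if (!(mu_0 >= mu_inf && mu_inf > 0)) stop("need mu_0 >= mu_inf > 0", call. = FALSE)
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (rho <= 0) stop("rho must be > 0", call. = FALSE)
  structure(list(rho = rho, mu_0 = mu_0, mu_inf = mu_inf, lambda = lambda,
                 a_cy = a_cy, n_cy = n_cy), class = "rheology_params")
}

#' Newtonian limit of the rheology (for verification runs)
#' @param mu dynamic viscosity (Pa s).
#' @param rho density (kg/m^3).
#' @return a [rheology_params] with `mu_0 = mu_inf = mu`.
#' @export
newtonian_rheology <- function(mu = 4e-3, rho = 1056) {
  rheology_params(rho = rho, mu_0 = mu, mu_inf = mu)
}

#' Carreau-Yasuda viscosity
#'
#' @param gamma_dot shear rate (1/s), `>= 0` (vectorized).
#' @param rheo a [rheology_params].
#' @return viscosity (Pa s), bounded in `[mu_inf, mu_0]`.
#' @export
cy_viscosity <- function(gamma_dot, rheo = rheology_params()) {
  if (any(gamma_dot < 0)) stop("shear rate must be >= 0", call. = FALSE)
  rheo$mu_inf + (rheo$mu_0 - rheo$mu_inf) *
    (1 + (rheo$lambda * gamma_dot)^rheo$a_cy)^((rheo$n_cy - 1) / rheo$a_cy)
}

#' Entry-tear orifice
#'
#' The only communication between the true and false lumen: a quasi-steady
#' sharp-edged orifice.
#'
#' @param A_tear orifice area (m^2), default 18.5 mm^2.
#' @param Cd discharge coefficient in (0, 1], default 0.6.
#' @return object of class `tear_orifice`.
#' @export
tear_orifice <- function(A_tear = 18.5e-6, Cd = 0.6) {
  stopifnot_finite(c(A_tear, Cd), "tear_orifice")
  if (A_tear <= 0) stop("A_tear must be > 0", call. = FALSE)
  if (Cd <= 0 || Cd > 1) stop("Cd must be in (0, 1]", call. = FALSE)
  structure(list(A_tear = A_tear, Cd = Cd), class = "tear_orifice")
}

#' Quasi-steady orifice flow through the entry tear
#'
#' @param deltaP transmural pressure drop across the tear (Pa); sign sets
#'   the flow direction (positive: true to false lumen).
#' @param tear a [tear_orifice].
#' @param rho blood density (kg/m^3).
#' @return flow (m^3/s), odd in `deltaP`:
#'   `Q = sign(dP) Cd A sqrt(2|dP|/rho)`.
#' @export
tear_flow <- function(deltaP, tear = tear_orifice(), rho = 1056) {
  stopifnot(inherits(tear, "tear_orifice"))
  sign(deltaP) * tear$Cd * tear$A_tear * sqrt(2 * abs(deltaP) / rho)
}

#' Nodal wall stiffness from area compliance
#'
#' The moving-boundary wall law relates nodal displacement linearly to
#' transmural pressure through a stiffness `K`. For a circular cross
#' section with area compliance `C_A = dA/dp`,
#' \deqn{K = 2\sqrt{\pi A_0} / C_A \quad (\mathrm{N/m^3}),}
#' since `dA/dp = 2 pi r / K` at `A = A0`.
#'
#' @param C_A area compliance (m^2/Pa), `>= 0`; `C_A = 0` marks a rigid
#'   node and yields `K = Inf`.
#' @param A0 reference cross-sectional area (m^2), `> 0`.
#' @return stiffness K (N/m^3).
#' @export
nodal_stiffness <- function(C_A, A0) {
  if (any(A0 <= 0)) stop("A0 must be > 0", call. = FALSE)
  if (any(C_A < 0)) stop("C_A must be >= 0", call. = FALSE)
  ifelse(C_A == 0, Inf, 2 * sqrt(pi * A0) / C_A)
}

#' Wall displacement under the linear moving-boundary law
#'
#' @param p local pressure (Pa).
#' @param p_ext external (reference diastolic) pressure (Pa).
#' @param K nodal stiffness (N/m^3), `> 0`.
#' @return outward radial displacement (m): `(p - p_ext)/K`.
#' @export
wall_displacement <- function(p, p_ext, K) {
  if (any(K <= 0)) stop("K must be > 0", call. = FALSE)
  (p - p_ext) / K
}

#' Lumen area from pressure under the moving-boundary tube law
#'
#' Composes the displacement law with the circular cross-section:
#' `A(p) = pi (r0 + (p - p_ext)/K)^2`, `r0 = sqrt(A0/pi)`.
#'
#' @param A0 reference area at `p = p_ext` (m^2).
#' @param K nodal stiffness (N/m^3).
#' @param p pressure (Pa).
#' @param p_ext external pressure (Pa).
#' @return area (m^2); errors on wall collapse (`r0 + delta <= 0`).
#' @export
area_from_pressure <- function(A0, K, p, p_ext) {
  r <- sqrt(A0 / pi) + wall_displacement(p, p_ext, K)
  if (any(r <= 0)) stop("wall collapse: r0 + delta <= 0", call. = FALSE)
  pi * r^2
}

# inverse tube law (vectorized)
pressure_from_area <- function(A, A0, K, p_ext) {
  p_ext + K * (sqrt(A / pi) - sqrt(A0 / pi))
}

#' Poiseuille wall shear stress with shear-dependent viscosity
#'
#' Assumes a Poiseuille profile: wall shear rate `4 Q / (pi r^3)`,
#' `tau_w = mu(gamma_w) * gamma_w`. The viscosity/shear-rate pair is
#' iterated to self-consistency (at most 5 fixed-point sweeps; for the
#' Poiseuille closure the shear rate is independent of viscosity, so one
#' sweep suffices).
#'
#' @param Q flow (m^3/s), vectorized.
#' @param A lumen area (m^2), `> 0`.
#' @param rheo a [rheology_params].
#' @return wall shear stress (Pa), sign following `Q`.
#' @export
wall_shear <- function(Q, A, rheo = rheology_params()) {
  if (any(A <= 0)) stop("A must be > 0", call. = FALSE)
  r <- sqrt(A / pi)
  gam <- 4 * Q / (pi * r^3)
  mu <- cy_viscosity(abs(gam), rheo)
  for (i in 1:4) {
    mu_new <- cy_viscosity(abs(gam), rheo)
    if (max(abs(mu_new - mu)) < 1e-12) break
    mu <- mu_new
  }
  mu * gam
}

#' One-dimensional vessel segment with the moving-boundary wall law
#'
#' @param name segment name.
#' @param length segment length (m), `> 0`.
#' @param n_nodes number of axial grid nodes (`>= 8`).
#' @param A0 reference area at `p = p_ext` (m^2); scalar or per-node vector.
#' @param C_A area compliance (m^2/Pa), `>= 0`; scalar or per-node vector.
#' @param p_ext external pressure (Pa), default 76 mmHg.
#' @return object of class `vessel_segment` carrying the grid `x`, per-node
#'   `A0`, `C_A` and stiffness `K`.
#' @export
vessel_segment <- function(name, length, n_nodes = 8L, A0, C_A,
                           p_ext = 76 * MMHG_TO_PA) {
  if (length <= 0) stop("segment length must be > 0", call. = FALSE)
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 8L) stop("a segment needs at least 8 grid nodes", call. = FALSE)
  A0 <- rep_len(as.numeric(A0), n_nodes)
  C_A <- rep_len(as.numeric(C_A), n_nodes)
  if (any(A0 <= 0)) stop("A0 must be > 0 everywhere", call. = FALSE)
  if (any(C_A < 0)) stop("C_A must be >= 0", call. = FALSE)
  x <- seq(0, length, length.out = n_nodes)
  structure(list(name = name, length = length, n = n_nodes, x = x,
                 dx = x[2L] - x[1L], A0 = A0, C_A = C_A,
                 K = nodal_stiffness(C_A, A0), p_ext = p_ext),
            class = "vessel_segment")
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf("<vessel_segment> %s: L = %.3g m, %d nodes, A0 = %.3g m^2, C_A = %.3g m^2/Pa\n",
              x$name, x$length, x$n, mean(x$A0), mean(x$C_A)))
  invisible(x)
}

#' Branched network geometry for the pulse-wave solver
#'
#' @param segments named list of [vessel_segment]s.
#' @param junctions list of junctions; each is a list of ends, an end being
#'   `list(seg = "name", end = "proximal"|"distal")`.
#' @param boundaries named list of boundary conditions; each is
#'   `list(seg, end, type)` with type one of `"q_in"` (prescribed inflow),
#'   `"q_out"` (prescribed outflow), `"wk3"` (Windkessel terminal, with an
#'   optional `params` [wk3_params]), `"closed"` (zero flow).
#' @param dissection `NULL`, or `list(tl, fl, tear = tear_orifice(),
#'   tear_pos = 0.01)`: names of the true/false lumen segments, the tear
#'   orifice, and the tear position (m from the proximal TL end). The FL
#'   must have a `closed` distal boundary and its proximal end is fed only
#'   through the tear.
#' @param meta free-form fixture metadata (regional distensibilities,
#'   diameters) used by the tuning pipeline.
#' @return object of class `network_geometry`.
#' @export
network_geometry <- function(segments, junctions, boundaries,
                             dissection = NULL, meta = list()) {
  lapply(segments, function(s) stopifnot(inherits(s, "vessel_segment")))
  ends_seen <- character(0)
  use_end <- function(seg, end) {
    key <- paste(seg, end, sep = ":")
    if (!seg %in% names(segments)) stop("unknown segment: ", seg, call. = FALSE)
    if (key %in% ends_seen) stop("segment end used twice: ", key, call. = FALSE)
    ends_seen <<- c(ends_seen, key)
  }
  for (j in junctions) for (e in j) use_end(e$seg, e$end)
  for (nm in names(boundaries)) {
    b <- boundaries[[nm]]
    if (!b$type %in% c("q_in", "q_out", "wk3", "closed")) {
      stop("unknown boundary type: ", b$type, call. = FALSE)
    }
    use_end(b$seg, b$end)
  }
  if (!is.null(dissection)) {
    stopifnot(inherits(dissection$tear, "tear_orifice"))
    if (!all(c(dissection$tl, dissection$fl) %in% names(segments))) {
      stop("dissection must name existing TL/FL segments", call. = FALSE)
    }
    use_end(dissection$fl, "proximal")  # fed only through the tear
    fl_cl <- vapply(boundaries, function(b) {
      b$seg == dissection$fl && b$end == "distal" && b$type == "closed"
    }, logical(1))
    if (!any(fl_cl)) stop("FL distal end must be a closed boundary", call. = FALSE)
  }
  missing <- setdiff(
    as.vector(outer(names(segments), c("proximal", "distal"), paste, sep = ":")),
    ends_seen)
  if (length(missing)) {
    stop("unconnected segment end(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(segments = segments, junctions = junctions,
                 boundaries = boundaries, dissection = dissection, meta = meta),
            class = "network_geometry")
}

#' @export
print.network_geometry <- function(x, ...) {
  cat(sprintf("<network_geometry> %d segments, %d junctions, %d boundaries%s\n",
              length(x$segments), length(x$junctions), length(x$boundaries),
              if (is.null(x$dissection)) "" else ", dissected (TL/FL + tear)"))
  invisible(x)
}

#' Attach WK3 parameters to the geometry's terminal boundaries
#'
#' @param geom a [network_geometry].
#' @param params named list of [wk3_params]; names must match `wk3`
#'   boundaries.
#' @return the geometry with terminal parameters set.
#' @export
set_terminal_params <- function(geom, params) {
  stopifnot(inherits(geom, "network_geometry"))
  for (nm in names(params)) {
    b <- geom$boundaries[[nm]]
    if (is.null(b) || b$type != "wk3") stop("not a wk3 boundary: ", nm, call. = FALSE)
    stopifnot(inherits(params[[nm]], "wk3_params"))
    geom$boundaries[[nm]]$params <- params[[nm]]
  }
  geom
}

#' Set per-segment area compliance
#'
#' @param geom a [network_geometry].
#' @param C_A named list/vector of area compliances (m^2/Pa) per segment.
#' @return updated geometry (stiffness recomputed).
#' @export
set_segment_compliance <- function(geom, C_A) {
  for (nm in names(C_A)) {
    s <- geom$segments[[nm]]
    if (is.null(s)) stop("unknown segment: ", nm, call. = FALSE)
    s$C_A <- rep_len(as.numeric(C_A[[nm]]), s$n)
    s$K <- nodal_stiffness(s$C_A, s$A0)
    geom$segments[[nm]] <- s
  }
  geom
}

# ---- quasi-1D solver ------------------------------------------------------

# Riemann-invariant helpers for the sqrt tube law: c = gam * A^(1/4),
# invariants u +- 4c along dx/dt = u +- c.
seg_gamma <- function(K, rho) sqrt(K / (2 * rho)) * pi^(-0.25)

# solve f(A) = Q/A + s*4*gam*A^(1/4) - W = 0 for a prescribed-flow end
.solve_area_flow <- function(Q, W, gam, s, A_init, A0) {
  A <- A_init
  for (i in 1:30) {
    f <- Q / A + s * 4 * gam * A^0.25 - W
    df <- -Q / A^2 + s * gam * A^(-0.75)
    step <- f / df
    A_new <- A - step
    if (!is.finite(A_new) || A_new <= 0.05 * A0 || A_new > 20 * A0) break
    if (abs(A_new - A) < 1e-14 * A0 + 1e-16) { A <- A_new; break }
    A <- A_new
  }
  if (!is.finite(A) || A <= 0.05 * A0 || A > 20 * A0 ||
      abs(Q / A + s * 4 * gam * A^0.25 - W) > 1e-6 * max(abs(W), 1)) {
    g <- function(a) Q / a + s * 4 * gam * a^0.25 - W
    lo <- 0.05 * A0; hi <- 20 * A0
    if (g(lo) * g(hi) > 0) stop("boundary area solve failed", call. = FALSE)
    A <- stats::uniroot(g, c(lo, hi), tol = 1e-15)$root
  }
  A
}

#' Solve pulse-wave propagation on a compliant branched network
#'
#' Cross-sectionally averaged mass and momentum
#' \deqn{\partial_t A + \partial_x Q = 0,\qquad
#'  \partial_t Q + \partial_x(Q^2/A) + (A/\rho)\partial_x p = f,}
#' closed by the moving-boundary tube law [area_from_pressure], are
#' integrated with the two-step (Richtmyer) Lax-Wendroff scheme.
#' Junctions enforce mass conservation and static-pressure continuity via
#' Riemann invariants; `wk3` terminals are advanced with the lagged
#' backward-Euler coupling of [wk3_step]; a dissection exchanges flow
#' between lumina through the quasi-steady [tear_flow] orifice. With
#' `rigid = TRUE` the network reduces to its incompressible 0D limit
#' (segments become inertance-resistance blocks solved by [solve_lumped];
#' the false lumen, being a closed rigid cavity, carries exactly zero
#' flow).
#'
#' @param geom a [network_geometry] with WK3 parameters attached.
#' @param sources named list of flow [waveform]s (ml/s) for every `q_in` /
#'   `q_out` boundary.
#' @param dt output time step (s); the scheme sub-steps internally to keep
#'   the CFL number below `cfl`.
#' @param n_cycles maximum number of cardiac cycles (default 10).
#' @param rigid logical; freeze `A = A0` (0D limit).
#' @param rheo a [rheology_params].
#' @param cfl Courant factor (default 0.9).
#' @param tol_cycle cycle-to-cycle relative pressure change defining
#'   periodic steady state (default 1%).
#' @param P_init initial pressure (mmHg, default 80).
#' @param visc_gamma wall viscoelasticity (Voigt) scale `Gamma_w`
#'   (Pa s m) entering the tube law as `p = p_elastic + Gamma dA/dt` with
#'   `Gamma = Gamma_w / A0^(3/2)` (the wall-property scaling: thinner,
#'   smaller vessels damp relatively more). Via mass conservation this
#'   acts as an implicit axial diffusion of `Q` with diffusivity
#'   `Gamma_w / (rho sqrt(A0))`. The default 0.3 leaves the aortic pulse
#'   essentially elastic (viscoelastic fraction < 0.1%) while damping the
#'   otherwise undamped quarter-wave resonances of short, stiff side
#'   branches terminated by prescribed flows; set 0 to disable.
#' @return object of class `sim_result`: per-segment matrices (time x node)
#'   of `P` (Pa), `Q` (m^3/s), `A` (m^2), `tau_w` (Pa); time base `t`,
#'   period `T`, `cycles`, `converged`, and per-cycle volume bookkeeping in
#'   `$balance`.
#' @export
solve_pulsewave <- function(geom, sources, dt = 1e-3, n_cycles = 10L,
                            rigid = FALSE, rheo = rheology_params(),
                            cfl = 0.9, tol_cycle = 0.01, P_init = 80,
                            visc_gamma = 0.3) {
  stopifnot(inherits(geom, "network_geometry"))
  lapply(sources, function(w) stopifnot(is_waveform(w)))
  qb <- names(Filter(function(b) b$type %in% c("q_in", "q_out"), geom$boundaries))
  if (!setequal(qb, names(sources))) {
    stop("sources must be given for exactly the prescribed-flow boundaries: ",
         paste(qb, collapse = ", "), call. = FALSE)
  }
  if (rigid) return(solve_pulsewave_rigid(geom, sources, dt, n_cycles, rheo, P_init))

  rho <- rheo$rho
  Tp <- sources[[1L]]$T
  m <- round(Tp / dt)
  if (abs(m * dt - Tp) > 1e-9 * Tp) stop("dt must divide the period", call. = FALSE)

  segs <- geom$segments
  segn <- names(segs)
  for (s in segs) {
    if (any(s$C_A <= 0)) {
      stop("compliant solve needs C_A > 0 on every node (segment ", s$name, ")",
           call. = FALSE)
    }
  }
  S <- lapply(segs, function(s) {
    gam <- seg_gamma(s$K, rho)
    p0 <- P_init * MMHG_TO_PA
    A <- area_from_pressure(s$A0, s$K, p0, s$p_ext)
    list(n = s$n, dx = s$dx, A0 = s$A0, K = s$K, r0 = sqrt(s$A0 / pi),
         gam = gam, p_ext = s$p_ext, Bc = s$K / (3 * rho * sqrt(pi)),
         A = A, Q = rep(0, s$n))
  })
  names(S) <- segn

  # per-boundary WK3 states (clinical units) and prescribed flows in SI
  wk3_bnd <- Filter(function(b) b$type == "wk3", geom$boundaries)
  for (nm in names(wk3_bnd)) {
    if (is.null(wk3_bnd[[nm]]$params)) {
      stop("wk3 boundary without parameters: ", nm, call. = FALSE)
    }
  }
  wk_state <- lapply(wk3_bnd, function(b) wk3_state(P = P_init, Q_prev = 0))
  src_fun <- lapply(sources, function(w) {
    function(tt) wf_interp(w, tt) * 1e-6  # ml/s -> m^3/s
  })

  # junction bookkeeping: for each junction, per end: seg, side (+1 distal / -1 proximal)
  juncs <- lapply(geom$junctions, function(j) {
    lapply(j, function(e) list(seg = e$seg, distal = identical(e$end, "distal")))
  })
  jP <- rep(P_init * MMHG_TO_PA, length(juncs))

  dis <- geom$dissection
  tear_Q <- 0
  if (!is.null(dis)) {
    tl <- segs[[dis$tl]]
    j_tear <- which.min(abs(tl$x - (dis$tear_pos %||% 0.01)))
  }

  n_out <- m
  t_grid <- seq(0, by = dt, length.out = n_out)
  Ph <- lapply(S, function(s) matrix(0, n_out, s$n))
  Qh <- lapply(S, function(s) matrix(0, n_out, s$n))
  Ah <- lapply(S, function(s) matrix(0, n_out, s$n))
  names(Ph) <- names(Qh) <- names(Ah) <- segn
  Ph_prev <- NULL
  converged <- FALSE; resid <- NA_real_

  pressure_of <- function(st) pressure_from_area(st$A, st$A0, st$K, st$p_ext)

  visc_cache <- new.env(parent = emptyenv())
  bnd_q <- lapply(geom$boundaries, function(b) 0)  # last boundary flow (SI) for wk3 lag

  cycle <- 0L
  for (cycle in seq_len(n_cycles)) {
    for (i_out in seq_len(n_out)) {
      t_now <- t_grid[i_out]
      # CFL-limited substep count for this output step
      dt_lim <- Inf
      for (s in segn) {
        st <- S[[s]]
        c_loc <- st$gam * st$A^0.25
        dt_lim <- min(dt_lim, st$dx / max(abs(st$Q / st$A) + c_loc))
      }
      n_sub <- max(1L, ceiling(dt / (cfl * dt_lim)))
      if (n_sub > 500L) {
        stop(sprintf("CFL violation: required substep %.3g s is too small (suggest dt <= %.3g s)",
                     dt / n_sub, cfl * dt_lim), call. = FALSE)
      }
      h <- dt / n_sub
      for (i_sub in seq_len(n_sub)) {
        t_new <- t_now + h * i_sub
        # tear exchange flow from lagged pressures (under-relaxed)
        srcS1 <- NULL
        if (!is.null(dis)) {
          pTL <- pressure_of(S[[dis$tl]])[j_tear]
          pFL <- pressure_of(S[[dis$fl]])[1L]
          tear_Q <- 0.7 * tear_Q + 0.3 * tear_flow(pTL - pFL, dis$tear, rho)
        }
        Snew <- S
        for (s in segn) {
          st <- S[[s]]
          A <- st$A; Q <- st$Q; n <- st$n; dx <- st$dx
          F2 <- Q^2 / A + st$Bc * A^1.5
          # friction with CY wall viscosity (Poiseuille closure)
          gam_w <- 4 * abs(Q) / (pi * (A / pi)^1.5)
          mu_w <- cy_viscosity(gam_w, rheo)
          fr <- -8 * pi * mu_w * Q / (rho * A)
          s1 <- rep(0, n)
          if (!is.null(dis) && s == dis$tl) s1[j_tear] <- -tear_Q / dx
          # half step at interfaces
          idx <- seq_len(n - 1L)
          Am <- 0.5 * (A[idx] + A[idx + 1L]) - h / (2 * dx) * (Q[idx + 1L] - Q[idx]) +
            0.5 * h * 0.5 * (s1[idx] + s1[idx + 1L])
          Bm <- 0.5 * (st$Bc[idx] + st$Bc[idx + 1L])
          Qm <- 0.5 * (Q[idx] + Q[idx + 1L]) - h / (2 * dx) * (F2[idx + 1L] - F2[idx]) +
            0.5 * h * 0.5 * (fr[idx] + fr[idx + 1L])
          if (any(Am <= 0)) stop("wall collapse in segment ", s, call. = FALSE)
          F2m <- Qm^2 / Am + Bm * Am^1.5
          ii <- seq.int(2L, n - 1L)
          A_new <- A; Q_new <- Q
          A_new[ii] <- A[ii] - h / dx * (Qm[ii] - Qm[ii - 1L]) + h * s1[ii]
          Q_new[ii] <- Q[ii] - h / dx * (F2m[ii] - F2m[ii - 1L]) + h * fr[ii]
          if (any(A_new[ii] <= 0)) stop("wall collapse in segment ", s, call. = FALSE)
          if (visc_gamma > 0) {
            # Voigt wall viscoelasticity: implicit solve of
            # (I - h nu d2/dx2) Q = Q*, nu = A0 Gamma / rho; ends pinned
            lam <- h * visc_gamma / (sqrt(mean(st$A0)) * rho) / dx^2
            Q_new <- .visc_smooth(Q_new, lam, visc_cache, s, n)
          }
          Snew[[s]]$A <- A_new
          Snew[[s]]$Q <- Q_new
        }
        # boundaries (characteristic-based, invariants from old adjacent interior)
        for (nm in names(geom$boundaries)) {
          b <- geom$boundaries[[nm]]
          st <- S[[b$seg]]; stn <- Snew[[b$seg]]
          n <- st$n
          if (b$end == "proximal") {
            iadj <- 2L; ib <- 1L; sgn <- -1       # outgoing invariant W2 = u - 4c
          } else {
            iadj <- n - 1L; ib <- n; sgn <- +1    # outgoing invariant W1 = u + 4c
          }
          gam <- st$gam[ib]
          # outgoing invariant extrapolated from the updated interior
          uadj <- stn$Q[iadj] / stn$A[iadj]
          W <- uadj + sgn * 4 * st$gam[iadj] * stn$A[iadj]^0.25
          if (b$type %in% c("q_in", "q_out")) {
            Qb <- src_fun[[nm]](t_new)
            # axial sign: inflow at a proximal end and outflow at a distal
            # end both run in +x; the mirrored cases run in -x
            flip <- (b$type == "q_in" && b$end == "distal") ||
              (b$type == "q_out" && b$end == "proximal")
            if (flip) Qb <- -Qb
            A_new <- .solve_area_flow(Qb, W, gam, sgn, st$A[ib], st$A0[ib])
            stn$A[ib] <- A_new; stn$Q[ib] <- Qb
          } else if (b$type == "wk3") {
            # implicit coupling: the backward-Euler WK3 relation
            # P = alpha + beta * Q (clinical units) is solved together
            # with the outgoing characteristic; a lagged update is
            # unstable once R1 reaches the characteristic impedance,
            # which step 4 imposes by design
            stt <- wk_state[[nm]]
            co <- wk3_coeffs(b$params, h)
            alpha <- co$a * stt$P + co$g * stt$Q_prev   # mmHg
            s_ax <- if (b$end == "distal") 1 else -1    # axial flow into terminal
            K_b <- st$K[ib]; r0_b <- st$r0[ib]; pext_b <- st$p_ext
            P <- stt$P * MMHG_TO_PA
            for (itn in 1:30) {
              r <- r0_b + (P - pext_b) / K_b
              A_b <- pi * r^2
              c_b <- gam * A_b^0.25
              u_b <- W - sgn * 4 * c_b
              dA <- 2 * pi * r / K_b
              dc <- 0.25 * gam * A_b^(-0.75) * dA
              # wk3 inverse: terminal inflow implied by pressure P
              q_wk <- (P / MMHG_TO_PA - alpha) / co$b * 1e-6     # m^3/s
              Fv <- s_ax * u_b * A_b - q_wk
              dF <- s_ax * (-sgn * 4 * dc * A_b + u_b * dA) -
                1e-6 / (MMHG_TO_PA * co$b)
              stp <- Fv / dF
              P <- P - stp
              if (abs(stp) < 1e-9) break
            }
            r <- r0_b + (P - pext_b) / K_b
            A_new <- pi * r^2
            u <- W - sgn * 4 * gam * A_new^0.25
            q_into <- s_ax * u * A_new * 1e6                      # ml/s
            stt$P_prev <- stt$P; stt$P <- P / MMHG_TO_PA; stt$Q_prev <- q_into
            wk_state[[nm]] <- stt
            stn$A[ib] <- A_new; stn$Q[ib] <- u * A_new
            bnd_q[[nm]] <- u * A_new
          } else if (b$type == "closed") {
            # u = 0; area from the outgoing invariant
            cb <- sgn * W / 4
            if (cb <= 0) stop("characteristic failure at closed end ", nm, call. = FALSE)
            stn$A[ib] <- (cb / gam)^4
            stn$Q[ib] <- 0
          }
          Snew[[b$seg]] <- stn
        }
        # FL proximal end: prescribed tear inflow
        if (!is.null(dis)) {
          st <- S[[dis$fl]]; stn <- Snew[[dis$fl]]
          gam <- st$gam[1L]
          uadj <- stn$Q[2L] / stn$A[2L]
          W2 <- uadj - 4 * st$gam[2L] * stn$A[2L]^0.25
          A_new <- .solve_area_flow(tear_Q, W2, gam, -1, st$A[1L], st$A0[1L])
          stn$A[1L] <- A_new; stn$Q[1L] <- tear_Q
          Snew[[dis$fl]] <- stn
        }
        # junctions: static-pressure continuity + mass conservation
        for (jj in seq_along(juncs)) {
          ends <- juncs[[jj]]
          W <- u <- gam <- K <- r0 <- pext <- sgn <- numeric(length(ends))
          for (k in seq_along(ends)) {
            e <- ends[[k]]; st <- S[[e$seg]]; stn <- Snew[[e$seg]]
            if (e$distal) {
              iadj <- st$n - 1L; ib <- st$n; sgn[k] <- 1
            } else {
              iadj <- 2L; ib <- 1L; sgn[k] <- -1
            }
            gam[k] <- st$gam[ib]; K[k] <- st$K[ib]; r0[k] <- st$r0[ib]
            pext[k] <- st$p_ext
            W[k] <- stn$Q[iadj] / stn$A[iadj] +
              sgn[k] * 4 * st$gam[iadj] * stn$A[iadj]^0.25
          }
          P <- jP[jj]
          for (it in 1:30) {
            r <- r0 + (P - pext) / K
            A <- pi * r^2
            cA <- gam * A^0.25
            u <- W - sgn * 4 * cA
            f <- sum(sgn * u * A)
            dA <- 2 * pi * r / K
            dc <- 0.25 * gam * A^(-0.75) * dA
            df <- sum(sgn * (-sgn * 4 * dc * A + u * dA))
            step <- f / df
            P <- P - step
            if (abs(step) < 1e-10) break
          }
          jP[jj] <- P
          for (k in seq_along(ends)) {
            e <- ends[[k]]; stn <- Snew[[e$seg]]
            ib <- if (e$distal) stn$n else 1L
            A_k <- pi * (r0[k] + (P - pext[k]) / K[k])^2
            u_k <- W[k] - sgn[k] * 4 * gam[k] * A_k^0.25
            stn$A[ib] <- A_k; stn$Q[ib] <- u_k * A_k
            Snew[[e$seg]] <- stn
          }
        }
        S <- Snew
      }
      for (s in segn) {
        Ah[[s]][i_out, ] <- S[[s]]$A
        Qh[[s]][i_out, ] <- S[[s]]$Q
        Ph[[s]][i_out, ] <- pressure_of(S[[s]])
      }
    }
    if (!is.null(Ph_prev)) {
      num <- max(vapply(segn, function(s) max(abs(Ph[[s]] - Ph_prev[[s]])), numeric(1)))
      den <- max(vapply(segn, function(s) max(abs(Ph[[s]])), numeric(1)))
      resid <- num / den
      if (resid < tol_cycle) { converged <- TRUE; break }
    }
    Ph_prev <- Ph
  }
  if (!converged) {
    warning(sprintf("solve_pulsewave: periodicity %.3g%% not reached in %d cycles (residual %.3g%%)",
                    100 * tol_cycle, n_cycles, 100 * resid), call. = FALSE)
  }

  tau <- lapply(segn, function(s) {
    tw <- wall_shear(as.vector(Qh[[s]]), as.vector(Ah[[s]]), rheo)
    matrix(tw, n_out, S[[s]]$n)
  })
  names(tau) <- segn

  res_segments <- lapply(segn, function(s) {
    list(x = segs[[s]]$x, P = Ph[[s]], Q = Qh[[s]], A = Ah[[s]], tau_w = tau[[s]])
  })
  names(res_segments) <- segn
  out <- structure(list(segments = res_segments, t = t_grid, T = Tp, dt = dt,
                        cycles = cycle, converged = converged, residual = resid,
                        rigid = FALSE, boundaries = geom$boundaries,
                        dissection = geom$dissection),
                   class = "sim_result")
  out$balance <- volume_balance(out, sources)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# solve (I - lam * D2) x = q with Dirichlet ends pinned to q[1], q[n];
# the Thomas forward-elimination coefficients depend only on (lam, n)
# and are cached per segment
.visc_smooth <- function(q, lam, cache, key, n) {
  ck <- get0(key, envir = cache)
  if (is.null(ck) || abs(ck$lam - lam) > 1e-12 * lam) {
    # rows 2..n-1: -lam, 1+2lam, -lam; rows 1, n: identity
    cp <- numeric(n)
    cp[1L] <- 0
    b <- 1 + 2 * lam
    for (i in 2:(n - 1L)) cp[i] <- -lam / (b + lam * cp[i - 1L])
    ck <- list(lam = lam, cp = cp, b = b)
    assign(key, ck, envir = cache)
  }
  cp <- ck$cp; b <- ck$b
  dp <- numeric(n)
  dp[1L] <- q[1L]
  for (i in 2:(n - 1L)) {
    dp[i] <- (q[i] + lam * dp[i - 1L]) / (b + lam * cp[i - 1L])
  }
  x <- q
  for (i in (n - 1L):2) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

# rigid (incompressible) limit: assemble the geometry into the lumped 0D
# network and map node series back onto the grids. The FL is a closed rigid
# cavity: zero flow, pressure slaved to the TL tear node.
solve_pulsewave_rigid <- function(geom, sources, dt, n_cycles, rheo, P_init) {
  lump <- geometry_to_lumped(geom, sources, mu = 4e-3, rho = rheo$rho)
  sol <- solve_lumped(lump$net, dt = dt, n_cycles = max(n_cycles, 20L),
                      tol = 5e-3, P0 = P_init)
  Tp <- sources[[1L]]$T
  t_grid <- sol$pressures[[1L]]$t
  n_out <- length(t_grid)
  dis <- geom$dissection
  segn <- names(geom$segments)
  seg_order <- if (is.null(dis)) segn else c(setdiff(segn, dis$fl), dis$fl)
  res_segments <- list()
  for (s in seg_order) {
    seg <- geom$segments[[s]]
    n <- seg$n
    if (!is.null(dis) && s == dis$fl) {
      # closed rigid cavity: exactly zero flow
      tlP <- res_segments[[dis$tl]]
      P <- matrix(rep(tlP$P[, 1L], n), n_out, n)
      res_segments[[s]] <- list(x = seg$x, P = P, Q = matrix(0, n_out, n),
                                A = matrix(rep(seg$A0, each = n_out), n_out, n),
                                tau_w = matrix(0, n_out, n))
      next
    }
    Pfrom <- sol$pressures[[lump$ends[[s]]["from"]]]$v * MMHG_TO_PA
    Pto <- sol$pressures[[lump$ends[[s]]["to"]]]$v * MMHG_TO_PA
    Qs <- sol$block_flows[[s]]$v * 1e-6
    w <- seg$x / seg$length
    P <- outer(Pfrom, rep(1, n)) * outer(rep(1, n_out), 1 - w) +
      outer(Pto, rep(1, n)) * outer(rep(1, n_out), w)
    Q <- matrix(rep(Qs, n), n_out, n)
    A <- matrix(rep(seg$A0, each = n_out), n_out, n)
    res_segments[[s]] <- list(x = seg$x, P = P, Q = Q, A = A,
                              tau_w = matrix(wall_shear(as.vector(Q), as.vector(A), rheo),
                                             n_out, n))
  }
  out <- structure(list(segments = res_segments[segn], t = t_grid, T = Tp, dt = dt,
                        cycles = sol$cycles, converged = sol$converged,
                        residual = sol$residual, rigid = TRUE,
                        boundaries = geom$boundaries, dissection = dis,
                        lumped = sol),
                   class = "sim_result")
  out$balance <- volume_balance(out, sources)
  out
}

#' Convert a 1D geometry to its lumped (0D) analogue
#'
#' Each segment becomes an inertance-resistance block with the standard
#' identities `L = rho l / A0` and `R = 8 pi mu l / A0^2` (Poiseuille),
#' converted to clinical units. The false lumen (closed, no through-flow
#' in the rigid limit) is omitted.
#'
#' @param geom a [network_geometry].
#' @param sources named list of prescribed flow [waveform]s (ml/s).
#' @param mu reference dynamic viscosity (Pa s) for the Poiseuille
#'   resistance (default 4e-3).
#' @param rho blood density (kg/m^3).
#' @param terminal_params optional named list of [wk3_params] overriding
#'   (or standing in for) the parameters attached to the geometry's
#'   `wk3` boundaries.
#' @return list with `net` (a [lumped_network]) and `ends` (per-segment
#'   from/to node names).
#' @export
geometry_to_lumped <- function(geom, sources, mu = 4e-3, rho = 1056,
                               terminal_params = NULL) {
  stopifnot(inherits(geom, "network_geometry"))
  dis <- geom$dissection
  # node naming: junction j<i>; boundary nodes carry the boundary name
  end_node <- new.env()
  for (jj in seq_along(geom$junctions)) {
    for (e in geom$junctions[[jj]]) {
      assign(paste(e$seg, e$end, sep = ":"), paste0("j", jj), envir = end_node)
    }
  }
  for (nm in names(geom$boundaries)) {
    b <- geom$boundaries[[nm]]
    assign(paste(b$seg, b$end, sep = ":"), nm, envir = end_node)
  }
  blocks <- NULL
  ends <- list()
  for (s in names(geom$segments)) {
    if (!is.null(dis) && s == dis$fl) next
    seg <- geom$segments[[s]]
    A0m <- mean(seg$A0)
    L <- rho * seg$length / A0m / MMHG_S_ML_TO_SI            # mmHg s^2/ml
    R <- 8 * pi * mu * seg$length / A0m^2 / MMHG_S_ML_TO_SI  # mmHg s/ml
    from <- get0(paste(s, "proximal", sep = ":"), envir = end_node)
    to <- get0(paste(s, "distal", sep = ":"), envir = end_node)
    if (is.null(from) || is.null(to)) stop("unmapped end for segment ", s, call. = FALSE)
    blocks <- rbind(blocks, data.frame(name = s, from = from, to = to,
                                       L = L, R = R, stringsAsFactors = FALSE))
    ends[[s]] <- c(from = from, to = to)
  }
  terminals <- list()
  srcs <- list()
  for (nm in names(geom$boundaries)) {
    b <- geom$boundaries[[nm]]
    if (b$type == "wk3") {
      p <- terminal_params[[nm]] %||% b$params
      if (is.null(p)) stop("wk3 boundary without parameters: ", nm, call. = FALSE)
      terminals[[nm]] <- p
    } else if (b$type == "q_in") {
      srcs[[nm]] <- sources[[nm]]
    } else if (b$type == "q_out") {
      w <- sources[[nm]]
      srcs[[nm]] <- waveform(w$t, -w$v, w$T)
    }
  }
  list(net = lumped_network(blocks, terminals, srcs), ends = ends)
}

# per-cycle volume bookkeeping over the recorded (last) cycle
volume_balance <- function(res, sources) {
  dtv <- res$dt
  q_in <- 0; q_out <- 0
  for (nm in names(res$boundaries)) {
    b <- res$boundaries[[nm]]
    seg <- res$segments[[b$seg]]
    ib <- if (b$end == "distal") ncol(seg$Q) else 1L
    q <- seg$Q[, ib]
    if (b$type == "q_in") q_in <- q_in + sum(q) * dtv
    if (b$type %in% c("q_out", "wk3")) {
      q_out <- q_out + sum(q) * dtv * (if (b$end == "distal") 1 else -1)
    }
  }
  # stroke volume scale: forward volume through the (first) inflow boundary
  sv <- q_in
  for (nm in names(res$boundaries)) {
    b <- res$boundaries[[nm]]
    if (b$type == "q_in") {
      ib <- if (b$end == "distal") ncol(res$segments[[b$seg]]$Q) else 1L
      sv <- sum(pmax(res$segments[[b$seg]]$Q[, ib], 0)) * dtv
      break
    }
  }
  # change in stored volume across the recorded cycle (zero at exact
  # periodicity); one-step offset at the cycle seam is O(dt)
  dV <- 0
  for (s in names(res$segments)) {
    sg <- res$segments[[s]]
    m <- nrow(sg$A)
    dA <- sg$A[m, ] - sg$A[1L, ]
    n <- length(dA)
    dV <- dV + sum(diff(sg$x) * (dA[-1L] + dA[-n]) / 2)
  }
  list(inflow_volume = q_in * 1e6, outflow_volume = q_out * 1e6,
       stored_delta = dV * 1e6, stroke_volume = sv * 1e6,
       relative_error = abs(q_in - q_out - dV) / sv)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s model: %d segments, %d samples/cycle, T = %.3g s\n",
              if (x$rigid) "rigid" else "compliant",
              length(x$segments), length(x$t), x$T))
  cat(sprintf("  cycles run %d, periodic: %s; per-cycle volume error %.3g%% of stroke volume\n",
              x$cycles, x$converged, 100 * x$balance$relative_error))
  invisible(x)
}

#' Extract probe waveforms from a simulation result
#'
#' @param res a `sim_result` from [solve_pulsewave].
#' @param seg segment name.
#' @param x_frac fractional position along the segment in `[0, 1]`
#'   (nearest grid node is used).
#' @return list of [waveform]s: `P` (Pa), `Q` (m^3/s), `A` (m^2),
#'   `tau_w` (Pa).
#' @export
result_probe <- function(res, seg, x_frac = 0.5) {
  stopifnot(inherits(res, "sim_result"))
  sg <- res$segments[[seg]]
  if (is.null(sg)) stop("unknown segment: ", seg, call. = FALSE)
  j <- which.min(abs(sg$x / max(sg$x) - x_frac))
  list(P = waveform(res$t, sg$P[, j], res$T),
       Q = waveform(res$t, sg$Q[, j], res$T),
       A = waveform(res$t, sg$A[, j], res$T),
       tau_w = waveform(res$t, sg$tau_w[, j], res$T))
}
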