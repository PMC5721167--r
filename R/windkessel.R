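#' Three-element Windkessel (RCR) parameters
#'
#' The WK3 outlet model lumps the downstream vasculature into a proximal
#' resistance `R1` (absorbs incoming waves), a distal resistance `R2` and
#' a compliance `C`. Flow `Q` into the terminal and mean pressure `P` over
#' the coupled boundary obey
#' \deqn{P + R_2 C \frac{dP}{dt} = (R_1 + R_2) Q + R_1 R_2 C \frac{dQ}{dt}.}
#'
#' @param R1 proximal resistance (mmHg s/ml), `>= 0`.
#' @param R2 distal resistance (mmHg s/ml), `> 0`.
#' @param C compliance (ml/mmHg), `> 0`.
#' @return object of class `wk3_params`.
#' @examples
#' wk3_params(R1 = 0.115, R2 = 3.608, C = 0.157)  # abdominal aortic outlet
#' @export
wk3_params <- function(R1, R2, C) {
  stopifnot_finite(c(R1, R2, C), "wk3_params")
  if (R1 < 0) stop("R1 must be >= 0", call. = FALSE)
  if (R2 <= 0) stop("R2 must be > 0", call. = FALSE)
  if (C <= 0) stop("C must be > 0", call. = FALSE)
  structure(list(R1 = R1, R2 = R2, C = C), class = "wk3_params")
}

#' @export
print.wk3_params <- function(x, ...) {
  cat(sprintf("<wk3> R1 = %.4g, R2 = %.4g mmHg s/ml, C = %.4g ml/mmHg\n",
              x$R1, x$R2, x$C))
  invisible(x)
}

#' Inertance-resistance segment block
#'
#' Elementary 0D building block of the lumped arterial network: a vessel
#' segment reduced to an inertance `L` and a resistance `R` in series,
#' advancing `dQ/dt = (P_in - P_out - R Q)/L`.
#'
#' @param L inertance (mmHg s^2/ml), `> 0`.
#' @param R resistance (mmHg s/ml), `>= 0`.
#' @return object of class `lr_block`.
#' @export
lr_block <- function(L, R) {
  stopifnot_finite(c(L, R), "lr_block")
  if (L <= 0) stop("L must be > 0", call. = FALSE)
  if (R < 0) stop("R must be >= 0", call. = FALSE)
  structure(list(L = L, R = R), class = "lr_block")
}

#' Lagged state of a coupled WK3 boundary
#'
#' The coupling contract advances the WK3 ODE with a first-order backward
#' Euler step using flow and pressure values from the previous time step.
#'
#' @param P current boundary pressure (mmHg).
#' @param Q_prev flow at the previous step (ml/s).
#' @param P_prev pressure at the previous step (mmHg).
#' @return object of class `wk3_state`.
#' @export
wk3_state <- function(P = 80, Q_prev = 0, P_prev = P) {
  stopifnot_finite(c(P, Q_prev, P_prev), "wk3_state")
  structure(list(P = P, Q_prev = Q_prev, P_prev = P_prev), class = "wk3_state")
}

# backward-Euler update coefficients: P_now = a * P_prev + b * Q_now + g * Q_prev
wk3_coeffs <- function(params, dt) {
  tau <- params$R2 * params$C
  den <- 1 + tau / dt
  list(a = (tau / dt) / den,
       b = (params$R1 + params$R2 + params$R1 * tau / dt) / den,
       g = -(params$R1 * tau / dt) / den)
}

#' Advance a WK3 boundary by one backward-Euler step
#'
#' Discretizes the WK3 pressure-flow relation with first-order backward
#' differences for both `dP/dt` and `dQ/dt`:
#' \deqn{P_n (1 + \tau/\Delta t) = (\tau/\Delta t) P_{n-1} +
#'   (R_1 + R_2) Q_n + R_1 \tau (Q_n - Q_{n-1})/\Delta t,\quad \tau = R_2 C.}
#'
#' @param state a [wk3_state] (updated and returned).
#' @param Q_now flow at the current step (ml/s).
#' @param params a [wk3_params].
#' @param dt time step (s), `> 0`.
#' @return the updated [wk3_state]; the new boundary pressure is `$P` (mmHg).
#' @examples
#' st <- wk3_state(P = 113.55, Q_prev = 30.5)
#' st <- wk3_step(st, 30.5, wk3_params(0.115, 3.608, 0.157), 1e-3)
#' st$P  # steady state: (R1 + R2) * Q
#' @export
wk3_step <- function(state, Q_now, params, dt) {
  stopifnot(inherits(state, "wk3_state"), inherits(params, "wk3_params"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  stopifnot_finite(Q_now, "Q_now")
  co <- wk3_coeffs(params, dt)
  P_now <- co$a * state$P + co$b * Q_now + co$g * state$Q_prev
  state$P_prev <- state$P
  state$P <- P_now
  state$Q_prev <- Q_now
  state
}

# Vectorized WK3 trajectory for a prescribed flow vector (one linear
# recurrence per step; stats::filter does the heavy lifting). Returns the
# pressure at each step given P0 before the first step.
wk3_series <- function(Q, params, dt, P0, Q0 = Q[length(Q)]) {
  co <- wk3_coeffs(params, dt)
  Qprev <- c(Q0, Q[-length(Q)])
  f <- co$b * Q + co$g * Qprev
  f[1L] <- f[1L] + co$a * P0
  as.numeric(stats::filter(f, co$a, method = "recursive"))
}

# Periodic steady-state WK3 response to one cycle of prescribed flow.
# The one-cycle affine map P_end = a^m * P_start + g is solved for its
# fixed point, then one cycle is generated from it.
wk3_periodic <- function(Q, params, dt) {
  m <- length(Q)
  co <- wk3_coeffs(params, dt)
  g <- wk3_series(Q, params, dt, P0 = 0)[m]
  am <- co$a^m
  P_start <- g / (1 - am)
  wk3_series(Q, params, dt, P0 = P_start)
}

#' Advance an inertance-resistance block by one backward-Euler step
#'
#' @param Q flow at the previous step (ml/s).
#' @param P_in,P_out upstream and downstream pressures (mmHg).
#' @param block an [lr_block].
#' @param dt time step (s), `> 0`.
#' @return flow (ml/s) after one implicit step of
#'   `dQ/dt = (P_in - P_out - R Q)/L`.
#' @export
lr_step <- function(Q, P_in, P_out, block, dt) {
  stopifnot(inherits(block, "lr_block"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  stopifnot_finite(c(Q, P_in, P_out), "lr_step inputs")
  (Q + dt / block$L * (P_in - P_out)) / (1 + dt * block$R / block$L)
}

#' Lumped (0D) arterial network
#'
#' Named inertance-resistance blocks connect named pressure nodes; WK3
#' terminals drain nodes to the venous reference (0 mmHg); sources inject
#' prescribed flow waveforms at nodes (negative values withdraw flow, e.g.
#' prescribed carotid outflows).
#'
#' @param blocks data.frame with columns `name`, `from`, `to`, `L`, `R`
#'   (clinical units).
#' @param terminals named list of [wk3_params]; names are node names.
#' @param sources named list of [waveform] flows (ml/s); names are node
#'   names; positive into the network.
#' @return object of class `lumped_network`.
#' @export
lumped_network <- function(blocks, terminals, sources) {
  stopifnot(is.data.frame(blocks),
            all(c("name", "from", "to", "L", "R") %in% names(blocks)))
  if (any(blocks$L <= 0)) stop("all block inertances must be > 0", call. = FALSE)
  if (any(blocks$R < 0)) stop("all block resistances must be >= 0", call. = FALSE)
  lapply(terminals, function(p) stopifnot(inherits(p, "wk3_params")))
  lapply(sources, function(w) stopifnot(is_waveform(w)))
  nodes <- unique(c(blocks$from, blocks$to, names(terminals), names(sources)))
  # connectivity: every terminal reachable from a source through blocks
  adj <- lapply(nodes, function(n) {
    c(blocks$to[blocks$from == n], blocks$from[blocks$to == n])
  })
  names(adj) <- nodes
  seen <- character(0); frontier <- names(sources)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
  }
  unreachable <- setdiff(names(terminals), seen)
  if (length(unreachable)) {
    stop("terminal(s) not reachable from any source: ",
         paste(unreachable, collapse = ", "), call. = FALSE)
  }
  structure(list(blocks = blocks, terminals = terminals, sources = sources,
                 nodes = nodes), class = "lumped_network")
}

#' @export
print.lumped_network <- function(x, ...) {
  cat(sprintf("<lumped_network> %d nodes, %d LR blocks, %d WK3 terminals, %d sources\n",
              length(x$nodes), nrow(x$blocks), length(x$terminals), length(x$sources)))
  invisible(x)
}

#' Solve a lumped network to periodic steady state
#'
#' The full 0D system (KCL at every node, implicit LR block updates, WK3
#' terminal updates) is advanced with a backward-Euler scheme. The system
#' is linear and time-invariant, so the step matrix is factored once.
#' Cycles are repeated until the cycle-to-cycle maximum relative change of
#' all node pressures falls below `tol` (default 0.5%).
#'
#' @param net a [lumped_network]; all sources must share one period.
#' @param dt time step (s); must divide the period.
#' @param n_cycles maximum number of cardiac cycles (default 20).
#' @param tol periodicity tolerance on node pressures (relative).
#' @param P0 initial node/capacitor pressure (mmHg, default 80, the
#'   diastolic target).
#' @return list with `pressures` (named list of node pressure [waveform]s,
#'   mmHg), `block_flows`, `terminal_flows` (named lists of flow
#'   [waveform]s, ml/s), `converged`, `cycles`, `residual`.
#' @export
solve_lumped <- function(net, dt = 1e-3, n_cycles = 20L, tol = 5e-3, P0 = 80) {
  stopifnot(inherits(net, "lumped_network"))
  periods <- vapply(net$sources, function(w) w$T, numeric(1))
  if (length(periods) == 0L) stop("network has no sources", call. = FALSE)
  if (max(periods) - min(periods) > 1e-9 * max(periods)) {
    stop("all source waveforms must share one period", call. = FALSE)
  }
  Tp <- periods[[1L]]
  m <- round(Tp / dt)
  if (abs(m * dt - Tp) > 1e-9 * Tp) stop("dt must divide the period", call. = FALSE)

  nodes <- net$nodes
  nb <- nrow(net$blocks); nt <- length(net$terminals); nn <- length(nodes)
  term_nodes <- names(net$terminals)
  # unknown layout: [P_nodes, Q_blocks, Q_terms, Pc_terms]
  iP <- seq_len(nn)
  iQ <- nn + seq_len(nb)
  iT <- nn + nb + seq_len(nt)
  iC <- nn + nb + nt + seq_len(nt)
  nx <- nn + nb + 2L * nt
  node_id <- stats::setNames(seq_len(nn), nodes)

  M <- matrix(0, nx, nx)
  # KCL rows (one per node): sum of block flows in - out - terminal draw = -src
  for (b in seq_len(nb)) {
    M[node_id[[net$blocks$from[b]]], iQ[b]] <- M[node_id[[net$blocks$from[b]]], iQ[b]] - 1
    M[node_id[[net$blocks$to[b]]],   iQ[b]] <- M[node_id[[net$blocks$to[b]]],   iQ[b]] + 1
  }
  for (k in seq_len(nt)) {
    M[node_id[[term_nodes[k]]], iT[k]] <- M[node_id[[term_nodes[k]]], iT[k]] - 1
  }
  # block rows: (1 + dt R/L) Q - (dt/L)(P_from - P_to) = Q_prev
  for (b in seq_len(nb)) {
    r <- iQ[b]
    L <- net$blocks$L[b]; R <- net$blocks$R[b]
    M[r, r] <- 1 + dt * R / L
    M[r, node_id[[net$blocks$from[b]]]] <- -dt / L
    M[r, node_id[[net$blocks$to[b]]]] <- dt / L
  }
  # terminal rows: P_node - R1 Qt - Pc = 0 ; (1 + dt/(R2 C)) Pc - (dt/C) Qt = Pc_prev
  for (k in seq_len(nt)) {
    p <- net$terminals[[k]]
    M[iT[k], node_id[[term_nodes[k]]]] <- 1
    M[iT[k], iT[k]] <- -p$R1
    M[iT[k], iC[k]] <- -1
    M[iC[k], iC[k]] <- 1 + dt / (p$R2 * p$C)
    M[iC[k], iT[k]] <- -dt / p$C
  }
  Minv <- solve(M)

  # precompute source injections per step (columns: nodes)
  t_grid <- seq(0, by = dt, length.out = m)
  src <- matrix(0, m, nn)
  for (s in names(net$sources)) {
    src[, node_id[[s]]] <- src[, node_id[[s]]] +
      wf_interp(net$sources[[s]], t_grid + dt)  # implicit step targets t + dt
  }

  x <- numeric(nx)
  x[iP] <- P0; x[iC] <- P0
  Phist_prev <- NULL
  converged <- FALSE; resid <- NA_real_; cyc <- 0L
  Phist <- matrix(0, m, nn); Qbhist <- matrix(0, m, nb); Qthist <- matrix(0, m, nt)
  for (cyc in seq_len(n_cycles)) {
    for (i in seq_len(m)) {
      b <- numeric(nx)
      b[iP] <- -src[i, ]
      b[iQ] <- x[iQ]
      b[iC] <- x[iC]
      x <- Minv %*% b
      Phist[i, ] <- x[iP]; Qbhist[i, ] <- x[iQ]; Qthist[i, ] <- x[iT]
    }
    if (!is.null(Phist_prev)) {
      resid <- max(abs(Phist - Phist_prev)) / max(abs(Phist))
      if (resid < tol) { converged <- TRUE; break }
    }
    Phist_prev <- Phist
  }
  if (!converged) {
    warning(sprintf("solve_lumped: periodicity %.3g%% not reached in %d cycles (residual %.3g%%)",
                    100 * tol, n_cycles, 100 * resid), call. = FALSE)
  }
  mk <- function(vals) waveform(t_grid, vals, Tp)
  list(
    pressures = stats::setNames(lapply(seq_len(nn), function(j) mk(Phist[, j])), nodes),
    block_flows = stats::setNames(lapply(seq_len(nb), function(j) mk(Qbhist[, j])), net$blocks$name),
    terminal_flows = stats::setNames(lapply(seq_len(nt), function(j) mk(Qthist[, j])), term_nodes),
    converged = converged, cycles = cyc, residual = resid
  )
}
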