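#' Foot-to-foot pulse-wave velocity between two pressure probes
#'
#' The wave foot is the pressure minimum immediately preceding the
#' systolic upstroke (the point of maximal slope), refined to sub-sample
#' precision by parabolic interpolation around the minimum. The PWV is
#' the probe separation divided by the foot-to-foot transit time (taken
#' modulo the period).
#'
#' @param P_a,P_b pressure [waveform]s at the upstream and downstream
#'   probe (same period; any common pressure unit).
#' @param distance probe separation (m), `> 0`.
#' @return pulse-wave velocity (m/s).
#' @export
foot_to_foot_pwv <- function(P_a, P_b, distance) {
  stopifnot(is_waveform(P_a), is_waveform(P_b))
  if (distance <= 0) stop("distance must be > 0", call. = FALSE)
  if (abs(P_a$T - P_b$T) > 1e-9 * P_a$T) {
    stop("waveforms must share one period", call. = FALSE)
  }
  ta <- wave_foot_time(P_a)
  tb <- wave_foot_time(P_b)
  dt_foot <- (tb - ta) %% P_a$T
  if (dt_foot <= 0 || dt_foot >= P_a$T) {
    stop("foot-to-foot delay unresolved: refine dt or check probe order",
         call. = FALSE)
  }
  distance / dt_foot
}

# locate the wave foot: minimum preceding the maximal upstroke slope,
# with parabolic sub-sample refinement; ties broken by earliest time.
# The cycle is rotated so the systolic peak sits mid-array and the
# original wrap interface (where residual non-periodicity of a simulated
# cycle leaves a small jump) is excluded from the slope search.
wave_foot_time <- function(P) {
  v <- P$v; n <- length(v); h <- wf_dt(P)
  k0 <- which.max(v)
  rot <- ((seq_len(n) + k0 - n %/% 2 - 2L) %% n) + 1L  # rotated -> original
  w <- v[rot]
  slope <- diff(w) / h
  wrap_pos <- which(rot == n)                # interface rot==n -> rot==1
  if (length(wrap_pos) && wrap_pos[1L] < n) slope[wrap_pos[1L]] <- -Inf
  i_up <- which.max(slope)
  i <- i_up
  while (i > 1L && w[i - 1L] < w[i]) i <- i - 1L
  im <- max(i - 1L, 1L); ip <- min(i + 1L, n)
  y1 <- w[im]; y2 <- w[i]; y3 <- w[ip]
  den <- (y1 - 2 * y2 + y3)
  delta <- if (abs(den) > .Machine$double.eps) 0.5 * (y1 - y3) / den else 0
  delta <- max(-0.5, min(0.5, delta))
  (P$t[rot[i]] + delta * h) %% P$T
}

#' Percentage cross-sectional area variation
#'
#' `dA% = (A - A0)/A0 * 100` with `A0` the lowest area over the cycle;
#' the minimum of the output is exactly 0 and the result is invariant to
#' rescaling `A`.
#'
#' @param A lumen-area [waveform], strictly positive.
#' @return [waveform] in percent.
#' @export
delta_area_pct <- function(A) {
  dA <- normalized_area_variation(A)
  waveform(dA$t, 100 * dA$v, dA$T)
}

#' Time-averaged wall shear stress and oscillatory shear index
#'
#' `TAWSS = (1/T) int |tau_w| dt`;
#' `OSI = 0.5 (1 - |int tau_w dt| / int |tau_w| dt)`.
#' OSI is 0 for unidirectional shear and 0.5 for perfectly oscillatory
#' shear; for identically zero shear the convention `OSI = 0` is used.
#' Integrals are trapezoidal over the periodic closure of the cycle.
#'
#' @param tau_w wall-shear-stress [waveform] (Pa) over one period.
#' @return list with `TAWSS` (Pa, `>= 0`) and `OSI` (in `[0, 0.5]`).
#' @export
tawss_osi <- function(tau_w) {
  stopifnot(is_waveform(tau_w))
  int_abs <- mean(abs(tau_w$v)) * tau_w$T
  int_sgn <- mean(tau_w$v) * tau_w$T
  TAWSS <- int_abs / tau_w$T
  OSI <- if (int_abs == 0) 0 else 0.5 * (1 - abs(int_sgn) / int_abs)
  list(TAWSS = TAWSS, OSI = min(max(OSI, 0), 0.5))
}

#' Transmural pressure across the intimal flap
#'
#' `TMP(t) = P_TL(t) - P_FL(t)` (mmHg), the pressure difference between
#' true and false lumen averaged over a cross-section. Its sign governs
#' the direction of flap excursion.
#'
#' @param P_TL,P_FL pressure [waveform]s (mmHg) on a common time base.
#' @return [waveform] of TMP (mmHg) with attributes `max`, `min` and
#'   `zero_crossings`.
#' @export
transmural_pressure <- function(P_TL, P_FL) {
  stopifnot(is_waveform(P_TL), is_waveform(P_FL))
  if (abs(P_TL$T - P_FL$T) > 1e-9 * P_TL$T ||
      length(P_TL$t) != length(P_FL$t)) {
    stop("TL/FL waveforms must share one time base", call. = FALSE)
  }
  tmp <- waveform(P_TL$t, P_TL$v - P_FL$v, P_TL$T)
  s <- sign(tmp$v)
  crossings <- sum(abs(diff(c(s, s[1L]))) > 0 & s != 0)
  attr(tmp, "max") <- max(tmp$v)
  attr(tmp, "min") <- min(tmp$v)
  attr(tmp, "zero_crossings") <- crossings
  tmp
}

#' Blood volume stored in the modelled aorta during systole
#'
#' Integrates the instantaneous imbalance between inflow and total
#' outflow over the systolic window: the compliant vessel stores this
#' volume during systole and releases it in diastole. The default window
#' runs from the inflow upstroke (wave foot) to the return of the inflow
#' to its baseline after the peak.
#'
#' @param Q_in inflow [waveform] (ml/s).
#' @param Q_outs list of outflow [waveform]s (ml/s) on the same time base.
#' @param window optional `c(t_start, t_end)` (s); the window may wrap
#'   across the cycle seam (`t_end` up to `t_start + T`), but its length
#'   must not exceed one period.
#' @return stored volume (ml), with the window used as attribute
#'   `window`.
#' @export
stored_volume <- function(Q_in, Q_outs, window = NULL) {
  stopifnot(is_waveform(Q_in))
  lapply(Q_outs, function(w) {
    stopifnot(is_waveform(w))
    if (length(w$t) != length(Q_in$t) || abs(w$T - Q_in$T) > 1e-9 * Q_in$T) {
      stop("all waveforms must share the inflow time base", call. = FALSE)
    }
  })
  if (is.null(window)) {
    window <- systole_window(Q_in)
  }
  dur <- window[2L] - window[1L]
  if (any(window < 0) || dur <= 0 || dur > Q_in$T) {
    stop("window must lie within one period", call. = FALSE)
  }
  net <- Q_in$v - Reduce(`+`, lapply(Q_outs, function(w) w$v))
  rel <- (Q_in$t - window[1L]) %% Q_in$T     # time since window start
  idx <- which(rel <= dur)
  ord <- idx[order(rel[idx])]
  h <- wf_dt(Q_in)
  vals <- net[ord]
  vol <- sum((vals[-1L] + vals[-length(vals)]) / 2) * h
  attr(vol, "window") <- window
  vol
}

#' Systolic window of an inflow waveform
#'
#' From the inflow upstroke (wave foot) to the first return to the foot
#' level after the peak; the window may wrap across the cycle seam, in
#' which case `t_end > T`.
#'
#' @param Q_in inflow [waveform] (ml/s).
#' @return `c(t_start, t_end)` (s).
#' @export
systole_window <- function(Q_in) {
  tf <- wave_foot_time(Q_in)
  base <- wf_interp(Q_in, tf)
  i_pk <- which.max(Q_in$v)
  t_rel <- (Q_in$t - tf) %% Q_in$T          # time since the foot
  t_pk <- t_rel[i_pk]
  after <- which(t_rel > t_pk & Q_in$v <= base + 1e-9 * max(abs(Q_in$v)))
  t_end <- if (length(after)) min(t_rel[after]) else Q_in$T / 2
  c(tf, tf + t_end)
}

#' Clinical index report for a dissection simulation
#'
#' Convenience wrapper computing the full index set from a `sim_result`:
#' foot-to-foot PWV along a named segment, peak area variation and
#' TAWSS/OSI at requested probes, and (for dissected geometries) the
#' TL-FL transmural pressure.
#'
#' @param res a `sim_result` from [solve_pulsewave].
#' @param pwv_segment segment along which to measure PWV (proximal vs
#'   distal probe); default the first segment.
#' @param probes named list of `list(seg, x_frac)` probe positions.
#' @param tmp_x_frac fractional position for the TL/FL TMP comparison.
#' @return object of class `index_report`.
#' @export
index_report <- function(res, pwv_segment = names(res$segments)[1L],
                         probes = NULL, tmp_x_frac = 0.5) {
  stopifnot(inherits(res, "sim_result"))
  seg <- res$segments[[pwv_segment]]
  L <- max(seg$x)
  pa <- result_probe(res, pwv_segment, 0)$P
  pb <- result_probe(res, pwv_segment, 1)$P
  pwv <- tryCatch(foot_to_foot_pwv(pa, pb, L), error = function(e) NA_real_)
  if (is.null(probes)) {
    probes <- stats::setNames(
      lapply(names(res$segments), function(s) list(seg = s, x_frac = 0.5)),
      names(res$segments))
  }
  per_probe <- lapply(probes, function(p) {
    pr <- result_probe(res, p$seg, p$x_frac)
    sh <- tawss_osi(pr$tau_w)
    list(peak_dA_pct = max(delta_area_pct(pr$A)$v),
         TAWSS = sh$TAWSS, OSI = sh$OSI)
  })
  tmp <- NULL
  if (!is.null(res$dissection)) {
    ptl <- result_probe(res, res$dissection$tl, tmp_x_frac)$P
    pfl <- result_probe(res, res$dissection$fl, tmp_x_frac)$P
    tmp <- transmural_pressure(
      waveform(ptl$t, ptl$v / MMHG_TO_PA, ptl$T),
      waveform(pfl$t, pfl$v / MMHG_TO_PA, pfl$T))
  }
  structure(list(PWV = pwv, probes = per_probe, TMP = tmp),
            class = "index_report")
}

#' @export
print.index_report <- function(x, ...) {
  cat(sprintf("<index_report> PWV = %.2f m/s\n", x$PWV))
  for (nm in names(x$probes)) {
    p <- x$probes[[nm]]
    cat(sprintf("  %-8s dA%%max = %5.1f  TAWSS = %6.3f Pa  OSI = %.3f\n",
                nm, p$peak_dA_pct, p$TAWSS, p$OSI))
  }
  if (!is.null(x$TMP)) {
    cat(sprintf("  TMP range [%.1f, %.1f] mmHg\n",
                attr(x$TMP, "min"), attr(x$TMP, "max")))
  }
  invisible(x)
}
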