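#' Table of target mean branch flows (ml/s)
#'
#' Mean flows used to tune the Windkessel outlets: supra-aortic and
#' visceral branches plus the abdominal aortic outlet. The carotids (RCC
#' 12.7, LCC 8.9 ml/s) are prescribed-flow boundaries, not Windkessel
#' outlets, and are returned by [prescribed_mean_flows].
#'
#' @return named numeric vector of WK3-outlet mean-flow targets.
#' @export
table1_mean_flows <- function() {
  c(RSA = 9.8, LSA = 9.8, CT = 20.7, SMA = 14.0, RRA = 14.0, LRA = 14.0,
    AbAo = 30.5)
}

#' @rdname table1_mean_flows
#' @export
prescribed_mean_flows <- function() c(RCC = 12.7, LCC = 8.9)

#' Specification of the synthetic aortic inflow
#'
#' Emulates a PC-MRI aortic-root flow curve: a half-sine systolic
#' ejection, a small sinusoidal early-diastolic backflow lobe, and zero
#' flow for the rest of diastole. The cycle integral is renormalized to
#' the stroke volume exactly.
#'
#' @param SV stroke volume (ml), default 107.6.
#' @param HR heart rate (bpm), default 75.
#' @param systolic_fraction fraction of the cycle occupied by ejection,
#'   default 1/3.
#' @param reverse_fraction fraction of SV returned as early-diastolic
#'   backflow, default 0.02.
#' @param n_samples samples per cycle, default 800 (1 ms at 75 bpm).
#' @param seed integer seed recorded in the spec (generation itself is
#'   deterministic).
#' @return object of class `inflow_spec`.
#' @export
inflow_spec <- function(SV = 107.6, HR = 75, systolic_fraction = 1 / 3,
                        reverse_fraction = 0.02, n_samples = 800L,
                        seed = 1L) {
  if (SV <= 0) stop("SV must be > 0", call. = FALSE)
  if (HR <= 0) stop("HR must be > 0", call. = FALSE)
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    stop("systolic_fraction must be in (0, 1)", call. = FALSE)
  }
  if (reverse_fraction < 0 || reverse_fraction >= 0.5) {
    stop("reverse_fraction must be in [0, 0.5)", call. = FALSE)
  }
  structure(list(SV = SV, HR = HR, systolic_fraction = systolic_fraction,
                 reverse_fraction = reverse_fraction,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "inflow_spec")
}

#' Generate the synthetic aortic inflow waveform
#'
#' @param spec an [inflow_spec].
#' @return flow [waveform] (ml/s) whose cycle integral equals `SV` to
#'   machine precision.
#' @examples
#' wf <- synth_inflow(inflow_spec())
#' cycle_mean(wf)  # 107.6 * 75 / 60 = 134.5 ml/s
#' @export
synth_inflow <- function(spec = inflow_spec()) {
  stopifnot(inherits(spec, "inflow_spec"))
  Tp <- 60 / spec$HR
  m <- spec$n_samples
  t <- seq(0, Tp, length.out = m + 1L)[seq_len(m)]
  Ts <- spec$systolic_fraction * Tp
  Tr <- 0.1 * Tp                       # backflow lobe duration
  if (Ts + Tr >= Tp) stop("systolic + backflow window exceeds the cycle", call. = FALSE)
  ej <- ifelse(t < Ts, sin(pi * t / Ts), 0)
  bl <- t >= Ts & t < Ts + Tr
  bk <- numeric(m)
  bk[bl] <- -sin(pi * (t[bl] - Ts) / Tr)
  rf <- spec$reverse_fraction
  ej <- ej * (spec$SV * (1 + rf)) / (mean(ej) * Tp)
  if (rf > 0) bk <- bk * (rf * spec$SV) / (abs(mean(bk)) * Tp) else bk <- 0
  waveform(t, ej + bk, Tp)
}

#' Generate prescribed branch flow waveforms with exact cycle means
#'
#' Scaled copies of a carotid-like template (the systolic envelope with
#' strongly reduced pulsatility: continuous anterograde flow); only the
#' cycle means are contractual.
#'
#' @param means named mean flows (ml/s), `>= 0`.
#' @param HR heart rate (bpm).
#' @param n_samples samples per cycle.
#' @param pulsatility relative amplitude retained from the template
#'   (default 0.4).
#' @return named list of flow [waveform]s (ml/s).
#' @export
synth_branch_flows <- function(means = prescribed_mean_flows(), HR = 75,
                               n_samples = 800L, pulsatility = 0.4) {
  if (any(means < 0)) stop("means must be >= 0", call. = FALSE)
  tmpl <- synth_inflow(inflow_spec(HR = HR, n_samples = n_samples,
                                   reverse_fraction = 0))
  shape <- 1 + pulsatility * (tmpl$v / cycle_mean(tmpl) - 1)
  out <- lapply(means, function(mu) waveform(tmpl$t, mu * shape, tmpl$T))
  names(out) <- names(means)
  out
}

#' Default configuration of the idealized dissected-aorta fixture
#'
#' Segment dimensions are documented literature-typical adult values, not
#' patient measurements: the inlet diameter (32 mm) reproduces the
#' printed mean Reynolds (about 1408) and Womersley (about 23) numbers
#' under the default inflow and blood properties. Regional
#' distensibilities (1/Pa) drive the synthetic cine-MRI-like area
#' signals: 1.18e-5 ascending (11% area variation over a 70 mmHg pulse),
#' 0.42e-5 in the dissected descending region (combined TL+FL), 1.78e-5
#' abdominal.
#'
#' @param n_nodes grid nodes per segment (default 16; pressure extremes
#'   are grid-converged to about 1.5% at this resolution).
#' @param dissected logical; include the TL/FL split with the entry tear
#'   (default TRUE).
#' @param tear_area_mm2 entry-tear area (mm^2), default 18.5.
#' @param cd tear discharge coefficient, default 0.6.
#' @return object of class `fixture_config` (a list with the segment
#'   table and dissection/distensibility defaults; editable).
#' @export
fixture_config <- function(n_nodes = 16L, dissected = TRUE,
                           tear_area_mm2 = 18.5, cd = 0.6) {
  segs <- data.frame(
    name     = c("asc", "bt", "rsa", "rcc", "lcc", "lsa",
                 "tl", "fl", "ct", "sma", "rra", "lra", "pa", "pb", "abd"),
    length_m = c(0.10, 0.03, 0.03, 0.03, 0.03, 0.03,
                 0.20, 0.20, 0.03, 0.03, 0.03, 0.03, 0.03, 0.02, 0.10),
    diameter_mm = c(32, 12, 9, 7, 7, 9,
                    NA, NA, 8, 7, 6, 6, 18, 17, 16),
    area_mm2 = c(rep(NA, 6), 250, 350, rep(NA, 7)),
    stringsAsFactors = FALSE)
  segs$area_mm2 <- ifelse(is.na(segs$area_mm2),
                          pi * (segs$diameter_mm / 2)^2, segs$area_mm2)
  segs$diameter_mm <- ifelse(is.na(segs$diameter_mm),
                             2 * sqrt(segs$area_mm2 / pi), segs$diameter_mm)
  distensibility <- list(asc = 1.18e-5, tl = 0.42e-5, fl = 0.42e-5,
                         pa = 1.78e-5, pb = 1.78e-5, abd = 1.78e-5)
  structure(list(segments = segs, n_nodes = as.integer(n_nodes),
                 dissected = isTRUE(dissected),
                 tear_area_mm2 = tear_area_mm2, cd = cd,
                 distensibility = distensibility,
                 p_ext_mmHg = 76),
            class = "fixture_config")
}

#' Build the idealized dissected-aorta network geometry
#'
#' Topology: ascending aorta + arch feeding the brachiocephalic trunk
#' (splitting into RSA and RCC), LCC and LSA; descending aorta replaced
#' by parallel true/false lumina with one proximal entry tear and a
#' closed FL distal end; visceral branches (CT, SMA, RRA, LRA) off the
#' paravisceral aorta; abdominal aortic outlet (AbAo). Terminals are
#' {RSA, LSA, CT, SMA, RRA, LRA, AbAo}; prescribed-flow boundaries are
#' {inlet, RCC, LCC}.
#'
#' Segment area compliances are initialized from the configured regional
#' distensibilities (`C_A = D * A0`; branch vessels from the diameter-PWV
#' law); the tuning pipeline re-estimates them from synthetic area data.
#'
#' @param cfg a [fixture_config].
#' @return a [network_geometry] with `meta` carrying the distensibility
#'   defaults, per-segment diameters and prescribed branch means.
#' @export
idealized_dissected_aorta <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  st <- cfg$segments
  if (!cfg$dissected) {
    # merge the two lumina into a single descending segment
    keep <- st$name != "fl"
    st <- st[keep, , drop = FALSE]
    st$area_mm2[st$name == "tl"] <- 250 + 350
    st$diameter_mm[st$name == "tl"] <- 2 * sqrt(st$area_mm2[st$name == "tl"] / pi)
  }
  p_ext <- cfg$p_ext_mmHg * MMHG_TO_PA
  rho <- 1056
  segments <- list()
  for (i in seq_len(nrow(st))) {
    nm <- st$name[i]
    A0 <- st$area_mm2[i] * 1e-6
    D <- cfg$distensibility[[nm]]
    if (is.null(D)) {
      D <- distensibility_from_pwv(pwv_from_diameter(st$diameter_mm[i]), rho)
    }
    C_A <- D * A0
    if (cfg$dissected && nm %in% c("tl", "fl")) {
      # external-wall compliance of the dissected region split by area
      A_tot <- sum(st$area_mm2[st$name %in% c("tl", "fl")]) * 1e-6
      C_A <- cfg$distensibility[[nm]] * A_tot * (A0 / A_tot)
    }
    segments[[nm]] <- vessel_segment(nm, st$length_m[i], cfg$n_nodes,
                                     A0 = A0, C_A = C_A, p_ext = p_ext)
  }
  e <- function(seg, end) list(seg = seg, end = end)
  junctions <- list(
    list(e("asc", "distal"), e("bt", "proximal"), e("lcc", "proximal"),
         e("lsa", "proximal"), e("tl", "proximal")),
    list(e("bt", "distal"), e("rsa", "proximal"), e("rcc", "proximal")),
    list(e("tl", "distal"), e("ct", "proximal"), e("pa", "proximal")),
    list(e("pa", "distal"), e("sma", "proximal"), e("pb", "proximal")),
    list(e("pb", "distal"), e("rra", "proximal"), e("lra", "proximal"),
         e("abd", "proximal")))
  boundaries <- list(
    inlet = list(seg = "asc", end = "proximal", type = "q_in"),
    RCC = list(seg = "rcc", end = "distal", type = "q_out"),
    LCC = list(seg = "lcc", end = "distal", type = "q_out"),
    RSA = list(seg = "rsa", end = "distal", type = "wk3"),
    LSA = list(seg = "lsa", end = "distal", type = "wk3"),
    CT = list(seg = "ct", end = "distal", type = "wk3"),
    SMA = list(seg = "sma", end = "distal", type = "wk3"),
    RRA = list(seg = "rra", end = "distal", type = "wk3"),
    LRA = list(seg = "lra", end = "distal", type = "wk3"),
    AbAo = list(seg = "abd", end = "distal", type = "wk3"))
  dissection <- NULL
  if (cfg$dissected) {
    boundaries$fl_distal <- list(seg = "fl", end = "distal", type = "closed")
    dissection <- list(tl = "tl", fl = "fl",
                       tear = tear_orifice(cfg$tear_area_mm2 * 1e-6, cfg$cd),
                       tear_pos = 0.01)
  }
  meta <- list(distensibility = cfg$distensibility,
               diameter_mm = stats::setNames(as.list(st$diameter_mm), st$name),
               prescribed_means = prescribed_mean_flows(),
               config = cfg)
  network_geometry(segments, junctions, boundaries, dissection, meta)
}

#' Synthesize a cine-MRI-like lumen area waveform from a pressure wave
#'
#' Linear distension law `A(t) = A0 (1 + D (P(t) - min P))`, optionally
#' corrupted by seeded multiplicative Gaussian noise. Noise-free
#' generation followed by [estimate_distensibility] recovers `D`.
#'
#' @param P pressure [waveform] (Pa).
#' @param D distensibility (1/Pa), `>= 0`.
#' @param A0 reference (diastolic) area (m^2).
#' @param noise_sd relative noise standard deviation, `>= 0`.
#' @param seed integer seed for the noise (deterministic given the seed).
#' @return area [waveform] (m^2).
#' @export
synth_area_waveform <- function(P, D, A0, noise_sd = 0, seed = 1L) {
  stopifnot(is_waveform(P))
  if (D < 0) stop("D must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  A <- A0 * (1 + D * (P$v - min(P$v)))
  if (noise_sd > 0) {
    eps <- withr_rng(seed, stats::rnorm(length(A), 0, noise_sd))
    A <- A * (1 + eps)
  }
  waveform(P$t, A, P$T)
}

# evaluate expr under a local, restored RNG state
withr_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
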