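#' Read / write waveform CSV files
#'
#' CSV with a required header `time_s,value` and strictly increasing
#' uniform times. Round-trips are exact to better than 1e-12 relative
#' (values are written with full double precision, locale-independent).
#'
#' @param path file path.
#' @param period optional period (s); inferred as last time + spacing.
#' @return [waveform] for the reader; invisible `path` for the writer.
#' @export
read_waveform_csv <- function(path, period = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("waveform CSV needs a header and >= 2 rows", call. = FALSE)
  hdr <- tolower(gsub("\\s", "", lines[1L]))
  if (hdr != "time_s,value") {
    stop("expected header 'time_s,value', found: ", lines[1L], call. = FALSE)
  }
  body <- lines[-1L]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("ragged row at line %d: '%s'", bad[1L] + 1L, body[bad[1L]]),
         call. = FALSE)
  }
  t <- as.numeric(vapply(parts, `[[`, "", 1L))
  v <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(t) || anyNA(v)) {
    ln <- which(is.na(t) | is.na(v))[1L]
    stop(sprintf("unparseable number at line %d: '%s'", ln + 1L, body[ln]),
         call. = FALSE)
  }
  nonmono <- which(diff(t) <= 0)
  if (length(nonmono)) {
    stop(sprintf("non-monotone time at line %d", nonmono[1L] + 2L), call. = FALSE)
  }
  waveform(t, v, period)
}

#' @rdname read_waveform_csv
#' @param wf a [waveform] to write.
#' @export
write_waveform_csv <- function(wf, path) {
  stopifnot(is_waveform(wf))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("time_s,value", con)
  writeLines(paste(format_dbl(wf$t), format_dbl(wf$v), sep = ","), con)
  invisible(path)
}

format_dbl <- function(x) sprintf("%.17g", x)

#' Write / read a network geometry as YAML
#'
#' Serializes segments (length, nodes, `A0`/`C_A` profiles, external
#' pressure), junctions, boundaries (with any attached WK3 parameters),
#' the dissection block and fixture metadata. `read_geometry_yaml`
#' reconstructs an identical [network_geometry].
#'
#' @param geom a [network_geometry].
#' @param path file path.
#' @export
write_geometry_yaml <- function(geom, path) {
  stopifnot(inherits(geom, "network_geometry"))
  segs <- lapply(geom$segments, function(s) {
    list(name = s$name, length_m = s$length, nodes = s$n,
         A0_profile = as.list(s$A0), CA_profile = as.list(s$C_A),
         p_ext_mmHg = s$p_ext / MMHG_TO_PA)
  })
  bnds <- lapply(geom$boundaries, function(b) {
    out <- list(seg = b$seg, end = b$end, type = b$type)
    if (!is.null(b$params)) {
      out$wk3 <- list(R1 = b$params$R1, R2 = b$params$R2, C = b$params$C)
    }
    out
  })
  dis <- NULL
  if (!is.null(geom$dissection)) {
    dis <- list(tl = geom$dissection$tl, fl = geom$dissection$fl,
                tear_area_mm2 = geom$dissection$tear$A_tear * 1e6,
                cd = geom$dissection$tear$Cd,
                tear_pos_m = geom$dissection$tear_pos %||% 0.01)
  }
  meta <- geom$meta
  meta$config <- NULL  # non-scalar S3 config is rebuilt from defaults
  if (!is.null(meta$prescribed_means)) {
    meta$prescribed_means <- as.list(meta$prescribed_means)  # keep names in YAML
  }
  yaml::write_yaml(list(segments = unname(segs),
                        junctions = geom$junctions,
                        boundaries = bnds,
                        dissection = dis,
                        meta = meta),
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_geometry_yaml
#' @return a [network_geometry].
#' @export
read_geometry_yaml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  for (req in c("segments", "junctions", "boundaries")) {
    if (is.null(doc[[req]])) stop("geometry YAML missing field: ", req, call. = FALSE)
  }
  segments <- list()
  for (s in doc$segments) {
    for (req in c("name", "length_m", "nodes", "A0_profile", "CA_profile")) {
      if (is.null(s[[req]])) {
        stop(sprintf("segment '%s': missing field %s", s$name %||% "?", req),
             call. = FALSE)
      }
    }
    segments[[s$name]] <- vessel_segment(
      s$name, s$length_m, s$nodes,
      A0 = unlist(s$A0_profile), C_A = unlist(s$CA_profile),
      p_ext = (s$p_ext_mmHg %||% 76) * MMHG_TO_PA)
  }
  boundaries <- lapply(doc$boundaries, function(b) {
    out <- list(seg = b$seg, end = b$end, type = b$type)
    if (!is.null(b$wk3)) out$params <- wk3_params(b$wk3$R1, b$wk3$R2, b$wk3$C)
    out
  })
  dis <- NULL
  if (!is.null(doc$dissection)) {
    dis <- list(tl = doc$dissection$tl, fl = doc$dissection$fl,
                tear = tear_orifice(doc$dissection$tear_area_mm2 * 1e-6,
                                    doc$dissection$cd),
                tear_pos = doc$dissection$tear_pos_m)
  }
  meta <- doc$meta %||% list()
  if (!is.null(meta$prescribed_means)) {
    meta$prescribed_means <- unlist(meta$prescribed_means)
  }
  network_geometry(segments, doc$junctions, boundaries, dis, meta)
}

#' Read tuning targets from YAML
#'
#' Schema: `P_sys_mmHg`, `P_dia_mmHg`, `mean_flows_ml_s` (map outlet ->
#' value), optional `r1_fraction`.
#'
#' @param path file path.
#' @return a [tuning_targets].
#' @export
read_targets_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  tuning_targets(P_sys = doc$P_sys_mmHg, P_dia = doc$P_dia_mmHg,
                 mean_flows = unlist(doc$mean_flows_ml_s),
                 r1_fraction = doc$r1_fraction %||% 0.056)
}

#' @rdname read_targets_yaml
#' @param targets a [tuning_targets] to write.
#' @export
write_targets_yaml <- function(targets, path) {
  stopifnot(inherits(targets, "tuning_targets"))
  yaml::write_yaml(list(P_sys_mmHg = targets$P_sys, P_dia_mmHg = targets$P_dia,
                        mean_flows_ml_s = as.list(targets$mean_flows),
                        r1_fraction = targets$r1_fraction),
                   path, precision = 15)
  invisible(path)
}

#' Validate and normalize a run configuration
#'
#' Fills defaults (dt 1 ms, 8 cycles, CFL 0.9, seed 1), converts
#' pressures to internal units through the single conversion constant,
#' checks that referenced files exist, and aggregates all problems into
#' one error. Unknown keys are rejected.
#'
#' @param config a named list (or path to a YAML file) with any of:
#'   `geometry`, `inflow`, `targets` (file paths; omitted entries fall
#'   back to built-in fixtures), `dt`, `cycles`, `rigid`, `cfl`, `seed`,
#'   `out_dir`, `verbose`.
#' @return validated config (class `run_config`) with an `applied_defaults`
#'   attribute listing every filled default.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("geometry", "inflow", "targets", "dt", "cycles", "rigid",
             "cfl", "seed", "out_dir", "verbose")
  errs <- character(0)
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    errs <- c(errs, paste("unknown key(s):", paste(unknown, collapse = ", ")))
  }
  defaults <- list(dt = 1e-3, cycles = 8L, rigid = FALSE, cfl = 0.9,
                   seed = 1L, out_dir = "pulsead_out", verbose = FALSE)
  applied <- character(0)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
      applied <- c(applied, sprintf("%s = %s", k, format(defaults[[k]])))
    }
  }
  if (!is.numeric(config$dt) || config$dt <= 0) errs <- c(errs, "dt must be > 0")
  if (!is.numeric(config$cfl) || config$cfl <= 0 || config$cfl > 1) {
    errs <- c(errs, "cfl must be in (0, 1]")
  }
  for (k in c("geometry", "inflow", "targets")) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]])) {
      errs <- c(errs, sprintf("%s file not found: %s", k, config[[k]]))
    }
  }
  if (isTRUE(config$rigid) && !is.null(config$geometry)) {
    # informative only; compliance profiles in the file are ignored when rigid
  }
  if (length(errs)) {
    stop(paste0("invalid configuration:\n  - ",
                paste(errs, collapse = "\n  - ")), call. = FALSE)
  }
  structure(config, class = "run_config", applied_defaults = applied)
}

#' Run the end-to-end pipeline and write all artifacts
#'
#' Fixture (or file-based) inputs -> 4-step tuning -> compliant (and
#' optionally rigid) simulation -> clinical indices. Writes
#' `report.json` (tuning report), per-probe result CSVs, `indices.json`
#' and an append-only `run.log` into the output directory. Deterministic
#' given the seed.
#'
#' @param config a validated [validate_config] list (or raw list / YAML
#'   path, validated on entry).
#' @return (invisibly) list with the tuning report, index report and
#'   output paths.
#' @export
run_all <- function(config = list()) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  logline <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(...)),
        file = logf, append = TRUE)
  }
  logline("run_all start; seed=%d dt=%g cycles=%d rigid=%s", config$seed,
          config$dt, config$cycles, config$rigid)
  logline("resolved config: %s", jsonlite::toJSON(unclass(config), auto_unbox = TRUE))
  set.seed(config$seed)

  geom <- if (!is.null(config$geometry)) read_geometry_yaml(config$geometry) else
    idealized_dissected_aorta(fixture_config())
  inflow <- if (!is.null(config$inflow)) read_waveform_csv(config$inflow) else
    synth_inflow(inflow_spec(seed = config$seed))
  targets <- if (!is.null(config$targets)) read_targets_yaml(config$targets) else
    tuning_targets()

  stage <- "tune"
  result <- tryCatch({
    rep <- tune_pipeline(geom, inflow, targets, rigid_only = config$rigid,
                         simulate = !config$rigid, dt = config$dt,
                         n_cycles = config$cycles)
    stage <- "indices"
    idx <- NULL
    if (!config$rigid) {
      idx <- index_report(rep$simulation, pwv_segment = "asc")
    }
    list(report = rep, indices = idx)
  }, error = function(e) {
    logline("FAILED at stage %s: %s", stage, conditionMessage(e))
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  report_path <- file.path(config$out_dir, "report.json")
  write_tuning_report_json(result$report, report_path)
  logline("wrote %s", report_path)

  idx_path <- NULL
  if (!is.null(result$indices)) {
    idx_path <- file.path(config$out_dir, "indices.json")
    write_index_report_json(result$indices, idx_path)
    logline("wrote %s", idx_path)
    sim <- result$report$simulation
    for (s in names(sim$segments)) {
      pr <- result_probe(sim, s, 0.5)
      df <- data.frame(time_s = pr$P$t, P_Pa = pr$P$v, Q_m3_s = pr$Q$v,
                       A_m2 = pr$A$v, tau_w_Pa = pr$tau_w$v)
      utils::write.csv(df, file.path(config$out_dir, paste0("probe_", s, ".csv")),
                       row.names = FALSE)
    }
    logline("wrote %d probe CSVs", length(sim$segments))
  }
  logline("run_all done")
  invisible(list(report = result$report, indices = result$indices,
                 paths = list(report = report_path, indices = idx_path,
                              log = logf)))
}

#' Serialize a tuning report to JSON (units in field names)
#'
#' @param rep a `tuning_report` from [tune_pipeline].
#' @param path output file.
#' @export
write_tuning_report_json <- function(rep, path) {
  stopifnot(inherits(rep, "tuning_report"))
  outlets <- names(rep$params %||% rep$step2$params)
  per_outlet <- lapply(outlets, function(o) {
    p <- (rep$params %||% rep$step2$params)[[o]]
    out <- list(R1_mmHg_s_ml = p$R1, R2_mmHg_s_ml = p$R2, C_ml_mmHg = p$C,
                Q_target_ml_s = unname(rep$targets$mean_flows[o]))
    if (!is.null(rep$achieved)) out$Q_achieved_ml_s <- unname(rep$achieved[o])
    if (!is.null(rep$step2$P_mean)) out$P_mean_mmHg <- unname(rep$step2$P_mean[o])
    out
  })
  names(per_outlet) <- outlets
  doc <- list(
    outlets = per_outlet,
    step1 = list(C_sys_ml_mmHg = rep$step1$C_sys,
                 R_tot_mmHg_s_ml = rep$step1$R_tot,
                 P_sys_mmHg = rep$step1$P_sys, P_dia_mmHg = rep$step1$P_dia,
                 iterations = rep$step1$iterations),
    convergence = list(step2_iterations = rep$step2$iterations,
                       step2_residual = rep$step2$residual))
  if (!is.null(rep$budget)) {
    doc$budget <- list(C_sys_ml_mmHg = rep$budget$C_sys,
                       C_aorta_ml_mmHg = rep$budget$C_aorta,
                       C_per_ml_mmHg = rep$budget$C_per)
  }
  if (!is.null(rep$max_deviation_pct)) {
    doc$achieved_vs_target <- list(
      max_relative_deviation_pct = rep$max_deviation_pct,
      P_sys_mmHg = unname(rep$achieved["P_sys"]),
      P_dia_mmHg = unname(rep$achieved["P_dia"]))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialize an index report to JSON (units in field names)
#'
#' @param idx an `index_report`.
#' @param path output file.
#' @export
write_index_report_json <- function(idx, path) {
  stopifnot(inherits(idx, "index_report"))
  doc <- list(PWV_m_s = idx$PWV,
              probes = lapply(idx$probes, function(p) {
                list(peak_dA_pct = p$peak_dA_pct, TAWSS_Pa = p$TAWSS,
                     OSI = p$OSI)
              }))
  if (!is.null(idx$TMP)) {
    doc$TMP_mmHg <- list(max = attr(idx$TMP, "max"), min = attr(idx$TMP, "min"),
                         zero_crossings = attr(idx$TMP, "zero_crossings"))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
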