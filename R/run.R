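#' Run the full offline measurement workflow
#'
#' Executes, as configured: marker-disc tracking over a frame sequence,
#' speckle displacement between a before/after pair, gauge calibration,
#' instant rigidity over a load-step table and, when a treated-specimen
#' table is also given, normalization against the intact one. Each stage
#' is isolated: a failing stage is recorded in the report and later,
#' independent stages still run. Outputs (CSV/JSON plus a structured log)
#' are written to `out_dir` and every file records the configuration hash.
#'
#' @param config validated configuration (see [load_config()] /
#'   [validate_config()]).
#' @param out_dir report directory, created if needed.
#' @return invisibly, the report list (also written as `report.json`).
#' @export
run_full <- function(config, out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, level, msg) {
    cat(sprintf("%s [%s] %s: %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                level, stage, msg), file = log_path, append = TRUE)
  }
  save_config(cfg, file.path(out_dir, "config.json"))
  report <- list(config_hash = hash, seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("spinetrack")),
                 stages = list())
  stage <- function(name, depends_ok = TRUE, f) {
    if (!depends_ok) {
      report$stages[[name]] <<- list(status = "skipped")
      logf(name, "INFO", "skipped (unmet dependency or not configured)")
      return(NULL)
    }
    logf(name, "INFO", "started")
    r <- tryCatch(list(status = "ok", value = f()),
                  error = function(e) list(status = "error",
                                           message = conditionMessage(e)))
    report$stages[[name]] <<- r[setdiff(names(r), "value")]
    if (r$status == "ok") logf(name, "INFO", "finished")
    else logf(name, "ERROR", r$message)
    if (r$status == "ok") r$value else NULL
  }

  pl <- cfg$pipeline
  dcfg <- disc_config(
    threshold_min = pl$threshold_min,
    threshold_max = if (is.null(pl$threshold_max)) Inf else pl$threshold_max,
    threshold_rel = pl$threshold_rel, se_radius = pl$se_radius,
    min_pixels = pl$min_pixels, max_jump_px = pl$max_jump_px,
    smooth_sigma = pl$smooth_sigma)

  tracks <- stage("tracking", !is.null(cfg$paths$frames), function() {
    files <- sort(Sys.glob(cfg$paths$frames))
    dets <- lapply(files, function(f) detect_discs(read_gray_image(f), dcfg))
    tr <- assemble_tracks(dets, max_jump = pl$max_jump_px)
    out <- data.frame(frame = tr$frame, disc_id = tr$disc_id,
                      x_px = tr$x, y_px = tr$y, pixel_count = tr$pixel_count)
    write_report_csv(out, file.path(out_dir, "tracks.csv"), hash)
    out
  })

  stage("displacement",
        !is.null(cfg$paths$speckle_before) && !is.null(cfg$paths$speckle_after),
        function() {
    d <- measure_displacement(read_gray_image(cfg$paths$speckle_before),
                              read_gray_image(cfg$paths$speckle_after),
                              window = pl$fft_window, mm_per_px = pl$mm_per_px,
                              eps = pl$fringe_eps)
    write_report_json(list(magnitude_px = d$magnitude_px,
                           magnitude_mm = d$magnitude_mm,
                           direction_deg = d$direction_deg,
                           contrast = d$contrast,
                           sign_resolved = d$sign_resolved),
                      file.path(out_dir, "displacement.json"), hash)
    d
  })

  fit <- stage("calibration", !is.null(cfg$paths$calibration_csv), function() {
    tab <- utils::read.csv(cfg$paths$calibration_csv)
    fit <- fit_linear(tab)
    write_report_json(list(a = fit$a, b = fit$b, r_squared = fit$r_squared,
                           residual_sd = fit$residual_sd, n = fit$n),
                      file.path(out_dir, "calibration_fit.json"), hash)
    fit
  })

  arms <- c(bending = cfg$geometry$arm_bending_m %||% NA_real_,
            torsion = cfg$geometry$arm_torsion_m %||% NA_real_)
  read_steps <- function(path) {
    tab <- utils::read.csv(path)
    if (is.null(tab$force_N) || cfg$protocol$n_avg > 1L)
      tab <- aggregate_steps(tab, n_avg = cfg$protocol$n_avg, fit = fit)
    tab
  }
  rigid <- stage("rigidity", !is.null(cfg$paths$steps_csv), function() {
    res <- run_protocol(read_steps(cfg$paths$steps_csv), arms = arms,
                        variant = cfg$protocol$variant,
                        warmup_hz = cfg$protocol$warmup_hz)
    write_report_csv(as.data.frame(res), file.path(out_dir, "rigidity.csv"), hash)
    res
  })

  stage("normalization",
        !is.null(cfg$paths$steps_treated_csv) && !is.null(rigid),
        function() {
    treated <- run_protocol(read_steps(cfg$paths$steps_treated_csv),
                            arms = arms, variant = cfg$protocol$variant)
    norm <- normalize_to_intact(rigid, treated)
    write_report_csv(norm, file.path(out_dir, "normalized.csv"), hash)
    norm
  })

  report$n_tracks <- if (!is.null(tracks)) length(unique(tracks$disc_id)) else NULL
  write_report_json(report, file.path(out_dir, "report.json"), hash)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

write_report_json <- function(x, path, hash) {
  x$config_hash <- hash
  jsonlite::write_json(sort_keys(x), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
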