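#' Default run configuration
#'
#' Nested list mirroring the JSON run configuration: input paths, pipeline
#' parameters, geometry (lever arms) and protocol metadata. All
#' randomness in the toolkit flows from the config-declared seed; there is
#' no wall-clock seeding.
#'
#' @return list with sections `paths`, `pipeline`, `geometry`, `protocol`
#'   and a top-level `seed`.
#' @export
default_config <- function() {
  list(
    paths = list(frames = NULL, calibration_csv = NULL, steps_csv = NULL,
                 steps_treated_csv = NULL, speckle_before = NULL,
                 speckle_after = NULL),
    pipeline = list(threshold_min = NULL, threshold_max = NULL,
                    threshold_rel = 0.35, se_radius = 1L, min_pixels = 20L,
                    max_jump_px = 15, smooth_sigma = 1, fft_window = "hann",
                    mm_per_px = NULL, fringe_eps = 0.06),
    geometry = list(arm_bending_m = NULL, arm_torsion_m = NULL),
    protocol = list(repeats = 10L, n_avg = 1L, warmup_hz = 0.1,
                    variant = "shift"),
    seed = 1L
  )
}

#' Load and validate a JSON run configuration
#'
#' Reads the file, rejects unknown keys (naming the offending field path),
#' fills defaults, checks numeric ranges and verifies that every referenced
#' input path exists.
#'
#' @param path JSON configuration file.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_config(raw, base_dir = dirname(path))
}

#' @rdname load_config
#' @param config configuration list to validate (as from [default_config()]).
#' @param base_dir directory against which relative paths are resolved.
#' @export
validate_config <- function(config, base_dir = ".") {
  def <- default_config()
  cfg <- merge_known(config, def, prefix = character(0))
  p <- cfg$pipeline
  check_range <- function(val, name, lo, hi = Inf) {
    if (!is.null(val) && (!is.numeric(val) || val < lo || val > hi))
      stop("config error at pipeline.", name, ": must be in [", lo, ", ", hi, "]")
  }
  check_range(p$threshold_rel, "threshold_rel", 1e-6, 1)
  check_range(p$se_radius, "se_radius", 0, 25)
  check_range(p$min_pixels, "min_pixels", 1)
  check_range(p$max_jump_px, "max_jump_px", 1e-6)
  check_range(p$smooth_sigma, "smooth_sigma", 0, 10)
  check_range(p$mm_per_px, "mm_per_px", 1e-9)
  check_range(p$fringe_eps, "fringe_eps", 0, 1)
  if (!p$fft_window %in% c("hann", "none"))
    stop("config error at pipeline.fft_window: must be 'hann' or 'none'")
  if (!cfg$protocol$variant %in% c("shift", "angle"))
    stop("config error at protocol.variant: must be 'shift' or 'angle'")
  if (!is.null(cfg$geometry$arm_bending_m) && cfg$geometry$arm_bending_m <= 0)
    stop("config error at geometry.arm_bending_m: must be positive")
  if (!is.null(cfg$geometry$arm_torsion_m) && cfg$geometry$arm_torsion_m <= 0)
    stop("config error at geometry.arm_torsion_m: must be positive")
  cfg$seed <- as.integer(cfg$seed)
  for (key in c("calibration_csv", "steps_csv", "steps_treated_csv",
                "speckle_before", "speckle_after")) {
    pth <- cfg$paths[[key]]
    if (!is.null(pth)) {
      full <- resolve_path(pth, base_dir)
      if (!file.exists(full))
        stop("config error at paths.", key, ": file not found: ", pth)
      cfg$paths[[key]] <- full
    }
  }
  if (!is.null(cfg$paths$frames)) {
    g <- resolve_path(cfg$paths$frames, base_dir)
    if (length(Sys.glob(g)) == 0L)
      stop("config error at paths.frames: glob matches no files: ",
           cfg$paths$frames)
    cfg$paths$frames <- g
  }
  cfg
}

resolve_path <- function(p, base_dir) {
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
}

# Overlay user values onto defaults, rejecting unknown keys recursively.
merge_known <- function(user, def, prefix) {
  if (is.null(user)) return(def)
  unknown <- setdiff(names(user), names(def))
  if (length(unknown) > 0)
    stop("config error: unknown key '",
         paste(c(prefix, unknown[1L]), collapse = "."), "'")
  out <- def
  for (k in names(user)) {
    if (is.list(def[[k]])) {
      if (!is.list(user[[k]]) && !is.null(user[[k]]))
        stop("config error: '", paste(c(prefix, k), collapse = "."),
             "' must be an object")
      out[[k]] <- merge_known(user[[k]], def[[k]], c(prefix, k))
    } else if (!is.null(user[[k]])) {
      out[[k]] <- user[[k]]
    }
  }
  out
}

#' Save a configuration as canonical JSON
#'
#' Pretty-printed with sorted keys so that saved configurations diff
#' cleanly; `save_config()` followed by [load_config()] round-trips.
#'
#' @param config configuration list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(sort_keys(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x) > 0)
    lapply(x[order(names(x))], sort_keys)
  else x
}

#' Hash of a configuration
#'
#' MD5 of the canonical (sorted-key) JSON rendering; stamped into every
#' output file of a run so results can be traced to the configuration
#' that produced them.
#'
#' @param config configuration list.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(sort_keys(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}
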