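#' Loading modes of the rig
#'
#' The seven loading modes exercised by the spine tester: sagittal flexion
#' and extension, left/right lateral bending, left/right axial torsion and
#' axial compression. Bending and torsion modes act through a lever arm;
#' compression does not.
#'
#' @return character vector of mode names.
#' @export
loading_modes <- function() {
  c("flexion", "extension", "lateral_left", "lateral_right",
    "torsion_left", "torsion_right", "compression")
}

mode_family <- function(mode) {
  switch(mode,
    compression = "compression",
    torsion_left = , torsion_right = "torsion",
    flexion = , extension = , lateral_left = , lateral_right = "bending",
    stop("unknown loading mode: ", mode))
}

#' Instant rigidity of one load step
#'
#' Instant (immediate) rigidity is the ratio of the applied load to the
#' resulting deformation at a single load step. For axial compression it
#' is force over length change, `F / dl` in N/mm. For torsion the torque
#' `F r` is divided either by the rotation angle (`F r / phi`, Nm/rad) or,
#' in the simplified shift form used with camera-measured motion, by the
#' shift `d` of the constant arm (`F r / d`, Nm/mm). Bending
#' (flexion/extension/lateral) uses the same two forms with arm `l` and
#' angle `alpha`.
#'
#' All functions are vectorized over their numeric arguments. Forces are
#' in Newton, displacements in millimetres, angles in radians and arms in
#' metres, giving the printed units N/mm, Nm/rad and Nm/mm.
#'
#' @param force_N applied force, N.
#' @param displacement_mm measured length change or arm shift, mm.
#' @param angle_rad measured rotation/bend angle, rad (angle variant).
#' @param arm_m lever arm, m (> 0).
#' @param variant `"angle"` or `"shift"`.
#' @return numeric rigidity values (N/mm, Nm/rad or Nm/mm).
#' @export
#' @examples
#' rigidity_compression(100, 2)          # 50 N/mm
#' rigidity_torsion(10, 0.2, angle_rad = 0.1, variant = "angle")  # 20 Nm/rad
rigidity_compression <- function(force_N, displacement_mm) {
  if (any(displacement_mm == 0))
    stop("undefined rigidity: zero displacement")
  force_N / displacement_mm
}

#' @rdname rigidity_compression
#' @export
rigidity_torsion <- function(force_N, arm_m, angle_rad = NULL,
                             displacement_mm = NULL,
                             variant = c("shift", "angle")) {
  moment_rigidity(force_N, arm_m, angle_rad, displacement_mm,
                  match.arg(variant))
}

#' @rdname rigidity_compression
#' @export
rigidity_bending <- function(force_N, arm_m, angle_rad = NULL,
                             displacement_mm = NULL,
                             variant = c("shift", "angle")) {
  moment_rigidity(force_N, arm_m, angle_rad, displacement_mm,
                  match.arg(variant))
}

moment_rigidity <- function(force_N, arm_m, angle_rad, displacement_mm,
                            variant) {
  if (any(!is.finite(arm_m)) || any(arm_m <= 0))
    stop("lever arm must be positive")
  den <- if (variant == "angle") angle_rad else displacement_mm
  if (is.null(den) || all(is.na(den)))
    stop("missing ", if (variant == "angle") "angle_rad" else "displacement_mm",
         " for variant '", variant, "'")
  if (any(den == 0, na.rm = TRUE)) stop("undefined rigidity: zero denominator")
  force_N * arm_m / den
}

#' Average repeated gauge readings into load steps
#'
#' The rig's stepwise protocol takes several strain-gauge readings at each
#' load step and averages them to suppress noise; the number of averaged
#' readings is adjustable. Voltages are converted to force through a
#' calibration fit before averaging when one is supplied.
#'
#' @param readings data.frame with one row per reading: columns `mode`,
#'   `step`, optionally `rep` (default 1), `force_N` or `voltage`, and
#'   optionally `displacement_mm`, `angle_rad`, `arm_m`.
#' @param n_avg number of readings averaged per step (>= 1); every step
#'   must supply at least `n_avg` readings, and the first `n_avg` are used.
#' @param fit optional `gauge_cal` used to convert `voltage` to `force_N`.
#' @return data.frame of aggregated load steps with one row per
#'   (`mode`, `rep`, `step`) and a `n_readings_averaged` column.
#' @export
aggregate_steps <- function(readings, n_avg = 1L, fit = NULL) {
  stopifnot(is.data.frame(readings), n_avg >= 1L)
  r <- readings
  if (is.null(r$rep)) r$rep <- 1L
  if (is.null(r$force_N)) {
    if (is.null(r$voltage) || is.null(fit))
      stop("readings need 'force_N', or 'voltage' plus a calibration fit")
    r$force_N <- apply_calibration(fit, r$voltage)
  }
  key <- interaction(r$mode, r$rep, r$step, drop = TRUE)
  pieces <- lapply(split(r, key), function(g) {
    if (nrow(g) < n_avg)
      stop("step with fewer than n_avg = ", n_avg, " readings")
    g <- g[seq_len(n_avg), , drop = FALSE]
    data.frame(mode = g$mode[1L], rep = g$rep[1L], step = g$step[1L],
               force_N = mean(g$force_N),
               displacement_mm = mean_or_na(g$displacement_mm),
               angle_rad = mean_or_na(g$angle_rad),
               arm_m = mean_or_na(g$arm_m),
               n_readings_averaged = n_avg)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$mode, out$rep, out$step), , drop = FALSE]
  rownames(out) <- NULL
  out
}

mean_or_na <- function(x) if (is.null(x) || all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)

#' Run the instant-rigidity protocol over a load-step table
#'
#' Computes the per-step instant rigidity for every loading mode present
#' in `steps` and summarizes each mode as mean and sample SD over the
#' per-repeat means (the protocol repeats the whole measurement sequence;
#' ten repeats on the rig). Modes requested via `expect_modes` but absent
#' from the data are reported with a message and omitted from the result.
#'
#' @param steps load-step data.frame (see [aggregate_steps()] /
#'   [simulate_load_steps()]): columns `mode`, `rep`, `step`, `force_N`,
#'   `displacement_mm` and/or `angle_rad`, optionally `arm_m`.
#' @param arms named numeric vector supplying lever arms in metres,
#'   names `bending` and `torsion`; used where `steps$arm_m` is missing.
#'   The rig's arm lengths are laboratory configuration with no default.
#' @param variant `"shift"` (denominator is the arm shift, mm) or
#'   `"angle"` (denominator is the angle, rad). Compression always uses
#'   force over length change.
#' @param expect_modes optional character vector of modes that should be
#'   present.
#' @param warmup_hz,warmup_cycles warm-up metadata recorded with the
#'   result (the warm-up motion itself is hardware-side and not computed
#'   on).
#' @return named list of `rigidity_result` objects, class
#'   `rigidity_results`.
#' @export
run_protocol <- function(steps, arms = NULL, variant = c("shift", "angle"),
                         expect_modes = NULL, warmup_hz = 0.1,
                         warmup_cycles = NA_integer_) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(steps), nrow(steps) >= 1L)
  if (is.null(steps$rep)) steps$rep <- 1L
  modes <- unique(as.character(steps$mode))
  bad <- setdiff(modes, loading_modes())
  if (length(bad) > 0) stop("unknown loading mode(s): ", paste(bad, collapse = ", "))
  if (!is.null(expect_modes)) {
    missing_modes <- setdiff(expect_modes, modes)
    if (length(missing_modes) > 0)
      message("modes absent from input, omitted: ",
              paste(missing_modes, collapse = ", "))
  }
  res <- lapply(modes, function(m) {
    g <- steps[steps$mode == m, , drop = FALSE]
    fam <- mode_family(m)
    if (fam == "compression") {
      vals <- rigidity_compression(g$force_N, g$displacement_mm)
      units <- "N/mm"
    } else {
      arm <- g$arm_m
      if (is.null(arm) || all(is.na(arm))) {
        if (is.null(arms) || is.na(arms[fam]))
          stop("lever arm for ", fam, " modes not supplied (no default)")
        arm <- unname(arms[fam])
      }
      vals <- moment_rigidity(g$force_N, arm, g$angle_rad, g$displacement_mm,
                              variant)
      units <- if (variant == "angle") "Nm/rad" else "Nm/mm"
    }
    per_rep <- tapply(vals, g$rep, mean)
    structure(list(mode = m, variant = if (fam == "compression") NA_character_ else variant,
                   units = units,
                   values = data.frame(rep = g$rep, step = g$step, rigidity = vals),
                   per_repeat = as.numeric(per_rep),
                   mean = mean(per_rep),
                   sd = if (length(per_rep) > 1L) stats::sd(per_rep) else 0,
                   n_repeats = length(per_rep)),
              class = "rigidity_result")
  })
  names(res) <- modes
  structure(res, class = "rigidity_results",
            warmup = list(frequency_hz = warmup_hz, cycles = warmup_cycles))
}

#' @export
print.rigidity_result <- function(x, ...) {
  cat(sprintf("%-14s %8.4g +/- %.3g %s (%d repeats)\n", x$mode, x$mean, x$sd,
              x$units, x$n_repeats))
  invisible(x)
}

#' @export
print.rigidity_results <- function(x, ...) {
  cat("Instant rigidity by loading mode\n")
  for (r in x) print(r)
  invisible(x)
}

#' @export
as.data.frame.rigidity_results <- function(x, ...) {
  do.call(rbind, lapply(unname(x), function(r)
    data.frame(mode = r$mode, units = r$units, mean = r$mean, sd = r$sd,
               n_repeats = r$n_repeats)))
}

#' Normalize treated-specimen rigidity to the intact specimen
#'
#' Expresses the rigidity of a treated (e.g. implant-stabilized) specimen
#' as a percentage of the intact specimen, mode by mode; the intact
#' specimen maps to exactly 100\%.
#'
#' @param intact,treated `rigidity_result` objects of the same mode and
#'   units, or `rigidity_results` lists (common modes are compared).
#' @return for single results, a percentage; for result lists, a
#'   data.frame with columns `mode`, `units`, `intact_mean`,
#'   `treated_mean`, `percent`.
#' @export
normalize_to_intact <- function(intact, treated) {
  if (inherits(intact, "rigidity_results") && inherits(treated, "rigidity_results")) {
    common <- intersect(names(intact), names(treated))
    if (length(common) == 0L) stop("no common loading modes")
    out <- do.call(rbind, lapply(common, function(m)
      data.frame(mode = m, units = intact[[m]]$units,
                 intact_mean = intact[[m]]$mean,
                 treated_mean = treated[[m]]$mean,
                 percent = normalize_to_intact(intact[[m]], treated[[m]]))))
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(inherits(intact, "rigidity_result"), inherits(treated, "rigidity_result"))
  if (!identical(intact$mode, treated$mode) || !identical(intact$units, treated$units))
    stop("mode/unit mismatch: cannot normalize ", treated$mode, " [", treated$units,
         "] against ", intact$mode, " [", intact$units, "]")
  if (intact$mean == 0) stop("intact mean rigidity is zero")
  100 * treated$mean / intact$mean
}
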