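#' Deterministic child seed for one grid combination
#'
#' Child seeds depend only on the base seed and the wavelength, so every run
#' at one wavelength — across skin presets, cardiac phases and saturations —
#' shares its per-packet random substreams. Together with the engine's
#' per-packet stream indexing this makes every contrast in the grid a
#' common-random-number paired comparison, and adding grid points never
#' perturbs existing ones.
#'
#' @param base_seed Integer base seed.
#' @param lambda_nm Wavelength in nm.
#' @return Integer child seed.
#' @export
child_seed <- function(base_seed, lambda_nm) {
  as.integer(base_seed) + 97L * as.integer(round(lambda_nm))
}

#' Run the simulation grid for one skin preset
#'
#' Executes one transport run per (wavelength, cardiac phase, arterial
#' saturation) combination: the raw material for a calibration curve.
#'
#' @param skin Preset name (`"light"`, `"moderate"`, `"dark"`) or a
#'   [tissue_config()].
#' @param sat_grid Arterial saturations; default 0.70 to 1.00 by 0.05.
#' @param wavelengths Wavelengths in nm (default 660 and 940).
#' @param detector A [detector_spec()].
#' @param settings An [engine_settings()].
#' @param base_seed Integer base seed (see [child_seed()]).
#' @param table A [chromophore_table()].
#' @return Data frame of reflectance records: `skin_type, lambda_nm, phase,
#'   sat_a, reflectance, detected_count, launched_count, seed`.
#' @export
run_grid <- function(skin, sat_grid = seq(0.70, 1.00, by = 0.05),
                     wavelengths = c(660, 940),
                     detector = detector_spec(),
                     settings = engine_settings(detected = 1e5),
                     base_seed = 1,
                     table = chromophore_table()) {
  stopifnot(length(sat_grid) >= 1, length(wavelengths) >= 1)
  config <- if (inherits(skin, "tissue_config")) skin else tissue_config(skin)
  skin_label <- if (is.character(skin)) skin else "custom"
  combos <- expand.grid(phase = c("diastole", "systole"),
                        lambda_nm = wavelengths, sat_a = sat_grid,
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    seed <- child_seed(base_seed, cb$lambda_nm)
    stack <- build_stack(config, cb$lambda_nm,
                         physiological_state(cb$sat_a, cb$phase), table)
    res <- tryCatch(
      transport(stack, detector, settings, seed),
      error = function(e) stop("transport failed for (", skin_label, ", ",
                               cb$lambda_nm, " nm, ", cb$phase, ", SaO2 ",
                               cb$sat_a, "): ", conditionMessage(e),
                               call. = FALSE))
    data.frame(skin_type = skin_label, lambda_nm = cb$lambda_nm,
               phase = cb$phase, sat_a = cb$sat_a,
               reflectance = res$reflectance,
               detected_count = res$detected_count,
               launched_count = res$launched_count,
               seed = seed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reduce one saturation's records to a pulse-oximetry point
#'
#' From the four reflectance records of one arterial saturation (two
#' wavelengths times two cardiac phases) computes, per wavelength, the DC
#' component (diastolic reflectance), the AC component (diastolic minus
#' systolic reflectance — the pulsatile modulation), the perfusion index
#' `PI = AC / DC`, and the ratio of ratios `R = PI_660 / PI_940`.
#'
#' @param records Data frame as from [run_grid()], restricted to one `sat_a`.
#' @param dc Convention for the DC component: diastolic reflectance
#'   (`"diastole"`, default) or the mean of the two phases (`"mean"`).
#' @return One-row data frame: `sat_a, ac_660, dc_660, pi_660, ac_940,
#'   dc_940, pi_940, r`.
#' @export
reduce_point <- function(records, dc = c("diastole", "mean")) {
  dc <- match.arg(dc)
  if (length(unique(records$sat_a)) != 1) {
    stop("reduce_point expects records for exactly one saturation", call. = FALSE)
  }
  if (nrow(records) != 4) {
    stop("reduce_point expects exactly 4 records (2 wavelengths x 2 phases), got ",
         nrow(records), call. = FALSE)
  }
  one <- function(lambda) {
    dia <- records$reflectance[records$lambda_nm == lambda &
                               records$phase == "diastole"]
    sys <- records$reflectance[records$lambda_nm == lambda &
                               records$phase == "systole"]
    if (length(dia) != 1 || length(sys) != 1) {
      stop("missing phase record at ", lambda, " nm", call. = FALSE)
    }
    dc_val <- if (dc == "diastole") dia else (dia + sys) / 2
    if (dc_val <= 0) stop("degenerate signal: DC = 0 at ", lambda, " nm",
                          call. = FALSE)
    c(ac = dia - sys, dc = dc_val, pi = (dia - sys) / dc_val)
  }
  r660 <- one(660)
  r940 <- one(940)
  if (r940[["pi"]] == 0) stop("degenerate signal: PI at 940 nm is 0", call. = FALSE)
  data.frame(sat_a = records$sat_a[1],
             ac_660 = r660[["ac"]], dc_660 = r660[["dc"]], pi_660 = r660[["pi"]],
             ac_940 = r940[["ac"]], dc_940 = r940[["dc"]], pi_940 = r940[["pi"]],
             r = r660[["pi"]] / r940[["pi"]])
}

#' Ratio-of-ratios curve for one skin preset
#'
#' Runs the full simulation grid and reduces it to one (saturation, R) point
#' per grid saturation — the simulated calibration data.
#'
#' @inheritParams run_grid
#' @param dc DC convention passed to [reduce_point()].
#' @return Data frame with one row per saturation: `skin_type, sat_a,
#'   ac_660, dc_660, pi_660, ac_940, dc_940, pi_940, r`.
#' @export
ratio_curve <- function(skin, sat_grid = seq(0.70, 1.00, by = 0.05),
                        wavelengths = c(660, 940),
                        detector = detector_spec(),
                        settings = engine_settings(detected = 1e5),
                        base_seed = 1,
                        table = chromophore_table(),
                        dc = "diastole") {
  records <- run_grid(skin, sat_grid, wavelengths, detector, settings,
                      base_seed, table)
  points <- do.call(rbind, lapply(sort(unique(records$sat_a)), function(s) {
    reduce_point(records[records$sat_a == s, ], dc = dc)
  }))
  cbind(skin_type = records$skin_type[1], points, stringsAsFactors = FALSE)
}
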