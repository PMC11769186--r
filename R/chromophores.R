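#' Melanin absorption coefficient
#'
#' Closed-form power law for the absorption coefficient of a melanosome,
#' `6.6e10 * lambda^-3.33` with `lambda` in nm and the result in mm^-1.
#' Evaluated in log space for numerical stability.
#'
#' @param lambda_nm Wavelength in nanometres (vectorised, all `> 0`).
#' @return Absorption coefficient(s) in mm^-1.
#' @examples
#' melanin_mua(c(660, 940))
#' @export
melanin_mua <- function(lambda_nm) {
  stopifnot(is.numeric(lambda_nm))
  if (any(!is.finite(lambda_nm)) || any(lambda_nm <= 0)) {
    stop("wavelength must be positive and finite", call. = FALSE)
  }
  exp(log(6.6e10) - 3.33 * log(lambda_nm))
}

#' Pigment-free skin baseline absorption coefficient
#'
#' Closed-form power law `7.84e7 * lambda^-3.255` (lambda in nm, result in
#' mm^-1) for bloodless, melanin-free skin tissue.
#'
#' @inheritParams melanin_mua
#' @return Absorption coefficient(s) in mm^-1.
#' @examples
#' skin_baseline_mua(c(660, 940))
#' @export
skin_baseline_mua <- function(lambda_nm) {
  stopifnot(is.numeric(lambda_nm))
  if (any(!is.finite(lambda_nm)) || any(lambda_nm <= 0)) {
    stop("wavelength must be positive and finite", call. = FALSE)
  }
  exp(log(7.84e7) - 3.255 * log(lambda_nm))
}

#' Load a chromophore absorption table
#'
#' Reads a CSV with columns `wavelength_nm, mu_a_hbo2_mm, mu_a_hhb_mm,
#' mu_a_water_mm` giving absorption coefficients (mm^-1) of fully oxygenated
#' whole blood, fully deoxygenated whole blood, and water at each wavelength.
#' The packaged default holds literature-compiled values at the two pulse
#' oximetry operating wavelengths, 660 nm and 940 nm (whole blood at a
#' standard haemoglobin concentration of 150 g/L).
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A `chromophore_table`: data frame keyed by wavelength.
#' @examples
#' tab <- chromophore_table()
#' mua_lookup(tab, 660)
#' @export
chromophore_table <- function(path = system.file("extdata", "chromophores.csv",
                                                 package = "pulseoxmc")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("wavelength_nm", "mu_a_hbo2_mm", "mu_a_hhb_mm", "mu_a_water_mm")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("chromophore table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(as.matrix(tab[required[-1]]) < 0) || anyNA(tab[required])) {
    stop("chromophore absorption coefficients must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(tab$wavelength_nm)) {
    stop("duplicate wavelengths in chromophore table", call. = FALSE)
  }
  structure(tab[required], class = c("chromophore_table", "data.frame"))
}

#' Look up chromophore absorption coefficients at one wavelength
#'
#' Exact lookup only: an absent wavelength is an error, never silently
#' interpolated. Set `interpolate = TRUE` to allow log-linear interpolation
#' between tabulated wavelengths (for spectral sweeps).
#'
#' @param table A [chromophore_table()].
#' @param lambda_nm Single wavelength in nm.
#' @param interpolate Allow log-linear interpolation (default `FALSE`).
#' @return Named list `mu_a_hbo2`, `mu_a_hhb`, `mu_a_water` (mm^-1).
#' @export
mua_lookup <- function(table, lambda_nm, interpolate = FALSE) {
  stopifnot(inherits(table, "chromophore_table"), length(lambda_nm) == 1)
  i <- which(table$wavelength_nm == lambda_nm)
  if (length(i) == 1) {
    return(list(mu_a_hbo2 = table$mu_a_hbo2_mm[i],
                mu_a_hhb = table$mu_a_hhb_mm[i],
                mu_a_water = table$mu_a_water_mm[i]))
  }
  if (!interpolate) {
    stop("wavelength ", lambda_nm, " nm not in chromophore table ",
         "(available: ", paste(table$wavelength_nm, collapse = ", "), ")",
         call. = FALSE)
  }
  if (lambda_nm < min(table$wavelength_nm) || lambda_nm > max(table$wavelength_nm)) {
    stop("wavelength ", lambda_nm, " nm outside tabulated range", call. = FALSE)
  }
  interp1 <- function(col) {
    y <- log(pmax(table[[col]], .Machine$double.xmin))
    exp(stats::approx(log(table$wavelength_nm), y, xout = log(lambda_nm))$y)
  }
  list(mu_a_hbo2 = interp1("mu_a_hbo2_mm"),
       mu_a_hhb = interp1("mu_a_hhb_mm"),
       mu_a_water = interp1("mu_a_water_mm"))
}

#' Epidermis composition
#'
#' Volume fractions of the epidermal chromophores: melanosomes (`vmel`, the
#' pigmentation proxy) and water (`vw`). Presets for the three modelled skin
#' types set `vmel` to 0.0255 (light), 0.155 (moderate) and 0.305 (dark).
#'
#' @param vmel Melanosome volume fraction in `[0, 1]`.
#' @param vw Water volume fraction in `[0, 1]`; `vmel + vw <= 1`.
#' @return An `epidermis_composition` object.
#' @export
epidermis_composition <- function(vmel, vw = 0) {
  stopifnot(is.numeric(vmel), is.numeric(vw),
            length(vmel) == 1, length(vw) == 1)
  if (vmel < 0 || vw < 0 || vmel + vw > 1) {
    stop("epidermis composition requires vmel >= 0, vw >= 0, vmel + vw <= 1",
         call. = FALSE)
  }
  structure(list(vmel = vmel, vw = vw), class = "epidermis_composition")
}

#' Blood-bearing layer composition
#'
#' Volume fractions of arterial blood (`v_art`), venous blood (`v_ven`) and
#' water (`v_water`) in a dermal (or other perfused) layer, with arterial and
#' venous oxygen saturations. Venous saturation defaults to 10 percentage
#' points below arterial, the standard physiological offset used throughout
#' the model (see [venous_sat()]).
#'
#' @param v_art,v_ven,v_water Volume fractions, each `>= 0`, summing to `<= 1`.
#' @param sat_art Arterial oxygen saturation in `[0, 1]`.
#' @param sat_ven Venous oxygen saturation in `[0, 1]`; default `sat_art - 0.10`.
#' @return A `blood_composition` object.
#' @export
blood_composition <- function(v_art, v_ven, v_water, sat_art,
                              sat_ven = venous_sat(sat_art)) {
  vals <- c(v_art = v_art, v_ven = v_ven, v_water = v_water,
            sat_art = sat_art, sat_ven = sat_ven)
  stopifnot(is.numeric(vals), length(vals) == 5)
  if (any(vals[1:3] < 0) || sum(vals[1:3]) > 1 + 1e-12) {
    stop("blood fractions must be >= 0 and v_art + v_ven + v_water <= 1",
         call. = FALSE)
  }
  if (sat_art < 0 || sat_art > 1 || sat_ven < 0 || sat_ven > 1) {
    stop("saturations must lie in [0, 1]", call. = FALSE)
  }
  structure(list(v_art = v_art, v_ven = v_ven, v_water = v_water,
                 sat_art = sat_art, sat_ven = sat_ven),
            class = "blood_composition")
}

#' Venous saturation from arterial saturation
#'
#' Venous oxygen saturation is taken as 10 percentage points below arterial.
#'
#' @param sat_art Arterial saturation in `[0.10, 1]` (vectorised).
#' @return `sat_art - 0.10`.
#' @export
venous_sat <- function(sat_art) {
  stopifnot(is.numeric(sat_art))
  if (any(sat_art < 0.10) || any(sat_art > 1)) {
    stop("arterial saturation must lie in [0.10, 1] so that venous ",
         "saturation (sat_art - 0.10) is non-negative", call. = FALSE)
  }
  sat_art - 0.10
}

#' Epidermal absorption coefficient
#'
#' Composes the epidermal mu_a from melanosome and water fractions:
#' `vmel * mu_a_melanin + vw * mu_a_water + (1 - vw - vmel) * mu_a_baseline`,
#' with the melanin and baseline terms given by the packaged power laws.
#'
#' @param lambda_nm Wavelength in nm (must be tabulated).
#' @param comp An [epidermis_composition()].
#' @param table A [chromophore_table()] supplying the water coefficient.
#' @return mu_a in mm^-1.
#' @export
epidermis_mua <- function(lambda_nm, comp, table = chromophore_table()) {
  stopifnot(inherits(comp, "epidermis_composition"))
  mu_w <- mua_lookup(table, lambda_nm)$mu_a_water
  comp$vmel * melanin_mua(lambda_nm) +
    comp$vw * mu_w +
    (1 - comp$vw - comp$vmel) * skin_baseline_mua(lambda_nm)
}

#' Absorption coefficient of a perfused (dermal) layer
#'
#' Composes mu_a of a blood-bearing layer from its arterial and venous blood,
#' water, and residual baseline tissue:
#' \deqn{\mu_a = [s_A \mu_{a,HbO_2} + (1-s_A)\mu_{a,HHb}] v_A +
#'              [s_V \mu_{a,HbO_2} + (1-s_V)\mu_{a,HHb}] v_V +
#'              v_w \mu_{a,w} + (1 - v_A - v_V - v_w)\,7.84\times10^7 \lambda^{-3.255}}
#'
#' @param lambda_nm Wavelength in nm (must be tabulated).
#' @param comp A [blood_composition()].
#' @param table A [chromophore_table()].
#' @return mu_a in mm^-1.
#' @export
blood_layer_mua <- function(lambda_nm, comp, table = chromophore_table()) {
  stopifnot(inherits(comp, "blood_composition"))
  mu <- mua_lookup(table, lambda_nm)
  arterial <- (comp$sat_art * mu$mu_a_hbo2 + (1 - comp$sat_art) * mu$mu_a_hhb) * comp$v_art
  venous <- (comp$sat_ven * mu$mu_a_hbo2 + (1 - comp$sat_ven) * mu$mu_a_hhb) * comp$v_ven
  residual <- 1 - (comp$v_art + comp$v_ven + comp$v_water)
  arterial + venous + comp$v_water * mu$mu_a_water +
    residual * skin_baseline_mua(lambda_nm)
}

#' Melanosome-fraction presets for the three modelled skin types
#'
#' @return Named numeric vector of melanosome volume fractions.
#' @export
vmel_presets <- function() {
  c(light = 0.0255, moderate = 0.155, dark = 0.305)
}
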