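#' Detector specification
#'
#' The photodetector is a disc on the tissue surface, centred `offset_mm`
#' from the source along +x (reflectance-mode geometry; 3 mm by default),
#' accepting all exit angles. Detection is tallied with the
#' azimuthal-symmetry estimator: every packet leaving the surface at radial
#' distance r from the source deposits `weight * f(r)`, where `f(r)` is the
#' fraction of the circle of radius r covered by the disc. For the laterally
#' uniform slab geometry this is an unbiased estimator of the disc signal
#' with far lower variance than counting literal disc hits.
#'
#' @param offset_mm Source-detector separation in mm (default 3).
#' @param radius_mm Detector disc radius in mm (default 1, an active area of
#'   about 3 mm^2, typical of wearable reflectance photodiodes).
#' @return A `detector_spec` object.
#' @export
detector_spec <- function(offset_mm = 3, radius_mm = 1) {
  stopifnot(offset_mm >= 0, radius_mm > 0)
  structure(list(offset_mm = offset_mm, radius_mm = radius_mm),
            class = "detector_spec")
}

#' Engine settings
#'
#' @param detected Stop after this many detected packets (the primary stop
#'   criterion; the headline runs use 1e6, desk-scale runs 1e5 or less).
#' @param launched Alternative stop criterion: stop after this many launched
#'   packets. Exactly one of `detected`/`launched` may be given.
#' @param max_launched Safety cap on launches when running to a detected
#'   target.
#' @param roulette_threshold Packet weight below which roulette is played.
#' @param roulette_survival Survival probability of roulette (survivors are
#'   reweighted by its inverse, keeping the expectation unbiased).
#' @param r_max_mm Lateral escape cutoff: packets beyond this radius are
#'   terminated and tallied as absorbed-equivalent loss (reported in
#'   `lost_weight`).
#' @return An `engine_settings` object.
#' @export
engine_settings <- function(detected = NULL, launched = NULL,
                            max_launched = 1e9,
                            roulette_threshold = 1e-4,
                            roulette_survival = 0.1,
                            r_max_mm = 50) {
  if (is.null(detected) == is.null(launched)) {
    stop("give exactly one of 'detected' or 'launched'", call. = FALSE)
  }
  target <- if (is.null(detected)) launched else detected
  if (target < 1) stop("stop target must be >= 1", call. = FALSE)
  stopifnot(roulette_threshold > 0, roulette_threshold < 1,
            roulette_survival > 0, roulette_survival <= 1, r_max_mm > 0)
  structure(list(stop_mode = if (is.null(detected)) "launched" else "detected",
                 stop_target = target, max_launched = max_launched,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 r_max_mm = r_max_mm),
            class = "engine_settings")
}

#' Run photon-packet transport through a resolved tissue stack
#'
#' Launches a pencil beam at the origin along +z into the stack and traces
#' photon packets (hop-drop-spin with implicit capture, Henyey-Greenstein
#' scattering, unpolarised Fresnel/Snell boundary physics, roulette
#' termination) until the stop criterion is met. Reflectance is the detected
#' weight divided by the launched weight.
#'
#' @param stack A [build_stack()] result.
#' @param detector A [detector_spec()].
#' @param settings An [engine_settings()].
#' @param seed Single integer seed; the same seed and inputs give a
#'   bit-identical result.
#' @return A `transport_result` list: launched/detected counts and weights,
#'   weight by fate (specular, diffuse reflected, transmitted, absorbed,
#'   lateral loss), `reflectance`, `total_reflectance`, `transmittance`,
#'   plus the `seed` used.
#' @examples
#' \donttest{
#' st <- build_stack(tissue_config("light"), 940, physiological_state(0.98))
#' transport(st, settings = engine_settings(launched = 2000), seed = 1)$reflectance
#' }
#' @export
transport <- function(stack, detector = detector_spec(),
                      settings = engine_settings(detected = 1e5),
                      seed = 1) {
  stopifnot(inherits(stack, "tissue_stack"),
            inherits(detector, "detector_spec"),
            inherits(settings, "engine_settings"),
            length(seed) == 1, is.finite(seed))
  layers <- as.matrix(stack[, c("mu_a", "mu_s", "g", "n", "z_top", "z_bottom")])
  bone <- attr(stack, "bone")
  bone_vec <- if (is.null(bone)) NULL else {
    c(bone$depth_mm, bone$radius_mm,
      per_wavelength(bone$mu_a_mm, attr(stack, "lambda_nm")),
      per_wavelength(bone$mu_s_mm, attr(stack, "lambda_nm")),
      per_wavelength(bone$g, attr(stack, "lambda_nm")), bone$n)
  }
  res <- mc_transport_cpp(layers,
                          n_above = attr(stack, "ambient_n"),
                          n_below = attr(stack, "ambient_n"),
                          det_offset = detector$offset_mm,
                          det_radius = detector$radius_mm,
                          stop_mode = settings$stop_mode,
                          stop_target = settings$stop_target,
                          max_launched = settings$max_launched,
                          r_max = settings$r_max_mm,
                          w_threshold = settings$roulette_threshold,
                          p_survive = settings$roulette_survival,
                          bone = bone_vec,
                          seed = seed)
  res$seed <- seed
  class(res) <- "transport_result"
  res
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf(paste0("transport_result: %g launched, %g detected ",
                     "(reflectance %.4g)\n"),
              x$launched_count, x$detected_count, x$reflectance))
  cat(sprintf("  weight by fate: specular %.4g, diffuse %.4g, transmitted %.4g, absorbed %.4g\n",
              x$specular_weight, x$diffuse_reflected_weight,
              x$transmitted_weight, x$absorbed_weight))
  invisible(x)
}

#' Sample photon free-path lengths
#'
#' Draws step lengths `s = -ln(xi) / mu_t` with `xi ~ U(0, 1]`, the
#' exponential free path between interaction events.
#'
#' @param n Number of draws.
#' @param mu_t Total attenuation coefficient (mm^-1, `> 0`).
#' @param seed Integer seed.
#' @return Numeric vector of step lengths (mm).
#' @export
sample_step <- function(n, mu_t, seed = 1) {
  mc_sample_steps_cpp(n, mu_t, seed)
}

#' Sample Henyey-Greenstein deflection cosines
#'
#' Inverse-transform samples of the Henyey-Greenstein phase function; the
#' isotropic limit `g = 0` gives `cos(theta)` uniform on `[-1, 1]`, and the
#' mean deflection cosine equals `g`.
#'
#' @param n Number of draws.
#' @param g Anisotropy in `[-1, 1]`.
#' @param seed Integer seed.
#' @return Numeric vector of deflection cosines.
#' @export
hg_cos_theta <- function(n, g, seed = 1) {
  mc_hg_cos_cpp(n, g, seed)
}

#' Scatter a direction by the Henyey-Greenstein phase function
#'
#' @param direction Unit (or unnormalised) length-3 direction vector.
#' @param g Anisotropy in `[-1, 1]`.
#' @param n Number of independent scattered directions to draw.
#' @param seed Integer seed.
#' @return `n x 3` matrix of unit direction vectors.
#' @export
scatter_direction <- function(direction, g, n = 1, seed = 1) {
  mc_scatter_cpp(direction, g, n, seed)
}

#' Unpolarised Fresnel reflectance
#'
#' @param cos_i Cosine(s) of the incidence angle, in `[0, 1]`.
#' @param n1,n2 Refractive indices of the incidence and transmission media.
#' @return Reflection probability in `[0, 1]` (1 beyond the critical angle).
#' @export
fresnel_reflectance <- function(cos_i, n1, n2) {
  fresnel_reflectance_cpp(cos_i, n1, n2)
}

#' Play roulette on packet weights
#'
#' Packets below `threshold` survive with probability `p_survive` and are
#' reweighted by `1 / p_survive`, otherwise terminated (weight 0); the
#' expected weight is conserved.
#'
#' @param weights Packet weights.
#' @param threshold Roulette threshold.
#' @param p_survive Survival probability.
#' @param seed Integer seed.
#' @return Post-roulette weights.
#' @export
roulette <- function(weights, threshold = 1e-4, p_survive = 0.1, seed = 1) {
  stopifnot(p_survive > 0, p_survive <= 1)
  mc_roulette_cpp(weights, threshold, p_survive, seed)
}

#' Detector arc-coverage fraction
#'
#' For a packet exiting the surface at radial distance `r` from the source,
#' the fraction of its exit circle covered by a detector disc of radius `a`
#' centred `d` from the source — the weight factor of the
#' azimuthal-symmetry detection estimator.
#'
#' @param r Exit radial distance(s), mm.
#' @param d Detector centre offset, mm.
#' @param a Detector radius, mm.
#' @return Coverage fraction(s) in `[0, 1]`.
#' @export
detector_arc_fraction <- function(r, d = 3, a = 1) {
  arc_fraction_cpp(r, d, a)
}
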