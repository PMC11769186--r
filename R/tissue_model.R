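#' Load and validate a tissue configuration
#'
#' Reads a YAML description of the layered finger model: an ordered list of
#' slabs (epidermis downwards), each with thickness (mm), refractive index,
#' per-wavelength scattering coefficient `mu_s_mm` and anisotropy `g`, and a
#' composition that is either `epidermis` (melanosome + water fractions),
#' `blood` (arterial/venous/water fractions at diastole) or `fixed`
#' (tabulated mu_a per wavelength). An optional `bone` block describes a
#' cylinder perpendicular to the sagittal plane (`depth_mm` of the axis,
#' `radius_mm`, fixed optical properties); `bone: null` selects the slab-only
#' geometry.
#'
#' @param path YAML file path, or one of the shipped preset names
#'   `"light"`, `"moderate"`, `"dark"`.
#' @return A validated `tissue_config` list.
#' @examples
#' cfg <- tissue_config("light")
#' names(cfg$layers[[1]])
#' @export
tissue_config <- function(path) {
  presets <- c("light", "moderate", "dark")
  if (path %in% presets) {
    path <- system.file("extdata", paste0("finger_", path, ".yaml"),
                        package = "pulseoxmc")
  }
  cfg <- yaml::read_yaml(path)
  validate_tissue_config(cfg)
}

validate_tissue_config <- function(cfg) {
  if (is.null(cfg$layers) || length(cfg$layers) < 1) {
    stop("tissue config: at least one layer required", call. = FALSE)
  }
  if (is.null(cfg$ambient_n)) cfg$ambient_n <- 1.0
  if (cfg$ambient_n < 1) stop("tissue config: ambient_n must be >= 1", call. = FALSE)
  for (i in seq_along(cfg$layers)) {
    ly <- cfg$layers[[i]]
    where <- sprintf("layers[%d] ('%s')", i, ly$name %||% "?")
    for (f in c("name", "thickness_mm", "n", "mu_s_mm", "g", "composition")) {
      if (is.null(ly[[f]])) stop("tissue config: ", where, " missing field '", f, "'",
                                 call. = FALSE)
    }
    if (ly$thickness_mm <= 0) stop("tissue config: ", where, " thickness must be > 0",
                                   call. = FALSE)
    if (ly$n < 1) stop("tissue config: ", where, " refractive index must be >= 1",
                       call. = FALSE)
    if (any(unlist(ly$mu_s_mm) < 0)) stop("tissue config: ", where, " mu_s must be >= 0",
                                          call. = FALSE)
    if (any(abs(unlist(ly$g)) > 1)) stop("tissue config: ", where, " g must be in [-1, 1]",
                                         call. = FALSE)
    type <- ly$composition$type %||% stop("tissue config: ", where,
                                          " composition.type missing", call. = FALSE)
    if (!type %in% c("epidermis", "blood", "fixed")) {
      stop("tissue config: ", where, " unknown composition type '", type, "'",
           call. = FALSE)
    }
  }
  if (!is.null(cfg$bone)) {
    for (f in c("depth_mm", "radius_mm", "mu_a_mm", "mu_s_mm", "g", "n")) {
      if (is.null(cfg$bone[[f]])) stop("tissue config: bone missing field '", f, "'",
                                       call. = FALSE)
    }
  }
  structure(cfg, class = "tissue_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Physiological state of the model
#'
#' Arterial oxygen saturation plus cardiac phase. The standard simulation
#' grid spans saturations 0.70 to 1.00 in steps of 0.05; free-form values
#' are accepted for sweeps. Venous saturation is always derived as
#' `sat_art - 0.10`, never stored independently.
#'
#' @param sat_art Arterial saturation in `[0.10, 1]`.
#' @param phase `"diastole"` or `"systole"`.
#' @return A `physiological_state` object.
#' @export
physiological_state <- function(sat_art, phase = c("diastole", "systole")) {
  phase <- match.arg(phase)
  venous_sat(sat_art)  # validates range
  structure(list(sat_art = sat_art, phase = phase), class = "physiological_state")
}

#' Systolic blood-volume rule
#'
#' The systolic phase is modelled by doubling the diastolic blood volume,
#' distributed equally between the arterial and venous compartments: each
#' compartment's volume fraction doubles.
#'
#' @param comp A diastolic [blood_composition()].
#' @return The systolic `blood_composition`.
#' @export
apply_systole <- function(comp) {
  stopifnot(inherits(comp, "blood_composition"))
  if (2 * (comp$v_art + comp$v_ven) + comp$v_water > 1 + 1e-12) {
    stop("systolic doubling exceeds the unit volume budget ",
         "(2*(v_art + v_ven) + v_water > 1)", call. = FALSE)
  }
  blood_composition(2 * comp$v_art, 2 * comp$v_ven, comp$v_water,
                    comp$sat_art, comp$sat_ven)
}

resolve_layer_composition <- function(ly, state, table) {
  type <- ly$composition$type
  if (type == "epidermis") {
    return(epidermis_composition(ly$composition$vmel, ly$composition$vw %||% 0))
  }
  if (type == "blood") {
    comp <- blood_composition(ly$composition$v_art, ly$composition$v_ven,
                              ly$composition$v_water, state$sat_art)
    if (state$phase == "systole") comp <- apply_systole(comp)
    return(comp)
  }
  NULL  # fixed
}

per_wavelength <- function(x, lambda_nm) {
  key <- as.character(lambda_nm)
  if (is.null(x[[key]])) {
    stop("no value tabulated at ", lambda_nm, " nm (available: ",
         paste(names(x), collapse = ", "), ")", call. = FALSE)
  }
  x[[key]]
}

#' Build a resolved tissue stack
#'
#' Resolves the layered geometry at one wavelength and one physiological
#' state into concrete per-layer optical properties: mu_a is composed through
#' the chromophore model (epidermal melanin/water, dermal arterial + venous
#' blood with the systolic doubling rule, or fixed values), mu_s, g and n are
#' taken from the configuration.
#'
#' @param config A [tissue_config()].
#' @param lambda_nm Wavelength in nm (must be tabulated in `config` and `table`).
#' @param state A [physiological_state()].
#' @param table A [chromophore_table()].
#' @return A `tissue_stack`: data frame with one row per layer
#'   (`name, z_top, z_bottom, thickness, mu_a, mu_s, g, n`) plus attributes
#'   `ambient_n`, `bone`, `lambda_nm`, `state`.
#' @export
build_stack <- function(config, lambda_nm, state, table = chromophore_table()) {
  stopifnot(inherits(config, "tissue_config"),
            inherits(state, "physiological_state"))
  n_layers <- length(config$layers)
  out <- data.frame(name = character(n_layers), z_top = 0, z_bottom = 0,
                    thickness = 0, mu_a = 0, mu_s = 0, g = 0, n = 0,
                    stringsAsFactors = FALSE)
  z <- 0
  for (i in seq_len(n_layers)) {
    ly <- config$layers[[i]]
    comp <- resolve_layer_composition(ly, state, table)
    mu_a <- if (is.null(comp)) {
      per_wavelength(ly$composition$mu_a_mm, lambda_nm)
    } else if (inherits(comp, "epidermis_composition")) {
      epidermis_mua(lambda_nm, comp, table)
    } else {
      blood_layer_mua(lambda_nm, comp, table)
    }
    if (!is.finite(mu_a) || mu_a < 0) {
      stop("layer '", ly$name, "' resolved to invalid mu_a", call. = FALSE)
    }
    out$name[i] <- ly$name
    out$z_top[i] <- z
    out$thickness[i] <- ly$thickness_mm
    z <- z + ly$thickness_mm
    out$z_bottom[i] <- z
    out$mu_a[i] <- mu_a
    out$mu_s[i] <- per_wavelength(ly$mu_s_mm, lambda_nm)
    out$g[i] <- per_wavelength(ly$g, lambda_nm)
    out$n[i] <- ly$n
  }
  structure(out,
            ambient_n = config$ambient_n, bone = config$bone,
            lambda_nm = lambda_nm, state = state,
            class = c("tissue_stack", "data.frame"))
}

#' Classify a point against a tissue stack
#'
#' Depth is measured positive downward from the air-tissue surface at z = 0.
#' Every point maps to exactly one region: `"above_surface"` (z < 0),
#' `"below_stack"` (z beyond the last layer), `"inside_bone"` (within the
#' bone cylinder, if configured), or the 1-based layer index.
#'
#' @param point Numeric length-3 `(x, y, z)` in mm.
#' @param stack A [build_stack()] result.
#' @return Integer layer index, or one of the region labels above.
#' @export
locate <- function(point, stack) {
  stopifnot(inherits(stack, "tissue_stack"), length(point) == 3)
  z <- point[3]
  if (z < 0) return("above_surface")
  if (z >= stack$z_bottom[nrow(stack)]) return("below_stack")
  bone <- attr(stack, "bone")
  if (!is.null(bone)) {
    # cylinder axis along y at depth_mm below the surface, x = 0
    if ((point[1]^2 + (z - bone$depth_mm)^2) <= bone$radius_mm^2) {
      return("inside_bone")
    }
  }
  which(z >= stack$z_top & z < stack$z_bottom)[1]
}

#' @export
print.tissue_stack <- function(x, ...) {
  st <- attr(x, "state")
  cat(sprintf("tissue_stack: %d layers, %.0f nm, %s, SaO2 %.0f%%\n",
              nrow(x), attr(x, "lambda_nm"), st$phase, 100 * st$sat_art))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Serialise a tissue configuration back to YAML
#'
#' Round-trips through [tissue_config()]: rebuilding from the written file
#' yields identical resolved stacks.
#'
#' @param config A [tissue_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tissue_config <- function(config, path) {
  stopifnot(inherits(config, "tissue_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
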