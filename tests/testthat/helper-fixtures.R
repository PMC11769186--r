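# fixtures built in code: tiny configs and a placeholder chromophore table

# single homogeneous slab with fixed optical properties
slab_config <- function(mu_a, mu_s, g, n = 1.0, thickness = 1.0,
                        ambient_n = 1.0, lambda = 660) {
  key <- as.character(lambda)
  cfg <- list(
    ambient_n = ambient_n,
    layers = list(list(
      name = "slab", thickness_mm = thickness, n = n,
      mu_s_mm = stats::setNames(list(mu_s), key),
      g = stats::setNames(list(g), key),
      composition = list(type = "fixed",
                         mu_a_mm = stats::setNames(list(mu_a), key)))),
    bone = NULL)
  pulseoxmc:::validate_tissue_config(cfg)
}

slab_stack <- function(mu_a, mu_s, g, n = 1.0, thickness = 1.0,
                       ambient_n = 1.0, lambda = 660) {
  build_stack(slab_config(mu_a, mu_s, g, n, thickness, ambient_n, lambda),
              lambda, physiological_state(0.98))
}

# chromophore table with stated placeholder spectra (written to a temp CSV)
placeholder_table <- function(hbo2 = 0.15, hhb = 1.5, water = 0.00036,
                              lambda = 660) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  write.csv(data.frame(wavelength_nm = lambda, mu_a_hbo2_mm = hbo2,
                       mu_a_hhb_mm = hhb, mu_a_water_mm = water),
            path, row.names = FALSE)
  chromophore_table(path)
}

# hand-built reflectance records for reduce_point arithmetic
fake_records <- function(dia_660, sys_660, dia_940, sys_940, sat_a = 0.95) {
  data.frame(
    skin_type = "x", sat_a = sat_a,
    lambda_nm = c(660, 660, 940, 940),
    phase = c("diastole", "systole", "diastole", "systole"),
    reflectance = c(dia_660, sys_660, dia_940, sys_940),
    stringsAsFactors = FALSE)
}
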