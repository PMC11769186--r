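wavelength_nm,mu_a_hbo2_mm,mu_a_hhb_mm,mu_a_water_mm
660,0.1712,1.7284,0.00036
940,0.6503,0.3714,0.0267
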