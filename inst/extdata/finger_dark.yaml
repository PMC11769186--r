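# Layered finger model, dark skin (melanosome fraction 30.5%).
# Layer inventory, thicknesses, scattering properties and blood/water
# fractions are literature-derived defaults for a human finger; absorption
# of the epidermis and the perfused layers is composed at run time from the
# chromophore table and the compositions below (diastolic blood volumes;
# systole is derived by doubling them).
ambient_n: 1.0
layers:
  - name: epidermis
    thickness_mm: 0.10
    "n": 1.40
    mu_s_mm: {660: 45.0, 940: 30.0}
    g: {660: 0.85, 940: 0.85}
    composition:
      type: epidermis
      vmel: 0.305
      vw: 0.20
  - name: papillary_dermis
    thickness_mm: 0.20
    "n": 1.39
    mu_s_mm: {660: 25.0, 940: 18.0}
    g: {660: 0.90, 940: 0.92}
    composition:
      type: blood
      v_art: 0.006
      v_ven: 0.006
      v_water: 0.50
  - name: upper_blood_net_dermis
    thickness_mm: 0.20
    "n": 1.39
    mu_s_mm: {660: 30.0, 940: 20.0}
    g: {660: 0.90, 940: 0.92}
    composition:
      type: blood
      v_art: 0.020
      v_ven: 0.020
      v_water: 0.60
  - name: reticular_dermis
    thickness_mm: 0.80
    "n": 1.40
    mu_s_mm: {660: 20.0, 940: 16.0}
    g: {660: 0.90, 940: 0.92}
    composition:
      type: blood
      v_art: 0.004
      v_ven: 0.004
      v_water: 0.70
  - name: deep_blood_net_dermis
    thickness_mm: 0.30
    "n": 1.38
    mu_s_mm: {660: 30.0, 940: 25.0}
    g: {660: 0.95, 940: 0.95}
    composition:
      type: blood
      v_art: 0.050
      v_ven: 0.050
      v_water: 0.70
  - name: subcutaneous_fat
    thickness_mm: 2.0
    "n": 1.44
    mu_s_mm: {660: 12.0, 940: 10.0}
    g: {660: 0.85, 940: 0.85}
    composition:
      type: fixed
      mu_a_mm: {660: 0.010, 940: 0.012}
  - name: muscle
    thickness_mm: 3.0
    "n": 1.37
    mu_s_mm: {660: 8.0, 940: 6.0}
    g: {660: 0.90, 940: 0.90}
    composition:
      type: blood
      v_art: 0.010
      v_ven: 0.010
      v_water: 0.76
bone: null
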