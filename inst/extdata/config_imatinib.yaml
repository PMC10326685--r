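# Default drug / system / perpetrator parameter set for the imatinib PBPK model.
#
# Intrinsic-clearance, binding and interaction constants are calibrated so that
# the model reproduces the published steady-state behaviour of imatinib
# (dilute-limit fu_p = 0.05 at the reference AAG concentration, typical adult
# CL/F of 9-10.5 L/h at 400 mg daily, 3% non-CYP3A4/2C8 metabolic share,
# terminal half-life ~18 h).  They are model calibration constants, not
# transcribed in-vitro measurements.
#
# Units are carried in key names: mg, L, h canonical; enzyme kinetic constants
# in uM are converted internally via molecular weight.
drug:
  name: imatinib
  molecular_weight_g_mol: 493.6
  aag_molecular_weight_g_mol: 44000.0
  ka_per_h: 0.61
  fa_fraction: 0.98
  blood_plasma_ratio: 0.9
  fu_ref_fraction: 0.05
  aag_ref_g_per_L: 0.91
  binding_capacity_per_aag: 1.0
  clint_per_pmol_uL_min:
    CYP3A4_hepatic: 0.155
    CYP2C8_hepatic: 0.8
    CYP3A4_gut: 0.126
    other_CYP: 1.0
  clint_biliary_per_abundance_L_h:
    P-gp: 98.0
    BCRP: 192.0
  cl_renal_ref_L_per_h: 1.9
  renal_filtration_like_fraction: 0.798
  egfr_ref_mL_min: 100.0
  autoinhibition:
    KI_uM: 0.05
    kinact_per_h: 0.03
  vc_per_kg_L: 1.6
  vp_per_kg_L: 1.1
  q_inter_L_per_h: 30.0
  kp_liver: 12.0
  fu_gut: 0.05
  gut_wall_volume_L: 0.25
  gut_transit_per_h: 3.0

system:
  qh_bsa_coef_L_h_per_m2: 47.4
  qh_age_decline_per_yr: 0.004
  liver_weight_bsa_coef_g: 452.0
  liver_weight_bsa_exponent: 2.05
  liver_weight_age_decline_per_yr: 0.003
  liver_weight_cv: 0.15
  reference_liver_weight_g: 1650.0
  age_reference_yr: 20.0
  mppgl_mean_mg_per_g: 40.0
  mppgl_cv: 0.3
  enzyme_abundance:
    CYP3A4_hepatic: {mean_pmol_mg: 93.0, cv: 0.4, min: 0.0, max: 600.0}
    CYP2C8_hepatic: {mean_pmol_mg: 22.4, cv: 0.4, min: 0.0, max: 85.0}
  gut_cyp3a4_abundance: {mean_nmol: 66.0, cv: 0.4, min: 2.0, max: 250.0}
  cyp3a4_cyp2c8_rank_correlation: 0.68
  transporter_abundance:
    P-gp: {mean_pmol_per_1e6_cells: 0.201, cv: 0.46}
    BCRP: {mean_pmol_per_1e6_cells: 0.044, cv: 0.4}
  aag_distribution:
    cv: 0.2
    min_g_per_L: 0.36
    max_g_per_L: 1.46
    mean_g_per_L:
      European: {male: 0.93, female: 0.88}
      Chinese: {male: 0.85, female: 0.8}
      Japanese: {male: 0.85, female: 0.8}
  serum_creatinine_umol_L:
    male: {mean: 80.0, sd: 13.0}
    female: {mean: 65.0, sd: 11.0}
  kdeg_per_h:
    CYP3A4_hepatic: 0.0158
    CYP3A4_gut: 0.03
    CYP2C8_hepatic: 0.0158
  body_size:
    European:
      weight_male_kg: [83.0, 13.0]
      weight_female_kg: [68.0, 12.0]
      height_male_cm: [176.0, 7.0]
      height_female_cm: [163.0, 6.5]
    Chinese:
      weight_male_kg: [70.0, 10.0]
      weight_female_kg: [58.0, 9.0]
      height_male_cm: [170.0, 6.5]
      height_female_cm: [158.0, 6.0]
    Japanese:
      weight_male_kg: [68.0, 10.0]
      weight_female_kg: [55.0, 8.0]
      height_male_cm: [170.0, 6.5]
      height_female_cm: [157.0, 6.0]
  cirrhosis_multipliers:
    A: {liver_weight: 0.9, qh: 0.9, cyp: 0.8, aag: 0.9}
    B: {liver_weight: 0.7, qh: 0.65, cyp: 0.55, aag: 0.75}
    C: {liver_weight: 0.55, qh: 0.5, cyp: 0.4, aag: 0.65}
  renal_multipliers:
    30to60: {aag: 1.3, cyp: 0.85, egfr_set: 45.0}
    lt30: {aag: 1.5, cyp: 0.7, egfr_set: 25.0}

# Perpetrator forcing functions (one-compartment oral PK; V and CL are
# apparent, V/F and CL/F) plus enzyme interaction terms.  Interaction
# constants are calibration constants informed by the published interaction
# models for each compound.
perpetrators:
  diltiazem:
    regimen: {dose_mg: 45.0, interval_h: 6.0, n_doses: 56, start_offset_h: 0.0}
    pk: {mw_g_mol: 414.5, ka_per_h: 1.0, v_over_f_L: 400.0, cl_over_f_L_per_h: 60.0, fu: 0.22, blood_plasma_ratio: 1.0}
    interactions:
      - {enzyme: CYP3A4, site: hepatic, mechanism: mbi, KI_uM: 2.2, kinact_per_h: 0.7}
      - {enzyme: CYP3A4, site: gut, mechanism: mbi, KI_uM: 8.0, kinact_per_h: 0.7}
  verapamil:
    regimen: {dose_mg: 60.0, interval_h: 8.0, n_doses: 42, start_offset_h: 0.0}
    pk: {mw_g_mol: 454.6, ka_per_h: 1.0, v_over_f_L: 500.0, cl_over_f_L_per_h: 80.0, fu: 0.1, blood_plasma_ratio: 0.84}
    interactions:
      - {enzyme: CYP3A4, site: hepatic, mechanism: mbi, KI_uM: 2.9, kinact_per_h: 4.2}
      - {enzyme: CYP3A4, site: gut, mechanism: mbi, KI_uM: 8.0, kinact_per_h: 4.2}
  hyperforin:
    regimen: {dose_mg: 45.0, interval_h: 24.0, n_doses: 14, start_offset_h: 0.0}
    pk: {mw_g_mol: 536.8, ka_per_h: 0.5, v_over_f_L: 300.0, cl_over_f_L_per_h: 15.0, fu: 0.01, blood_plasma_ratio: 1.0}
    interactions:
      - {enzyme: CYP3A4, site: gut, mechanism: induction, Indmax: 9.0, IndC50_uM: 0.0042}
  trimethoprim:
    regimen: {dose_mg: 300.0, interval_h: 24.0, n_doses: 7, start_offset_h: 168.0}
    pk: {mw_g_mol: 290.3, ka_per_h: 1.5, v_over_f_L: 110.0, cl_over_f_L_per_h: 5.5, fu: 0.5, blood_plasma_ratio: 1.0}
    interactions:
      - {enzyme: CYP2C8, site: hepatic, mechanism: competitive, Ki_uM: 4.2}
  clopidogrel:
    regimen: {dose_mg: 75.0, interval_h: 24.0, n_doses: 14, start_offset_h: 0.0}
    pk:
      mw_g_mol: 321.8
      ka_per_h: 1.5
      v_over_f_L: 300.0
      cl_over_f_L_per_h: 105.0
      fu: 0.02
      blood_plasma_ratio: 1.0
      metabolite: {name: clopidogrel_acyl_glucuronide, fraction_formed: 0.4, ke_per_h: 0.15, v_L: 80.0, fu: 0.1}
    interactions:
      - {enzyme: CYP2C8, site: hepatic, mechanism: mbi, driver: metabolite, KI_uM: 9.9, kinact_per_h: 7.9}
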