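profile:
  name: DCM
  hr: 78.0
  ees_lv: 0.4
  v0_lv: 60.0
  v30: 210.0
  s_lv: 0.117
  rv_params:
    ees: 0.75
    v0: 10.0
    s: 0.08
    v30: 180.0
  atrial_params:
    e_la: 0.25
    v0_la: 20.0
    e_ra: 0.2
    v0_ra: 20.0
  systemic:
    resistance: 1.0
    compliance: 1.3
    v0_arterial: 500.0
    venous_compliance: 70.0
    venous_resistance: 0.025
    v0_venous: 2800.0
  pulmonary:
    resistance: 0.153
    compliance: 3.0
    v0_arterial: 80.0
    venous_compliance: 12.0
    venous_resistance: 0.012
    v0_venous: 300.0
  valves:
    r_mv: 0.005
    r_av: 0.008
    r_tv: 0.005
    r_pv: 0.006
  activation:
    sys_frac: 0.27
    n1: 1.9
    n2: 35.0
  total_blood_volume: 4700.0
  target_hemodynamics:
    co: 4.7
    sap_sys: 87.0
    sap_dia: 81.0
    sap_mean: 84.0
    pap_sys: 37.0
    pap_dia: 16.0
    pap_mean: 24.0
    pcwp: 12.0
    edv: 183.0
    esv: 154.0
pump:
  speed_setpoint: 2800.0
  hq_coeffs:
  - 1.38e-05
  - -1.07e-03
  - -6.0e-01
  impeller_inertia: 3.2e-05
  torque_constant: 0.02
  friction_coeff: 1.0e-05
  torque_coeffs:
  - 1.1e-05
  - 1.0e-05
  controller_gains:
  - 0.035
  - 0.08
  i_max: 3.0
  inertance: 0.002
  r_outflow: 0.12
  estimator_coeffs:
  - 0.02
  - 2.1e-05
  - 1.0e-05
  sample_rate_pump: 50.0
  flow_filter_hz: 3.5
  flow_mean_filter_hz: 0.2
  flow_pulsatility_gain: 0.075
  speed_filter_hz: 15.0
suction:
  collapse_threshold_pressure: 0.0
  collapse_steepness: 6.0
  hysteresis_pressure: 1.2
  r_open: 0.035
  r_collapsed: 3.5
  collapse_exponent: 1.0
  recovery_time_constant: 0.04
  release_time_constant: 0.5
  ground_truth_fraction: 0.5
  enabled: yes
speed_list:
- 2500.0
- 2600.0
- 2700.0
- 2800.0
- 2900.0
- 3000.0
- 3100.0
- 3200.0
hypovolemia_step: 0.02
stop_criterion_flow_peak: 2.0
n_beats_per_stage: 25.0
settle_beats: 5.0
solver:
  dt: 0.00025
noise:
  enabled: no
  sd_flow: 0.0
  sd_speed: 0.0
  seed: ~
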