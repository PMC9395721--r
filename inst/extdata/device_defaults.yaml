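# Behavioral statistical model of the multilevel RRAM conductance states.
#
# These numbers are CALIBRATIONS, not measurements: the distribution
# parameters (sigma0, mu_inf, tau_d, sigma_growth, p_drift, sign) were
# chosen once to reproduce the qualitative programming/drift behavior of
# 4-kbit HfO2 1T1R arrays -- ML-Set leaves a downward-drifting
# subpopulation in L2-L5 that saturates within a week, ML-Hybrid shows a
# smaller displaced fraction with inverted shift sign, and L6-L9 are
# produced by the same set procedure in both algorithms. sigma0 and
# mu_inf are in uS, tau_d in hours, p_drift is the drifting-cell
# fraction, sigma_growth multiplies sigma0 for the drifting component.
schema: 1
time_saturation_h: 168
conductance_scale_uS_per_weight: 100
levels:           # programming targets G_trg, uS
  L1: 25
  L2: 50
  L3: 75
  L4: 100
  L5: 125
  L6: 150
  L7: 175
  L8: 200
  L9: 225
algorithms:
  ml_set:
    # set-only staircase from the reset state; one program-and-verify pass
    programming_cost: {L1: 1, L2: 1, L3: 1, L4: 1, L5: 1, L6: 1, L7: 1, L8: 1, L9: 1}
    levels:
      L1: {sigma0: 6.0, mu_inf: 10.0, tau_d: 24, sigma_growth: 1.5, p_drift: 0.20, sign: -1}
      L2: {sigma0: 3.5, mu_inf: 22.0, tau_d: 24, sigma_growth: 1.6, p_drift: 0.30, sign: -1}
      L3: {sigma0: 3.2, mu_inf: 18.0, tau_d: 24, sigma_growth: 1.6, p_drift: 0.25, sign: -1}
      L4: {sigma0: 3.0, mu_inf: 15.0, tau_d: 24, sigma_growth: 1.5, p_drift: 0.20, sign: -1}
      L5: {sigma0: 2.8, mu_inf: 12.0, tau_d: 24, sigma_growth: 1.5, p_drift: 0.15, sign: -1}
      L6: {sigma0: 2.5, mu_inf: 5.0, tau_d: 24, sigma_growth: 1.2, p_drift: 0.05, sign: -1}
      L7: {sigma0: 2.5, mu_inf: 5.0, tau_d: 24, sigma_growth: 1.2, p_drift: 0.05, sign: -1}
      L8: {sigma0: 2.5, mu_inf: 5.0, tau_d: 24, sigma_growth: 1.2, p_drift: 0.05, sign: -1}
      L9: {sigma0: 2.5, mu_inf: 5.0, tau_d: 24, sigma_growth: 1.2, p_drift: 0.05, sign: -1}
  ml_hybrid:
    # L2-L5 reached by controlled reset from L8 (reset + set: doubled
    # per-cell programming cost); L6-L9 shared with ml_set
    programming_cost: {L1: 1, L2: 2, L3: 2, L4: 2, L5: 2, L6: 1, L7: 1, L8: 1, L9: 1}
    levels:
      L1: {sigma0: 6.0, mu_inf: 10.0, tau_d: 24, sigma_growth: 1.5, p_drift: 0.20, sign: -1}
      L2: {sigma0: 3.0, mu_inf: 20.0, tau_d: 24, sigma_growth: 1.3, p_drift: 0.08, sign: 1}
      L3: {sigma0: 2.9, mu_inf: 17.0, tau_d: 24, sigma_growth: 1.3, p_drift: 0.07, sign: 1}
      L4: {sigma0: 2.8, mu_inf: 14.0, tau_d: 24, sigma_growth: 1.3, p_drift: 0.06, sign: 1}
      L5: {sigma0: 2.7, mu_inf: 11.0, tau_d: 24, sigma_growth: 1.3, p_drift: 0.05, sign: 1}
      L6: {sigma0: 2.5, mu_inf: 5.0, tau_d: 24, sigma_growth: 1.2, p_drift: 0.05, sign: -1}
      L7: {sigma0: 2.5, mu_inf: 5.0, tau_d: 24, sigma_growth: 1.2, p_drift: 0.05, sign: -1}
      L8: {sigma0: 2.5, mu_inf: 5.0, tau_d: 24, sigma_growth: 1.2, p_drift: 0.05, sign: -1}
      L9: {sigma0: 2.5, mu_inf: 5.0, tau_d: 24, sigma_growth: 1.2, p_drift: 0.05, sign: -1}
# Program-and-verify recipes recorded as annotation only; the package
# never simulates pulse-level physics.
recipes:
  forming:
    algorithm: ISPVA
    V_G_V: 1.4
    V_TE_start_V: 2.0
    V_TE_stop_V: 5.0
    V_TE_step_V: 0.01
    target_uS: 200
  reset:
    algorithm: ISPVA
    V_G_V: 2.7
    V_BE_start_V: 0.5
    V_BE_stop_V: 2.0
    V_BE_step_V: 0.1
  ml_set:
    algorithm: ISPVA
    V_G_start_V: 0.5
    V_G_stop_V: 1.7
    V_G_step_V: 0.01
    V_TE_V: 1.2
    t_p_us: 1.0
    t_rise_ns: 100
    t_fall_ns: 100
    verify_delay_s: 1
  ml_hybrid_reset:
    algorithm: IGVVA
    V_BE_V: 1.2
    V_G_start_V: 1.5
    V_G_stop_V: 2.9
    V_G_step_V: 0.01
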