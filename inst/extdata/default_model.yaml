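# Healthy baseline configuration of the closed-loop circulation model.
# Units: resistances Pa.s.mm^-3, inertances Pa.s^2.mm^-3,
# compliances mm^3.Pa^-1, elastances Pa.mm^-3, times s, V0 in mL.
heart:
  elastance:
    E_maxL: 0.394
    E_minL: 9.0e-05
    E_maxR: 0.152
    E_minR: 9.0e-05
    T: 0.684
    t_max: 0.377
    t_toRelax: 0.104
    V0_mL: 10.0
  valves:
    R_MV: 3.9e-04
    L_MV: 1.0e-05
    R_AV: 1.0e-05
    L_AV: 1.0e-05
    R_TV: 1.0e-05
    L_TV: 1.0e-05
    R_PV: 1.0e-05
    L_PV: 1.0e-05
  atria:
    C_la: 10.0
    C_ra: 2.0
compartments:
  lung:
    R_p: 2.7e-04
    C: 1.0
    R_d: 2.65e-03
  digestive:
    R_p: 0.05607
    C: 0.63
    R_d: 0.5811
  other_organs:
    R_p: 0.01869
    C: 6.302
    R_d: 0.1937
  central_venous:
    R_p: 1.4e-04
    C: 12.0
    R_d: 1.42e-03
hepatic:
  R_pv_p: 3.18e-03
  R_pv_d: 0.03184
  C_pv: 1.2
  R_ha_p: 0.17755
  R_ha_d: 1.84015
  C_ha: 0.63
  R_hs: 8.84e-03
  C_hs: 1.0
  R_lhv: 1.0e-05
  R_mhv: 1.0e-05
  R_rhv: 1.0e-05
valve_law:
  steepness_Pa: 2.7
  closed_resistance_factor: 1.0e+06
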