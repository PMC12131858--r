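# Example study configuration: linezolid 600 mg q12h reproduced in the
# hollow-fiber rig, as unbound-plasma (iv) and CSF (absorption) profiles.
# Units: volumes L, flows L/h, rates 1/h, times h, concentrations mg/L.
seed: 1
grid_step: 0.01
flow_resolution: 0.1
duration_resolution: 1
target_volume_mL: 2
rig:
  v_central_L: 0.300
  v_cartridge_L: 0.078
  f_ics: 0.23077
  q_cartridge_L_h: 3.6
  cl_elim_L_h: 0.0828
  q_diffusion_L_h: 0.387
  exp_duration_h: 96
regimens:
  - label: plasma_600_q12
    mode: iv
    cmax1_mg_L: 10.7
    ke_1_h: 0.230
    tau_h: 12
    t_infusion_h: 0.5
    n_doses: 8
  - label: csf_600_q12
    mode: absorption
    cmax1_mg_L: 4.25
    ka_1_h: 0.300
    ke_1_h: 0.230
    tau_h: 12
    n_doses: 8
    n_sub_intervals: 12
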