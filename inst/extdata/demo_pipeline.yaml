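# Demo configuration for run_pipeline() / exec/thylakoid-biophys:
# simulate each data type at known ground truth and analyse it.
seed: 7
stages:
  channel:
    gamma_pos: 96.1
    gamma_neg: 60
    voltages: [-80, -60, -40, 40, 60, 80]
    duration_s: 10
    noise_sd: 0.8
  selectivity:
    p_ratio: 0.17
  ecs:
    s_light: 1.0
    f_dpsi: 0.6
    tau_ms: 25
    noise_sd: 0.005
  pam:
    f_m: 2
    npq: [0.5, 1.0, 1.5]
    phi: [0.6, 0.5, 0.4]
    pulse_times: [30, 60, 90]
  sans:
    rel_noise: 0.02
  cd:
    noise_sd: 0.02
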