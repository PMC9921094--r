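scenario:
  name: c
  odor_source:
  - 0.0
  - 0.0
  wind_source:
  - -0.5
  - 0.0
  wind_speed: 1.0
  mean_wind_direction: 0.0
  turbulence:
    direction_sd: 0.5
    speed_sd: 0.29999999999999999
    correlation_time: 2.0
  field_bounds:
  - -0.5
  - 2.0
  - -1.0
  - 1.0
  start_pose:
  - 1.5
  - 0.29999999999999999
  - 3.14159265358979312
  plume:
    release_rate: 10.0
    sigma0: 0.02
    growth_rate: 0.005
    jitter_sd: 0.02
    q: 1.0
  transport_wind: ~
algorithm: rmi
gains:
  corrected: yes
  breakpoint: 0.69999999999999996
  v_min: 50.0
  v_max: 250.0
  w_min: 0.5
  w_max: 3.0
sensing:
  threshold: 100.0
  forward_offset: 0.05
  lateral_offset: 0.03
  window: 5.0
  refractory: 0.5
  dead_band: 0.05
control:
  surge_duration: 0.5
  surge_turn_angle: 0.52359877559829882
  zigzag_turn_angle: 1.04719755119659763
  zigzag_leg_duration: 1.0
  straight_fraction: 1.0
  szl_v: 150.0
  szl_w: 1.5
  sc_v: 150.0
  sc_w: 1.5
  sc_lost_timeout: 1.0
  sc_cast_initial: 1.5
  sc_cast_factor: 2.0
  sc_cast_max: 8.0
dt: 0.01
t_max: 180.0
success_radius: 0.10000000000000001
warmup: 6.0
n_trials: 20
seed: 1
out_dir: '.'
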