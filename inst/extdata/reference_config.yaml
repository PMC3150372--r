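# Reference swarm configuration: a 25-particle group that converges from a
# random initial configuration to the rotating-mill steady state.
schema_version: 1
model:
  neighbourhood: geometric
  attraction: true
  alignment: true
  infer_update_rate: false
params:
  attraction_weight: 1.0
  alignment_weight: 0.25
  interaction_radius: 2.0
  blind_angle: 1.5707963267948966   # pi / 2
  noise_sd: 0.15
  speed: 0.2
  update_prob: 1.0
  arena_size: 10.0
run:
  n_particles: 25
  n_steps: 10
  seeds: [1, 2, 3, 4, 5]
  resolution: 9
  burn_in:
    threshold: 0.8
    window: 10
    max_steps: 3000
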