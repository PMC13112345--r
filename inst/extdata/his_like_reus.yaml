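# Basic (His-like) titratable particle, replica-exchange umbrella sampling
# with the split force-constant rule: soft umbrellas (500 kJ/mol/nm^2) in
# the water phase (>= 8 A), stiff ones (1000) from 6 A inward.
model:
  residue_class: base
  pka_w: 6.54
  temperature: 300
  z_water_ref: 2.0
  terms:
    protonated:
      - {shape: sigmoid-step, amplitude: 18, center: 0.1, width: 0.3}
    deprotonated:
      - {shape: gaussian, amplitude: -4, center: 0.2, width: 0.45}
method: reus
replicates: 3
seeds: [11, 12, 13]
diffusion: 0.1
schedule:
  dt: 0.1
  n_steps: 2000
  titration_period: 20
  record_period: 2
  exchange_period: 20
  exchange_offset: 10
  equilibration_cutoff: 25
ph_ladder:
  values: [4.5, 5.5, 6.5, 7.5]
window_ladder:
  start: 20
  stop: -12
  spacing: 2
  k_outer: 500
  k_inner: 1000
  k_boundary: 7
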