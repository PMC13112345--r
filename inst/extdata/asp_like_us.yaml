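# Acidic (Asp-like) titratable particle, umbrella-sampling campaign.
# The pH ladder is the 4 simulation values around the aqueous pKa plus the
# two extended values on the ionized (high-pH) side.
model:
  residue_class: acid
  pka_w: 3.94
  temperature: 300
  z_water_ref: 2.0
  terms:
    protonated:
      - {shape: gaussian, amplitude: -4, center: 0.2, width: 0.45}
    deprotonated:
      - {shape: sigmoid-step, amplitude: 18, center: 0.1, width: 0.3}
method: us
replicates: 3
seeds: [101, 102, 103]
diffusion: 0.1
schedule:
  dt: 0.1
  n_steps: 4000
  titration_period: 20
  record_period: 2
  equilibration_cutoff: 25
ph_ladder:
  values: [3, 4, 5, 6]
  extend: true
window_ladder:
  start: 20
  stop: -12
  spacing: 2
  k: 1000
analysis:
  bin_width_A: 0.2
  scan_from: -12
  scan_to: 22
  stride: 0.25
  min_points: 50
  mono_slack: 0.02
  n_boot: 1000
  equilibration_cutoff: 25
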