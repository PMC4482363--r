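geometry:
  cell_radius: 10.0
  nucleus_radius: 4.0
  membrane_thickness: 0.2
motion:
  D: 1.0
  dt: 1.0
counts:
  scale_factor: 0.1
  bound_fraction: 0.6666667
  tilrr_fraction: 1.0
  endogenous_tilrr_fraction: 0.1
binding:
  regime: slow
  kon_radius: 0.065
  koff_per_min: 0.025
  slow_factor: 50.0
  release_level: active_90_100
  dissociator_radius_40: 0.034
  dissociator_radius_90: 0.1
  priming_radius: 0.56
  priming_hits: 40.0
  k_deact_adiss_per_min: 0.05
  dissociate_from_cytoskeleton: yes
  dissociate_from_nfkb: yes
  cytoskeleton_binding: yes
pathway:
  variant: wt
  low_high_ratio: 0.32
  r_myd88: 0.39
  r_pi3k: 0.39
  r_cascade: 0.067
  r_cascade_mid: 0.121
  r_tak_activation: 0.235
  r_ikk_activation: 0.162
  r_ras: 0.067
  r_akt: 0.121
  r_caspase: 0.235
  r_phospho: 0.184
  r_basal_phospho: 0.15
  r_assoc: 0.34
  r_nfkb_dissociator: 0.2
  r_import: 0.215
  r_export: 0.28
  r_tx_ikb: 0.12
  r_tx_il8: 0.03
  allow_ikb_import: yes
  ras_on_branch: pi3k
  k_deact_per_min: 0.2
  k_caspase_basal_per_min: 0.0333333
  tx_time_min: 20.0
  burst_ikb: 16.0
  burst_il8: 12.0
  tx_ikb_fraction: 0.5
  pikb_lag_min: 2.0
protocol:
  stim_start_min: 0.0
  stim_duration_min: 1000000.0
  dose: 1.0
run:
  duration_min: 60.0
  record_every_min: 1.0
  replicates: 3.0
  seed: 1.0
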