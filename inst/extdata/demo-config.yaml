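# Example generator configuration for a small demonstration cohort.
# Any field of cohort_config() can be overridden here; unspecified fields
# keep their defaults. Load with: load_config("demo-config.yaml", "cohort")
seed: 7
n_participants: 60
timeseries:
  enabled: true
  n_nodes: 24
  n_systems: 4
  frames_per_run: 164
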