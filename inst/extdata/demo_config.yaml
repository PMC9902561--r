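# Demo pipeline configuration: paired stack/control synthetic experiment
# at 15 pN, 3 replicates of 300 tethers per arm. Run with
#   Rscript inst/scripts/cfm-pipeline.R run --config demo_config.yaml
# or run_pipeline("demo_config.yaml") from R.
seed: 1
out_dir: cfmstack_demo_out
temperature_K: 294.15
force_pN: 15
frame_interval_s: 5
simulate:
  dG_stack: -1.5        # kcal/mol, ground truth encoded in the off-rate ratio
  control_rate: 0.02    # s^-1, no-stack arm off-rate at 15 pN
  n_tethers: 300
  n_replicates: 3
  duration_s: 3600
  stuck_fraction: 0.02
  slow_fraction: 0.01
  render_movies: false
track:
  theta: 0.5
  persistence: 3
  roi_scale: 1.5
  min_separation_px: 10
  sensitivity: 0.3
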