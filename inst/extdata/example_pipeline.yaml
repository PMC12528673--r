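# Example pipeline configuration. All keys mirror pipeline_config();
# anything omitted keeps the package default.
out_dir: cropsense_run
seed: 1
horizon: 30
scene:
  n_rows: 64
  n_cols: 64
  noise_sd: 0.01
weather:
  n_days: 1125           # 3 years of training plus the 30-day held-out tail
  start_date: "2024-01-01"
classifier:
  max_epochs: 30
forecaster:
  epochs: 50
evi:
  G: 2.5
  C1: 6.0
  C2: 7.5
  L: 1.0
ndvi_as_printed: false
rules: default
land_class_source: predicted
verbose: true
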