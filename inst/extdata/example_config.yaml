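# Example pipeline configuration for `kcsfcnet run --config ...`
# Keys mirror run_config(); preprocess/model mirror preprocess_config()
# and kcs_config(). Unknown keys are rejected.
n_subjects: 3
snr: [2, 1, 0.5]
seed: 1
n_folds: 5
test_fraction: 0.2
alpha: 0.05
percentile: 99
k: 3
perplexity: 10
preprocess:
  fs_target: 128
  band: [4, 40]
  filter_order: 5
  window: [0.5, 2.5]
model:
  n_filters: 2
  epochs: 500
  learning_rate: 0.001
  dropout_rate: 0.5
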