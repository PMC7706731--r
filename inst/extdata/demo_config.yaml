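# Demo configuration for `run_pipeline()` / `enhancerkit run`.
# Small enough to finish in a few minutes on one CPU.
seed: 42
out_dir: "enhancerkit_demo"
scale: "desk"
cohort:
  n_regions: 150
  region_length: 500
model:
  epochs: 4
thresholds:
  class_call: 0.5
  topic_binarize: 0.995
  bls_presence: 0
evolve:
  tree: "((human:0.05,dog:0.07):0.1,(mouse:0.12,fish:0.3):0.05);"
  motif_loss_rate: 0.15
interpret:
  n_regions: 15
  n_refs: 8
  n_steps: 8
fragments:
  depth: 50
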