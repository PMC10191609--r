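# Example run configuration for the tfgate command-line interface.
# Usage: Rscript inst/cli/tfgate.R simulate --config example_run.yaml
seed: 7
output_dir: tfgate_out
synthetic:
  n_cells: 2
  n_shared_pos: 200
  n_neg: 200
model:
  kmer_order: 2
  n_kernels: 16
  motif_width: 15
train:
  learning_rate: 0.001
  batch_size: 32
  max_epochs: 10
  patience: 5
interpret:
  top_k: 3
  stream: kmer
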