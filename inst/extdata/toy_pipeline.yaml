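# Toy end-to-end configuration: simulate a short movie of two
# morphological classes, segment it label-free, learn twin-VAE latents,
# cluster into states and estimate transition dynamics.
# Run with:
#   Rscript inst/scripts/run_pipeline.R --config inst/extdata/toy_pipeline.yaml \
#           --out toy_out --seed 5
seed: 5
simulate:
  enabled: true
  nCells: 10
  T: 8
  frameShape: [224, 224]
  minutesPerFrame: 3
labelfree:
  steps: 250
  nPatches: 1200
encoders:
  J: 8
  steps: 200
  hidden: [64, 16]
cluster:
  knn_k: 10
umap:
  n_neighbors: 10
dynamics:
  D0: 20
  D1: 15
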