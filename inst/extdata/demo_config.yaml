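# Demo pipeline configuration: simulate a small labelled synthetic dataset,
# train the dense-network quality classifier and write metrics + artifacts.
seed: 20260924
out_dir: trackqc_demo_output
simulate:
  n_images: 60
  fraction_adequate: 0.5
  width: 320
  height: 320
model: nn
target_precision: 0.97
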