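# Demo pipeline configuration: 6 MeV electron beam, small image, modest
# Monte Carlo statistics. Runs in well under five minutes.
beam: 6MeV
seed: 1
n_primaries: 800
image_size: [60, 46]
pixel_scale: 4
counts_scale: 20000
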