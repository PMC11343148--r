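n_genes: 50
isoforms_per_gene: 1
slope: 1.0
intercept: -2.0
clip_noise_sd: 0.5
clip_library_size: 50000.0
ribo_library_size: 50000.0
abund_meanlog: 3.0
abund_sdlog: 1.5
nb_dispersion: 0.05
frac_stringent: 0.2
frac_fmrp_down: 0.1
frac_fmrp_up: 0.1
beta_effect: 3.0
delta_down: -2.0
delta_up: 2.0
frac_ribo_up: 0.1
frac_ribo_down: 0.1
ribo_lfc_effect: 1.0
n_clip_reps: 4.0
n_ribo_reps: 3.0
include_markers: no
marker_enrichment: 2.0
pseudocount: 0.01
seed: 101
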