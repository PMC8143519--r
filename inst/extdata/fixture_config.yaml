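# Packaged synthetic fixture: single-tissue regeneration time course with
# planted premature-shift genes, sized for fast end-to-end runs.
seed: 7
simulate:
  n_genes: 400
  n_archetypes: 8
  tissues: [soft_tissue]
  frac_shifted: 0.1
  noise_sd: 0.25
  n_gene_sets: 10
  set_size_range: [15, 30]
params:
  clusters: 8
  n_perm: 200
  top_transitions: 2
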