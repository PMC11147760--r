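# demo pipeline configuration: a small synthetic run
seed: 1
sim:
  n_patients: 2
  cells_per_sample: 150
  tcells_per_sample: 60
  n_genes: 600
  n_programs: 4
  signature_size: 60
  lowq_signature_size: 10
  activation_size: 25
  tcell_response_size: 40
qc:
  min_genes: 50
  max_mito: 0.75
discovery:
  k_programs: 4
  n_hvgs: 300
  min_markers: 40
  max_mito: 0.20
  signature_n: 30
bulk:
  n_samples: 30
  noise_sd: 0.3
lr:
  n_pairs: 15
  complex_fraction: 0.3
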