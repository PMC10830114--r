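# Demo pipeline configuration: toy-scale genome, full stage structure.
seed: 1
sim:
  genome_length: 2.0e6
  n_cpg_clusters: 120
  n_true_dmrs: 12
  mean_depth: 18.6
  samples_per_group:
    WT: 3
    3aKO: 3
    3bKO: 3
    DKO: 3
comparisons:
  - a: WT
    b: 3aKO
  - a: WT
    b: 3bKO
  - a: WT
    b: DKO
dmr_params: {}
addback:
  ko: 3aKO
  levels: [0.0, 0.5, 1.0]
floxing:
  efficiency: 0.96
isoform:
  junction_depth: 200
psm:
  n_proteins: 80
  sample_shifts:
    S1: 0.5
    S2: 0.0
    S3: -0.5
    S4: 0.0
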