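# Demonstration run: small synthetic five-species ortholog set with the
# default planted pairs, full pipeline.
seed: 8
outlier_k: 3
pseudocount: auto
n_sets: 20
set_size: 5
control_pairs: [ATA-CGA, GCG-CGA]
simulate:
  n_species: 3
  n_genes: 40
  gene_length_range: [30, 60]
  occurrences: 5
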