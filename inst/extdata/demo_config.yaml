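# Small demonstration community for `skincat run`: two species, two bins
# each, two samples. Thresholds are left at the package defaults.
seed: 1
simulate:
  n_species: 2
  genome_length: 13100
  n_genes_per_genome: 5
  n_contigs: 2
  n_markers: 5
  n_samples: 2
  n_snvs: 80
  bgc_clusters_per_family: 2
  bgc_genes: 3
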