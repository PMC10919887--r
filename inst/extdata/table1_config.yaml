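# Standard four-set run configuration: forward-time ZW simulations on the
# default 1,678-bp two-exon locus.  Sets differ in the baseline
# recombination rate r0 and the chromosome count 2N.
n_replicates: 100
base_seed: 1
gene_model:
  total_length: 1678
  n_exons: 2
  exon_fraction: 0.5
  seed: 1
sets:
  Set1: {mu: 1.0e-8, r0: 1.0e-6, c: 0.03, pop_chromosomes: 100, generations: 100000}
  Set2: {mu: 1.0e-8, r0: 1.0e-8, c: 0.03, pop_chromosomes: 100, generations: 100000}
  Set3: {mu: 1.0e-8, r0: 1.0e-6, c: 0.03, pop_chromosomes: 10000, generations: 100000}
  Set4: {mu: 1.0e-8, r0: 1.0e-8, c: 0.03, pop_chromosomes: 10000, generations: 100000}
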