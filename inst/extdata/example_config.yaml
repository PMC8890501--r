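# Example pipeline configuration. Omitted keys use package defaults
# (the 7-position ribozyme library, 8 magnesium levels, 3 replicates).
out_dir: results/pipeline_run
seed: 42
stages: [simulate, fitness, topography, doseresponse, evolve]
write_fastq_files: false
eps: 0
generator:
  depth: 100000          # scaled down from the study depth for a quick run
  dead_fraction: 0.03
simulation:
  population_size: 1000
  mutation_rate: 0.01
  generations: 300
  replicates: 10
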