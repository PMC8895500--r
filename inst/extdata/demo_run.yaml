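# Demo run configuration: a small maternal-zygotic cross with one switching
# gene, one null gene, one sex-dimorphic ICR and the preset colony amplicons.
seed: 1
stages: [simulate, pscore, expression, methylation, colony]
thresholds:
  delta_pscore: 0.1
  alpha: 0.05
  fc: 0.5
  fc_sex: 0.3
  min_counts: 10
  min_tpm: 1.0
  min_site_reads: 3
design:
  - {genotype: "M+Z+", sex: "F", "n": 3}
  - {genotype: "M-Z+", sex: "F", "n": 3}
  - {genotype: "M-Z-", sex: "F", "n": 3}
  - {genotype: "M+Z+", sex: "M", "n": 3}
  - {genotype: "M-Z+", sex: "M", "n": 3}
  - {genotype: "M-Z-", sex: "M", "n": 3}
genes:
  - gene_id: switch_demo
    gene_length: 2000
    mean_expression: 300
    dispersion: 0.1
    snp_informative_fraction: 0.7
    allelic_concentration: 50
    paternal_fraction:
      - {genotype: "M+Z+", sex: "F", theta: 0.98}
      - {genotype: "M-Z+", sex: "F", theta: 0.75}
      - {genotype: "M-Z-", sex: "F", theta: 0.50}
      - {genotype: "M+Z+", sex: "M", theta: 0.98}
      - {genotype: "M-Z+", sex: "M", theta: 0.75}
      - {genotype: "M-Z-", sex: "M", theta: 0.50}
  - gene_id: null_demo
    gene_length: 1500
    mean_expression: 200
    dispersion: 0.1
    snp_informative_fraction: 0.7
    allelic_concentration: 50
    paternal_fraction: 0.5
icrs:
  - icr: {name: Rasgrf1, chrom: chr9, start: 89774439, end: 89774883,
          germline_origin: paternal}
    cpg_positions: [89774450, 89774472, 89774494, 89774516, 89774538,
                    89774560, 89774582, 89774604, 89774626, 89774648]
    methylated_allele_level:
      - {genotype: "M+Z+", sex: "F", level: 0.90}
      - {genotype: "M-Z+", sex: "F", level: 0.90}
      - {genotype: "M-Z-", sex: "F", level: 0.50}
      - {genotype: "M+Z+", sex: "M", level: 0.90}
      - {genotype: "M-Z+", sex: "M", level: 0.90}
      - {genotype: "M-Z-", sex: "M", level: 0.10}
    unmethylated_allele_level: 0.03
    read_depth: 30
    conversion_failure_rate: 0.005
    snp_informative_fraction: 0.6
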