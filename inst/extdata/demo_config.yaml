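# Demo configuration: six simulated tumor cohorts sharing three planted
# co-expression modules; the first module carries nine survival risk genes.
seed: 42
simulation:
  cancers: [GBM, BRCA, OVCA, COAD, READ, LUAD]
  samples_per_cancer: 120
  modules:
    - {size: 40, cancers: [GBM, BRCA, OVCA, COAD, READ, LUAD], cor: 0.8}
    - {size: 40, cancers: [GBM, BRCA, OVCA, COAD, READ, LUAD], cor: 0.7}
    - {size: 40, cancers: [GBM, BRCA, OVCA, COAD, READ, LUAD], cor: 0.7}
  n_background_genes: 180
  risk:
    module: M1
    n_genes: 9
    log_hazard_per_unit: 0.9162907   # ln(2.5) per unit of latent score
    baseline_hazard: 0.00094951      # ln(2)/730: median 2 years at score 0
    censoring_rate: 0.2
network:
  power: 6            # or "auto" for the scale-free fit selection
  mode: unsigned
  min_module_size: 30
  cut_height: auto    # static cut at 1 - TOM = 0.99
preservation:
  n_perm: 50
  required_class: strong
  overlap_p: 0.05
hubs:
  edge_threshold: 0.02
  min_degree: 10
risk:
  p_threshold: 0.01
  threshold_years: 2
  allowed_outliers: 0
panel:
  n_individual: 3
resample:
  n_rd: 100
  rd_size: 60
  alpha: 0.05
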