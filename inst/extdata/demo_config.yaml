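# Demo pipeline configuration: a small inbred panel with planted DMRs of
# both genetic (cis-SNP-controlled) and purely epigenetic kinds, plus two
# causal chains for the Mendelian-randomization stage.
population:
  n_lines: 60
  subgroup_proportions: {SS: 0.25, NSS: 0.40, TST: 0.35}
  n_snps: 300
  n_chromosomes: 2
  chromosome_length: 5.0e+6
  divergence: 0.15
  maf_floor: 0.05
  seed: 1
dmrs:
  - {n_regions: 4, contexts: [CG], kind: genetic_cis, mef_target: 0.3}
  - {n_regions: 4, contexts: [CG], kind: pure_epigenetic, mef_target: 0.2}
  - {n_regions: 2, contexts: [CHH], kind: pure_epigenetic, mef_target: 0.3}
  - {n_regions: 2, contexts: [CG], kind: tissue_stable_background}
chains:
  - {n_genes: 2, direction_model: causal, beta_dmr_on_expr: 1.5, noise_sd: 0.3}
  - {n_genes: 2, direction_model: consequential, beta_snp_on_dmr: 0.5,
     beta_dmr_on_expr: 0.2, noise_sd: 0.3}
contexts: [CG, CHH]
alpha_mqtl: 0.05
alpha_trait: 0.01
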