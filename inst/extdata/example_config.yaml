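# Example hologwas run configuration.
#
# `hologwas simulate --config <this file> --out data/` writes a synthetic
# dataset to the paths under `inputs`; `hologwas all --config <this file>`
# then runs the full pipeline on it.
inputs:
  genotypes: data/genotypes        # PLINK prefix (or .vcf / dosage .tsv)
  otus: data/otus.tsv              # samples x OTUs relative abundances
  phenotypes: data/phenotypes.tsv  # first column = sample ID
models:
  - GWAS
  - M-GWAS
  - HWAS-CG
  - HWAS-H
qc:
  maf_min: 0.05
  cr_min: 0.95
  otu_prevalence_min: 0.2
covariates:
  n_pcs: 0            # genotype PCs added as fixed covariates
kernels:
  center_otus: true
  pseudocount: auto
  pd_policy: jitter
thresholds:
  alpha: 0.05
  gwst_mode: none     # none | permutation | fixed
  gwst_T: 1000
simulate:             # used by the `simulate` subcommand
  "n": 300            # quoted: bare n is a YAML 1.1 boolean
  q: 2000
  p: 200
  var_fractions: [0.3, 0.2, 0.1, 0.4]
  n_causal: 1
  causal_effect: 0.6
  architecture: HWAS-H
seed: 42
out_dir: hologwas_run
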