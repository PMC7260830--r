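# signetmod

Network-level association of mutational-signature exposures with gene
expression modules and mutated subnetworks.

## What problem this solves

The strength of a mutational signature in a tumor — the number of mutations
attributed to that signature, optionally split into clustered ("cloud", C)
and dispersed (D) contexts — can be treated as a continuous phenotype of the
patient. For cancer genomicists asking *what drives a mutagenic process*,
this package answers two complementary questions on a cohort:

1. **Expression side** — which gene modules have expression correlated with a
   signature's exposure? Genes are screened by Spearman correlation
   (|ρ| ≥ 0.3, BH-adjusted p ≤ 0.005 against at least one signature-context
   phenotype), their correlation profiles are clustered by consensus K-means
   (100 runs, k cycled over a range, average-linkage cut of the consensus
   matrix), and clusters are annotated by hypergeometric gene-set enrichment
   — including a restricted mode for focus sets such as DNA-metabolic genes.

2. **Alteration side** — which connected subnetworks, altered in a mutually
   exclusive fashion, associate with the exposure? For a gene set *S* with
   per-patient coverage counts *c_j* and phenotype z-scores *w_j*, the
   objective is

   ```
   Σ_{j : c_j ≥ 1} w_j  −  λ · Σ_j max(0, c_j − 1) · |w_j|
   ```

   maximized over sets of size exactly k that are connected in a
   confidence-thresholded interaction network (score ≥ 900/1000) and have
   induced edge density ≥ 0.5. The search is an exact branch-and-bound
   (C++), with phenotype-permutation p-values (+1 corrected), a 5%-increase
   rule to choose k, BH/FDR control across the tested signature-contexts,
   and per-gene robustness across attribution reruns.

Upstream of both, mutations are attributed to a fixed signature catalog by a
per-patient multinomial-mixture EM (majority vote over 31 random restarts),
split into cloud/dispersed by inter-mutation distance, filtered to abundant
signature-contexts (> 10% share within their group), and turned into
phenotypes as z-scores of log10 counts. A synthetic-data generator
(`simulate_study()`) produces every input with planted, retained ground
truth, so the whole chain is testable without external data.

## Worked example

Plant a connected 4-gene module whose mutually exclusive alterations shift a
continuous phenotype, then recover it:

```r
library(signetmod)

cfg <- simulation_config(seed = 42)          # 200 patients, 50 genes, 4-gene module
net <- generate_network(cfg$n_genes, cfg$edge_density, cfg$planted_module,
                        seed = cfg$seed)
sim <- generate_alterations_and_phenotype(cfg, net)

sol <- find_best_module(sim$alterations, sim$phenotype, net,
                        objective_config(k = 4))
print(sol)
#> module_solution: {g0001, g0002, g0003, g0004}
#>  objective 52.57195, density 0.5, connected TRUE

pt <- permutation_test(sim$alterations, sim$phenotype, net,
                       objective_config(k = 4), N = 99, seed = 1,
                       observed = sol)
pt$p
#> [1] 0.01
```

The search returns exactly the planted module (`cfg$planted_module`), with a
proven-optimal objective of 52.57: the sum of phenotype z-scores over covered
patients minus the exclusivity penalty for the ~10% of covered patients
carrying two module alterations. No permuted phenotype reaches the observed
objective, so the empirical p is its floor, 1/(99+1) = 0.01.

## The analysis workflow

`analysis/` contains the numbered drivers of the full study on a synthetic
cohort (200 patients, 60 genes, 4 signatures, three planted expression
modules at Spearman 0.6, one planted alteration module at effect 2.0):

```sh
Rscript analysis/01_simulate.R              # cohort + truth under results/data/
Rscript analysis/02_signature_phenotypes.R  # attribution, exposures, phenotypes
Rscript analysis/03_expression_modules.R    # correlation, consensus clusters, enrichment
Rscript analysis/04_network_modules.R       # subnetwork search, permutation, FDR
Rscript analysis/05_report.R                # collated results/report.json
```

Each stage prints what it found and writes plain TSV/JSON under `results/`.
On this cohort the expression clustering recovers the three planted modules
at adjusted Rand index 1.0; the subnetwork search at the planted size k = 4
returns exactly the planted genes (permutation p = 0.0099), while the
5%-increase rule settles on the 3-gene core whose marginal coverage is
substantial; and none of the 8 exposure phenotypes — which the generator does
not couple to alterations — yields an FDR-significant module.

File-based orchestration for external data is available via
`run_pipeline(input_dir, out_dir, config)`; see `?run_pipeline` and the
vignette (`vignettes/signature-network-associations.Rmd`) for the model,
parameter meanings and design choices.

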