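---
title: "Associating mutational-signature exposures with expression modules and mutated subnetworks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Associating mutational-signature exposures with expression modules and mutated subnetworks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signetmod)
```

## The question

Mutational signatures are characteristic distributions over the 96
trinucleotide-context single-base-substitution channels, each linked (more or
less confidently) to a mutagenic process: spontaneous deamination of
5-methylcytosine, APOBEC cytosine deamination, homologous-recombination
deficiency, and so on. For an individual tumor, the *exposure* to a signature
— the number of its mutations attributed to that signature — measures how
strongly that process has acted on the genome. `signetmod` treats these
exposures as continuous cancer phenotypes and asks two complementary
questions:

1. Which **gene-expression modules** correlate with an exposure? (Clusters of
   genes whose expression tracks a mutagenic process hint at transcriptional
   programs coupled to it.)
2. Which **connected, mutually exclusively altered subnetworks** associate
   with an exposure? (If a repair pathway's inactivation causes a signature,
   different patients should carry different single hits in that pathway, and
   carrying any hit should coincide with high exposure.)

Because mutations in close genomic proximity ("cloud" mutations, as in
kataegis) behave differently from isolated ("dispersed") ones, each
signature's exposure is split into a cloud (C) and a dispersed (D) context,
and each abundant signature-context becomes its own phenotype.

## Phenotype construction

**Cloud/dispersed split.** A mutation is a cloud mutation iff it has a
same-sample, same-chromosome neighbor within a distance threshold
(`split_cloud_dispersed()`, default 1000 bp). The threshold is configurable;
1000 bp is of the order of the inter-mutation distances used to call
clustered mutation events, and any threshold that separates the two spacing
regimes gives identical labels on data with a clear gap, which is what the
generator produces and what tests verify.

**Attribution.** Each patient's SNV channel counts are fit with a
multinomial mixture over a fixed signature catalog by EM
(`attribute_mutations()`). With fixed component distributions the
log-likelihood is concave in the mixture weights, so restarts agree in the
limit; we nevertheless run 31 random initializations and take the majority
per-mutation assignment (maximum-posterior signature per channel), which also
guards against premature convergence on flat likelihoods. Sequential
dependency between nearby mutations is deliberately **not** modeled: cloud
mutations are attributed with the same per-patient mixture as dispersed
ones. This is a simplification relative to hidden-Markov treatments of
clustered mutations; it keeps the attribution a well-understood convex
problem and is sufficient for exposure phenotypes, which aggregate over many
mutations.

**Exposure table and abundance filter.** Counts are tabulated per patient and
signature-context label ("2C", "13D", ...). A label is carried forward iff
its signature's share of all mutations *within its context group* strictly
exceeds 10% (`filter_abundant()`). The per-group reading (share of C among
C, share of D among D) is what allows a signature to be abundant in one
context but not the other.

**Phenotype transform.** Exposure counts are heavy-tailed, so the phenotype
is `z(log10(count + 1))` with the sample (n−1) standard deviation
(`make_phenotype()`). The paper-style pipeline only requires *some* monotone
variance-stabilizing transform: Spearman correlation is invariant to it, and
the subnetwork objective uses the z-scores only through sums, where the log
tames outliers. Base, pseudocount and the sd convention are recorded as
attributes on every phenotype vector. Zero-variance counts are an error —
the phenotype is undefined, not silently constant.

## Expression modules

`correlate()` computes the Spearman correlation of every gene with every
phenotype over their shared patients (at least 3 required), with two-sided
p-values from the t approximation on the rank correlation, and
Benjamini–Hochberg adjustment **jointly across all gene × phenotype pairs**.
The joint scope is the conservative reading of "BH-corrected"; a
per-phenotype scope is available via `adjust_scope`. Genes with constant
expression have no defined rank correlation; they are flagged in `dropped`
and excluded.

`select_genes()` keeps genes with `|rho| >= 0.3` and adjusted `p <= 0.005`
for at least one phenotype. Under a global null (no planted correlation)
these defaults retain essentially nothing — an empirical-FDR property the
test suite checks with the generator.

`consensus_cluster()` runs K-means 100 times on the selected genes'
correlation-profile rows. The number of clusters k cycles **round-robin**
through a range (5–50 for a transcriptome-scale run; 2–20 for a restricted
focus set) so the range is covered evenly — the even coverage is our choice
where a protocol is otherwise unspecified. The consensus matrix (fraction of
runs co-clustering each gene pair) is then cut by average-linkage
hierarchical clustering of `1 − consensus` into `final_k` clusters.
Average linkage is the standard consensus-clustering choice; the linkage is
recorded in the result. `final_k` is a user decision, not automatic: the
dendrogram rarely dictates a unique cut, and downstream interpretation (one
row per cluster in the mean-correlation heatmap) is what fixes the
granularity. When k equals the number of distinct profile rows the optimal
partition is computed directly (one cluster per distinct point) rather than
by Lloyd iterations.

`enrich()` is an upper-tail hypergeometric test of a cluster against an
annotation set within an explicit background, reported at nominal p < 0.05.
In restricted mode (`enrich_clusters(..., focus_set = )`) the background is
the focus set and a term is tested only if it shares ≥ 2 genes with the
focus set and the intersection itself is hypergeometrically surprising
(p < 0.05) against the full universe — this keeps huge generic terms from
piggy-backing on a restricted analysis.

## Alteration matrices

`build_matrix()` marks a patient altered in a gene iff the patient has at
least one **non-silent** mutation in the gene — excluding mutations
attributed to the *target* signature — or the (patient, gene) pair is
annotated as biallelically inactivated. Three deliberate choices:

* The exclusion removes **both** C and D attributions of the target's
  underlying COSMIC signature, whichever context is the phenotype. Excluding
  the phenotype's own mutations blocks the trivial reverse-causal loop
  (process X mutates gene g, so g "associates" with X).
* Indels are removed by default exactly when the underlying signature is 3
  or 8, which are believed to produce a high indel burden (overridable).
  Indels carry no substitution channel and are never signature-attributed,
  so without this rule they always survive the exclusion.
* Consequence calls (silent/non-silent) are taken from the input; no
  annotation engine is embedded.

Genes altered in under 1% of patients are removed. `subset_samples()`
re-applies the frequency floor after subsetting (e.g. per molecular
subtype), so gene inclusion can flip with the cohort. Biallelic annotations
bypass both the exclusion and the indel rule — they are not mutations.

## The subnetwork search

For a gene set S, with `c_j` the number of genes of S altered in patient j
and `w_j` the phenotype z-score, the objective
(`score_module()`) is

    sum_{j : c_j >= 1} w_j  −  λ · sum_j max(0, c_j − 1) · |w_j|

The first term rewards covering high-phenotype patients (covering a
low-phenotype patient costs, since their `w_j` is negative). The second term
is the mutual-exclusivity penalty: every *redundant* alteration of an
already-covered patient is charged λ times the phenotype magnitude. λ
defaults to 1 and is recorded in every solution. Only the positive direction
is searched; negate the phenotype for the other tail.

`find_best_module()` maximizes this over gene sets of size exactly k that
are **connected** in the interaction network (edges thresholded at
confidence ≥ 900/1000) and whose induced subgraph has edge density ≥ 0.5.
Density does not imply connectivity for k ≥ 4, so both are enforced. The
search is an exact branch-and-bound written in C++: connected induced
subgraphs are enumerated exactly once by the rooted-extension (ESU) scheme,
and partial sets are pruned with the admissible bound *current score + sum
of positive w over still-uncovered patients* — valid because growing a set
can only add coverage and deepen penalties. We chose this exact
combinatorial formulation over a mixed-integer program: it needs no solver
dependency, returns proven optima on the problem sizes the method targets
(networks restricted to recurrently altered genes, k ≤ 7), and its
correctness is checkable against a brute-force enumerator
(`enumerate_oracle()`), which the test suite does on hundreds of random
instances. A time limit (default 600 s) returns the best incumbent flagged
`proven_optimal = FALSE`. Ties are broken toward the lexicographically
smallest gene set, so results are deterministic. Every solution is
re-validated independently of the search (`validate_solution()`): size,
connectivity, density and objective are recomputed from the inputs.

## Significance, module size, and robustness

`permutation_test()` permutes the phenotype values across patients and
re-runs the **full** optimization per permutation; the empirical p-value
uses the +1 correction, `p = (1 + #{permuted ≥ observed}) / (1 + N)`, so it
is never 0 and its granularity (1/(N+1)) is explicit. N defaults to 100 —
enough to resolve the 0.1 FDR threshold across ten-odd phenotypes while
keeping a full per-k scan affordable; raise it for sharper p-values.

`select_k()` chooses the largest k such that for **every** step 2..k the
optimal objective grew by more than 5% and the permutation p-value did not
increase; if no k ≥ 2 qualifies, k = 1. Boundary conventions: a tie in p
counts as "did not increase" (allowed); a tie in objective fails the 5%
rule. The rule is invariant to uniform positive rescaling of objectives. In
practice it selects a tight core: a planted gene whose marginal coverage is
thin (it covers few patients the rest of the module misses) can be left out
at the chosen k while still appearing at k+1 — the per-k table is always
reported so this is visible.

`fdr_significance()` applies BH across the family of signature-context
phenotypes tested in one run and flags modules with adjusted p < 0.1.
`robustness()` reports, per gene, the fraction of attribution reruns (the
EM seed perturbs assignments, hence the exclusion filter, hence the matrix)
whose selected module contains the gene; `gene_association_p()` gives each
module gene a single-gene empirical association p-value.

## The synthetic cohort: what it does and does not emulate

`simulate_study()` generates every input the pipeline reads, with ground
truth retained:

* **Exposures and catalogs**: per patient, each signature's mutation count is
  Poisson with an independent log-normal activity multiplier
  (`exposure_dispersion`, default 0.5) — heterogeneity in process activity
  across patients, independent across processes. Channels are drawn from the
  signature's multinomial. Synthetic catalogs are Dirichlet draws
  (spiky at the default concentration 0.3), optionally with disjoint
  supports for unambiguous attribution tests.
* **Cloud geometry**: clouds are runs of 2–10 mutations spaced uniformly
  below `cloud_spacing_bp`; everything else is spaced at 10× that. Real
  kataegis geometry is richer; any geometry separable by a distance
  threshold suffices to test the split, which is the point.
* **Alterations and phenotype**: a connected planted module (its spanning
  tree is forced into the network, topped up to the 0.5 density floor)
  covers a `module_coverage` fraction of patients (default 0.3 — the config
  needs an explicit coverage rate for the module to cover anyone; 30% is a
  typical pathway-alteration frequency in a driver-enriched cohort).
  Covered patients get exactly one altered module gene with probability
  `exclusivity`, otherwise two, and a phenotype mean shift of
  `module_effect` on the log scale; Gaussian noise is added on that scale
  and the phenotype is z-scored. Background genes are altered i.i.d. at
  `background_alteration_rate`.
* **Expression**: module genes are `scaled rank(exposure) + noise`, with the
  noise SD set from the target Spearman correlation
  (`sd = sqrt(1/rho² − 1)`, the rank-scale Pearson identity, accurate to a
  few percent for Spearman at these magnitudes); other genes are pure noise.

Not emulated: real genome coordinates, replication timing, trinucleotide
content of a reference genome, copy number, expression covariance structure
beyond the planted modules, or coupling between the alteration module and
the signature exposures (the planted phenotype is its own vector). Passing
tests therefore demonstrate that the machinery recovers structure *of the
kind the model assumes*, at realistic noise — not that the model captures
everything in real cohorts.

## Verification at a glance

The test suite checks, among others: exact agreement of the branch-and-bound
with brute-force enumeration on 100+ random instances (≤ 15 genes, k ≤ 4);
exact recovery of a planted 4-gene module (effect 2.0, exclusivity 0.9,
200 patients, 2% background) in ≥ 90% of 20 seeds; calibration of the
permutation p under a null generator (50 replicates of a 15-gene,
40-patient instance at N = 99: the fraction of p ≤ 0.05 stays in
[0.01, 0.10]); recovery of three planted expression modules at Spearman 0.6
with mean adjusted Rand index ≥ 0.9 over 10 seeds; EM recovery of a 70/30
two-signature mixture from 1000 mutations within ±0.05; and a set of exact
closed-form identities (hypergeometric tail 6/252, BH on [.01,.02,.03,.04],
the log10 z-transform of [9, 99, 999], path density 2/3, permutation
p = 1/100). These problem sizes were chosen so the whole suite runs in well
under a minute per property while keeping Monte-Carlo error comfortably
inside the asserted margins.

## Known limitations

* The exclusivity-penalized objective is one defensible functional form of
  "coverage with mutual exclusivity"; published ILP formulations differ in
  detail, and results are only comparable at the level of the stated
  objective.
* Exact search scales exponentially in the worst case; it is intended for
  networks already restricted to recurrently altered genes. The time limit
  and incumbent flag make the failure mode explicit rather than silent.
* Attribution ignores sequential dependency between nearby mutations, which
  can misattribute individual cloud mutations even when exposures are
  accurate.
* Permutation p-values have granularity 1/(N+1); FDR decisions near the
  threshold need larger N.
* Gene identifiers are opaque strings; harmonizing identifiers across
  expression, mutation and network inputs is the caller's responsibility
  (mismatches are dropped by intersection and logged).
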