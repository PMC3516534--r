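---
title: "Methods: multi-evidence crosstalk discovery between two gene systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-evidence crosstalk discovery between two gene systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(internode)
```

# The problem and the model

Two biological systems — in the motivating application, the insulin
signalling cascade (a curated parts list of ~200 genes) and the
mitochondrial proteome (~700 genes) — are suspected to communicate through
genes that belong to neither but interact with both. `internode` formalizes
this as a two-stage construction over a *functional interactome*: an
undirected graph over gene symbols in which each edge carries a multiset of
evidence records from heterogeneous sources.

**Evidence sources and filters.** Each source contributes edges only after
its own quality filter:

* `PPIhigh` — protein–protein interactions reported independently by at
  least `min_labs = 2` laboratories, both genes expressed (boolean call) in
  at least one of four insulin-sensitive tissues (adipose, muscle, liver,
  heart). The lab count is the replication unit because screening artefacts
  are laboratory-correlated.
* `PPIcorr` — single-laboratory PPIs rescued when both genes are
  tissue-expressed *and* their profiles across a reference co-expression
  compendium correlate significantly at Benjamini–Hochberg FDR < 0.05
  (Pearson by default, Spearman available). The source studies leave both
  the statistic and the cutoff unstated; we chose the standard test with the
  threshold exposed as `corr_fdr_alpha`, and both correlation signs qualify
  since negative co-regulation is still functional coupling. Genes absent
  from the compendium cannot gain rescue — passing silently by default would
  let the least-measured genes through the weakest filter.
* `COMPLEX` — clique expansion of complex memberships; a pair sharing *k*
  complexes carries *k* records, because shared membership in independent
  complexes is independent evidence.
* `MET_adj` — gene pairs catalysing metabolic reactions that share at least
  one metabolite not on a currency list (default: ATP, ADP, AMP, NAD(H),
  NADP(H), H₂O, H⁺, CO₂, Pi, CoA). Direction is ignored. Without the
  exclusion, currency metabolites connect nearly every enzyme pair; the
  list is configurable since its boundary is a judgement call.
* `PATH` — pathway co-membership relations, de-duplicated per pathway.

**Internodes.** Given parts lists *A* and *B*, a gene *g ∉ A ∪ B* is an
*internode* when it has ≥1 edge to each system. Each record tallies distinct
partners (`links`) and evidence records (`evid`) per system, so
`evid ≥ links` always. Ranking is by total evidence, then total links, then
symbol — fully deterministic. Genes appearing in *both* parts lists (possible
with curated inputs) are system members, not linkers: they are excluded from
candidacy with a warning and count for either side of direct links. The
high-confidence subset keeps records with ≥3 evidence records per system
(`min_evidence`), the threshold used to define the published 31-gene
candidate table that ships as a fixture (`table1_fixture()`).

**Indirect connectivity.** "How connected is system-A gene *a* to system
B?" is answered by counting distinct (internode, *b* ∈ B) pairs bridged
through length-2 paths. The published analyses report per-source indirect
contributions in units that differ between sentences (per-pair vs
per-evidence accounting); `build_crosstalk()` therefore reports **both**
tallies in `$contributions`.

# Evaluation layers

**Signature over-representation.** For a query set of size *K* in a
universe of size *N* (the interactome's gene universe), each gene set of
size *n* with overlap *k* forms the 2×2 table [[k, K−k], [n−k, N−K−n+k]],
tested by Pearson chi-square *without* continuity correction (Fisher's
exact test available for small tables). Sets with k < 10 (`min_overlap`)
are excluded from testing *and* from the Bonferroni denominator, which is
computed from the data: the source study's printed threshold (4.41×10⁻⁶) is
inconsistent with 0.05 divided by its printed collection size, so no fixed
denominator is hard-coded. Zero cells fall back to Haldane-corrected odds
ratios, flagged in the output.

**Expression GSEA.** Genes are ranked by signal-to-noise
(μ₁−μ₀)/(σ₁+σ₀) with each σ floored at 0.2·|μ| and 0.2 absolute (the
floor keeps near-constant probes from dominating; Welch *t* available);
ties break alphabetically so rankings are strict. The enrichment score is
the signed maximum of the weighted running sum (hits add |stat|^w
normalized over hits, default w = 1; misses subtract 1/(N−n_hits)).
Significance is sign-restricted: p compares |ES| only against same-sign
permutation scores with add-one smoothing, NES divides ES by the mean
|same-sign null ES|, and the FDR q compares same-sign tail fractions of
null and observed NES. Label permutation (preserving gene–gene correlation)
is used when both groups have ≥7 samples, set-size-matched gene permutation
otherwise. A set with no same-sign null scores gets p = 1 and a flag rather
than a fabricated value.

**GWAS gene scores.** SNPs map to a gene when they lie within
`window_bp = 500000` of its extreme transcript boundaries (1-based
inclusive; BED input is converted explicitly — the dialect is declared,
never sniffed, because silent off-by-one errors are the classic failure
here). A gene's raw score is −log₁₀ of its best SNP p-value (ties →
lowest position); the corrected score is the least-squares residual on
log₁₀(gene length + 2·window) and log₁₀(SNP count). This residualization
is a deliberate simplification of MAGENTA's confounder correction: no LD
panel is consumed, so SNP count stands in for the number of independent
SNPs, and the regression accepts extra covariate columns when better
confounders are available. Enrichment above the 95th percentile
(`percentile_cutoff`, strictly above the empirical quantile, ties
excluded) is judged against `n_sim = 10000` size-matched random sets from
the *scored* universe; genes with no mapped SNP leave both the set and the
sampling universe. No HLA exclusion is applied by default (flag provided).

**Risk score.** For a panel of LD-independent SNPs oriented to the
risk-increasing allele, the effect of the unweighted allele-count score on
the trait is estimable from summary statistics alone. With weights wⱼ the
pooled effect is β̂ = Σwⱼβⱼ/Σwⱼ and se = √(Σwⱼ²seⱼ²)/Σwⱼ. The default
wⱼ = 1/seⱼ² is what makes the summary-level estimator coincide with the
individual-level regression of the trait on the allele-count score under
linkage equilibrium (var(gⱼ) ∝ 1/seⱼ²); the description in the source text
("the inverse of the standard error") is ambiguous because its formula
images did not render, so wⱼ = 1/seⱼ is also implemented behind a config
key, with the parameter-recovery test pinned to the default. SNPs with
β = 0 have no defined risk direction; they are kept and flagged.

**Null machinery.** Network nulls use degree-preserving double-edge swaps
(default 10× the edge count, no self-loops or multi-edges, evidence
replaced by one synthetic `RANDOM` record per pair); the source text says
only "randomly generated interactions", so a density-matched Erdős–Rényi
mode is provided as an alternative, with degree-preserving as default since
hub structure drives internode counts. Empirical p-values are add-one
smoothed, (b+1)/(n+1), never exactly zero at finite n; the raw frequency
is reported alongside for comparability with frequency-style published
values. Compound extremeness ("null p smaller AND effect positive") is
supported through predicate functions. Every randomized operation requires
an explicit seed; no global RNG state is consumed or mutated.

# What the generators emulate — and what they do not

`gen_interactome()` plants two systems, linker genes wired to both, and
background genes wired to one, spreading evidence over all five sources and
emitting every raw input table (PPIs with lab counts, complexes, reactions,
pathways, tissue calls, a co-expression matrix in which planted `PPIcorr`
pairs share a latent factor against σ = 0.2 noise over 200 samples) plus
decoy PPIs designed to be removed by the filters. `gen_expression()` plants
signed mean shifts (in σ units) on signal sets over iid normal baselines.
`gen_sumstats()` simulates LD-free genotypes Binomial(2, maf), a linear
phenotype with standard normal noise, and per-SNP marginal OLS; gene regions
are spaced 2 Mb apart so 500 kb windows never overlap, and the ledger
records each SNP's gene, the causal SNPs, and an individual-level regression
oracle for the risk score.

These generators deliberately omit: linkage disequilibrium (every
downstream method assumes linkage equilibrium, so an LD mode would test
nothing the methods claim), microarray noise models, probe-level effects,
scale-free degree distributions, and human genome coordinates. Passing
tests therefore demonstrate correctness of the algorithms under their own
assumptions — not robustness to LD, batch effects or annotation error in
real data.

Default simulation sizes (8 planted internodes over ~70 genes; 18-SNP
panels at n = 5000 individuals; 2000-gene expression matrices at 12
samples/group with 1000 permutations) were chosen as the smallest problems
at which the planted structure is unambiguous and the estimators operate in
their intended regime.

# Numerical choices and degenerate inputs

* Pair keys are lexicographically canonicalized; all outputs are sorted
  deterministically, so equal inputs give byte-identical outputs.
* Quantile cutoffs use R's default empirical quantile (type 7); counting is
  strictly above the cutoff value.
* A single scored gene cannot be residualized: the corrected score falls
  back to the raw score with a message. Constant confounder columns are
  dropped from the regression.
* Zero-variance expression groups are handled by the σ floor; an ES is
  undefined when a set covers all ranked genes (no miss steps) — that is an
  error, not a silent 0.
* Empty interactomes, empty null draws, windows < 0, se ≤ 0, p ∉ (0,1] and
  duplicate SNP ids are errors with row context, caught at read time.

# Known limitations

* Gene identity is plain uppercase symbols; no ortholog or identifier
  mapping is performed.
* The confounder correction is a documented simplification of MAGENTA's
  (no LD-based covariates), so absolute gene scores are not comparable to
  MAGENTA's — only the enrichment machinery around them is.
* The published headline numbers that depend on proprietary consortium data
  (the 886-gene network, the 18-vs-12 enrichment, the fasting-glucose risk
  score p-value) are not reproducible from this package; the packaged
  candidate table and the synthetic ledgers define what is checked instead.
* `empirical_p` is exchangeable-sampling based; covariate-matched null gene
  sets are out of scope.
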