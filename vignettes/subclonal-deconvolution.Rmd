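---
title: "Subclonal deconvolution and clone-tree reconstruction with clonephylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subclonal deconvolution and clone-tree reconstruction with clonephylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

clonephylo reconstructs the clonal architecture of a tumour from somatic SNV
read counts observed in several samples of the same patient — multi-region
biopsies or multiple metastases. This vignette is the package's account of
the underlying models, the choices that were genuinely open, and what the
bundled simulations do and do not demonstrate.

## The quantities

For an SNV observed with `alt` mutant reads out of `depth` at a locus with
tumour copy number $CN_t$ (major allele $CN_{maj}$), in a sample of purity
$\rho$, the expected variant allele frequency of a mutation carried by a
fraction $CCF$ of tumour cells on $m$ chromosomal copies is

$$ E[VAF] = \frac{m \cdot CCF \cdot \rho}{\rho\,CN_t + (1-\rho)\,CN_n}, $$

with $CN_n = 2$ on autosomes (sex chromosomes are excluded by default).
`expected_vaf()` is this forward model; `mutation_copy_number()` is its
inverse, giving $n_{mut} = m \cdot CCF$ from an observed VAF. The remaining
unknown, the multiplicity $m$, is chosen by binomial maximum likelihood
(`assign_multiplicity()`): $m$ ranges over $1..CN_{maj}$ — an SNV cannot
occupy more copies than the major allele — and the $m$ whose clonal
expectation best explains `alt` of `depth` wins. The CCF estimate is then
$n_{mut}/m$.

### Numerical policies

Read-count noise puts some estimates above 1. Values in $(1, 1.5]$ are
clipped to 1 and flagged `capped` — they are consistent with a clonal
mutation at this depth and keep the truncal peak at 1 — while values above
1.5 are flagged `implausible` and excluded from clustering, since no
plausible configuration of a correctly genotyped diploid-locus SNV reaches
them. Cells with fewer than 10 reads are flagged `low_depth` but retained
(the binomial likelihood already down-weights them); only cells with no
usable information (depth 0, or no covering copy-number segment) leave the
likelihood. Note that capping makes the *mean* of capped CCFs a biased
estimator near 1; where an unbiased cluster-level average is needed, average
`mutation_cn / multiplicity` instead, which the recovery tests do.

### Purity without copy number

For targeted data with no reliable copy-number calls
(`ccf_assuming_diploid()`), analysis is restricted to loci diploid in all
informative samples and purity is taken from the VAF density: a Gaussian
kernel density (Silverman's rule-of-thumb bandwidth, 512-point grid on
$[0,1]$) is fitted to the VAFs, and among its strict local maxima the peak at
the highest VAF is declared clonal, so purity $= \min(1, 2 \cdot
VAF_{peak})$. Choosing the highest-VAF peak rather than the tallest protects
the estimate when subclonal mutations outnumber clonal ones.

## Pseudo-heterogeneity filtering

Presence/absence differences between samples are only evidence of clonal
structure if copy number cannot explain them. Two filters run before
clustering:

* `cna_consistent_loci()` keeps an SNV only when the allele-specific state
  (major, minor) at its locus is identical across samples; uncovered loci
  are removed as ambiguous.
* `filter_pseudo_heterogeneity()` removes an SNV that is effectively absent
  in some sample (CCF < 0.05 *and* at most 1 supporting read — the joint
  condition resists depth noise) whenever that sample shows LOH or any total
  copy-number decrease relative to every SNV-bearing sample. The test is
  deliberately conservative: if deletion *could* explain the loss, the SNV
  is discarded rather than risk manufacturing heterogeneity.

Both report per-SNV reason codes and are idempotent.

## The clustering model

SNVs are clustered jointly across samples with a Dirichlet-process binomial
mixture (`run_gibbs()`). A component $k$ is a point in CCF space, one
coordinate $\theta_{ks}$ per sample; an SNV assigned to it contributes
$alt_{is} \sim \mathrm{Binom}(depth_{is},\ \theta_{ks} \cdot c_{is})$ in each
sample, where $c_{is}$ is the purity/copy-number factor above with
$CCF = 1$. Working on raw read counts rather than Gaussian-smoothed CCF
points weights deep sites more than shallow ones and handles the highly
non-Gaussian error of low-coverage cells for free; CCF point estimates are
used only to initialise (k-means) and to report.

Inference is Gibbs sampling under a truncated stick-breaking representation:

* truncation at 30 components — comfortably above the handful of clusters
  seen in practice;
* concentration $\alpha \sim \mathrm{Gamma}(1,1)$, resampled every sweep;
* component locations on independent $\mathrm{Uniform}(0, 1.2)$ priors;
  allowing mild super-clonal mass stops the truncal component being squeezed
  against the boundary, and summaries cap reported locations into $[0,1]$;
* locations resampled by griddy Gibbs on a 0.02-step grid — the grid makes
  each conditional draw exact up to discretisation, mixes far better than a
  random-walk step, and its cost collapses because the conversion factors
  $c_{is}$ take few distinct values per sample;
* defaults of 2,000 sweeps, 1,000 burn-in, thinning 10 (all configurable in
  `cluster_config()`). On the simulated data the posterior is sharply
  peaked and chains from different seeds agree to within 0.05 in every
  coordinate, which is the label-switching tolerance the tests assert.

`call_clusters()` summarises the trace: occupancy-conditional posterior
median locations, merging of components indistinguishable within 0.05 in
every sample, maximum-posterior hard assignments. A component group modally
holding fewer than 5 SNVs (`min_snvs`) is not called as a cluster: DP
mixtures routinely park individual outlier SNVs in their own component, and
a cluster is meant to be a peak in the posterior mutation density, which a
singleton is not. SNVs of uncalled groups are reassigned to their
best-supported remaining cluster. `annotate_clonality()`
labels each cluster per sample — clonal when $|CCF-1| \le 0.1$, absent when
$CCF \le 0.05$, subclonal otherwise — and flags as truncal the cluster
clonal in every sample. The clonal/absence tolerances were chosen once to
separate the 0.3 / 0.7 / 1.0 levels of the validation designs and are not
tuned per dataset. `filter_small_clusters()` drops clusters under 1% of
clustered SNVs (inclusive threshold) before tree building on real-scale
data; the simulation recovery runs skip it, because at full scale a 50-SNV
branch is far below 1% of a 100,000-SNV trunk yet is exactly what the study
design asks the sampler to find.

## Clone trees

Under the infinite sites assumption, per-sample CCFs constrain ancestry:
an ancestor must dominate its descendant (greater-or-equal everywhere,
strictly greater somewhere); siblings may not sum above their parent in any
sample (else they are collinear); and two clusters whose CCF ordering flips
between samples must branch. `build_trees()` enumerates parent assignments
rooted at the truncal cluster, depth-first with dominance pruning, and
audits every complete tree against all three rules. Because estimated CCFs
are noisy, all rules take a tolerance `eps`, default 0.1 — the rules are
exact only for true CCFs. When several trees survive, all are returned
ranked by the total tolerance they consumed (summed child-over-parent and
sibling-sum excesses), most parsimonious first. When none survives, the
cluster implicated in the most unplaceable relationships is removed as a
putative artefact (ties broken toward fewer SNVs) and enumeration retried.
Enumeration is exact up to 12 clusters and fails loudly beyond, advising
pruning, rather than switching silently to a heuristic.

`sample_subtree()` restricts the patient tree to the clones present in one
sample (CCF > 0.05, root always kept); `assign_drivers()` places driver
SNVs on the branch of their cluster, preserving input order on the trunk.
Trees serialise as Newick (labels = cluster ids, branch lengths = SNV
counts) with a JSON sidecar for per-sample CCFs and drivers.

## The simulator and what the tests show

`simulate_reads()` draws, for every SNV and sample, a depth from
$\mathrm{Poisson}(\lambda)$ and mutant reads from
$\mathrm{Binom}(depth, E[VAF])$. The six standard designs
(`simulation_design()`) emulate a four-metastasis patient at $\lambda = 34$
with purities drawn uniformly in $[0.7, 0.95]$ — a typical range for
macrodissected metastatic tumour samples; the draw happens once at spec
construction and is overridable: design 1 is a 100,000-SNV trunk
alone; designs 2–6 add six non-truncal clusters as three bifurcations — two
mutually exclusive clonal clusters (CCF 1 in samples 1–2 / 0 in 3–4 and vice
versa; which samples carry which clade is an arbitrary labelling, fixed
here once), and under each a pair of second-step
subclones at mean CCF 0.7 and 0.3, each unique to one sample — with equal
per-branch burdens of 50, 100, 150, 200 or 500 SNVs (totals 100,300 to
103,000).

All loci are simulated diploid with multiplicity 1, matching a design that
specifies no copy-number aberrations; the per-locus copy-number machinery is
exercised by separate fixtures instead. The simulator does not model
sequencing error, mapping bias, FFPE artefacts, indels or mutational
signatures — passing recovery tests therefore show that the inference
machinery is correct under its own noise model (Poisson coverage, binomial
sampling, purity dilution), not that it is robust to artefact-laden real
data, which is what the pseudo-heterogeneity and artefact-removal layers
are for.

The recovery suite runs the designs with the trunk scaled to 5,000 SNVs and
burdens unchanged — small enough for a laptop-scale test run, large enough
that a 50-SNV branch is still a sub-1% minority — and asserts: no spurious
clusters from the truncal-only design across three seeds; all six branch
clusters recovered at every burden with locations within 0.1 of truth and
under 1% of branch SNVs leaking into the trunk; second-step subclones
within 0.05 of 0.7 and 0.3 in their carrying samples; and the generating
three-bifurcation topology returned by the tree builder, whose search is
additionally checked against brute-force enumeration on random instances.

## Known limitations

* Purity and ploidy are consumed, not estimated (beyond the diploid VAF-peak
  route); allele-specific copy number comes from upstream callers.
* Indels and structural variants are out of scope — this is an SNV-centric
  analysis.
* Multiple maximum-likelihood multiplicities tie toward the smaller $m$
  (hence the larger CCF); ties are rare off the exact midpoint.
* The DP sampler is a single chain; the tests aggregate over seeds rather
  than computing formal convergence diagnostics.
* Tree enumeration is exponential and bounded at 12 clusters; beyond that,
  prune small clusters first.
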