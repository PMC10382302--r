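---
title: "Methods: TF co-occurrence in 3D chromatin with chromcooc"
author: "chromcooc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TF co-occurrence in 3D chromatin with chromcooc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromcooc)
```

## The question and the model

Chromatin-conformation assays (ChIA-PET, Hi-C) report pairs of genomic
anchors in spatial contact; ChIP-seq reports where DNA-binding factors sit
on the linear genome. `chromcooc` asks, for every pair of factors, whether
they co-occupy *spatially proximal* regions (the two ends of a contact
edge) or *sequentially contiguous* regions (the same merged region) more
often ("attraction") or less often ("repulsion") than expected by chance.

The data are organized as two graphs:

* the **interaction network**: nodes are merged genomic regions, edges are
  long-range contacts;
* the **binding network**: a bipartite graph linking each factor to the
  regions it binds (from ChIP-seq peaks, or from motif occurrences when no
  binding data exist).

The null model must respect two strong confounders: some factors bind far
more regions than others, and highly connected regions accumulate more
binding. Chance is therefore defined by randomizing the *binding* network
while holding the interaction network fixed: every factor-region link is
reassigned, within the same factor, to a region of similar interaction
degree. Degrees up to 5 are matched exactly, degrees 6–10 within ±2, and
degrees above 10 form one open class (capped by the construction-time
maximum of 20). Per-factor out-degrees are conserved exactly: replacement
regions are drawn uniformly *without replacement* per factor, the original
region remaining in its own candidate pool. Overlapping windowed classes
are served scarcest-pool-first so that rare high-degree regions are not
starved; in the (pathological) event that a pool is still exhausted,
surplus links keep their original regions — out-degree conservation takes
precedence over the degree class, and a warning is raised.

## Counting and significance

Spatial co-occurrence of factors $i$ and $j$ counts, over every edge
$\{u,v\}$, the ordered endpoint assignments ($i$ at $u$ and $j$ at $v$, or
vice versa): 0, 1 or 2 per edge, collapsing to 1 per edge for homotypic
pairs. A flag (`count = "presence"`) switches to 0/1-per-edge counting.
Sequential co-occurrence counts regions bound by both factors. Observed
counts are compared against `replicates` (default 1000) randomized binding
networks; when both modes are analysed together they score the *same*
ensemble, which is consistent and halves the cost.

Two empirical tail probabilities are computed per pair — the fraction of
replicates with a count at least (attraction tail) or at most (repulsion
tail) the observed one, both tails including equality — and each tail list
is corrected across all pairs by Benjamini–Hochberg; pairs with
$q \le \alpha$ (default 0.05) are called attracting or repelling.
Homotypic pairs are included in the table and in the correction by default
(`include_homotypic = FALSE` excludes them).

**Permutation p-value estimator.** The raw fraction $k/R$ can be exactly
zero, and a zero p-value is always promoted to a discovery by any
multiple-testing procedure. In an exchangeable ensemble the probability
that the observed replicate is the strict extremum is of order $1/R$ *per
pair*, so with hundreds of pairs a raw-fraction analysis produces spurious
q ≤ 0.05 calls in a substantial share of *null* datasets — we measured
roughly 0.5 expected zero-p pairs per run, i.e. ~40% of control runs
contaminated, at the package's reference simulation condition. The
high-level drivers (`cooccurrence_test()`, `negative_control()`) therefore
default to the permutation estimator $(k+1)/(R+1)$, which counts the
observed replicate among the null set and is bounded below by $1/(R+1)$;
`empirical_pvalues()` keeps the raw fraction as its documented default for
the bare operation, with `pseudocount = TRUE` selecting the estimator.

**Calibration check.** `negative_control()` re-labels one randomized
replicate as "observed": a well-calibrated analysis then produces
approximately uniform p-values and no calls. When testing uniformity,
note that p-values of pairs sharing a factor are dependent (factors are
randomized independently, so *factor-disjoint* pairs give independent
counts), and that tied integer counts make the p-values conservatively
discrete; the package's own checks therefore apply the KS test to
factor-disjoint pairs pooled across independent runs.

With many true positives the BH threshold rises, so unplanted pairs are
still rejected at a rate close to the nominal FDR times the rejection
fraction; the false-discovery *proportion*, not the per-null-pair call
rate, is the controlled quantity.

## Network construction choices

Coordinates are 0-based half-open (BED convention) everywhere; "within
2 kbp" is measured end-to-start (overlap counts as distance ≤ 0). Anchors
are merged at gap ≤ 2 kbp; each contact pair maps to its merged regions;
self edges, duplicate edges and same-chromosome edges with an inter-region
gap ≤ 2 kbp are dropped; then regions with degree > 20 or length > 30 kbp
are removed with their incident edges (merging/averaging artefacts).
Degree removal cannot create new violations (degrees only decrease), so a
single pass suffices; `iterate_filter = TRUE` re-checks until stable for
completeness. Filtering order — merge, map, drop short-range, dedupe,
remove violators — is a documented choice; the degree/length filter runs
last so that the short-range filter sees the original connectivity.
Inter-chromosomal edges are kept by default
(`intra_chromosomal_only = TRUE` restricts them). Binding requires ≥ 1 bp
peak-region overlap (`mode = "midpoint"` offers the midpoint-containment
alternative). A/B-compartment stratification is plumbing:
`restrict_to_compartments()` keeps edges whose endpoints share the
majority-overlap compartment class.

## Motif machinery

Motifs are position weight matrices (MEME minimal input). The information
score $I = \sum_n (2 + \sum_b W_{nb}\log_2 W_{nb})$ (bits; 0 for uniform,
$2L$ for deterministic) selects one representative per similarity cluster,
ties broken lexicographically by name; $I$ is computed on the raw
probabilities. Scoring is the log2 likelihood ratio against a background
(default uniform 0.25); a pseudocount of $10^{-4}$ (rows renormalized)
floors zero entries so scores stay finite. A peak's motif score is the
maximum window LLR over both strands.

Occurrence calling needs $P(\text{score} \ge s)$ under the background: the
per-position score contributions are discretized onto `bins` (default
1000) equal-width bins and convolved position by position, exactly as
FIMO-style scanners do. Scanning uses the same integer grid as the
distribution, so reported p-values are exactly the distribution's survival
values; reported LLRs are the exact (undiscretized) sums. Windows
containing ambiguous bases are skipped; regions extending past a
chromosome end are clipped with a warning; hits pass at p ≤ 1e-4 (the
conventional scanner default). External FIMO TSV output is accepted
verbatim (`read_fimo()`) when bit-compatibility with an existing scan
matters.

For the strong-motif analysis, "strong" means reaching the factor's 90th
score percentile (type-7 quantile; ties at the threshold are included), a
*per-factor* threshold; "isolated" means a peak overlapping no network
region or one of degree 0 — both readings of "no spatial interactions"
unified by degree 0. Factors with fewer than 10 scored peaks are flagged
as quantile-unstable.

## Downstream statistics

Enrichment tests are exact one-sided hypergeometric upper tails on 2×2
tables (attract/avoid × interacting or not; group-1/group-2 targets × in
reference set or not), with "avoiding" meaning a repel call, not merely
not-attracting. Zero-margin tables return p = 1 with a warning. Target
genes: a factor targets a gene when a bound region lies within 2 kbp of
the gene's TSS directly or via one interaction edge; a gene is a group
target when at least 5 own-group factors and at most 3 other-group factors
target it (the stricter 3/0 variant is exposed as parameters).
TSS distances are measured from the peak midpoint (`mode = "edge"` for
nearest-edge) as plain base-pair differences. On shortest PPI paths, the
*union* of internal nodes over all shortest paths between a pair is
counted (a node is internal iff $d(a,w)+d(w,b)=d(a,b)$), once per pair,
restricted to an annotated-TF list; this avoids arbitrary tie-breaking
among equal-length paths. GO/trait enrichment is deliberately not
reimplemented: the package emits target-gene and background lists for
external tools, whose term databases are versioned.

The consensus network keeps pairs called attracting in at least
`min_support = 2` of the supplied analyses (typically spatial/sequential ×
binding/motif).

## The synthetic-data generator

`simulate_network()` draws a degree sequence (default Poisson(3), capped
at 20), realizes a simple graph with exactly those degrees, and lays
regions on a synthetic chromosome with lengths and gaps chosen so the
construction filters are no-ops — most real contact-anchor regions are
sub-kilobase, hence lengths of 0.5–1.5 kbp and 5 kbp gaps.

`simulate_bindings()` draws binding indicators from a pairwise Markov
random field: relative to independent binding at `base_bind_prob`, the
joint odds that two factors occupy the two ends of an edge are multiplied
by `attract_boost` (same-group pairs) or `repel_damp` (cross-group);
ungrouped factors carry no tilt and bind independently of everything.
Sampling is by block Gibbs — one factor's bindings are conditionally
independent given the rest because homotypic pairs carry no tilt — and at
every update the factor's intercept is chosen (by root-finding) so its
*expected* marginal rate equals `base_bind_prob`; realized rates deviate
only by binomial noise. Earlier link-rewiring schemes that tried to plant
each pair independently fail at realistic settings: dozens of simultaneous
pairwise boosts over shared link budgets cancel each other, whereas the
MRF realizes all pairwise odds tilts jointly. Two consequences worth
knowing: grouped factors' binding becomes degree-dependent (the field
grows with neighbourhood size), which is precisely the confounder the
degree-class null is built to absorb; and same-group factors concentrate
into shared territories, so homotypic pairs of grouped factors are
genuinely (and correctly) detected as self-attracting.

Default condition, chosen once: 2000 regions, Poisson(3) degrees, 20
factors in two groups of 8 plus 4 ungrouped, `attract_boost = 8`,
`repel_damp = 1/8`, `base_bind_prob = 0.10` (an active-regulatory-region
binding rate; power analyses in the tests use 0.05 where stated).

`simulate_motif_dataset()` plants exact consensus occurrences in i.i.d.
uniform background sequence at rate `p_iso` in degree-0 regions and
`p_int < p_iso` in interacting regions, emulating the observation that
isolated sites carry stronger motifs. What these generators do *not*
emulate: chromatin-state autocorrelation along the genome, GC and
mappability biases, peak-strength heterogeneity, and cell-population
averaging of contacts — passing tests demonstrate correctness of the
statistics under the stated generative model, not robustness to every
artefact of real data.

## Problem sizes and runtimes in the checks

The package's own checks run at desk scale: calibration uses 20 control
runs of 499 replicates each on the 2000-region network (~2 minutes);
planted-effect recovery uses 200 replicates (~10 seconds); the
randomization audit uses 500 replicates of a 30-region toy network; motif
checks enumerate all $4^L$ windows up to $L=6$ and 100 seeded
motif-dataset draws. Randomization ensembles stream — replicate maps are
regenerated from per-replicate seeds (drawn as a block from the master
seed, so replicate $i$ depends only on $(\text{seed}, i)$) rather than
stored.

## Known limitations

* Empirical resolution is bounded by $1/(R+1)$; with the default 1000
  replicates, q-values cannot resolve below ~$10^{-3}$ times the pair
  count ratio.
* The windowed (6–10) and open (>10) degree classes preserve degree only
  approximately; under strongly degree-dependent binding a small residual
  bias remains — the exact-match class for degrees ≤ 5 covers the bulk of
  typical contact networks.
* The exact-class degree multiset is conserved exactly only when windowed
  classes do not bleed across the ≤ 5 boundary (an original degree-6 link
  may legally land on a degree-4 region).
* Inter-chromosomal contacts are treated like any other edge; no
  distance-dependent contact model is fitted.
* The consensus network records support counts only; it does not model
  dependence between the four analyses.
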