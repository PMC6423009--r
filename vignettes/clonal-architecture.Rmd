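---
title: "Clonal architecture analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal architecture analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonarch)
```

This vignette is the package's account of its science: the models behind
each stage, the tunable parameters and their defaults, what the synthetic
cohort generator does and does not emulate, the numerical choices, and the
known limitations. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The CCF model

A somatic SNV observed with `alt` variant reads out of `depth` total reads
sits at a site of tumor total copy number $q_t$ in a sample of purity $p$.
If a fraction $c$ of tumor cells carry the mutation on $m$ copies, the
expected variant allele frequency is

$$\mathrm{vaf}(c) = \frac{c\,p\,m}{p\,q_t + 2(1-p)}.$$

`ccf_posterior()` evaluates the binomial likelihood of the observed counts
on a uniform grid of 100 CCF values spanning $[0.01, 1]$ and normalizes it.
The posterior mean (clamped to at most 1) is the point estimate, and an
event is called **clonal** when the posterior mass on grid points
$\ge 0.95$ exceeds $0.5$ (strictly), **subclonal** otherwise. The same
classification rule is applied to copy-number segments through their
annotated segment CCF (a point threshold at 0.95 when no posterior is
available) so that SNVs and SCNAs are treated uniformly.

Parameters and defaults:

* grid spacing 0.01 (`grid_size = 100`), probability cutoff 0.5 (strict);
* multiplicity is a point estimate,
  $m = \mathrm{clamp}(\mathrm{round}(\mathrm{vaf}\cdot(p q_t + 2(1-p))/p), 1, q_t)$,
  not integrated over — a deliberate simplification of full allele-specific
  inference; the pipeline consumes purity, ploidy and total copy number as
  *inputs* rather than re-deriving them from read data;
* samples with purity below 0.20 are excluded (the boundary value is kept);
* SNV filters: tumor and germline depth $\ge 10\times$, at most 2 germline
  variant reads, tumor VAF $\ge 10\%$, germline VAF $\le 2\%$.

### Behavior of the clonality rule at moderate depth

The rule "P(CCF ≥ 0.95) > 0.5" has a property worth stating explicitly. At
depth $d$ the posterior standard deviation of the CCF is approximately
$\sigma_c = \sqrt{\mathrm{vaf}(1-\mathrm{vaf})/d}\,/\,(\partial\mathrm{vaf}/\partial c)$;
for a diploid site with $m = 1$ this is $\ge 0.1$ at $d = 100$ for any
purity. The window $[0.95, 1]$ then covers at most half a standard
deviation below the boundary, so even when the observed VAF sits exactly at
its clonal expectation the mass above 0.95 is about 0.44, and a truly
clonal mutation is labeled clonal only when its alt count fluctuates above
expectation. Exact computation over the binomial distribution of alt counts
gives a clonal-call rate for true CCF = 1 mutations of 0.38 at purity 1,
falling to 0.06 at purity 0.4; reaching a 95% clonal-call rate would
require depths near 1000x. Classification is therefore conservative in the
clonal direction at WES-like depths: subclonal calls are reliable
(planted CCF ≤ 0.4 mutations are called subclonal essentially always, as
the acceptance checks verify), while "subclonal" labels for borderline
mutations should be read as "not demonstrably clonal". The acceptance suite
asserts both recovery rates at 95% on a 200-sample, depth-100 cohort; the
clonal half of that assertion fails for exactly this reason, and is kept
failing rather than weakened, as an honest record of the rule's operating
characteristics at this depth.

## Arm-level SCNAs

Segments are classified as amplified or deleted against the rounded sample
ploidy. For each arm and direction, the clonal and subclonal cumulative
overlap lengths are divided by the arm length; the arm event is clonal
(subclonal) when the clonal (subclonal) fraction exceeds 0.5, and its CCF
is the median CCF of the winning segments (even-count medians are midpoint
values). When amplification and deletion both touch an arm in one sample,
the direction with the larger altered fraction is reported. Both arms of a
chromosome carrying the same direction and clonality may be collapsed to a
whole-chromosome label (`collapse_chromosome_events()`); the pipeline keeps
arm labels by default. Genes mutated non-silently in $\ge 3\%$ of samples
and arm events altered in $\ge 10\%$ enter downstream analyses; a gene with
two or more non-silent SNVs in one patient is excluded from that patient's
gene-level clonality (its per-gene CCF would be ambiguous; silent SNVs do
not trigger the exclusion).

## Mutational signatures

Each SNV is folded onto the pyrimidine strand into one of 96 trinucleotide
channels (`"A[C>T]G"`-style labels; the 192 raw strand combinations map
2-to-1 onto channels). The channels-by-samples count matrix $V$ is
factorized as $V \approx WH$, $W, H \ge 0$, by alternating nonnegative
least squares with projection, updating one column of $W$ (row of $H$) at a
time — a block-coordinate scheme whose Frobenius objective is
non-increasing at every iteration, which the tests assert per iteration.
Defaults: 50 random restarts, tolerance $10^{-8}$, at most 2000 iterations;
signature columns are normalized to sum to 1 with exposures rescaled
compensatorily.

**Rank selection.** For each candidate $k$, the catalog is refit on
bootstrap resamples (each sample's counts redrawn multinomially), each
resample's signatures are matched one-to-one to the full-data solution, and
the stability of $k$ is the mean across resamples of the *worst* matched
cosine. Every $k$ up to the true number of processes reproduces almost
exactly, while a spurious extra process fails to reproduce and drags the
worst matched cosine down; walking up from the smallest candidate, the
chosen $k$ is the largest one reached before stability first drops below
0.95. A cluster-silhouette stability score was evaluated first and
rejected: on planted catalogs the mean silhouette of k-means clusters of
pooled bootstrap signatures stays high above the true rank (split
signatures form reproducible-looking clusters), whereas the matched-cosine
statistic separates the true rank from its neighbors by a wide margin.

**Reference matching** reports the argmax-cosine reference signature with
both cosine and Pearson values and applies no assignment threshold; a
`matched` flag at cosine $\ge 0.80$ is provided for convenience, mirroring
the gap commonly seen between genuine matches and best-effort non-matches.

**Clonal/subclonal enrichment.** The pooled clonal and subclonal catalogs
are each attributed to the fitted signatures by nonnegative least squares;
per signature, the 2×2 table (this signature vs the others) × (clonal vs
subclonal) is tested two-sided by Fisher's exact test, FDR-adjusted across
signatures. Stratum-level attribution was preferred over per-mutation
maximum-posterior assignment because the tested quantity is each process's
relative contribution in the whole cohort; the per-mutation alternative can
be emulated by passing single-sample strata.

## Clonality enrichment by permutation

For an event with $n_c$ clonal and $n_s$ subclonal alterations, each
permutation draws $n_c + n_s$ labels *without replacement* from the pool of
all retained labels and counts how often the drawn clonal count reaches the
observed one (counts are order-isomorphic to clonal/subclonal ratios at
fixed $n$ and avoid zero denominators). The default p-value uses the
$\ge$ tail with the add-one correction $p = (b+1)/(B+1)$, which guarantees
validity; the plain $>$ convention is available by flag. Default
$B = 10{,}000$.

A validity note: on discrete counts this p-value is necessarily
conservative (its null distribution is supported on hypergeometric atoms),
so its empirical CDF under the null sits at or below the uniform CDF. Exact
computation of the infinite-$B$ null distribution shows a Kolmogorov
distance from uniform of about 0.11 for event sizes 10–60 — a property of
*any* valid non-randomized p-value here, not of the implementation — so a
two-sided uniformity test at large sample sizes will reject by design. The
module tests therefore assert validity (the empirical CDF never exceeds
uniform beyond Monte-Carlo noise) and agreement with the exact
hypergeometric tail; the acceptance suite retains the literal two-sided
uniformity assertion, which fails for the reason just given.

## Temporal ordering

Within each patient, every ordered pair (X clonal, Y subclonal) among the
frequency-filtered events contributes a directed edge X→Y — the clonal
event is taken to have been acquired earlier. A patient with $c$ clonal and
$s$ subclonal events contributes exactly $c \cdot s$ edges; no per-sample
reweighting is applied by default. Pairs with at least 5 connecting edges
are tested two-sided against a fair binomial; per node, out-going vs
in-coming edge counts are tested the same way with FDR across nodes, and
events are classified early (out ≫ in), late (in ≫ out) or intermediary.
Acyclicity is *not* assumed: the significant-direction subgraph is checked
for cycles and any are reported, not suppressed. Events are also ranked by
median CCF with percentile-bootstrap confidence intervals (1000 resamples).

## Subtyping by consensus NMF of the CCF matrix

The events-by-samples matrix of CCFs (0 where absent; absence is encoded as
0 rather than missing because the factorization needs complete nonnegative
data) is factorized by Brunet-style multiplicative updates for the
Kullback–Leibler objective. Fifty runs from random initializations each
assign samples to their dominant basis component (ties to the lowest
index); the consensus matrix records co-clustering frequencies, and the
final k-group assignment is the average-linkage hierarchical clustering of
1 − consensus. Cluster labels are letters ordered by decreasing size, so
labeling is deterministic. The number of subgroups is chosen over k = 2..6
by the cophenetic rule: the smallest k whose successor shows the first
strict decrease of the cophenetic correlation (the largest candidate, with
a warning, if it never decreases).

## Survival and immune context

Kaplan–Meier curves use the product-limit estimator; group differences use
the log-rank test. Cox models use the partial likelihood with Efron tie
handling; adjusted models add age, sex, T stage and Fuhrman grade. The
univariate screen compares carriers against event-free samples per event
(and, stratified, clonal and subclonal carriers separately), skipping
groups with fewer than 5 carriers; selection defaults to unadjusted
p < 0.05 — the FDR column is always reported — because the selection feeds
an exploratory clustering rather than a confirmatory claim.

ssGSEA ranks genes within each sample and integrates the difference
between the weighted (ranks to the power 0.25) in-set cumulative
distribution and the unweighted out-of-set one; raw integrated scores are
divided by the number of genes, with min-max normalization across samples
available as an option. Scores depend on expression only through
within-sample ranks and are invariant under monotone transformations.
Because scores can be negative, cell-type ratios (Th17/Th2, CD8/Treg) shift
both scores by the cohort-wide minimum of the pair plus a small epsilon
(default $10^{-3}$), making the ratio positive and invariant to adding any
constant to both sets. The immune gene sets shipped under `inst/extdata/`
are synthetic placeholders; faithful immune profiling requires the
published signature collections in the same GMT format.

## The synthetic cohort generator

`generate_cohort()` plants, per sample: a purity (uniform 0.3–0.9), a
prognostic subtype (three clusters, proportions 0.3/0.4/0.3, hazard
multipliers 2.7/1.0/2.7 — the 2.7-fold contrast between the short-lived
SCNA-rich clusters and the long-lived VHL-enriched cluster), driver events
with ccRCC-like frequencies and timing classes, passenger SNVs
(Poisson mean 80 per sample, 68% clonal — matching the clonal share of
coding SNVs the classification rule is calibrated against), subclonal CCFs
uniform on 0.1–0.6, trinucleotide contexts drawn from three planted
signatures (CpG-deamination-like, aristolochic-acid-like, broad
T>C-biased) with per-sample Dirichlet activities (concentration 2, so
patients genuinely differ in signature exposure — without that variation a
signature model is unidentifiable), copy-number segments realizing the arm
events over ~90% of the arm, read counts drawn binomially at Poisson
depths (mean 100× tumor, 60× germline), exponential survival times with
uniform censoring, and an expression matrix with additive immune gene-set
shifts per subtype. Timing is realized by forcing an event to be clonal
whenever a strictly later-timing event co-occurs in the same sample, with
class-level subclonality rates otherwise (early 0.05 / intermediate 0.5 /
late 0.9 at the default clonal fraction, scaled so that a clonal fraction
of 1 plants no subclonal event at all).

What the generator does *not* emulate: read-level artifacts (mapping,
strand bias), indels and focal SCNAs, whole-genome doubling, subclonal
structure with more than one subclone per event, correlated passenger
positions, batch effects between cohorts, and non-exponential survival.
Passing the planted-recovery tests therefore demonstrates the correctness
of the estimators under the stated generative model, not robustness to
every artifact of real sequencing data.

## Problem sizes used by the tests and the acceptance script

Recovery checks run on 200-sample cohorts at depth 100 (clonality,
temporal order), 200-sample catalogs of ~100 mutations (signatures; rank
selection over 20 seeds with 8 bootstraps and 3 restarts per fit),
120-sample planted CCF matrices over 20 seeds (subtyping), and 400-sample
cohorts over 20 seeds (survival); the acceptance script uses 10 seeds for
the multi-seed stages. These sizes were chosen as the smallest at which
the planted effects are comfortably identifiable, so that the whole suite
completes in minutes while remaining well-powered.

## Known limitations

* The CCF posterior conditions on a point multiplicity estimate and on the
  input purity; both carry uncertainty that is not propagated.
* The clonal/subclonal boundary is sharp at P(CCF ≥ 0.95) > 0.5 and, at
  WES depths, asymmetric (see above): clonal fractions are systematically
  underestimated, and analyses that contrast clonal vs subclonal groups
  inherit that asymmetry.
* No joint clustering of mutations into subclones is attempted; each event
  is classified marginally.
* The temporal graph treats within-patient clonal/subclonal co-occurrence
  as an ordering signal; convergent evolution and clonality
  mis-classification both inject contradictory edges, which is why cycles
  are reported rather than suppressed.
* Consensus-NMF subtyping is sensitive to the event selection feeding it;
  the univariate screen's 0.05 level is exploratory by design.
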