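# clonarch

Clonal architecture analysis of tumor cohorts from cancer cell fractions
(CCFs), built around the genomics of clear cell renal cell carcinoma
(ccRCC): a low point-mutation burden, pervasive arm-level somatic
copy-number alterations (SCNAs) such as del(3p), amp(5q) and del(14q), and
driver genes (*VHL*, *PBRM1*, *SETD2*, *BAP1*) whose prognostic impact
depends on whether they are clonal (present in essentially all tumor cells)
or subclonal (confined to a subpopulation).

The package takes per-sample somatic SNV calls, copy-number segments and
purity estimates, and provides:

- **CCF estimation and clonality calls.** For an SNV with `alt` of `depth`
  reads at a site of tumor copy number *q<sub>t</sub>*, multiplicity *m*, in
  a sample of purity *p*, the expected variant allele frequency at cancer
  cell fraction *c* is

  vaf(*c*) = *c·p·m* / (*p·q<sub>t</sub>* + 2(1 − *p*)),

  and the CCF posterior is the binomial likelihood evaluated on a uniform
  grid over [0.01, 1]. An event is **clonal** when P(CCF ≥ 0.95) > 0.5,
  subclonal otherwise — the same rule is applied to SNVs and to arm-level
  SCNAs (an arm is altered when clonal or subclonal segments cover more than
  50% of its length; the arm CCF is the median segment CCF).
- **Mutational signatures.** 96-channel trinucleotide counts
  (pyrimidine-strand convention), alternating least-squares NMF with
  restarts, bootstrap rank selection, cosine/Pearson matching against a
  reference catalog, and Fisher tests for clonal vs subclonal enrichment of
  each process.
- **Clonality enrichment.** A permutation test (draws without replacement
  from the cohort's label pool) for genes/arms enriched in clonal or
  subclonal alterations, with Benjamini–Hochberg FDR.
- **Temporal ordering.** Directed edges X→Y wherever X is clonal and Y
  subclonal in the same patient; binomial tests on edge counts classify
  events as early / intermediary / late and orient event pairs.
- **Molecular subtyping.** Consensus KL-NMF of the events-by-samples CCF
  matrix with cophenetic-coefficient rank selection.
- **Outcome and immune context.** Kaplan–Meier/log-rank, Cox
  proportional-hazards models (Efron ties, optionally adjusted for age, sex,
  T stage, Fuhrman grade), ssGSEA immune scores and Th17/Th2, CD8/Treg
  ratios.
- **A synthetic-cohort generator** (`generate_cohort()`) that plants
  purities, clonal structure, signatures, arm events, subtypes and survival
  times and returns the ground truth, so every stage is testable end to end.

## Worked example

```r
library(clonarch)
library(dplyr)

co <- generate_cohort(cohort_config(n_samples = 100, seed = 7))
co
#> synthetic cohort: 100 samples, 8133 SNVs, 5300 segments, 324 planted arm events

calls <- co$mutations |>
  filter_snvs() |>
  snv_clonality(co$purity, co$segments) |>
  exclude_multihit_genes()
table(calls$clonality)
#>    clonal subclonal
#>      1090      5780

arms <- arm_events(co$segments, co$purity, co$arms)
frequency_filter(calls, arms, n_samples = 100) |> head(4)
#> # A tibble: 4 x 4
#>   event_id kind  n_altered frequency
#>   <chr>    <chr>     <int>     <dbl>
#> 1 del(3p)  arm          89      0.89
#> 2 VHL      gene         76      0.76
#> 3 del(14q) arm          53      0.53
#> 4 amp(5q)  arm          51      0.51

fit <- extract_signatures(build_context_matrix(calls), k = 3,
                          n_restarts = 10, seed = 1)
match_reference(fit, example_signatures())
#> # A tibble: 3 x 5
#>   signature best_match cosine pearson matched
#>   <chr>     <chr>       <dbl>   <dbl> <lgl>
#> 1 S1        CpG         0.999   0.999 TRUE
#> 2 S2        Broad       0.985   0.975 TRUE
#> 3 S3        AA          0.997   0.997 TRUE

grp <- co$truth$samples |> transmute(sample_id, risk = subtype %in% c("A", "C"))
cox_model(co$clinical, grp)
#> # A tibble: 1 x 7
#>   term     hazard_ratio ci_low ci_high p_value model          flagged
#>   <chr>           <dbl>  <dbl>   <dbl>   <dbl> <chr>          <lgl>
#> 1 riskTRUE         2.00   1.22    3.28 0.00604 cox_univariate FALSE
```

The mutation-frequency table recovers the planted driver landscape (an
early near-ubiquitous del(3p), frequent *VHL* mutations, intermediate
del(14q)/amp(5q)), and all three planted signatures are matched at cosine
0.99. The clonality table shows the depth-100 behavior of the
P(CCF >= 0.95) > 0.5 rule: subclonal calls dominate because at moderate
depth the posterior mass above 0.95 rarely exceeds one half even for truly
clonal mutations (see the methods vignette). The Cox fit estimates the
planted 2.7-fold hazard contrast between the poor-prognosis clusters (A, C)
and the VHL-enriched cluster B at 2.0 with a 95% CI of 1.2-3.3 at this
small n = 100; at n = 400 the estimate concentrates near 2.7 (the
acceptance script reports it across seeds).

Plot helpers: `plot_signatures()`, `plot_ccf_ranking()`, `plot_consensus()`,
`plot_temporal_graph()` and `autoplot()` on Kaplan-Meier results. All fitted
objects have `tidy()`/`glance()` methods. A thin command-line wrapper over
the same functions lives at `inst/scripts/clonarch-cli.R`.

Small plain-text fixtures ship under `inst/extdata/`: a *synthetic*
placeholder immune gene-set GMT and a *synthetic* reference signature
matrix; for analyses of real data supply published immune signatures and
the COSMIC catalog in the same formats.

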