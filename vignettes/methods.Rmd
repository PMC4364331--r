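---
title: "Discovering and scoring muscle-growth gene signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and scoring muscle-growth gene signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthsets)
```

## The problem

Muscle growth rate in cattle — average daily gain normalized to body size
(ADG/kg liveweight, units 1/day) — cannot be read off a single liveweight
measurement, but it leaves a transcriptional footprint in the longissimus
muscle. `growthsets` implements a pipeline for (i) finding small gene sets
whose average expression tracks ADG/kg across a single-timepoint cohort,
(ii) checking that those genes are genuinely co-expressed across a
developmental time course in two contrasting genotypes (high-muscling vs
high-marbling crosses), and (iii) attributing the co-expression clusters they
sit in to muscle-resident cell types (fibro/adipogenic progenitors,
endothelial cells, satellite cells, adipocytes, ...) via published marker
genes. ADG/kg itself follows

$$\mathrm{ADG/kg} = \frac{\mathrm{ADG}}{(w_\mathrm{start}+w_\mathrm{end})/2},$$

implemented in `compute_adg_per_kg()`.

All stages consume normalized log2 expression matrices (genes x samples).
Microarray normalization, probe-to-gene collapse and data retrieval are out
of scope by design: inputs are assumed gene-level and complete, and missing
values are rejected rather than imputed.

## Ranking and ranked-list enrichment

`rank_by_correlation()` scores every gene by the Pearson correlation of its
expression with the phenotype and sorts genes by signed r, descending.
Pearson (not Spearman) is used; ranking by |r| is exposed as an option but
signed ranking is the default, because the biological processes of interest
(cell cycle, ECM organization) rise with growth rate. Genes with constant
expression have undefined correlation and are excluded rather than assigned
r = 0, so an undefined value never occupies a rank; ties are broken by gene
ID so the ranking is a deterministic permutation.

Enrichment of a term at the top of the ranked list uses the minimum
hypergeometric (mHG) statistic: for a universe of $N$ genes with $B$ term
members, the hypergeometric upper tail of the hit count is evaluated at every
prefix $n = 1..N$, and the statistic is the minimum tail over all prefixes —
enrichment at the data-driven optimal cutoff. Because the cutoff is chosen by
minimizing, the raw minimum is not a p-value. `mhg_exact_pvalue()` computes
the exact null probability $P(\min\text{-scan} \le s)$ under uniformly random
rankings with a dynamic program over the lattice of (prefix length, hit
count) states: member positions form an exchangeable path from $(0,0)$ to
$(N,B)$, cells whose tail is at or below the observed statistic are flagged,
and the DP accumulates the probability mass entering flagged cells. That
accumulation (rather than one minus the surviving mass) keeps tiny p-values
at full floating precision. Tail probabilities are computed in log space
(`phyper(log.p = TRUE)`) so values of order $10^{-17}$ do not underflow. When
$N \cdot B$ exceeds a cap (default $10^7$ states) the DP is replaced by a
seeded Monte-Carlo permutation estimate. Cluster enrichment
(`enrich_cluster()`) is the ordinary one-sided hypergeometric test with the
clustered genes as the universe. All multiple-testing correction is
Benjamini–Hochberg (`bh_fdr()`, backed by `p.adjust`).

## Gene-set construction and scoring

Expression is standardized per gene to mean 0, SD 1 across a declared sample
universe (`zscore_standardize()`); the sample SD ($n-1$) is the default, with
the population form available, since the upstream convention is ambiguous.
A set's score in a sample is the arithmetic mean of its members' z-scores
(`set_score()`); five members is the default set size, a compromise between
noise suppression and parsimony.

`select_top_genes()` builds a set from an enriched term by walking the term's
members in correlation-rank order: the best-ranked gene is always accepted,
and each later gene is accepted only if its developmental profile correlates
at or above `coexpr_min` (default 0.6) with the running mean profile of the
genes accepted so far. The co-expression criterion is qualitative in the
source methodology; 0.6 was fixed once as a moderately strict profile
agreement. Profiles are stage-by-genotype mean z-scores
(`stage_profiles()`), i.e. the two genotypes are judged jointly.

Significance of a set–phenotype correlation is calibrated against an
empirical null of random same-size gene sets (`empirical_null_pvalue()`):
draws are uniform without replacement from the full gene universe (no
exclusions), exceedance is strict ($r_\mathrm{draw} > r_\mathrm{obs}$,
one-sided for higher correlation), and the estimator is
$p = (\#\mathrm{exceed}+1)/(n_\mathrm{draws}+1)$, which can never return
zero. The default draw count is 100{,}000, configurable (the methodology this
reimplements reports both $10^5$ and $10^7$ draws in different places; the
smaller figure is the default and the count is always recorded in the
result).

## Loose filtering, consensus clustering and marker attribution

`loose_coexpression_filter()` applies two sign-only rules to find genes at
least weakly co-expressed with the ECM program: pooled mean at birth above
the pooled mean at the final stage, and high-marbling mean above
high-muscling mean at 12 and 25 months. No significance threshold is used —
the filter is meant to be permissive.

`run_kmeans_analyses()` clusters the filtered genes on their
stage-by-genotype mean z profiles for k in {10, 13} over two windows (all
ten stages; the seven postnatal stages) — four analyses. k-means uses
Euclidean distance with 10 random restarts keeping the best within-cluster
sum of squares; the upstream tool's "default settings" are not fully
reproducible, so seeded determinism is provided instead. `estimate_k()`
supports choosing k by average-linkage hierarchical clustering: within a
candidate range (default 8–13), k is picked at the largest relative
merge-height gap. Clustering operates on stage-mean profiles, not per-animal
columns, because the profiles across the two genotypes at the same time are
the object of interest.

Clusters are annotated by hypergeometric GO enrichment
(`annotate_analyses()`, q <= 0.05). "Equivalent clusters" across analyses
are matched by shared term enrichment, not by label alignment.
`consensus_genes()` returns the term members whose containing cluster is
enriched for that term in at least `min_support` analyses; the default is 3
of 4 (the stricter all-4 reading is available by setting `min_support = 4`).
`attribute_markers()` applies the same support rule to marker genes: a
marker co-clustered with a term's enrichment in at least 3 of 4 analyses is
attributed to that process; ties are reported, never broken. A transcription
of the published muscle cell-type marker table ships in
`inst/extdata/muscle_cell_markers.csv`; because the published table's grid
formatting does not survive text extraction unambiguously, the CSV was
reconstructed from the explicit statements in the accompanying text plus the
cited marker literature, and is documented as a transcription.

## Contrast tests

All group contrasts use the Welch two-sample t-test (two-tailed, unequal
variances, Welch–Satterthwaite df). Set-level contrasts pool the member
z-values (set size x animals per group) by default, matching how the
original set significance was computed; a per-animal set-score mode is
available. The pooled mode assumes members are independent given the group:
when set members share a latent per-sample driver (as signature genes of one
cell type do), the pooled test is anticonservative and `mode = "score"`
should be preferred — the package's calibration tests use independent-noise
sets for exactly this reason. `single_gene_interval_test()` implements the
empirical alternative for single genes: the between-genotype mean difference
of the query gene is compared with the central 95% interval
(linear-interpolated quantiles; the quantile rule was unspecified upstream)
of that difference over all genes at the same stage. Normality checking
(one-sample Kolmogorov–Smirnov) is exposed as `normality_diagnostic()`, a
reported diagnostic and never a gate.

## The synthetic cohort generator

Because the original microarray matrices and a historical GO release would
be required to reproduce the published numbers, the package ships a
generator with recorded ground truth so every stage has parameter-recovery
tests instead.

The model: each of `n_celltypes` latent cell types drives one program of
`signatures_per_celltype` signature genes. In the phenotype cohort (default
48 animals, 2 sites x 2 HGP treatments), per-animal cell-type fractions are
Dirichlet with a fiber-dominated concentration (default roughly 60% muscle
fiber); a signature gene is its baseline (uniform 4–12 log2) plus
`signature_amplitude` (default 1 log2) times the standardized fraction of
its cell type, plus N(0, `noise_sd`²) log2 noise. ADG/kg is an affine map of
the proliferating-cell fraction plus noise — so phenotype recovery tests the
pipeline, not a planted gene. The phenotype noise is solved analytically so
each growth-program gene attains the target correlation `phenotype_effect`
(default 0.7) in expectation; targets above 0.999, or unreachable given
`noise_sd`, are rejected or warned. Noise defaults are free parameters
(no variance components were published for the normalized data);
`noise_sd = 0.5` log2 was fixed once as a typical microarray residual scale.

In the development cohort (ten stages from 60 days post conception to 30
months, two genotypes, 3–4 animals per stage per genotype), each cell type
follows a smooth stage profile: the ECM program rises to birth and declines
steadily after it, the proliferation program dips postnatally and resurges
late, and remaining programs get seeded smoothed random profiles
(standardized across stages), which keeps arbitrary program counts well
separated. Genotype offsets (default: +1 log2 for the ECM program in the
high-marbling genotype at 12 and 25 months, the shift the benchmark
conditions specify) are added to the affected signature genes.
`generate_annotation()` emits one GO-like term per program (exactly its
signature genes) plus random background terms drawn from background genes.

What the generator does *not* emulate: per-animal random effects shared
across genes (so pooled set tests are exactly calibrated here but not on
real arrays), probe-level artifacts, batch/dye effects, serial-biopsy
autocorrelation, and correlated background genes. Passing recovery tests on
these cohorts therefore demonstrates correctness of the algorithms under the
stated model, not performance on real microarray data.

## Numerical and design choices

- All randomness flows from integer seeds through locally scoped RNG streams
  (`with_seed`), so package calls never disturb the caller's RNG and equal
  configurations reproduce outputs bit-for-bit, including file checksums in
  the pipeline manifest.
- Expression TSV uses a strict dialect (tabs, `.` decimal, no quoting,
  15 significant digits) so write–read round trips are value-exact.
- mHG p-values: ties at the observed statistic are counted as hits using a
  relative tolerance of 1e-9; the DP state cap is $10^7$ cells with a
  20,000-permutation fallback.
- Degenerate inputs: constant genes are excluded (ranking, z-scores) with
  counts reported; a constant phenotype or single-sample universe is an
  error; an all-zero membership vector has mHG 1 at prefix 0; identical
  groups give t = 0, p = 1.
- Test and benchmark problem sizes (e.g. 2,000-gene cohorts for ranking
  recovery, 600-gene six-program cohorts for clustering recovery, 200
  replicates for null calibration) were chosen as the smallest scales at
  which the Monte-Carlo assertions are stable.

## Known limitations

- The consensus rule interprets "appearing more than three times in four
  analyses" as >= 3 of 4 (the literal 4-of-4 reading is available).
- The mHG implementation assumes the single-ranked-list mode; a
  target/background two-list mode is not provided.
- No GO-graph propagation or term redundancy reduction is applied.
- Multiple-testing control is per analysis stage; contrasts across many
  stages are reported unadjusted, as per-stage results.
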