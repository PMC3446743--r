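---
title: "Estimating the imprinted share of the transcriptome from SAGE catalogues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the imprinted share of the transcriptome from SAGE catalogues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintSAGE)
```

## The question and the measurement model

Genomic imprinting silences one parental allele of a small set of genes.
Roughly 1% of human genes are predicted to be imprinted, but how much of the
*transcriptome* — the total mRNA output of a cell — those genes account for
is a different quantity: a handful of highly expressed imprinted genes could
dominate a tissue's mRNA pool, or the whole panel could be marginal.

Serial Analysis of Gene Expression (SAGE) gives a direct way to measure
this. A SAGE library reduces each transcript to a 10-nt *tag*: the ten
nucleotides immediately 3' of the 3'-most recognition site of an anchoring
restriction enzyme (almost always NlaIII, site `CATG`). Tag counts are
proportional to transcript abundance, so for a panel of genes with known
tags, the panel's share of a library's transcriptome is simply

$$\text{share} = \frac{\sum_{\text{panel tags } t} n_t}{N_\text{reliable}},$$

where \(n_t\) is the tag's count and \(N_\text{reliable}\) is the library's
total count of informative tags. This package implements that estimate,
end to end, for a packaged panel of 173 established and candidate human
imprinted genes (53 established, 120 candidates), together with the
profile-clustering analyses used to explore how the panel's expression
varies across tissues.

## Pipeline stages and the choices behind them

### Virtual tag annotation

`extract_tag()` reproduces the tag rule: scan the mRNA-sense sequence for
every (possibly overlapping) occurrence of the enzyme site, take the
3'-most site with a complete 10-nt downstream window, and read the tag from
it. Three deliberate conventions:

* **Fallback, not failure.** If the 3'-most site sits within 10 nt of the
  transcript end (or its window contains an `N`), the next site upstream is
  used and the result is flagged `from_fallback_site`. Manual curation of
  "reliable 3' end tags" is not automatable; a deterministic fallback is the
  closest reproducible reading.
* **No poly-A trimming.** Extraction is a pure function of the input
  sequence; a tag equal to `AAAAAAAAAA` is flagged `noninformative` rather
  than being avoided, because poly-A handling belongs to catalogue cleaning.
* **No reverse-complement search.** SAGE tags derive from the sense strand
  of the transcript; sequences are taken as given.

A transcript with no site at all raises a typed condition
(`sage_no_site_error`): such genes are invisible to SAGE with that enzyme.
The packaged panel itself went from 174 candidate entries to 173 for
exactly this reason, and `annotate_panel()` reports such genes rather than
inventing a tag. The panel fixture carries the published per-gene flags:
`multi_mapping` (tag maps to more than one gene), `repetitive`, and
`replaced_unreliable` (3' end tag substituted for an unreliable internal
tag).

### Catalogue cleaning and normalization

`clean_catalogue()` removes the noninformative poly-A tag — exact equality
with `AAAAAAAAAA` only, since near-misses are legitimate tags — and records
the removed count. An optional `min_count` filter drops tags seen fewer
than `min_count` times; `min_count = 5` emulates, at tag level, the
clone-level clean-up that discarded sequencing clones with four or fewer
tags. Clone composition is not recoverable from published tag tables, so
this proxy is exposed as a parameter (default: off) instead of being
applied silently.

`normalize_catalogue()` computes tags per million,
\(\mathrm{tpm}_t = n_t / N_\text{reliable} \times 10^6\). tpm values are
kept at full floating precision; two-decimal rounding is applied only when
writing display tables.

`deduplicate_catalogues()` handles the duplicate-accession problem of
public SAGE repositories with two deterministic rules: known equivalence
pairs keep the first-listed accession, and catalogues with content-identical
count maps collapse to the first in input order. The repositories do not
document which member of a duplicate pair is canonical, so first-listed /
first-seen is a declared convention, not a recovered fact.

### Library selection

`select_libraries()` keeps a library iff (i) the sample is genetically
unaltered, (ii) the catalogue has at least 20,000 reliable tags (inclusive
threshold, compared against the post-cleaning reliable total), and (iii)
the dataset is complete. Criteria (i) and (iii) are curation flags supplied
in the metadata — they were human judgements in the original screen and the
pipeline does not try to infer them from free-text descriptions. Exclusions
report the first failing criterion in the fixed order i, ii, iii.

### Prevalence statistics

`build_matrix()` assembles the libraries × panel-genes tpm matrix.
`summarize_matrix()` yields, per library: cumulative (Sum), Average and Max
tpm, the percent of transcriptome (Sum / 10^6 × 100) and the single-gene
dominance (Max / Sum). Two arithmetic conventions matter:

* The Average divides by the full panel size (173), undetected genes
  included — this is the only convention consistent with the published
  per-library Sum/Average pairs (e.g. 43,563.92 / 173 = 251.81).
* When two panel genes share a tag, both gene columns receive the tag's tpm
  (with a warning), but cumulative sums count each distinct tag once, so
  shared tags cannot inflate the panel's transcriptome share. Shared tags
  remain an acknowledged overestimation risk at the per-gene level, which
  is why the `multi_mapping` flag is carried through.

Cohort means (`cohort_statistics()`) are unweighted across libraries:
each library contributes equally regardless of sequencing depth. A
tag-weighted alternative would answer a subtly different question (share of
all sequenced tags, dominated by the deepest libraries); the unweighted
mean matches how per-cluster averages are conventionally reported.
`detection_profiles()` counts, per gene, the libraries with a nonzero tag
and whether every detection was a single raw tag ("minimum level" — genes
never detected are vacuously minimum-level). `rank_deciles()` lists the
`ceiling(fraction × n)` libraries with the most and least cumulative panel
expression, ties broken by accession.

### Clustering

The clustering stage mirrors an EPCLUST-style analysis, whose exact
algorithmic details are not published; the rules below are this package's
declared, deterministic interpretation:

* **Distance** is `1 - Pearson r` (range [0, 2]). A zero-variance profile
  has no defined correlation; its distance is set to 1 with a warning.
* **K-means seeding** ("most distant (average)"): the first seed is the
  profile farthest from the grand mean profile; each subsequent seed
  maximizes its average distance to the seeds already chosen. Assignment
  uses correlation distance to arithmetic-mean centroids. All ties break to
  the lowest row index, so runs are bit-reproducible; no RNG is involved.
  Because the arithmetic mean is not the exact minimizer of summed
  correlation distance, an assignment pass could in principle raise the
  objective; the iteration therefore stops (keeping the previous labels)
  if it would, which guarantees a non-increasing objective trace.
* **Choice of k** (`choose_k()`): the smallest k whose partition isolates a
  solitary entry, the rule used to size the published cluster counts; if no
  k up to `k_max` does, `k_max` is returned with a warning.
* **Hierarchical trees** are unweighted average linkage (UPGMA) on the same
  distance, with ties broken toward the smallest original row indices,
  updated via the Lance–Williams recurrence (exact for average linkage).
  Average linkage is reducible, so merge heights are non-decreasing and the
  newick export (`write_newick()`) is an ultrametric tree. Results are
  cross-checked in the tests against both a naive recompute-everything
  oracle and `stats::hclust(method = "average")`.
* Profiles are **not** log-transformed by default: the published analysis
  used exponential color shading only for figure display, not as a change
  of metric.

## The synthetic cohort generator

Real SAGE cohorts come from a public repository and cannot be bundled;
`simulate_cohort()` generates cohorts with the statistical structure the
pipeline assumes, plus ground truth, so every stage is testable offline and
parameter recovery can be asserted end to end.

Per library: the reliable tag count is drawn uniformly from
`library_size_range` (default 20,000–400,000, matching the selection
threshold at the low end and deep libraries at the high end); poly-A tags
are added on top at odds \(p/(1-p)\) so the expected poly-A share of the
raw library is `polyA_fraction` (default 2%) while the reliable pool stays
exactly at its drawn size; a binomial share of reliable tags at the
library's target `panel_fraction` is split over the 173 panel genes by a
Dirichlet draw; the rest follows a heavy-tailed background model (Zipf,
exponent 1.1 by default — no abundance model is published for these
libraries, so any heavy-tailed choice serves, and the parameter is exposed)
over a pool of random distinct 10-mers excluding the poly-A and panel tags.

The default `panel_fraction` of 0.01 sits at the center of the observed
0.0008–0.045 range of the imprinted panel's transcriptome share; cluster
proportions default to 185/166/112/29 over C/N/IV/D, the composition of the
492-catalogue screen. The `dominance_concentration` Dirichlet parameter
steers single-gene dominance: empirically, 0.001 gives dominance around
0.9 (the bronchial-epithelium-like regime where one gene carries nearly all
panel expression) and values of 10 or more give balanced profiles with
dominance under a few percent. Exact duplicate libraries and planted
violators of each selection criterion are appended on request, and the
returned truth object records realized per-library panel fractions,
duplicate pairs and intended exclusions.

`simulate_panel_sequences()` inverts tag extraction: each gene gets a
random-background sequence whose 3'-most usable site is immediately
followed by the gene's tag, with a 3-nt 3' remainder — short enough that no
site inside or after the tag can carry a complete 10-nt window, so
`extract_tag()` provably recovers the planted tag.

What the generator does **not** emulate: sequencing error in tags,
ditag/concatemer artifacts, GC or length biases, and biologically
structured co-expression between panel genes (gene shares are exchangeable
Dirichlet draws). Passing tests therefore demonstrate that the pipeline's
arithmetic and selection logic are correct under realistic count
statistics, not that any biological conclusion transfers to a particular
real cohort.

## Numerical conventions and degenerate inputs

* tpm conservation: \(\sum_t \mathrm{tpm}_t = 10^6\) to a relative
  tolerance of \(10^{-6}\) for every non-empty cleaned catalogue.
* Empty catalogues are legal everywhere (zero reliable total, empty tpm
  map); dominance of an all-zero library is defined as 0 in summaries, and
  `dominance_report()` refuses zero-sum rows rather than returning NaN.
* Tag validation is strict (`[ACGT]{10}`) with line numbers in parse
  errors; counts must be non-negative integers.
* Tie-breaks are fixed everywhere (lowest row index in clustering,
  lexicographically smallest gene for the per-library argmax, accession
  order in decile ranking), so identical inputs give identical outputs.

## Worked example

```{r example}
panel <- load_panel_fixture()
table(panel$status)

cfg <- sim_config(n_libraries = 12, panel_fraction = 0.01,
                  background_tag_pool = 1000, seed = 7L)
sim <- simulate_cohort(cfg, panel)

cleaned <- lapply(deduplicate_catalogues(sim$catalogues)$catalogues,
                  clean_catalogue)
sel <- select_libraries(cleaned, sim$metadata)
ncats <- lapply(cleaned[vapply(cleaned, `[[`, "", "accession") %in% sel$kept],
                normalize_catalogue)

m <- build_matrix(ncats, panel)
summaries <- summarize_matrix(m, metadata = sim$metadata)
round(cohort_statistics(summaries)$overall, 3)  # recovers ~1.0 (percent)

dend <- hierarchical_profiles(m)
res <- choose_k(m, k_max = nrow(m))
res$k
```

Test problem sizes were chosen to keep the full suite fast while leaving no
code path untested: oracle comparisons run on hundreds to a thousand random
sequences, brute-force clustering oracles at n = 6–8 (exhaustive
enumeration grows combinatorially), and parameter recovery on cohorts of
8–50 libraries at depths of 20,000–400,000 tags.

## Known limitations

* One tag per gene: transcript isoforms with different 3'-most sites are
  not resolved; the packaged panel carries the published per-gene tag.
* Tag-to-gene ambiguity is flagged (`multi_mapping`), not resolved; no
  genome-wide disambiguation against a reference transcriptome is
  attempted.
* The clone-level clean-up of some source libraries can only be
  approximated by the per-tag `min_count` filter.
* The K-means and tree layouts of the original EPCLUST software are not
  recoverable; cluster *counts* under the solitary-entry rule can depend on
  such implementation details, so cross-tool agreement on exact cluster
  memberships should not be expected.
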