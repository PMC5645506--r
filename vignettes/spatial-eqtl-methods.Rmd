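---
title: "Spatial eQTL mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial eQTL mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spateqtl)
```

## The problem and the procedure

Genome-wide association studies tag disease-associated loci with SNPs, but
the tagged regulatory region and the gene it controls are often far apart on
the linear genome — or on different chromosomes.  spateqtl connects the two
through chromatin structure: a SNP is mapped onto the restriction fragment
it sits on, Hi-C proximity-ligation contacts identify the fragments that
physically touch it in at least one assayed cell line, genes overlapping
those partner fragments become candidate targets, and a genotype-expression
regression per tissue decides which candidates are expression quantitative
trait loci (eQTLs).  The spatial filter is the point: restricting the eQTL
tests to physically connected SNP-gene pairs shrinks the multiple-testing
burden by orders of magnitude relative to an all-pairs trans scan.

The stages, each an exported function:

1. **Digestion** (`digest_genome()`): an in-silico restriction digestion at
   every exact occurrence of the recognition site (default `GATC`, the MboI
   site).  MboI cuts 5' of its site, so the cut coordinate is the first
   base of each occurrence; every non-leading fragment begins with the
   site.  Fragments tile each chromosome exactly in 0-based half-open
   coordinates; a site at position zero would leave an empty leading
   fragment, which is suppressed.
2. **SNP placement** (`locate_fragment()`): 1-based SNP positions map to
   the unique fragment containing them.
3. **Contact lookup** (`load_contacts()`, `partners_of()`): fragment-pair
   contacts per cell line, strictly presence/absence.  Mirrored duplicates
   collapse; lookups are symmetric; partner sets are unions over cell
   lines.  No statistical filtering of contacts is applied: a contact
   captured in any cell line counts, reflecting the view that population
   Hi-C captures the repertoire of *possible* conformations rather than a
   single dominant structure.  A minimum-cell-line-support threshold can be
   imposed downstream via the `n_cell_lines` column, but the default is 1.
4. **Pair building** (`build_pairs()`): one row per distinct (SNP, gene),
   merging supporting cell lines and partner fragments.  Genes on the
   SNP's own fragment are included by default (`include_self = TRUE`) —
   the SNP's fragment is trivially co-localised with itself — and flagged
   `self_fragment` so sensitivity analyses can drop them.
5. **Association scan** (`run_eqtl_scan()`): per tissue, expression is
   rank-transformed to normal scores (Blom offset 3/8, ties sharing the
   mean rank) and regressed on ALT-allele dosage by ordinary least squares
   with an intercept; the two-sided p-value uses the t distribution with
   n − 2 degrees of freedom.  The slope convention is the effect of each
   additional ALT allele relative to REF.
6. **Selection and counting** (`select_significant()`,
   `filter_expressed()`, `summarize_network()`): stepwise
   Benjamini-Hochberg q-values, an RPKM expression filter, and the
   standard count vector (eQTL SNPs, eGenes, pairs, interactions).

`run_pipeline()` chains all stages from a YAML config;
`inst/cli/spatial-eqtl.R` wraps it for shell use.

## cis/trans classification

A pair is **trans** when SNP and gene are on different chromosomes or at
least 1 Mb apart, **cis** when closer.  Two conventions had to be fixed
where common usage is loose:

* **Distance anchor.** The distance runs from the SNP to the gene's
  transcription start site (gene start on +, gene end on −), matching the
  windowing convention of tissue eQTL resources.  The nearest gene edge is
  a defensible alternative; TSS was chosen and is what
  `classify_cis_trans()` implements, with `cis_window` configurable.
* **The exact 1 Mb tie.** "<1 Mb" (cis) and ">1 Mb" (trans) leave the point
  itself unassigned; exactly 1 Mb is classified trans, closing the
  boundary on the trans side.

## Multiple-testing families

The q-value of a test is the smallest FDR level at which the step-up
procedure would reject it:
`q_i = min over {j : p_j >= p_i} of (p_j * m / rank_j)`, capped at 1 and
monotone.  `bh_stepwise()` implements this directly and is cross-checked in
the tests against both a brute-force evaluation of the formula and
`stats::p.adjust(method = "BH")`.

The family structure is the consequential choice:

* **trans**: all trans tests — across SNPs, genes and tissues — form one
  family, mirroring the genome-wide character of trans discovery.
* **cis**: tests are corrected within per-gene families (all cis tests
  targeting one gene, pooled across tissues by default;
  `cis_family = "gene_tissue"` splits further).  A "calculated threshold
  per gene" is the natural reading of per-gene control; a
  permutation-derived per-gene threshold would be the heavier alternative
  and is left as a hook.

Significance is `q <= alpha` (default 0.05).  The inclusive comparison
follows the FDR ≤ 0.05 convention for reported counts; it is configurable
in spirit by adjusting `alpha`.

Whether cis families should pool across tissues is genuinely open; pooling
was chosen because a gene's regulatory element is the same physical object
in every tissue, and a per-tissue split multiplies small families, which
(as the fixture experiments below show) makes the realized false-discovery
proportion noticeably more variable.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `recognition_site` | `GATC` | DNA | MboI, the 4-cutter behind kb-resolution Hi-C |
| `cis_window` | 1e6 | bp | the conventional cis/trans boundary |
| `alpha` | 0.05 | FDR | reported-count convention |
| `rpkm_min` | 1.0 | RPKM | expressed-gene filter, strictly `>` |
| `tier_genome_wide` | 5e-8 | p | genome-wide association significance |
| `tier_suggestive` | 9e-6 | p | upper bound of the suggestive tier (inclusive) |
| `min_samples` | 10 | samples | smallest defensible two-parameter regression |
| `monte_carlo$k` | 483 | SNPs | background set size matching the disease panel |
| `monte_carlo$iterations` | 1000 | sets | Monte Carlo resolution |

## The association model and its limits

The regression is deliberately minimal: no PEER factors, sex, ancestry
components or other covariates.  Reference eQTL resources fit those; this
package's scan is an emulation sufficient for planted-truth testing and
method development.  For fidelity to a covariate-adjusted resource, pass
its export through `run_eqtl_scan(precomputed = ...)`: rows surviving the
spatial filter pass through unchanged, and `select_significant(recompute_q
= FALSE)` thresholds resource-supplied q-values as-is.  Missing genotypes
are dropped pairwise per test; samples are aligned by intersecting IDs,
and a cohort mismatch only errors when the intersection falls below
`min_samples`.

## Monte Carlo enrichment

`run_null()` draws `k` SNPs uniformly **with replacement** from a
background pool, runs the pipeline on each set, and assembles per-metric
null distributions; `compare_observed()` reports both the one-sample
t-test of the null values against the observed count and the empirical
mid-percentile (ties counted half).  The percentile is the defensible
statistic for count data — a t-test against a Monte Carlo null leans on
normality the counts need not have — so both are always co-reported.
Background SNPs are not matched on allele frequency, gene density or LD
score; that is a known limitation of uniform sampling.

Because the association test for a SNP-gene-tissue triple does not depend
on which other SNPs were sampled, the scan over the pool is computed once
and each iteration re-runs only sampling, family-wise selection, the
expression filter and counting.  This is numerically identical to
re-running every stage per iteration.  Iteration `i` uses substream seed
`seed + i` from R's generator, so per-iteration results are independent of
evaluation order and the whole distribution is reproducible from the base
seed.

## What the synthetic generator emulates — and what it does not

`make_fixture()` builds a complete input bundle whose ground truth is
known by construction: chromosome sequences are generated GATC-free and
the site is written in at chosen cut positions, so the fragment map is
exact; each SNP and each gene sits on its own fragment (disjoint sets), so
the planted links determine the spatial pair set exactly; genotypes are
Hardy-Weinberg draws at the stated MAF (the neutral default in the absence
of a stated genotype model); planted (SNP, gene, tissue) triples have
`expression = beta * dosage + Normal(0, noise_sd)` and everything else is
independent noise.  Decoy contacts stress deduplication without touching
SNP fragments, and default to 20.  The default panel is modest — 2 × 60 kb
chromosomes, 30 SNPs, 12 genes, 2 cell lines, 2 tissues, 100 samples,
MAF 0.3, noise SD 1, planted slopes 0.8 — sized so a planted effect has
power near 1 while a full test run stays in seconds.

The generator does **not** emulate LD between SNPs, Hi-C distance decay,
covariate structure, or realistic expression distributions.  Passing
tests therefore demonstrate the correctness of the bookkeeping, the
regression, the family-wise correction and the Monte Carlo machinery —
not robustness to the confounders of real cohort data.

Two structural options matter for interpretation:

* `separate_chromosomes = TRUE` places SNPs on the first chromosome and
  genes elsewhere, making every link trans and pooling all tests into one
  correction family.  The false-discovery-proportion experiment in the
  test suite (50 planted + 500 null tests, n = 200) uses this layout:
  with one pooled family of 550, the realized FDP concentrates near
  alpha × (500/550) ≈ 0.045, whereas scattering the same tests into many
  ten-test families each containing one extreme signal both raises the
  expected FDP (≈ 0.085) and inflates its variance enough that single
  realizations regularly cross 0.10.  This is a property of small-family
  BH worth knowing when choosing `cis_family`.
* `implied_null_rate()` returns the closed-form expectation of each count
  metric under uniform with-replacement sampling of `k` SNPs — the
  probability that at least one of `d` panel SNPs appears in `k` draws
  from `n` is `1 − (1 − d/n)^k` — assuming planted effects are detected
  with power ≈ 1 and no null is called.  It is the oracle the Monte Carlo
  tests compare against (within three null standard deviations).

## Numerical choices and degenerate inputs

* Recognition-site matching is exact; sites overlapping `N` runs are not
  cut (conservative and deterministic).  The scanner handles
  self-overlapping sites by advancing one base per match.
* A constant expression vector cannot be rank-normalised; the gene is
  dropped from testing with a reason code, as are tests with constant
  dosage or fewer than `min_samples` complete pairs.
* An exact linear fit has zero residual variance; its p-value is reported
  as 0 (and 1 for a zero slope).
* `q >= p` holds mathematically for BH q-values; a `pmax` guards the
  last-ulp rounding of `p * m / rank`.
* RPKM filtering is strictly greater-than: a gene at exactly 1.0 is not
  "expressed".
* Contacts referencing fragments absent from the index are rejected and
  counted; SNPs that map to no fragment are skipped with a warning, not an
  error.

## Problem sizes in the shipped tests

The suite checks digestion against a naive site-scan oracle on 1,000
random sequences up to 10 kb; the stepwise correction against a
brute-force oracle on 10,000 random p-vectors of length ≤ 8; the
regression against `stats::lm` at 1e-10 relative tolerance plus a
1,000-replicate null calibration at n = 60; the end-to-end
planted-recovery experiment at 550 tests with n = 200; and enrichment
calibration over 50 experiments of 100 Monte Carlo iterations on a
40-SNP panel.  These sizes keep a full run in a few minutes while leaving
each statistical check several standard errors of headroom.

## Known limitations

* No LD expansion of input SNPs: linked variants on one fragment are
  inseparable at restriction-fragment resolution, and the package reports
  them all rather than electing a causal one.
* No Hi-C contact significance modelling, matrix normalisation or TAD
  calling; the contact layer is presence/absence by design.
* No covariate model in the association scan (see above).
* Background sets for enrichment are drawn uniformly, unmatched on MAF or
  gene density.
* Gene-level bodies only; transcript-level overlap is out of scope.
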