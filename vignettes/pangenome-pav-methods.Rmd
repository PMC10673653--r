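---
title: "Methods: dual-evidence PAV classification and exact pangenome modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-evidence PAV classification and exact pangenome modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpav)
```

This vignette is the package's own account of the methods it implements:
the models, the tunable parameters and their defaults, the numerical
choices made where the design was genuinely open, what the synthetic
generator does and does not emulate, and the known limitations.

## The classification model

A cultivar panel consists of N independently annotated genomes. Orthology
clustering (e.g. OrthoFinder) partitions all genes into orthogroups; an
orthogroup's *occupancy* m is the number of accessions carrying at least
one member. The naive rule — core iff m = N — is biased upward because
family-level clustering will happily join a paralog at a non-syntenic locus
to a family, manufacturing presence in an accession where the ancestral
gene is actually gone.

`vpav` therefore conditions every ortholog call on positional evidence from
a whole-genome alignment, summarised as *anchors*: pairs of aligned
intervals between two genomes. For genes *g* (accession A) and *h*
(accession B), the anchor distance is

d(g, h) = min over anchors joining A and B of max(d_g, d_h),

where the per-side distance d_x is 0 if the anchor interval overlaps gene
*x*'s span on the matching chromosome and otherwise the bp gap between
them. A call is *retained* iff d(g, h) ≤ W. The defaults are:

* **W = 5000 bp, inclusive boundary.** "Within W of each other" is
  operationalised as the max of the two per-side gaps, minimised over
  anchors: both genes must be near the *same* alignment block. A member at
  exactly W is retained.
* **Support is existential ("any"), not universal.** An accession counts as
  supported-present in an orthogroup when at least one of its member genes
  has a retained call to at least one member in any other accession; one
  well-anchored gene rescues the accession's presence call. Requiring
  proximity to *every* counterpart accession would make a single aligner
  dropout veto an otherwise well-supported presence.
* **Filtered genes revert to singletons.** A gene whose every call is
  removed is no longer positional evidence for its family; it is re-seated
  as its own occupancy-1 unit (auxiliary). This is what lets the filter
  undo mis-merges: the family's occupancy drops back to its true value and
  the mis-merged gene is labelled auxiliary, not inherited-core.

A unit is **core** iff its retained members span all N accessions;
otherwise auxiliary. Singletons are auxiliary by construction (N ≥ 2).
Setting `W = Inf` (`mode = "orthogroup"`) recovers pure occupancy
classification; `W < 0` voids all calls.

The synteny-only alternative, `project_to_reference()`, marks a reference
gene present in accession X iff at least `coverage_threshold` of its span
is covered by the union of anchor intervals to X. The threshold defaults
to **0.5** — the natural majority rule when no published cutoff exists —
and is exposed as an argument; the comparison is inclusive (≥).

## Exact accumulation curves

The average core and pan counts over every combination of k accessions
depend on the presence structure only through the occupancy histogram
`counts[m]`: a group of occupancy m is inside all k chosen accessions with
probability C(m, k)/C(N, k) and missed entirely with probability
C(N−m, k)/C(N, k). Hence

* E[core(k)] = Σ_m counts[m] · C(m, k) / C(N, k)
* E[pan(k)] = Σ_m counts[m] · (1 − C(N−m, k) / C(N, k))

with C(a, b) = 0 for a < b. This is an exact O(N·G) replacement for the
exponential enumeration of subsets, which is retained behind a cap
(default 10^5 subsets) as the independent oracle; the suite checks
agreement to 1e−12 across random matrices and exact integer-numerator
equality on a hand-enumerated toy. `expected_pan()` is computed as a single
division of an integer-weight numerator to avoid accumulating one rounding
error per occupancy class. Degenerate inputs are defined: an empty
histogram yields an all-zero curve; k outside 1..N is an error.

Curve units follow the classification unit — orthogroups by default.
`unit = "gene"` weights each unit by its mean member count per carrying
accession (size/occupancy), giving gene-scale curves when paralog expansion
is enabled; both are emitted by the pipeline because either scale is in
common use. "Open" is operationalised as `gain(N) > closedness_threshold`
(default 0 units): plateau statements are otherwise qualitative.

## Feature and expression contrasts

On the collapsed one-isoform gene model, `gene_length = end − start + 1`,
`intron_count = cds_count − 1`, and the total intron length is the coding
footprint (first CDS start to last CDS end) minus the CDS length; these
identities are asserted row-wise in the tests. Multi-isoform genes are
collapsed to the isoform with the greatest total CDS length (ties by
transcript ID) — a deterministic rule chosen because per-gene feature
statistics need one model per gene and no standard says which. "Exon
count" is reported as CDS segment count, matching annotation practice for
coding gene models.

Class contrasts use the Wilcoxon rank-sum test: exact when both groups
have n ≤ 8, otherwise the normal approximation with continuity correction
(the suite checks the two agree within 0.02 at n = 8 vs 8). Density plots
in the literature are descriptive; attaching a rank-sum p makes
"auxiliary genes are shorter" assertable, but the medians and direction
are the primary output and the p-value is secondary. Genes without a TPM
record are excluded from the expression contrast only (recorded as `NA`,
never 0, since absence of quantification is not absence of expression).

## Term enrichment

`term_enrichment()` is the classic one-sided hypergeometric
over-representation test of a foreground against a universe, per term with
at least `min_count = 3` universe annotations (sparser terms are
uninformative and only pay a multiple-testing price). The odds ratio
contrasts the foreground rate with the universe rate, with a Haldane 0.5
correction when any 2×2 cell is empty; defined this way,
foreground = universe gives p = 1 and OR = 1 for every term, the correct
degenerate limit. FDR control is Benjamini–Hochberg. No GO-graph
decorrelation is attempted: published topGO-style FDR values depend on an
unstated algorithm/statistic choice, so printed enrichment p-values are
not reproduction targets; the package instead validates exactness (tail
sums), calibration and power on synthetic data. Enrichment is run at the
orthogroup level in the pipeline (one observation per family, terms
unioned over members) so that occupancy does not multiply-count a family's
annotation.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
not sequences:

* **Layout.** Orthogroups are ancestral genes on fixed 15 kb chromosome
  slots shared by all accessions, so true orthologs are positionally
  conserved; the generator errors when `chrom_length` cannot hold the
  requested slots.
* **Occupancy.** `floor(core_fraction · G)` groups get occupancy N
  (default `core_fraction = 0.53`, a mid-range crop value); the rest draw
  from `occupancy_model` over 1..N−1 — uniform by default, since real
  occupancy spectra for these panels are unpublished, with a beta option
  for the U-shaped spectra seen in other pangenomes. Carriers are uniform
  without replacement.
* **Features.** Gene length is log-normal with class means 3000 bp (core)
  vs 1200 bp (auxiliary) and sdlog 0.4, intron counts Poisson(3) vs
  Poisson(1), CDS fraction 0.6 — encoding "auxiliary genes are shorter
  with fewer introns" at magnitudes typical of plant annotations. TPM is
  log-normal with meanlog log(10) vs log(3), sdlog 1. Structure is drawn
  per orthogroup so copies are identical across accessions (zero jitter ⇒
  identical coordinates), which is what makes anchor emission exact.
* **Noise channels.** `og_error_rate` mis-merges that fraction of
  auxiliary singletons into a random family ≥ 50 kb away (the false
  presence calls the filter must remove); `anchor_dropout` deletes anchors
  at random; `anchor_jitter_sd` and `position_jitter_sd` shake endpoints.
  All default to 0: the defaults are the noiseless study conditions under
  which recovery must be exact.
* **Terms.** A defense-type term is planted at assignment probability
  0.20 in auxiliary vs 0.05 in core families, over three background terms
  at equal probabilities — the qualitative enrichment structure reported
  for auxiliary gene sets.
* **Determinism.** All randomness flows from `params$seed`; emit-stage
  draws use stage seeds drawn once inside `generate_truth()`, so identical
  parameters give byte-identical files.

What passing tests on this generator do **not** show: robustness to
fragmented assemblies (anchors here derive from the same coordinate frame
as the genes), to annotation disagreements between accessions (one gene
per group per accession by default), to tetraploid fractionation
(haplotype complexity is reduced to the reference-projection mode), or to
real aligner artefacts beyond independent dropout and Gaussian jitter.

## Test and verification design

Numerical tolerances are stated with their checks: 1e−12 for closed-form
vs enumeration and hypergeometric vs tail-sum agreement, 0.02 for the
exact-vs-normal rank-sum comparison, 3 standard errors for binomial
recovery of generator rates. The enrichment type-I calibration uses a
single class-independent term over 200 seeded replicates, because the
quantity being calibrated is the per-test false-positive rate of the
hypergeometric test (≤ 7% allows the binomial error around the nominal
5%); the power check plants the 0.20-vs-0.05 term at G = 5000 and requires
it to rank first by q in ≥ 95% of seeds. Problem sizes in the acceptance
suite — N = 11 with G = 20 000 for classification recovery, G = 5000 for
enrichment power, 2000 genes per class for the feature contrast — are the
package's chosen desk-scale study conditions: large enough that planted
effects are unambiguous, small enough to enumerate and to rerun routinely.

## Tie-breaks and other determinism rules

* Isoform collapse: largest CDS total, then lexicographically smallest
  transcript ID.
* Cross-species matching: greedy reciprocal-best by (score descending,
  then the orientation-free lexicographic gene pair), so
  `intersect_core(A, B)` and `intersect_core(B, A)` return the same
  matching and input row order is irrelevant. Greedy reciprocal-best was
  chosen because the linking evidence (orthology vs synteny) is an input,
  not something the package infers.
* Percentages are rounded half away from zero (`round_half_up()`), the
  rule that reproduces printed summary tables; base R's half-to-even would
  not.
* Pipeline outputs carry no timestamps; manifests key input checksums by
  paths relative to the output directory, so identical configurations give
  byte-identical runs wherever they execute.

## Known limitations

* The classifier consumes orthogroups and anchors; it does not infer
  them. Upstream errors beyond the modelled mis-merge/dropout channels
  propagate.
* Gene-level labels inherit from units; a truly present but never-anchored
  gene (e.g. in an unaligned assembly gap) will be demoted to auxiliary —
  the conservative direction for core-marker design, but a direction all
  the same.
* The accumulation model treats accessions as exchangeable; population
  structure (e.g. northern vs southern subpanels) should be modelled by
  running per subpanel, as the curves depend only on the occupancy
  histogram.
* No parametric (Heaps'-law) extrapolation is offered: the closed form is
  exact for the sampled panel, and extrapolating beyond it is a different
  inference problem.
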