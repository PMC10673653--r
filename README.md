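# vpav — pangenome core/auxiliary gene analysis

`vpav` analyses gene presence–absence variation (PAV) across a panel of
sequenced cultivars, as done in pangenome studies of crops such as cranberry
and highbush blueberry. It is aimed at researchers who already have
per-accession gene annotations (GFF3), an OrthoFinder-style orthogroup table,
and pairwise whole-genome-alignment anchors, and who want reproducible,
tested answers to the standard pangenome questions:

* **Which genes are core and which are auxiliary?** A gene is *core* when it
  is present in every one of the N accessions and *auxiliary* when it is
  absent from at least one. Orthogroup membership alone over-calls presence
  (family-level clustering can place a paralog anywhere in the genome), so
  `vpav` implements a dual-evidence rule: an ortholog call between genes
  *g* and *h* only counts when some alignment anchor lies within W bp
  (default W = 5000, inclusive) of **both** genes, measured as
  `min over anchors of max(d_g, d_h)` where `d_x` is 0 if the anchor
  overlaps gene *x* and the bp gap otherwise. Genes whose every call fails
  the filter revert to auxiliary singletons. A purely synteny-based
  alternative (`project_to_reference()`) marks a reference gene present in
  accession X when ≥ 50% of its span is covered by the union of anchors
  to X.

* **How does the pangenome grow as accessions are added?** For the
  occupancy histogram `counts[m]` (number of orthogroups present in exactly
  m of N accessions), the average core and pan sizes over *every* possible
  combination of k accessions have the exact closed form

      E[core(k)] = Σ_m counts[m] · C(m, k) / C(N, k)
      E[pan(k)]  = Σ_m counts[m] · (1 − C(N−m, k) / C(N, k))

  with `C(a, b) = 0` for a < b. `model_curve()` evaluates these for
  k = 1..N together with the marginal gain `pan(k) − pan(k−1)`, and the test
  suite proves the closed form equal to brute-force subset enumeration
  (`enumerate_curve()`).

* **How do core and auxiliary genes differ?** `compute_features()` derives
  per-gene length, CDS length/count, intron count/length and TPM;
  `compare_groups()` contrasts the classes with the Wilcoxon rank-sum test
  (exact for n ≤ 8 per group). `term_enrichment()` tests GO-term
  over-representation with the one-sided hypergeometric test and
  Benjamini–Hochberg FDR.

* **What is shared across species?** `intersect_core()` computes a greedy
  reciprocal-best 1:1 intersection of two species' core sets, and
  `conservation_in_outgroup()` scores how much of that shared core is found
  in outgroup genomes.

Because public pangenome panels are too large for routine testing, the
package ships a ground-truthed synthetic generator
(`simulation_params()` / `generate_truth()` / `simulate_pangenome()`) whose
emitters produce exactly the file formats the readers consume — including
controlled orthogroup mis-merges and anchor dropout — so every stage can be
validated against a known truth.

## Worked example

```r
library(vpav)
params <- simulation_params(n_accessions = 6, n_orthogroups = 1000,
                            core_fraction = 0.53, og_error_rate = 0.05, seed = 42)
truth  <- generate_truth(params)
anns   <- emit_annotations(truth)
tbl    <- emit_orthogroups(truth)   # 5% of auxiliary singletons mis-merged
anch   <- emit_anchors(truth)
labels <- classify_pav(tbl, anns, anch, W = 5000)
summarize_pav(labels, digits = 1)
model_curve(labels)
```

```
mean per-accession: 530.0 core / 759.8 total genes (69.8% core)
units: 530 core / 1000 total (53% core)
       k core_avg   pan_avg  aux_avg  gain_avg
1:     1 759.8333  759.8333   0.0000 759.83333
2:     2 650.6000  869.0667 218.4667 109.23333
3:     3 597.8000  925.5000 327.7000  56.43333
4:     4 566.5333  960.4000 393.8667  34.90000
5:     5 545.3333  983.8333 438.5000  23.43333
6:     6 530.0000 1000.0000 470.0000  16.16667
```

The planted 53% core fraction is recovered exactly at the orthogroup level
despite the injected mis-merges (the 5 kbp filter removes them), while the
per-accession gene-level core share is higher (69.8%) because auxiliary
genes are present in only a subset of accessions. The curve shows the core
estimate shrinking and the pangenome still growing at k = N — an "open"
pangenome (positive `gain_avg` at k = 6). Enrichment of the auxiliary set
then recovers the planted defense-type term:

```r
en <- term_enrichment(terms_by_orthogroup(emit_terms(truth), tbl),
                      foreground = subset(labels$units, label == "auxiliary")$unit_id,
                      universe   = labels$units$unit_id)
head(en, 1)
#       term_id                   term_name fg_with bg_with odds_ratio        fdr_q
# 1: GO:0009607 response to biotic stimulus      67      98   1.530207 2.366795e-05
```

`run_pipeline(run_config(out_dir))` wires all stages (simulate → classify →
model → features → enrich → report) into one deterministic run with a JSON
manifest; `pav_report()` renders a markdown digest.

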