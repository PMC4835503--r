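---
title: "Methods: comparing fungal transcriptional responses to non-self"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing fungal transcriptional responses to non-self}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nonself)
```

# The analysis this package implements

Filamentous fungi mount transcriptional responses both to heterospecific
non-self (bacteria) and to conspecific non-self: vegetative incompatibility
(VI), the genetically controlled programmed cell death that rejects a fusion
cell between genetically different isolates of one species. A recurring
comparative design contrasts a fungus's response to a bacterium it survives,
a bacterium it succumbs to, and the VI reaction, asking how far the three
overlap and what kinds of genes each recruits. `nonself` packages the
quantitative machinery of that design: gene *versatility* scoring,
differential-expression (DE) set construction and overlap statistics,
chromosomal landscapes, categorical enrichment, and cross-species comparison
through reciprocal-best-hit (RBH) orthologs — plus a seeded generator that
emulates the statistical structure of such a study so the entire pipeline is
testable without any external download.

# Versatility: orphan, bins, core

Versatility proxies how readily a gene is gained or lost over evolution, via
the number of genus-level homolog hits of its product (self hit included):

* **orphan** — exactly one (self) hit; index 0;
* **core genome** — an ortholog in a distantly related ascomycete; index
  `n_bins + 1` (11 with the default 10 bins);
* **remaining genes** — ranked by ascending hit count into `n_bins`
  equal-occupancy bins; index = bin number, bin 1 the most lineage-specific.

Core membership takes precedence over the hit count: orthology is the
stronger criterion, so a core gene with a single hit is classified core.
Occupancy balancing puts the larger bins first (6,698 genes over 10 bins
gives eight bins of 670 then two of 669); ties at a bin boundary are split
by a deterministic secondary sort on the gene id. An alternative that keeps
tied hit counts together (at the cost of exact occupancy) is available via
`keep_ties = TRUE`, since equal-occupancy splitting of ties is a convention,
not a biological claim.

# Response sets and thresholds

DE sets are built per condition and direction with strict inequalities:
up-regulated means `log2FC > min_abs_log2fc` and `p < max_p`, down-regulated
mirrors with `log2FC < -min_abs_log2fc`. The defaults are `min_abs_log2fc =
2` (a 4-fold change) and `max_p = 0.01`. Source material for this kind of
analysis is ambiguous between "log2FC > 2" and "FC > 2"; the threshold here
is always on the log2 scale, and the command-line wrapper exposes both
`--min-log2fc` and `--min-fc` (converted as `log2(fc)`), defaulting to the
log2 reading. A gene exactly at a threshold is excluded.

Time points of one condition are pooled as the union of the per-time-point
sets (`pool_conditions()`); for per-gene statistics on a pooled condition
(`pool_records()`) each gene keeps the record with the largest |log2FC| and
the smaller p-value — a reporting convention, chosen because the pooled set
is defined by "regulated at either time".

## Overlap statistics

* `venn()` — exhaustive, mutually exclusive region counts for 2–3 sets.
* `specific_fraction(A, B)` — `100·|A\B|/|A|`, the share of A's genes B
  misses.
* `overlap_test()` — Fisher exact (default) or chi-square on the 2×2 table
  over an **explicit** universe; fold = observed / (|A||B|/universe). The
  universe size is never defaulted because enrichment folds are entirely
  driven by that denominator and different analyses legitimately use
  different universes (annotated genes, all genes, ortholog pairs).
* `magnitude_bias()` — per shared gene, which condition regulates it more
  strongly (|log2FC| comparison, ties counted separately), tested with a
  two-sided binomial sign test by default. A Fisher variant (observed split
  vs an even split of the same total) is provided because figure captions in
  this literature often say "Fisher test" without defining the table; the
  sign test is the default because its null is exactly the 50:50 hypothesis
  being described.
* `fc_concordance()` — Spearman by default (fold changes are heavy-tailed),
  Pearson optional.
* `threshold_profile_overlap()` — rebuilds the sets over an ascending
  fold-change grid and reports the share also present in a reference set
  (e.g. the VI response), the standard way to show that overlap is carried
  by the moderately regulated genes.

P-values of exact tests that underflow double precision are printed as
`<1e-300` rather than `0`.

# Chromosomal landscapes

All positional analysis uses **gene ordinals** (rank along the chromosome),
not base pairs, because every operation is defined in gene units (a "window
of 100 genes"). BED exports map the closed 1-based ordinal interval
`[start, end]` to 0-based half-open `[start-1, end)`, stated in the file
header.

`window_profiles()` slides a 100-gene window (step 1 by default — the step
is a resolution choice, not a statistical one) and records the mean
versatility index and the fraction of window genes in each up-regulated
set. Region calling then applies a per-chromosome threshold:

* **versatility troughs** (regions dense in lineage-specific genes; named
  for the direction of the numeric index): runs of units with value
  strictly below the chromosome's mean − 1 SD;
* **expression hotspots**: the mirrored rule, mean + 1 SD, per condition.
  The mirror is a design choice — no explicit criterion is standard for the
  hotspot side, and symmetry keeps the two calls comparable.

Thresholds are per chromosome (the trough rule is defined "for the whole
chromosome"), computed over window means in the default window mode and
over per-gene indices in gene mode. The minimum-run rule drops runs of
fewer than `min_run = 5` **consecutive units** (windows in window mode,
genes in gene mode) before merging overlapping or adjacent spans. Counting
the run in units rather than in the genes a merged region spans matters in
window mode: any single flagged window already spans a whole window of
genes, so a gene-length rule would never suppress single-window noise —
which is precisely what the rule exists to do. Zero-variance chromosomes
yield no regions, with a warning. Regions are labelled `a`, `b`, … in
genome order, and `flag_telomeric()` marks regions within `k = 100` genes
of a chromosome end ((sub)telomeric annotation has no standard rule; the
margin is configurable).

`region_coincidence()` declares a trough coincident when it overlaps at
least `min_overlap = 1` gene of a hotspot in at least one condition, and
reports hotspots overlapping no other condition's hotspots as
condition-specific.

# Enrichment

`category_enrichment()` computes the Fisher exact two-tail p on
`[in set & category, in set & not; not in set & category, neither]` with
fold `(observed/|set|)/(genome count/universe)`; depletion (fold < 1) is
reported with the same two-tail p. `enrichment_table()` always emits a
Benjamini–Hochberg adjusted column next to the raw p — published tables in
this literature typically threshold raw p only, so both are reported and
the reader chooses. `sweep_thresholds()` rebuilds the set per fold-change
threshold (observed counts are non-increasing by nesting).
`sm_cluster_summary()` reports, per condition, genes up per
secondary-metabolite cluster, the number of clusters with ≥ 1 and ≥ 3
up-regulated genes, and the pooled-cluster-set enrichment.
`updown_bias()` tests a category's up/down split against 50:50 with a
two-sided binomial test (a Fisher variant is available; the exact published
construction for such p-values is usually unstated, so the implementation
names the test it ran). `common_core_report()` counts annotation terms on
the all-conditions intersection sets and reports terms occurring at least
5 times in either direction. Ontology structure is out of scope: GO terms
are flat labels as provided.

# Orthology

`best_hits()` takes the highest score per query, breaking ties by lower
e-value and then lexicographic subject id — BLAST output order is not
reproducible, so the tie-break must be explicit. `reciprocal_best_hits()`
keeps (a, b) iff each is the other's best hit; the output is symmetric in
its inputs and no gene occurs twice. `cross_species_overlap()` counts
ortholog pairs regulated the same way in both species and compares with the
independence expectation `|A∩pairs|·|B∩pairs|/n_orthologs`; the ortholog
pair set is used as the universe by default, with `n_orthologs` exposed
because the choice of universe for such tables is genuinely ambiguous.
`down_up_ratio()` forms `(down_overlap/down_total)/(up_overlap/up_total)`,
reported to one decimal, with a Fisher test of the two proportions.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the rest of the package is validated against.

**Genome** (`generate_genome()`): 10,635 genes on 7 chromosomes; 3,297 core
genes, 640 orphans, 6,698 intermediate genes. Hit counts: orphans 1; core
150–400; remaining log-uniform on 2–400 except inside the 19 implanted
60-gene regions, where they come from the low tail (2–5). About half the
region genes are orphans and core genes are excluded from regions, so the
regions are deep troughs of the index (mean ≈ 1 against a background of
≈ 7.5). Categories are assigned at exact counts (216 TF, 77 NLR, 21
histidine kinases, 18 autophagy genes, 801 secreted proteins with shorter
length draws so an SSP complement below 250 aa emerges, and 35 contiguous
secondary-metabolite clusters totalling 470 genes).

**Region layout** (`default_region_spec()`): 19 regions, 8 telomeric, 13
designated as up-regulation hotspots. The layout is constrained by how
mean ± SD thresholding behaves: a chromosome's threshold is only meaningful
when anchored by real signal mass, and an interior region contributes about
three times the window mass of a telomeric one (windows cannot start before
the chromosome). With 19 regions it is provably impossible to give every
chromosome two regions *and* every cold-region host two hotspot anchors, so
the layout concentrates the six cold (non-hotspot) regions on chromosomes
carrying two designated regions, and gives the last chromosome a single
interior hotspot (a noise hotspot there can coincide with nothing).

**Expression** (`generate_expression()`): regulated sets are drawn with
up-selection probability decreasing in the versatility proxy and
down-selection enriched in core genes (the monotone up/down ratio across
bins); the second bacterial condition shares 79% of the first's genes
(so 21%/22% of the first condition's up/down sets are specific to it) plus
its own specific genes; VI sets are drawn with odds 4 in favour of
bacterial-regulated genes, decaying with the bacterial effect size so the
most strongly regulated bacterial genes overlap VI least (the
threshold-profile decay). Genes in designated regions are up-regulated at
rate 0.85 in the bacterial conditions and VI; the contrast is set so that
detection of the implanted regions operates at roughly four background
standard deviations, i.e. the designed landscape is the ground truth, not a
marginal call. Non-designated (cold) regions are implanted as
**expression-neutral**: their genes draw at the genome-average rate, which
is what "only 13 of 19 regions coincide with a hotspot" means as a
generative statement. Secondary-metabolite clusters, which are up-biased
(odds 2.2) and spatially contiguous, are placed at least 200 genes (a
window plus calling edge) from the implanted regions so the two kinds of
spatial signal stay separable. VI additionally receives two specific
regions placed away from the troughs — the "condition-specific" regions the
coincidence report flags.

Effect sizes are `±(2 + Gamma(shape 4, scale 0.6))` on the log2 scale,
capped at 11.5 — always beyond the selection threshold, so a regulated gene
is regulated by construction and set recovery is exact up to the p-value
filter; the spread above 2 drives the threshold sweeps. VsSf magnitudes are
1.3× VsSm on shared genes (log-normal noise, σ = 0.10). SSP effect sizes
are further scaled (×1.6 above the floor) so SSP enrichment grows with the
fold-change threshold. Regulated p-values are log-uniform below 5×10⁻³;
null genes have log2FC ~ N(0, 0.4) and uniform p. Pooled sets are split
over the two time points with the study's observed both/early/late
proportions.

**Similarity** (`generate_similarity()`): ~712 true ortholog pairs
(0.22 × 3,228) with mutually top scores (250), near decoys (180–240),
background decoys (50–180), and Gaussian score noise (σ = 10). Decoy
records are constructed never to be reciprocal, so RBH errors are pure
misses (precision 1; recall ≈ 0.93 at the default noise): with noise 0 the
true map is recovered exactly, and the generator's recall stays above 0.9
at its default.

**Determinism**: every table draws from its own RNG stream derived from the
master seed by a fixed label (`stream_seed()`), so adding an output never
perturbs existing ones, and identical seeds give byte-identical files.

## What the generator does and does not emulate

It emulates set sizes and overlap structure, versatility composition and
its spatial clustering, category enrichment patterns, magnitude bias, and
an ortholog map with realistic noise. It does **not** emulate read-level
RNA-seq noise or DE-estimation uncertainty (log2FC and p are drawn, not
estimated), real sequence content, GO/Pfam ontology structure,
between-replicate correlation, or compositional artefacts of library
normalisation. A green test suite therefore demonstrates that the
*pipeline arithmetic and detection rules* behave as designed under the
study's statistical structure — not that the upstream DE calls of any real
experiment are sound.

# Numerical choices and degenerate inputs

* Strict inequalities everywhere thresholds appear.
* Chi-square tests are Pearson without continuity correction (counts here
  are genome-scale; the correction is immaterial and its omission keeps the
  statistic the textbook one).
* Fisher p symmetric under table transposition; verified against an
  exhaustive hypergeometric enumeration in the test suite.
* Empty sets or categories: folds are flagged undefined (`NA`) with a
  warning rather than silently zero; empty A in `specific_fraction()` is
  `NA` with a warning.
* Zero-variance inputs (uniform chromosome, constant fold changes) warn and
  return no regions / `NA` rather than erroring.
* Ties in `best_hits()` resolve by e-value then lexicographic subject id.
* `p = 0` from exact tests prints as `<1e-300`.

# Problem sizes in the tests

The test suite runs the full-scale generator (10,635 genes) where the
landscape design is the point, and small constructed instances elsewhere.
The exhaustive Fisher oracle covers all 2×2 tables with N ≤ 60 up to the
table's symmetry group (row/column swap and transposition, whose invariance
is asserted separately on sampled tables); RBH is checked against a
brute-force double loop on score matrices up to 20×20; parameter-recovery
checks use 20 independent datasets. The whole suite completes in about a
minute on one CPU; `scripts/acceptance.R` in a few seconds.

# Known limitations

* Window-mode region boundaries are only resolved to within one window
  size; gene mode gives exact boundaries but is noisier on real data.
* The coincidence count is a property of the mean ± SD rule at window
  resolution; other callers (HMMs, scan statistics) would give different
  region sets.
* The enrichment machinery treats annotations as flat labels; GO
  propagation must happen upstream if desired.
* The generator's independence assumptions (categories assigned
  independently of expression except through the configured odds) make it
  conservative for testing multiplicity behaviour of correlated categories.
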