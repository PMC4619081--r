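---
title: "Detecting promoter-like chromatin signatures at cell-type-regulated cassette exons"
author: "exonchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting promoter-like chromatin signatures at cell-type-regulated cassette exons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonchrom)
```

# The scientific question

Most pre-mRNA splicing happens co-transcriptionally, while the polymerase is
still on chromatin, so the chromatin context of an exon could in principle
influence whether it is included in the mature transcript. `exonchrom`
implements a complete, testable pipeline for one specific version of this
question: among internal (cassette) exons whose inclusion differs between two
cell types, is there a subset whose inclusion change co-occurs with a change
in promoter-characteristic histone acetylation/methylation marks — H3K9ac,
H3K27ac and H3K4me3 — on the exon itself? Exons with this property behave as
if a promoter-like chromatin state had been co-opted into splicing
regulation, typically through linear or spatial (chromatin-loop) proximity to
an active transcription start site (TSS).

The pipeline has five analysis stages plus a synthetic-data generator:

1. **Candidate catalog** (`load_annotation()`, `select_candidate_exons()`):
   internal exons from a GTF annotation that can be scored cleanly for
   cassette regulation.
2. **Inclusion calling** (`count_junctions()`,
   `call_differential_inclusion()`, `apply_regulation_filters()`,
   `pick_exon_per_gene()`): percent-spliced-in (PSI) from junction reads and
   one-sided Fisher exact tests per cell pair.
3. **Chromatin signal** (`exonic_average_signal()`, `differential_eas()`,
   `window_profile()`, `group_association_test()`): per-exon averages of
   ChIP-seq signal tracks and their between-cell differences.
4. **Promoter-like selection** (`standardize_features()`,
   `kmeans_partition()`, `select_promoter_like_clusters()`,
   `assign_cell_roles()`, `holdout_direction_validation()`): k-means on the
   differential-signal matrix and a deterministic concordance rule.
5. **Promoter context** (`gene_expression_from_cage()`,
   `distance_to_used_tss()`, `count_chia_pet_interactions()`,
   `same_state_extension()`, `tss_vs_exon_mark_shift()`,
   `motif_enrichment()`): CAGE-based active-TSS proximity, chromatin-loop
   interactions and chromatin-state extension.

`run_discovery()` orchestrates stages 1–4 from one validated `run_config()`
and writes reproducible outputs with a checksummed manifest;
`simulate_bundle()` generates a complete synthetic input set with recorded
ground truth; `evaluate_against_truth()` closes the loop.

# The statistical model

## Inclusion level

For a cassette exon, junction reads either support inclusion — reads whose
split exactly matches the upstream or downstream flanking intron (`JIR`,
counted on both junctions, hence twice per included molecule) — or exclusion,
reads spanning the flank-to-flank skipping junction (`JER`). The inclusion
level is

$$\psi = \frac{0.5\,JIR}{0.5\,JIR + JER},$$

where the factor 0.5 corrects the double counting of inclusion evidence.
$\psi = 0$ means fully skipped, $\psi = 1$ fully included. Replicates are
pooled before estimation; a replicate-concordance filter
(`replicate_concordance_filter()`, default tolerance 0.1 on $\psi$) stands in
for the irreproducible discovery rate procedure used on ENCODE data — full
IDR is out of scope, and the substitution is deliberately crude: it is a hard
cap on the between-replicate PSI difference, so at moderate sequencing depth
it also removes a noise-dependent fraction (~10 % at 150 reads/replicate) of
genuinely concordant exons. Treat it as a data-quality guard, not as part of
the inferential machinery.

## Differential inclusion

Per exon and cell pair, a 2×2 table of (inclusion, exclusion) reads ×
(cell1, cell2) is tested with *both* one-sided Fisher exact tests
(hypergeometric tails). Each tail is Benjamini–Hochberg-adjusted across all
testable exons of the pair, and exons are classified `more` (higher inclusion
in cell2), `less`, or `notAS` at q < 0.05. The package fixes one orientation
convention everywhere: $\Delta\psi = \psi_2 - \psi_1$ and "more included"
means higher in cell2. (Published descriptions of this design use both
wordings inconsistently; fixing one explicit convention was the only safe
choice.) Exons are testable only with ≥ 1 inclusion read in one cell and
≥ 1 exclusion read in the other, applied after replicate pooling.

Significant exons are further filtered: effect size at least 0.1 in absolute
PSI *or* two-fold (OR semantics — a 0.04 → 0.09 change passes on fold);
host-gene expression (sum of CAGE cluster scores within 100 nt of the gene's
TSSs) changed at most 10-fold; at least 75 % of a 900-bp window centred on
the acceptor uniquely mappable. One exon per gene and direction (lowest
p-value, leftmost on ties) prevents exon-rich genes from dominating.

## Differential chromatin signal and promoter-like selection

The exonic average signal (EAS) is the per-base mean of a signal track over
the exon; the differential signal is the cell2 − cell1 difference on the
same interval, by default as `log2(EAS + 1)` ratios (pseudocount 1). Using
the same genomic interval in both cells cancels sequence-composition biases.
The per-direction feature matrix (three promoter marks plus CTCF and the
input control) is column-standardized and partitioned by k-means (k = 4,
100 restarts, fixed seed; cluster labels ordered by descending mean H3K9ac
so runs are comparable). A cluster is **promoter-like** when its mean
z-scored differential signal is concordant with the inclusion direction and
at least τ = 1 in magnitude for *all three* promoter marks. This replaces
by-eye cluster selection with a deterministic, testable rule; CTCF and the
control contribute to the clustering geometry but never to the rule.

Within each selected exon comparison, the cell with higher inclusion is
labelled C-higher, the other C-lower; ties are dropped. Hold-out validation
(`holdout_direction_validation()`) asks, on a cell pair not used in
discovery, whether the sign of the summed three-mark differential matches
the sign of the inclusion change among exons with $|\Delta\psi| > 0.1$ and
total chromatin difference > 1.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| exon length band | 50–450 | bp | cassette exons; shorter/longer exons have different recognition modes |
| TSS/TTS clearance | 600 | nt | keeps promoter/terminator chromatin out of the exon signal |
| mappability | ≥ 0.75 of 900 bp | fraction | junction counting needs unique alignments around the acceptor |
| effect size | 0.1 or 2-fold | PSI | minimum biologically meaningful inclusion change |
| expression guard | ≤ 10-fold | CAGE score ratio | expression changes confound chromatin differences |
| α | 0.05 | BH q | standard FDR level |
| k, restarts | 4, 100 | — | k = 4 resolves one signal cluster per direction; restarts make it deterministic in practice |
| τ | 1.0 | z-units | "large" concordant shift on all three marks |
| CAGE radius | 100 | nt | cluster-to-TSS assignment |
| used-TSS score | ≥ 1 | tags | a cluster below 1 is not an active TSS |
| hold-out cutoffs | 0.1, 1.0 | PSI, summed log2 | eligibility for direction validation |

The TSS/TTS clearance is checked against all transcripts of the host gene
(strictest reading; `tss_scope = "member"` restricts it to transcripts
containing the exon — annotation conventions differ on which is meant, so
both are supported). The 900-bp mappability window is centred on the
acceptor. The "TSS locus" for the exon-vs-TSS mark comparison is ±200 bp
around the used TSS; the definition is not standardized, so it is a
parameter.

# The synthetic world

`sim_config()` states the world the generator emulates; its defaults are the
conditions the analysis was designed for, not knobs to tune per test:

* ~3 % of cassette exons regulated between the discovery cell pair
  (`frac_regulated = 0.03`), with inclusion changes mostly modest
  (`delta_psi_range = c(0.1, 0.5)`);
* 4 % of regulated exons planted promoter-like (`frac_promoter_like =
  0.04`);
* two replicates, `depth = 50` expected reads per junction class (total
  junction reads per exon and replicate ~ Poisson(3 × depth); inclusion
  reads are binomial with weight $w = 2\psi/(1+\psi)$, which inverts the
  PSI formula so the estimator is centred on the truth);
* mark effects additive on log2 track signal, `mark_effect = 2` z-units of
  the per-bin baseline noise (`noise_sd = 1`), confined to the exon in the
  C-higher cell only; TSSs get a large enrichment in every cell; the input
  control gets a mild opposite shift (open chromatin);
* alternative-TSS usage in 45 % of promoter-like exons, ChIA-PET links to
  the used TSS with probability 0.94 (C-higher) / 0.68 (C-lower), and a
  shared chromatin-state run with the TSS in 40 % of cases — the proportions
  reported for this class of exons.

One modeling subtlety is worth stating explicitly because a green test
depends on it: planted mark effects are defined in z-units of the *per-bin*
track noise, but the clustering features are exon *averages* of those
tracks. Averaging ~8 bins per exon across two cells shrinks the
feature-level noise SD to `noise_sd * sqrt(2/8) = 0.5`, so a +2 planted
shift is ~4 feature-level SDs. `simulate_delta_matrix()` (the direct
matrix-level shortcut used in clustering tests) reproduces this with its
`n_bins = 8` default; modeling the feature noise at the raw `noise_sd`
instead would make the planted cluster only ~2 SDs away and k-means would
absorb 5–6 % of null exons into it. Both routes — direct matrix and full
track simulation — are exercised in the test suite and agree.

What the generator does **not** emulate: read-level alignment artifacts,
fragment-size effects in ChIP, correlated noise between marks, genuine IDR
structure between replicates, unannotated transcription, or sequence-driven
motif occurrences (motif hits are supplied as a binary matrix). A green
planted-recovery test therefore establishes that the statistics and the
plumbing do what they claim on data matching the stated model — not that the
biological effect exists, nor how the pipeline behaves under alignment or
normalization pathologies.

# Numerical and design choices

* **Coordinates.** All internal coordinates are GRanges (1-based, closed),
  the Bioconductor convention; GTF is read 1-based inclusive, BED/BEDPE are
  written/read 0-based half-open. Junction TSVs use 1-based closed intron
  coordinates and exact-match semantics (an off-by-one junction is a
  different junction).
* **Fisher tails.** One-sided p-values are hypergeometric tail sums
  (`phyper`); the suite checks them against explicit `choose()`-based
  enumeration for every 2×2 table with total ≤ 60, to 1e-12.
* **Log2 vs raw differential signal.** Both are implemented; log2 with
  pseudocount 1 is the default as it is robust to sequencing-depth scale.
  Raw differences are available (`transform = "raw"`).
* **Signed-rank and rank-sum.** Group-level association reports both the
  one-sample Wilcoxon signed-rank (per group against zero) and the
  two-sample rank-sum (between direction groups), Bonferroni-corrected by
  the number of features — different summaries of the same question, both
  in common use; the report shows both rather than guessing one.
* **k-means determinism.** Seeded, 100 restarts, labels ordered by mean
  H3K9ac; on planted matrices the selection is invariant to seed and row
  order (verified over seeds in the suite).
* **Standardization before k-means.** Not universally standard, but without
  it the marks' arbitrary track scales weight the distance; z-scoring makes
  τ interpretable. It assumes promoter-like exons are a minority of the
  regulated set (a few percent, as stated); if half the rows were planted
  the column SDs would absorb the effect.
* **Ties and degenerate inputs.** Equal-PSI comparisons are dropped from
  role assignment; zero-variance feature columns standardize to zero with a
  warning; equidistant CAGE clusters assign to the leftmost TSS; windows
  truncated at chromosome boundaries are computed over the retained
  positions and flagged.
* **Cluster-count choice.** k = 4 is the default; `kmeans_inertia()` reports
  within-cluster inertia over k ∈ 2..5 for inspection rather than automating
  the choice.

# Known limitations

Only complete cassette (skipped-exon) events are modeled — no alternative
5'/3' splice sites, retained introns, or mutually exclusive exons. Splice-site
strength scoring is a pluggable interface (`pwm_scorer()` with maxEnt-style
window conventions: 9-nt donor, 23-nt acceptor); no scoring matrices are
bundled. The exclusion-junction definition assumes one skipping junction per
exon (from the member transcript with the nearest flanks), which is exact in
the synthetic world but a simplification for annotations where flanking
exons differ across transcripts. CAGE cluster calling, peak calling, IDR,
and mappability-track generation are consumed as inputs, not reimplemented.

# A worked example

```{r example, eval = FALSE}
library(exonchrom)
cfg <- sim_config(n_genes = 120, frac_regulated = 0.5,
                  frac_promoter_like = 0.15,
                  delta_psi_range = c(0.2, 0.5), depth = 80, seed = 7)
bundle <- simulate_bundle(cfg, "sim_bundle")
rc <- run_config(gtf = bundle$paths$gtf, fasta = bundle$paths$fasta,
                 junctions = bundle$paths$junctions,
                 mappability = bundle$paths$mappability,
                 cage = bundle$paths$cage, tracks = bundle$paths$tracks,
                 cell_pairs = list(c("cellA", "cellB")),
                 out_dir = "run_out")
res <- run_discovery(rc)
evaluate_against_truth(res, bundle$truth)
```

The run directory contains the candidate catalog (BED), per-pair call tables
(TSV), the filtered regulated set with per-mark differential signals, the
promoter-like BED (name field = cell pair), a cluster report, and a
`manifest.json` with parameters and md5 checksums — two runs with the same
inputs and seeds are byte-identical.
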