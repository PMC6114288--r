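---
title: "Region-resolved membrane proteomics for a non-genome-sequenced alga: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-resolved membrane proteomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(charaband)
```

## The scientific problem

Characean internodal cells develop alternating acidic and alkaline surface
zones (pH banding). The acidic zones carry charasomes — convoluted plasma
membrane invaginations enriched in PM H^+^ ATPases — and the question is how
the membrane proteome differs between the two zone types within a single
cell. The organism has no sequenced genome, so peptides from shotgun MS
cannot be assigned to annotated gene models. Instead, the pipeline implemented
here works the way region-resolved studies of non-model organisms do:

1. **Search database from the transcriptome.** Assembled unigenes are
   translated in all six reading frames and the longest open reading frame
   per unigene becomes the protein entry (`build_protein_db()`).
2. **Evidence-level ingestion.** The MS search engine's peptide-ion evidence
   table is consumed as-is; spectrum identification, FDR control and
   match-between-runs belong upstream and are out of scope.
3. **Semi-quantitative class statistics.** Because peptide-to-gene assignment
   is coarse, abundance contrasts are summarised per functional class
   (MapMan/Mercator BIN codes) as the *fraction of total* spectral counts
   (fot), with the acidic/alkaline contrast reported as `fot ratio − 1`
   (positive = acidic-enriched).
4. **Label-free intensity quantitation.** Peptide-ion intensities are
   normalized to the sample total, scaled per ion across treatments, averaged
   over replicates, and summed over proteotypic peptides per protein, with a
   Welch test on log intensities for the differential statistic.

## Database construction

**ORF definition.** An ORF candidate is any maximal stop-free stretch within
one of the six frame translations; a start codon is *not* required and
stretches truncated by the transcript ends are allowed, because de novo
assemblies are dominated by partial transcripts. The stricter
`met-to-stop` policy is available via the `policy` argument. `X` residues
(from `N`-containing codons) terminate candidates under the default so that
no fabricated residues enter the database.

**Determinism.** Equal-length candidates are resolved by a fixed frame order
(forward 0, 1, 2, then reverse 0, 1, 2) and leftmost-first within a frame.
Coordinates are 0-based half-open on the forward strand, with a strand flag,
so a database built from reverse-complemented input is identical up to
strand labels — a property the test suite asserts.

**Thresholds.** `min_aa = 30` residues for database entries (usual practice
for proteogenomic databases; the operation itself accepts `min_len = 1`).
Average molecular weights use IUPAC average residue masses with one water
(18.0153 Da), reported in kDa to one decimal for human-readable output.

**Digestion.** The study's serial LysC-then-trypsin digestion is modelled as
the union of both cleavage rules: after K regardless of the next residue
(LysC), and after K/R except before proline (trypsin). Zero-missed fragments
partition the parent exactly; missed-cleavage variants join adjacent
fragments.

**Peptide matching.** Peptides map to every database protein containing them
as a contiguous substring, with isoleucine and leucine treated as equivalent
by default because MS cannot distinguish them. Coverage is the union of all
(possibly overlapping) occurrence intervals.

## Evidence filtering

Reverse (decoy) and contaminant hits flagged by the upstream search are
removed first. The replicate-presence rule — only peptides found in all
biological replicates are kept — is ambiguous about scope, so both readings
are implemented: the default retains a peptide that is complete in *at least
one* condition (which preserves genuinely condition-specific proteins, and
matches count tables that contain zero-count cells in one fraction); a
`scope = "global"` switch requires completeness in every condition. Presence
is assessed on clean (unflagged) rows only, which makes the two filters
commute — another asserted property.

## Spectral counting and fot

Counts are evidence rows (spectra) per key per condition. For shared
(non-proteotypic) peptides the counting rule is not standard across studies;
the default counts a shared peptide's spectra once per *class* (never twice
within one class, which is the dominant sharing pattern), with a strict mode
that drops shared peptides entirely. The fot denominator is all retained,
annotated peptides of the condition, including the reserved class `35`
(not assigned), so per-condition fot sums to one over mutually exclusive
classes. Enrichment percentages are `round(100 × (acidic − alkaline) /
alkaline)` with half-away-from-zero rounding, matching the integer
percentages conventionally printed; rows with a zero alkaline count keep an
infinite (undefined) percentage rather than being dropped.

A packaged fixture (`chara_band_counts()`) carries the per-protein spectral
counts of the two published tables for the transport and vesicle-transport
classes, keyed by (code, name) pairs because two printed subclasses share a
numeric code. Subclass subtotals, grand totals and the printed enrichment
percentages (40% for the PM/V-type ATPase class, 45% for clathrin heavy
chain) are reproduced from the rows by `subclass_subtotals()` /
`table_grand_totals()` / `enrichment_percent()`.

## Label-free intensity ladder

The pipeline order is fixed: **normalize → scale → average → sum**.

* `build_quant_matrix()` keys ions by (sequence, charge, m/z). Repeated
  spectra of one ion within one sample are repeated measurements of the same
  eluting species and are aggregated by their **mean**, which keeps the
  per-sample ion intensity proportional to abundance regardless of how often
  data-dependent acquisition resampled the ion (a sum would grow with the
  spectral count and square the abundance signal). Zero intensities mean
  "identified, not quantified" and become missing values; nothing is imputed.
* `normalize_total()` divides each ion by its sample's total ion intensity
  (column sums become 1), absorbing loading and response factors; the test
  suite asserts exact scale invariance.
* `scale_across_treatments()` divides each ion by the grand mean of its
  per-treatment mean normalized intensities, computed over the treatments in
  which the ion was observed. After scaling, every ion is centred at 1, so
  scaled values carry *relative* (between-condition) information only;
  absolute abundance ordering is recoverable from the normalized stage, and
  a test verifies exactly that.
* `average_replicates()` takes per-condition means over observed replicates
  and requires at least `min_reps = 3` observations (the study design used
  at least three biological replicates).
* `protein_sums()` adds averaged scaled intensities over proteotypic ions
  only.
* `differential_test()` runs a two-sided Welch t-test on natural-log
  intensities (ion level, or replicate-wise proteotypic sums at protein
  level). The upstream software behind the published analysis is named but
  its test is not specified, so Welch is this package's documented default:
  it is robust to unequal variances and the log transform makes the
  multiplicative noise model approximately normal. Reported ratios are log2
  of the ratio of condition means. p-values are raw by default (mirroring a
  raw p = 0.05 threshold line); Benjamini–Hochberg adjustment is available
  behind `adjust = TRUE`. Degenerate inputs are resolved explicitly: two
  zero-variance groups with equal means give p = 1, with different means the
  smallest representable double; groups with fewer than two observations
  give NA.

## The synthetic-data generator

The generator stands in for the deposited raw data, which cannot ship with
the package. Its defaults describe the emulated design:

| parameter | default | meaning |
|---|---|---|
| conditions | acidic, alkaline | the two membrane fractions |
| `n_replicates` | 3 | biological replicates per condition |
| `n_classes` × `proteins_per_class` | 8 × 6 | BIN classes and members |
| `class_effect` | 2^0.5 … 2^−0.5 | acidic/alkaline abundance ratios, spanning the ±40% magnitude observed for transport/vesicle classes |
| `abundance_meanlog`, `abundance_sdlog` | 0, 1 | log-normal protein baselines |
| `count_scale` | 5 | Poisson spectra per unit abundance per peptide per sample; gives ≥ 500 expected spectra per class per condition, the regime where class fot contrasts are interpretable |
| `intensity_cv` | 0.2 | multiplicative log-normal intensity noise (20% CV) |
| `shared_peptide_fraction` | 0.1 | proteins receiving one peptide copied from another protein |
| `orf_len_range` | 60–150 aa | planted ORF lengths |

**Transcripts.** Each unigene carries exactly one planted ORF: random
codons (uniform over synonymous codons) embedded between a 12-nt boundary
cassette that contains a stop codon in every frame on both strands and
random flanking sequence, on a random strand and frame. Rejection sampling
(re-drawing codons, flanks, and ultimately the amino-acid sequence itself)
enforces that the planted ORF is *strictly* the unique longest stop-free
stretch, so database construction must recover it exactly — the end-to-end
suite asserts 100% recovery.

**Evidence.** Class effects multiply the acidic/alkaline abundance ratio,
applied symmetrically in log space so sample totals stay comparable.
Observable peptides are the 7–25-residue LysC+trypsin fragments; per peptide
and sample the spectral count is Poisson in the condition abundance (summed
over parents for shared peptides) and each observed spectrum carries an
intensity proportional to condition abundance with log-normal noise.
Flagged contaminant and reverse rows are appended at 2% and 1% of rows.
`expected_outputs()` turns the recorded ground truth into closed-form
expectations (Poisson means, fot shares, log2 effects) for recovery tests.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: per-peptide response factors (all peptides of a
protein share its intensity scale), retention-time structure and
match-between-runs, intensity-dependent missingness beyond Poisson zeros,
overdispersed counts, post-translational modifications, and incorrect
identifications surviving FDR control. Conclusions about the pipeline's
statistical calibration transfer to real data only to the extent that these
features are second-order.

## Problem sizes and numerical choices

The shipped analyses and tests use 48 simulated proteins (8 classes × 6),
three replicates per condition and roughly 10⁴ evidence rows; the
brute-force oracles run 200 random cases each; null calibration uses 1000
ions; the class-sign recovery experiment repeats 100 seeded simulations of
a 16-protein design. These sizes were chosen so the whole analysis is
reproducible on a laptop in minutes while keeping Monte-Carlo error well
below the assertion margins (binomial SE ≈ 0.007 at 1000 ions for the
type-I rate). Tolerances: exact identities (column sums, grand means) are
asserted at 10⁻⁹; fot sum-to-one at 10⁻¹²; recovery of planted log2 effects
at a 0.25 median absolute error, several times the observed ≈ 0.1.

## Known limitations

* The fot statistic has no attached inferential error model; it is a
  descriptive contrast, as in the original semi-quantitative analysis.
* The printed enrichment percentages for some protein groups (adaptins,
  coatamers) depend on an aggregation that cannot be reconstructed from the
  published rows; the package reproduces only the arithmetic it can define,
  and asserts only those values.
* Protein-level intensity sums are restricted to proteotypic peptides;
  proteins identified solely through shared peptides are reported as
  spectral counts but not quantified.
* The Welch test at three replicates per group has limited power; the
  pipeline reports effect sizes alongside p-values for that reason.
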