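---
title: "Methods: tsRNA profiling and differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tsRNA profiling and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsrnakit)
library(dplyr)
```

tRNA-derived small RNAs (tsRNAs) are 16–40 nt fragments cut from precursor
or mature tRNAs. They are abundant in exosomes — secreted vesicles whose
RNA cargo is recoverable from culture medium and plasma — which makes them
candidate "liquid biopsy" markers. `tsrnakit` implements the computational
half of such a study: from raw small RNA-seq reads to tsRNA class,
isoacceptor and length profiles, and to two-group differential expression.
This vignette documents the models, the parameters that matter, and the
design decisions, so that a reader can judge what the package's passing
tests do and do not establish.

## The reference model

A tRNA gene is annotated as a genomic interval with strand, an
amino-acid/anticodon label, optional introns (gene-local, half-open
intervals) and optionally the anticodon locus. All coordinates in the
package are 0-based, half-open, and gene-local coordinates always run
5'→3' on the sense strand, so minus-strand genes are handled exactly once,
at sequence extraction.

Two references are built per gene:

* **Mature tRNA** — the spliced gene body plus the non-templated 3' `CCA`
  added during maturation. Mature coordinates include the CCA, so the
  mature 3' end equals the sequence length; this makes 3'-anchored calls
  CCA-aware by construction. The anticodon interval is taken from the
  annotation when present (remapped through splicing), otherwise placed at
  the canonical mature interval (33, 36). Multicopy genes frequently
  produce byte-identical matures; these are collapsed to one canonical
  representative (sorted by isoacceptor label, then sequence, so the
  result is order-independent) and a total `gene → mature` map is kept.
* **Precursor tRNA** — a 50 nt 5' leader, the unspliced body and a 50 nt
  3' trailer, recorded with the boundary offset where the mature 3' end
  sits. The trailer carries the genomic poly-T (transcribed poly-U)
  pol-III terminator tract; 50 nt covers RNase Z trailer fragments.
  Flanks are truncated at contig edges and the realised lengths recorded.

Histidine −1 G addition and other non-templated edits beyond CCA are not
modelled.

## Preprocessing

Reads are trimmed of the 3' adapter by scanning for the *leftmost*
position where a prefix of the adapter matches the read suffix with
overlap ≥ 6 nt and mismatch fraction ≤ 0.1. Because retained inserts are
16–40 nt and reads are ≥ 50 nt, the 3' adapter must be read through:
reads without a 3' adapter hit are discarded. Choosing the leftmost
qualifying position keeps the shortest insert, the conservative
anti-chimera tie-break. A 5' adapter, when configured, is optional per
read: the longest adapter prefix found at the read start (same overlap and
mismatch rules) is removed, and reads without one pass unchanged.

"High quality" is operationalised as: mean Phred ≥ 20, no base below
Phred 5, no `N`. Length selection keeps 16–40 nt inclusive. Identical
inserts are collapsed to counted tags, and every sample's report satisfies
the conservation equation

```
reads_in = discarded_no_adapter + discarded_quality
         + discarded_length + sum(tag counts)
```

which the pipeline asserts on every run.

## Alignment and hierarchical class annotation

Tags are aligned **ungapped and full-length** to per-class references
(miRNA, rRNA, snoRNA, snRNA, piRNA decoy sets plus the tRNA
mature/precursor set), allowing at most one substitution by default:
16–40 nt tags rarely tolerate indels, while modification-induced
mismatches motivate allowing one. Reporting is *best-stratum per class*:
if a tag has an exact hit in a class, that class's mismatched hits are
suppressed, which prevents paralog bleed. The implementation indexes every
reference substring in a hash map; exact hits are direct lookups and
mismatched hits come from pigeonhole piece lookups verified by Hamming
count, so the search is exactly equivalent to a brute-force scan of every
offset (a property the test suite asserts against an independent
brute-force oracle, and cross-checks against `Biostrings::vmatchPattern`).

Each tag is assigned to the highest-priority class with at least one
alignment (`miRNA > tRNA > rRNA > snoRNA > snRNA > piRNA`, configurable);
unaligned tags are `other`. Within the winning class, the tag's
alignments receive uniform weights `1/n`. Whole-genome mapping is out of
scope; the curated per-class references reproduce the composition profile
without a genome download.

## tsRNA classification

For a tag aligned to a mature tRNA of length `L` at `[s, e)`:

* `tRNA-5` iff `s ≤ δ5` (default 1 nt, tolerating a non-templated start);
* `tRNA-3` iff `e ≥ L − δ3` (default 2 nt, tolerating partial CCA);
* `tRNA-i` otherwise;
* a tag satisfying **both** end rules is near-full-length tRNA carryover,
  not a fragment, and is left `unclassified`.

5'- and 3'-anchored fragments are subtyped: a **tRNA half (tRH)** arises
from angiogenin cleavage within the anticodon loop, so a fragment is a tRH
iff it is ≥ 28 nt long **and** its internal breakpoint (`e` for tRNA-5,
`s` for tRNA-3) falls within the anticodon interval padded by 2 nt;
otherwise it is a tRF. Interior fragments are i'-tRFs. The length cut and
window are this package's operationalisation — the class definitions fix
the positions, not the tolerances — and all four tolerances are exposed in
`classifier_params()`.

Precursor-derived **3'U tRFs** are recognised on precursor alignments
that extend past the mature 3' boundary into the trailer *and* end in at
least 2 T's (the transcribed poly-U left by RNase Z / pol-III
termination). Because the mature body is a substring of the precursor,
mature hits normally take precedence over precursor hits; the single
exception is a trailer-crossing candidate 3'U alignment, which is the only
signal that distinguishes precursor fragments.

Multi-mapping is resolved per tag: every retained alignment is classified,
and the majority class by weight wins; ties go conservatively to
`unclassified`. A classified tag contributes its whole weight, split
across the winning class's isoacceptors, so class fractions partition the
tRNA-annotated reads exactly.

The species unit for counting and DE is
`(isoacceptor, positional class, fragment sequence)` — e.g.
`tRNA-GlyGCC-5` plus the fragment — where the fragment sequence is the
*reference subsequence under the winning alignment*. For exact matches
this is the tag itself; for a tag carrying one tolerated mismatch it is
the parent fragment, so sequencing-error variants are counted with the
species they came from (mismatch-tolerant counting, as in
coordinate-keyed tRF annotation tools). Without this, every error read
founds a spurious singleton species, which at high depth can even pass
expression filters and contaminate DE calls.

## Profiles, normalisation, correlation, qPCR arithmetic

Composition fractions are computed over **weighted read counts** (the
convention behind published composition percentages); species-level
fractions are available via `weight_by = "species"`. Length histograms are
integer-binned over the 16–40 nt window with zero bins kept, and the mode
is reported. CPM uses the sample's total annotated small-RNA count as
library size. Replicate correlation is Pearson on `log2(CPM + 1)` over the
*union* of species (absent = 0; intersecting would inflate r); the
pseudocount is declared since no convention is universal.

Two count units coexist, deliberately:

* `build_count_matrix()` — per-sequence tsRNA species, the unit for
  classification outputs and differential expression;
* `feature_count_matrix()` — per reference feature (`class:reference`),
  where reads carrying a sequencing error fold into the feature they align
  to. Replicate-correlation figures use this unit: at desk-scale depth a
  per-sequence table is dominated by 0/1-count error-singleton tags, and a
  correlation over it measures singleton sampling rather than expression
  reproducibility.

Relative qPCR quantification is the standard ΔΔCt:
`2^-((Ct_t,case − Ct_ref,case) − (Ct_t,ctrl − Ct_ref,ctrl))`.

## Differential expression

With five samples per group and no reliable dispersion structure to
borrow, the test is a per-species two-sided **Welch t-test on
log2(CPM + 1)**, after filtering to species with ≥ 5 CPM in at least
`min(group size)` samples. Benjamini–Hochberg adjustment runs across the
post-filter species (that count is `m`). Calls use `q ≤ 0.05` and
`|log2FC| ≥ 1` by default; both are flags. Species with zero variance in
both groups get `p = 1` at equal means, and `p = 0` flagged `degenerate`
otherwise. Count-model alternatives (negative-binomial GLMs) are a
non-goal; the Welch choice is simple, transparent and directly testable
for type-I control.

## The simulator: what it emulates, and what it does not

The generator emits libraries with the statistical structure the analysis
assumes, plus a complete per-read ground truth:

* class mixture with **tRNA = 5%** of reads and miRNA dominant;
* tsRNA type probabilities 0.89 / 0.01 / 0.09 / 0.01 for
  tRNA-5 / tRNA-i / tRNA-3 / 3'U-tRF, so the three mature-derived classes
  stand at 90 / 1 / 9;
* 97% of tsRNA weight on Gly/Glu/Lys/Val isoacceptors;
* tRNA-5 cut model: fragment end ~ discretised Normal(32.5, 1) nt;
  tRNA-3 lengths 16–18 nt; tRNA-i lengths with peaks at 16–17 and
  28–32 nt; 3'U fragments crossing the boundary into the poly-T trailer;
* within-type species abundances spread log-normally (sdlog 0.5),
  mass-preserving per stratum, so class and type masses stay exact;
* substitution errors at 0.001 per base (no indels — consistent with the
  ungapped aligner), a 21 nt 3' adapter, 50 nt reads, uniformly high
  qualities.

A single library is a multinomial draw from the species pool (a technical
replicate); `simulate_two_group()` adds per-sample gamma abundance noise
(dispersion 0.1, an NB mixture) for biological replicates, and per-sample
seeds are derived deterministically from the master seed so any one sample
is regenerable alone. `simulate_count_matrix()` skips reads entirely and
draws NB counts for DE testing at scale (1,000 species in seconds).

Not modelled: realistic quality-score profiles, PCR duplicates, ligation
bias, indels, genomic multi-mapping outside the reference sets, and
modification-driven RT stops. Passing tests therefore establish the
*internal* correctness of trimming, annotation, classification and DE
under the stated noise model — not robustness to library-prep artefacts in
real data.

## Problem sizes and numerical choices

The validation suite runs, by choice, at desk scale:

* classification oracle: all 1,200 substrings (lengths 16–40) of a 75 nt
  mature, 100% agreement required;
* type-fraction recovery: one 50,000-read error-free library, each
  mature-derived fraction within ±1.5 percentage points (a 3σ binomial
  envelope);
* replicate correlation: two 100,000-read replicates, feature-level
  r ≥ 0.95;
* type-I control: twenty null datasets of 1,000 species, 5 vs 5; the mean
  fraction of q ≤ 0.05 calls must stay ≤ 0.07;
* spike-in recovery: 35 up- and 11 down-regulated species at |log2FC| = 2,
  5 vs 5 samples at 250,000 reads each. The depth follows a coverage rule:
  the least abundant spiked species (relative abundance ≈ 2 × 10⁻⁴ within
  5% tsRNA content) must keep roughly ten expected counts in its reduced
  group, otherwise count discreteness — not biology — limits recovery.
  Recall must reach 0.85 with every recovered sign correct.

Ties in the tRF/tRH majority vote fall to tRF; class-majority ties fall to
`unclassified`; fraction vectors are asserted to sum to 1 within 1e-9; and
every profile computation is deterministic, so repeated runs produce
byte-identical TSVs.

## A worked run

```{r example, eval = FALSE}
refs <- make_toy_references(12, seed = 7)
cfg <- simulation_config(seed = 42, n_reads = 50000)
sim <- simulate_library(cfg, refs)

pp <- preprocess_reads(sim$reads, cfg$adapter_3p)
idx <- build_tag_index(refs$references)
ann <- annotate_tags(pp$tags, idx)
rec <- classify_tags(ann, refs$reference)

composition_profile(rec, ann)
length_distribution(rec, "tRNA-5") |> attr("mode")
```

The same stages, file-based and with a manifest, run through
`run_pipeline()` on a sample sheet; `autoplot()` methods and
`plot_*()` functions draw the composition bars, length histograms,
replicate scatter, volcano and DE heatmap.

## Known limitations

* The classifier tolerances (δ5, δ3, half length, anticodon window) are
  declared defaults, not estimates; real datasets may justify
  recalibration.
* Genome-wide mapping is not performed; a fragment matching no configured
  reference lands in `other` rather than being discovered de novo.
* The Welch test treats log-CPM as approximately normal; at very low
  counts a count model would be preferable, and is deliberately out of
  scope.
* tRF-1 nomenclature harmonisation with external databases and
  modification-aware realignment are not attempted.
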