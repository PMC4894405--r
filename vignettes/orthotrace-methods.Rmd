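---
title: "Methods: gene-loss calling, promoter conservation, and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-loss calling, promoter conservation, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthotrace)
```

## The problem

When a well-known gene appears to be missing from a clade of genomes —
the motivating case is the plasma-membrane dopamine transporter (DAT,
*SLC6A3*), which is present throughout vertebrates but undetectable in
birds and reptiles — three analyses have to hold up together before "the
gene was lost" is a defensible claim:

1. **Synteny-anchored absence.** The locus where the gene should sit is
   identified by its flanking marker genes (for DAT, the CLPTM1L–LPCAT1
   pair). The interval between the flanks must be well assembled (no gap
   runs that could hide a gene), and homology hits anywhere in the genome
   must be accounted for — in transporter families the highest-scoring
   hits are usually closely related paralogs (NAT, SERT), not the gene
   under test.
2. **A parsimony argument.** Presence/absence verdicts across species are
   placed on the species tree; under Dollo parsimony (one gain, any
   number of losses) the minimal reconstruction locates the loss events.
3. **Regulatory follow-up.** If a paralog compensates for the lost gene,
   its promoter may carry regulatory elements characteristic of the lost
   gene's promoter. That is tested by scanning promoters with
   transcription-factor binding-site (TFBS) weight matrices, keeping only
   elements conserved within each lineage, and intersecting element sets
   across lineages.

orthotrace implements all three stages as composable functions plus two
orchestrators (`run_loss_pipeline()`, `run_promoter_pipeline()`), and —
because the original genome-scale inputs cannot ship with a package —
seeded simulators that generate miniature inputs with planted ground
truth for every stage.

## Presence/absence calling

### Evidence model

The caller consumes a 12-column tabular hit file (the common
local-alignment dialect: query/subject ids, percent identity, alignment
length, mismatches, gap opens, 1-based query and subject coordinates with
`s_start > s_end` encoding the minus strand, e-value, bit score).
Internally all coordinates are 0-based half-open and strand-explicit; the
conversion happens once, in the readers.

Local hits are first **chained** (`chain_hits()`): hits of one query
against one subject sequence and strand are merged whenever the
subject-side gap is at most `chain_gap` (default 10 kb — an intron
allowance at the scale of these loci). A chain's query coverage is the
length of the union of its query spans divided by the query length, so
split exon hits are credited once and overlapping hits are not
double-counted.

A chain qualifies as evidence for the target gene when

* coverage ≥ `min_query_coverage` (default 0.40),
* alignment-length-weighted mean identity ≥ `min_identity` (default 35%),
* e-value ≤ `max_evalue` (default 1e-5) whenever an e-value is present
  (a `"."` in the table disables this filter for that row — some
  aligners do not report one), and
* the chain region, translated, classifies to the target in a reference
  paralog panel (`classify_hit_paralog()`): the region's longest
  stop-free translated segment is aligned globally against each panel
  member and assigned to the best score, ties broken by identity and
  then panel order (and flagged).

The published analysis made these judgments manually; the thresholds here
are explicit artifact parameters, configurable and echoed into every
call's evidence record.

### Verdicts

`call_presence()` returns one of four verdicts. `present_syntenic`: a
qualifying chain overlaps the interval between the two flank genes.
`present_elsewhere`: a qualifying chain exists elsewhere — a translocated
gene must not be called lost. `absent`: no qualifying chain anywhere,
*and* both flanks were located, *and* the flanked interval's assembly-gap
(N) fraction is at most `gap_max` (default 0.10), so absence cannot be an
assembly artifact. Anything else is `indeterminate`, with the reason
recorded. Raising `min_query_coverage` can only remove qualifying chains,
so it never converts `absent` into a present verdict (tested as a
property).

### Dollo loss inference

`dollo_losses()` places the single gain at the most recent common
ancestor of the present tips — an absent outgroup is "never gained",
not "lost" — and charges one loss to the stem of each maximal all-absent
clade inside that ancestor's subtree. This reconstruction is minimal by
construction; the test suite verifies it against exhaustive enumeration
over all ancestral-state assignments with at most one origin, on 500+
random rooted trees of up to 12 tips. Species with indeterminate calls
are dropped from the tree before inference (and reported), rather than
forced into either state.

## Promoter conservation

### Scanning

A JASPAR-style count matrix is converted to log2-odds weights with a
pseudocount distributed by background frequency:

```
w[b, j] = log2( (counts[b, j] + p * bg[b]) / (N_j + p) / bg[b] )
```

Defaults: pseudocount `p = 0.8`, uniform background 0.25 — the
convention of the JASPAR-associated scanner family; the published
analysis does not state its internals, so both are explicit parameters
rather than baked in. A window's **relative profile score** is
`(score - s_min) / (s_max - s_min)`, where `s_min`/`s_max` are the
minimal/maximal attainable sums; it is 1 exactly at the per-column argmax
consensus and 0 at the anti-consensus. Hits are windows with relative
score strictly above the threshold (default 0.90, matching a published
">90%" cutoff; the comparison is configurable to ≥). Both strands are
scanned by default; minus-strand hits are scored on the reverse
complement and reported in plus-strand coordinates. Windows containing N
are skipped rather than scored with expected values — conservative and
reproducible. A degenerate matrix with `s_max == s_min` scores 1
everywhere by convention.

### Segments, conservation, sharing, anchoring

Promoters are the `W` bases immediately upstream of the TSS (default
W = 2500; the source analysis used "~2.5 kb", so W is configurable),
stored 5'→3' on the coding strand with index `W - 1` at position −1. A
hit is assigned to one of the consecutive upstream segments of `L` bp
(default 500) by its leftmost base: with `u = W - start`,
`k = floor((u - 1) / L) + 1`. The leftmost-base rule is a determinism
choice; midpoint or span-overlap rules would differ only for sites
straddling a boundary.

Within a lineage, a (matrix, segment) pair is **conserved** only if every
species has at least one hit of that matrix in that segment; each
(matrix, segment) pair is treated independently, so one matrix may be
conserved in several segments. Cross-lineage **shared** elements are the
intersection of conserved sets on (matrix, segment), optionally with a
±1 segment tolerance (default exact — "similar regions" is
operationalized as the same segment index).

For display, promoter maps of different lineages are aligned on an
anchor motif (an ARNT matrix in the motivating study) that is conserved
in the proximal segment of every lineage: in each lineage's reference
species (zebra finch for the avian set, mouse for the mammalian sets)
the most TSS-proximal conserved anchor hit defines position 0, and each
element is reported at `u_anchor - u_element` (further upstream =
negative). If the anchor is not conserved everywhere the report is
returned un-anchored with a flag — not an error.

### CpG islands

`find_cpg_islands()` implements the classical criteria (≥200 bp,
GC ≥ 0.5, observed/expected CpG ≥ 0.6, with obs/exp =
`#CG × length / (#C × #G)`) with a 1-bp sliding window and merging of
overlapping qualifying windows into maximal regions. It is a TSS
sanity-check: the distance from island to TSS is reportable, but the TSS
is never auto-shifted.

## Protein identity and similarity

`global_align()` is optimal global alignment under affine gaps (a gap of
length k costs `gap_open + k * gap_extend`; defaults 10 and 0.5), scored
with BLOSUM62 (BLOSUM45 selectable for highly divergent pairs). The
dynamic programming engine is Biostrings'; inputs are aligned in
canonical order internally so that swapping the sequences yields the
mirrored alignment and identity is exactly symmetric even when several
alignments are co-optimal. The suite checks the score against exhaustive
enumeration of all global alignments for short fuzzed pairs.

`identity_similarity()` follows the gap-excluded convention: the default
denominator counts only columns with a residue in both sequences
("gaps not taken into account"); identity counts identical columns,
similarity counts columns with a positive substitution score. Because
published percentages do not always say which denominator was used, the
shorter-sequence and full-alignment-length denominators are selectable.
A residue-range mask (`mask_region()`) restricts the comparison to, e.g.,
a transmembrane-domain span before aligning. Pairwise global alignment
stands in for a progressive multiple alignment here; for pairwise
percentages the two agree up to the usual alignment ambiguity, and MSA
is deliberately out of scope.

## The simulators: what they emulate, and what they do not

All generators take an integer seed, restore the caller's RNG state, and
are byte-reproducible (same seed ⇒ identical FASTA/table output) — the
truth records alone suffice to score every downstream stage.

* `simulate_promoter_set()` draws i.i.d. background at a given GC
  content (default 0.40) and overwrites planted motif sites at recorded
  offsets or uniformly within a target segment; consensus-mode sites have
  relative score exactly 1.0, so recovery is a logic test, not a
  statistical one. Overlapping plants are an error — no silent
  clobbering. Real promoters are not i.i.d. (CpG islands, repeats,
  phylogenetic correlation between species), so passing recovery tests
  demonstrates the bookkeeping — segment assignment, conservation
  filtering, intersection, anchoring — not motif discovery power on real
  sequence.
* `simulate_ortholog_proteins()` evolves a uniformly random root protein
  down a tree, substituting each site with per-branch probability `q`
  (replacement uniform over the other 19 residues, no indels). The model
  is intentionally non-biological so that expected pairwise identity has
  a closed form (`a·b + (1-a)(1-b)/19` with the per-path retention
  probabilities; `(1-q)² + q²/19` for a two-branch pair), recorded in the
  truth and used for calibration tests against exact binomial bands.
* `simulate_locus()` builds `flank_a | intergenic | flank_b | decoys`,
  optionally embedding the reverse-translated target gene (fixed codon
  per residue — reproducible and stop-free) in the interval, N-gap runs
  in the interval, and decoy paralogs *outside* it. Decoys are spaced
  11 kb from the locus — beyond the 10 kb chaining allowance — because
  real paralogs are distant loci, not neighbors; placing them closer
  would merge hits from distinct genes into one chain, an artifact no
  real genome exhibits. The accompanying hit table comes from the
  package's own toy translated search (`align_panel_to_genome()`):
  six-frame translation, stop-free segments ≥ 25 aa, batched
  Smith–Waterman against the query, raw scores ≥ 60 reported with bit
  scores and Karlin–Altschul e-values (gapped BLOSUM62 parameters
  λ = 0.267, K = 0.041), so weak chance alignments carry honest
  significance estimates and the default e-value filter behaves as it
  would on a real search. No external aligner is ever required. The toy
  search does not model splicing, frameshifts, or repeat content.

## Validation sizes and numerical choices

The shipped validation runs at sizes chosen to exercise each contract
thoroughly while staying desk-scale: 1000 fuzzed (matrix ≤ 8 columns,
sequence ≤ 300 bp) scanner cases against exhaustive two-strand
enumeration; 500 random trees (≤ 12 tips) against the exhaustive Dollo
oracle plus the 8-taxon amniote scenario (exactly one loss, on the stem
of the four-species clade planted absent); 200 simulated loci (half
planted present, half absent, with decoys and gap runs) demanding
sensitivity = specificity = 1 and `indeterminate` exactly for loci whose
planted N-fraction exceeds `gap_max`; 150 short fuzzed pairs against
exhaustive alignment enumeration; and identity recovery at q = 0.05,
0.10, 0.20 over 1000 residues within exact 99% binomial bands. Background
false-positive allowances in the planted-promoter test are derived by
exact enumeration of each matrix's score distribution under the
simulation background (a Poisson tail bound on the expected count), not
by a fitted tolerance.

Numerical conventions worth knowing: threshold comparison is strict
(`>`); relative scores are monotone in raw scores up to floating-point
ties; a pseudocount of zero with zero counts is rejected (non-finite
weights) rather than patched; `read_*` functions reject malformed input
with the offending line or row number instead of coercing; and every
tunable that affected a pipeline run is echoed into its JSON report
header, so a report is self-describing.

## Limitations

* Absence calls are only as good as the hit tables and flank annotations
  supplied; the package does not run homology searches against real
  genomes (the toy search exists for simulation, not discovery).
* The conservation analysis treats species as independent; no
  phylogenetic footprinting or branch-length weighting.
* The promoter model has no enhancers, no dinucleotide background, and
  no p-value calibration of motif scores; the relative-score threshold
  is a rank cutoff, not a significance statement.
* Dollo parsimony assumes a gene, once lost, is not regained; for gene
  families with frequent horizontal transfer or re-duplication that
  assumption is wrong and the inferred losses are lower bounds.
* CpG-island criteria are the classical fixed thresholds; specialized
  island finders differ in detail, and the reference tool's algorithm is
  unpublished.
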