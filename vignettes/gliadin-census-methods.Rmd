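---
title: "Methods: rule-based gliadin classification, epitope censusing and spot aggregation"
author: "gliadinCensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based gliadin classification, epitope censusing and spot aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Background

Wheat gliadins are the monomeric half of gluten. Three families are
distinguished by architecture: α-gliadins (one repetitive domain, two
non-repetitive domains, two polyglutamine domains, usually six
cysteines), γ-gliadins (five domains I–V with the degenerate repeat
PFPQ~1–2~(PQQ)~1–2~ in domain II, usually eight cysteines) and
ω-gliadins (short terminal domains around one long repetitive domain,
normally cysteine-free). The ω family splits into ω1,2 (mature starts
ARE-/ARQ-/KEL-, PQQPFP repeats) and ω5 (SRLL-/GRLL- starts, FPQQQ and
QQIPQQ repeats). Two health-relevant properties hang off this
architecture: short Q/P-rich cores recognized by celiac-disease (CD)
T cells — most prominently the protease-resistant 33-mer
`LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF` of D-genome α-gliadins — and the
ω5 cores (QQIPQQQ, QQFPQQQ) that dominate wheat-dependent
exercise-induced anaphylaxis (WDEIA). A gliadin with an *odd* cysteine
count has one unpaired thiol, can graft onto the glutenin polymer and
cap its growth ("chain terminator"), which matters for dough rheology.

`gliadinCensus` turns this body of rules into a deterministic,
configurable pipeline: maturation → classification → segmentation →
epitope census → genome assignment → spot-table aggregation, with a
seeded generator of gliadin-like sequences providing exact ground truth
for validation.

## Coordinate and counting conventions

All coordinates are 1-based and inclusive (the R/Bioconductor
convention; polyglutamine runs are returned as `IRanges`). Motif and
epitope counting is **overlapping at distinct start positions**: this
is the convention under which the 33-mer contains exactly one
DQ2.5-glia-α1a core (`PFPQPQLPY`, position 5) and three DQ2.5-glia-α2
cores (`PQPQLPYPQ`, positions 7/14/21), reproducing the published
per-protein counts for the 33-mer-bearing α-gliadins. A greedy
non-overlapping mode is available (`countOccurrences(mode =
"non_overlapping")`); for spacer-separated repeat copies the two modes
coincide. Note that overlapping counting yields *two* α1b
(`PYPQPQLPY`) copies inside the 33-mer while published tables count
one; the α1b convention is therefore ambiguous and nothing in the
package's validation rests on it.

For the degenerate γ repeat, the four literal expansions of
PFPQ~1–2~(PQQ)~1–2~ are tried at every start, longest first, and at
most one hit is recorded per start. This prevents a single physical
repeat from being counted once per nested expansion.

## Epitope catalog and deamidation

The shipped catalog (`defaultEpitopeCatalog()`) holds native cores,
optional deamidated cores (equal length, differing only as Q→E —
enforced by a validity method), the disease (CD/WDEIA) and source
family. Only four cores are marked `verified = TRUE`: α1a and α2, whose
sequences are pinned by their overlapping counts inside the 33-mer, and
WD-1/WD-2 (QQIPQQQ, QQFPQQQ). The remaining cores (α1b, α3, DQ8-α1, the
γ series, ω1/ω2, WD-3/WD-4) are configuration taken from the published
CD-epitope nomenclature and WDEIA literature; they are deliberately
data, not code, and can be replaced wholesale via
`readEpitopeCatalog()`.

Scanning defaults to `native_only` because deposited gliadin sequences
are genomically native — deamidation is performed by tissue
transglutaminase in the gut. In mode `both` the scanner also matches
the deamidated core and deduplicates per (epitope, start), preferring
the native form. The invariant we maintain (and property-test) is:
replacing each planted native core by its catalog deamidated form
leaves the (epitope, start) hit multiset unchanged in mode `both`. A
blanket Q→E substitution of a whole sequence would *not* preserve hits,
because native cores retain non-deamidatable Q positions.

## Classification cascade

`classifyGliadin()` is total and deterministic. Parameters (all in
`profilerConfig()`):

* **ω rule first**: cysteine count ≤ `omegaMaxCys` (1) and ω-motif
  coverage (fraction of residues under at least one PQQPFP/FPQQQ/QQIPQQ
  occurrence) ≥ `omegaDensityThreshold` (0.30). ω-gliadin bodies are
  motif-saturated, so real members sit far above this threshold, while
  cysteine-rich α/γ sequences are excluded by the parity of the first
  condition alone. The subtype is decided by **dominant repeat
  content** — ω5 iff FPQQQ + QQIPQQ copies outnumber PQQPFP — not by
  the N-terminal signature, because SRLL-starting sequences dominated
  by PQQPFP behave as ω1,2; the signature is recorded as evidence only.
* **γ**: ≥ `gammaMinRepeats` (5) degenerate repeats and 8 ± 1
  cysteines. The tolerance of one admits the observed 9-cysteine γ
  variants without opening the rule to α sequences (which carry no γ
  repeats).
* **α**: 33-mer presence, or ≥ `alphaMinRepeats` (3) α repeat motifs
  (PQPQLPY, PFPQPQ), or a VRV- mature start; and 6 ± 1 cysteines
  (admitting the published 7-cysteine variant).
* otherwise **unclassified** — LMW-GS and non-gluten proteins land here
  by design; the epitope census still runs on them.

Maturation is signature-based only (no signal-peptide model): the
earliest occurrence of any configured mature-start signature within the
first 40 residues marks the mature start. The default signature set
covers the ω starts (ARE/ARQ/KEL/SRL/GRL), the α start VRV, γ starts
NMQ/NIQ and the LMW-GS starts ISQ/SHI/MET. Records with no signature
are passed through unchanged with maturity `unknown` and a warning,
rather than failing the batch.

## Domain segmentation

Repetitive domains are computed as maximal spans of family-motif
occurrences in which gaps up to `segMaxGap` (6) residues are bridged
and spans shorter than `segMinRepLen` (10) are discarded. We chose
occurrence-coverage with gap merging over a sliding-window density
score because it recovers planted block boundaries *exactly* on
constructed sequences, whereas windowed densities smear boundaries by
up to half a window. When a catalog is supplied, family-matched epitope
cores count as repetitive content, so epitopes embedded in a repeat
domain do not interrupt it. Polyglutamine segments are maximal Q runs
(≥ `polyQMinLen`, default 6) outside repetitive spans; a prefix of up
to `maxSigPrefix` (12) residues before the first repetitive domain is
labeled as the N-terminal signature; the remainder is non-repetitive.
Segments are contiguous, non-overlapping and cover the mature sequence
exactly (property-tested). Exact domain boundaries for natural
sequences are *not* a validated surface — there is no quantitative
published boundary definition — only the coverage invariant and
recovery of generator-planted structure are.

## Genome assignment

Diagnostic motif rules are applied first (ω1,2: ARE→D, ARQ/KEL→A; ω5:
SRL/GRL→B; α containing CSTT→B). Everything else falls back to the
nearest labeled reference: global Needleman–Wunsch alignment under
identity scoring (match 1, mismatch 0, linear gap penalty 1 per gapped
position; computed via `Biostrings::pairwiseAlignment`) with identity =
matches / alignment length × 100. The phylogenetic step this replaces
(multiple alignment + tree rendering) decides only which labeled
cluster a query is nearest to, which nearest-reference identity
reproduces without MSA or tree output. If the two best references from
*different* genomes lie within `tieMargin` (0.5) identity points the
call is `unknown` — 0.5 is below the resolution at which within-cluster
similarities are typically reported, so genuine cluster membership is
never vetoed by the margin. Because published similarity values leave
the alignment variant (global/local, gap treatment) unspecified, no
numeric identity value is treated as a validation target; the DP is
instead checked against an exhaustive alignment enumeration for
sequences up to length 8. Co-optimal alignments can differ in
matches/alignment-length at equal score, so the oracle check asserts
membership in the co-optimal identity set.

## Spot-table aggregation

A spot table holds one row per (spot, protein) listing; a spot may be
listed under several families but carries at most one non-minor
(predominant) listing — published tables mark minor components with an
asterisk, and the same gel spot can legitimately appear as predominant
in one family table and minor in another. Conflicting predominant
listings are a validation error. `summarizeSpots()` groups distinct
spots by the predominant listing's category (minor-only spots count as
`unknown`), conserving total volume exactly; `countPredominantSpots()`
excludes minor listings; `genomeShare()` sums spot volumes by the
census genome call of the predominant protein, excluding minor
listings (whether published per-genome shares include minor spots is
unstated; excluding them is the conservative reading). Volumes are kept
at full precision internally and printed with 2 decimals on output.

The shipped `keumkangSpotTable()` fixture transcribes the
spot/protein/category/minor assignments of a published 98-spot survey;
per-spot volumes were only published as supplementary material, so the
fixture's volumes are synthetic — the published per-category totals
split randomly (fixed seed) within each category. Gel-derived
quantities (per-category volume percentages, per-genome volume shares)
are therefore exercised as bookkeeping, not reproduced as measurements.

## The synthetic generator and what it does (not) emulate

`generateProtein()` assembles signal peptide (a fixed cysteine-free
template) + mature signature + repetitive block (repeat units and
planted epitope copies in seeded random order) + polyglutamine runs +
non-repetitive blocks carrying exactly the requested cysteines. All
adjacent units are joined by 3-residue spacers drawn from
{A,S,T,N,G,V}; no three consecutive positions of any catalog core or
repeat unit lie within that alphabet, so a spacer can never complete a
spurious match and **planted counts equal scanned counts exactly** (we
dropped L/I from the commonly used neutral-spacer alphabet because both
occur inside catalog cores). When the 33-mer is embedded, its fixed
epitope content (1× α1a, 2× α1b, 3× α2) is added to the ground truth.
Family defaults are realistic: α with 6 cysteines, two polyQ domains
and ~16 repeat units; γ with 8 cysteines and ~12 repeats; ω1,2 with 15
PQQPFP copies; ω5 with 28 FPQQQ + 10 QQIPQQ copies, matching the scale
of published ω repeat censuses.

What the generator does **not** emulate: natural repeat degeneracy
(real repeats drift, overlap and nest, so natural motif counts are not
spacer-separated), pseudogene-derived stops, post-translational
processing beyond signal cleavage, molecular weight/pI and gel
migration, and MS/MS observability. Passing the round-trip properties
therefore demonstrates the correctness of the counting, classification
and aggregation machinery on sequences whose truth is knowable — it
does not certify classification accuracy on arbitrary natural
sequences, where only the deposited-accession checks apply.

## Validation problem sizes

The test suite validates: motif counts against a naive sliding-window
oracle on 1000 random strings (plus 400 in the unit tests);
overlapping ≥ non-overlapping universally; full parameter recovery
(family, subtype, cysteines, chain-terminator flag, every planted
epitope count) on 200 seeded random specs; volume conservation to
1e-9 and a group-sum oracle on randomized spot tables; pairwise
identity against exhaustive alignment enumeration for sequences up to
length 8; and ≥ 99/100 correct genome recoveries for 2%-mutated panel
copies. These sizes give the properties room to fail while keeping the
default run around a minute.

## Known limitations

* Non-verified catalog cores are literature-derived configuration;
  census columns for them are only as good as the catalog.
* Exact matching only — no fuzzy matching, PWM/HMM scoring or
  digestion simulation; a single substitution inside a core removes the
  hit, which is biologically realistic for T-cell cores but unforgiving
  toward sequencing errors.
* Maturation fails gracefully but silently mis-starts proteins whose
  mature start is not in the signature set; extend
  `profilerConfig(signatureSet=)` for unusual material.
* The deposited accessions used for the published motif/cysteine spot
  checks are not redistributed with the package; the corresponding
  acceptance test requires a one-time fetch into
  `inst/extdata/deposited/`.
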