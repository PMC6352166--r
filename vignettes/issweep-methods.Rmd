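---
title: "Annotating the bacterial IS mobilome with issweep: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating the bacterial IS mobilome with issweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(issweep)
```

## The problem

Insertion sequences (ISs) are minimal mobile elements — a transposase
gene between short terminal inverted repeats (IRs) — whose insertion
duplicates a short stretch of target DNA (the TSD). A bacterial genome
carries a mixture of intact, potentially mobile copies and truncated
scars left by past transposition and deletion. Counting and classifying
both classes per replicon, deciding which intact copies still encode a
functional transposase, and detecting *new* insertions that distinguish
laboratory-adapted strains from their parent are the three questions this
package answers. A fourth, more idiosyncratic one arises in *Thermus*:
a 32 bp segment of an IS110-family element has been recruited as a CRISPR
repeat, so tandem arrays of that segment must be separated from genuine
IS fragments before any census is trustworthy.

## Similarity search

The search stage re-implements what a BLASTn/BLASTX screen would do,
as a self-contained seed-and-extend aligner so that every reported hit is
reproducible and oracle-testable:

1. exact k-mer seeds (nucleotide `seed_len = 12`, protein
   `aa_seed_len = 3`) index the query consensus;
2. each seed is extended ungapped in both directions with an x-drop of
   20; only seeds reaching a triage score (`ungapped_trigger = 35`
   nucleotide, 45 protein) proceed, which keeps random k-mer collisions
   from triggering expensive work;
3. surviving seeds get a full local (Smith–Waterman, affine-gap) extension
   inside a window of half-width `band = 32` around the seed diagonal.

Scoring is +2/−3 with gaps −5/−2 at the nucleotide level and BLOSUM62
with gaps −11/−1 at the protein level. Identity is matches over aligned
columns, gap columns counting as mismatches, N/X never matching — a
conservative definition chosen because it cannot inflate identity at
assembly gaps. Hits pass at ≥ 80% nucleotide identity over ≥ 50 bp, or
≥ 30% amino-acid identity over ≥ 50 aa. E-values are deliberately not
computed: the screening thresholds are identity-based, and in place of an
E-value noise floor the translated level applies a raw-score floor
(`aa_min_score = 80`). That floor was chosen from the structure of the
problem: genuine transposase alignments at the 30% identity level span
hundreds of residues and score in the many hundreds, while the best
random local alignments passing the identity and length filters score
about 60 on a 100 kb genome, so 80 sits between the two regimes with a
wide margin on both sides.

The translated search emulates BLASTX by translating all six frames
(table 11) and aligning each reference transposase against them; hit
coordinates are mapped back to replicon nucleotides through the frame,
and onto the consensus through the recorded transposase CDS position.

`sw_oracle()` is the package's exactness anchor: a full-matrix
Smith–Waterman with Waterman–Eggert-style enumeration (the subject span
of each reported alignment is masked and the DP re-run). The test suite
drives the seeded search against it on hundreds of planted instances; the
documented caveat is that seeding may miss alignments within about two
identity points of the threshold, which the oracle-equivalence tests
therefore exempt.

## From hits to a census

Hits of one IS type and strand within `max_gap = 100` bp merge into a
locus whose coverage is the union of consensus intervals covered —
nucleotide and translated evidence can jointly support one locus.
A locus is **complete** when coverage ≥ 0.95 *and* its genomic span lies
within [0.9·min, 1.1·max] of the family's size range; everything else is
a **partial** copy (scar). The field does not define "complete"
operationally; 95% coverage plus a length window tolerates the terminal
variability real IS families show while rejecting half-elements, and both
knobs are exposed. Locus boundaries are the outermost hit ends, not
IR-extended, because that keeps them deterministic and checkable against
planted truth. Overlapping loci of *different* types are both kept
(nested and composite elements are real); same-type overlaps merge so a
single copy is never counted twice.

TSD detection requires the `dr_len`-bp windows immediately flanking the
locus to be identical — no mismatch tolerance, because the TSD is a
perfect duplication at insertion time and any relaxation manufactures
false TSDs at random flanks. Types with `dr_len = 0` never receive one;
loci at replicon edges are flagged rather than called. IR evidence
compares the locus termini (in consensus orientation) against the catalog
IRs, or against 25 bp consensus termini when the catalog has none, with
up to 3 mismatches per side.

## Activity

A complete locus is putatively active when its ORFs (≥ 80 aa, both
strands, table 11; maximal ORFs only — one per stop codon) restore at
least 90% of a reference transposase at ≥ 30% identity. Split-ORF
tolerance handles families like ISTth7 in which active copies encode the
transposase as consecutive N- and C-terminal ORFs: two same-strand ORFs
in translation order, N-region before C-region on the reference,
overlapping ≤ 30 aa and jointly covering ≥ 90%. The 90% and 30 aa values
operationalize a qualitative rule (ORF comparison against the reference
transposase) that has no published numeric form; both are arguments.
Coverage is measured on the *reference*, not the query, so insertions in
a query ORF cannot fake completeness. Failure reasons distinguish
truncation, frameshift (joint coverage reached by same-strand ORFs in
different frames) and interruption. DDE/DEDD motif checks — ordered
acidic residues spaced 40–160 aa apart — are annotations only: motif
content groups families, it does not decide activity, and a rule that
flipped verdicts on motif absence would silently misclassify diverged but
intact transposases.

## CRISPR repeats versus IS scars

The 32 bp repeat is taken from an explicit coordinate slice of its source
consensus. Copies are located exactly (0 mismatches by default, because
the recruited repeats are identical; a tolerance exists for other
genomes) on both strands, then chained: consecutive same-strand copies
whose gap is a 30–40 bp spacer form an array, and arrays with ≥ 3 copies
are CRISPR arrays. Three is the smallest count that separates an array
from a chance doubled fragment. Partial loci lying inside a CRISPR array
— allowing 40 bp (one spacer length) of slack at each array end, since an
alignment seeded on an array repeat can extend a few bases into flanking
background — are removed from the census and logged; complete loci are
never removed; isolated copies stay, as genuine IS fragments. Spacer sequences are not
extracted — the question here is census contamination, not CRISPR
biology.

## Insertion calling from soft clips

Reads spanning a novel IS junction align to the parent genome with
soft-clipped ends whose clipped bases come from the inserted element.
`extract_softclips()` keeps clips ≥ 10 bp at mapping quality ≥ 20 and
collapses duplicate (position, CIGAR, sequence) records so PCR duplicates
cannot inflate support. Clips cluster per replicon and side within 10 bp;
each cluster's majority-vote consensus (anchored at the junction side) is
compared against the first/last 60 bp of each catalog consensus and their
reverse complements, at ≥ 90% identity. A right-side flank and a
left-side flank of the same type within 20 bp pair into a call; the
positive overlap of the two flank positions *is* the TSD length, which is
why an 8 bp-TSD family yields calls whose `start`/`end` span exactly
8 bp. Calls need ≥ 4 reads per flank (a conventional clip-caller default,
exposed), or twice that for a flagged single-flank call.
`compare_samples()` merges reference loci and per-sample calls within the
same 10 bp window — clip positions jitter a few bp across samples — into
a presence/absence matrix from which novel and shared-novel counts per
replicon follow directly.

## The simulator

`simulate_catalog()` builds fully synthetic IS records with the anatomy
the pipeline relies on: 25 bp IRs (right = reverse complement of left),
one or two transposase CDSs whose catalytic DDE/DEDD residues are planted
at field-typical spacings, family-typical lengths and DR lengths taken
from `is_type_profiles()`, and GC-leaning codons with residue
frequencies biased toward Ala/Gly/Arg/Pro — typical of thermophile
proteomes — so coding segments sit near the host-like GC and simulated
elements reproduce the field observation that IS GC tracks host GC. The consensus
sequences contain no real IS sequence.

`simulate_genome()` plants elements in i.i.d. background at GC 0.681 (the
host genome's mean), with ≥ 500 bp of background between elements,
TSDs copied from the pre-insertion flank, contiguous consensus fragments
for scars, and spacer-separated repeat arrays. `derive_strain()` inserts
full copies (plus TSD) at chosen sites, and `simulate_alignments()` emits
coordinate-sorted SAM records computed from the known junctions: fully
conserved reads as `<n>M` at parent coordinates, junction-straddling
reads with the correct soft clip, element-internal reads as unmapped.
Reads whose aligned anchor would be under 20 bp are emitted unmapped, as
a real mapper would not place them confidently. Substitution errors are
i.i.d. at the configured rate; indels are off by default since
clip-position jitter is exercised separately through the clustering
window. Everything is reproducible from a single integer seed.

What the simulator deliberately does *not* model: mapper-induced
artifacts (mismapping near repeats, clip trimming), repeat-rich
background, indel sequencing errors, and coverage biases. Passing the
planted-recovery tests therefore demonstrates correctness of the
pipeline's logic under clean conditions, not robustness to every artifact
of real libraries — on real data the identity thresholds and support
minima carry that load.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run on deliberately modest
problem sizes — 70 + 40 kb two-replicon genomes with 15 planted elements
for the recovery properties, 40 kb parents with three insertions at 30×
for the caller, 200 planted alignment instances with subjects ≤ 2 kb for
oracle equivalence — chosen so the whole suite exercises every code path
in minutes on one CPU while leaving the statistics (exact counts, 100%
recall, zero false calls) unambiguous. Coordinates in all user-facing
tables are 1-based inclusive, the R/Bioconductor convention; the C++
cores work 0-based half-open and convert at the boundary. Alignment
tie-breaks are fixed (highest score, lowest subject end, lowest query
end; diagonal preferred over gaps) so identical inputs give byte-identical
outputs.

## Known limitations

* The catalog model keeps one consensus per type; highly diverged
  subfamilies would need separate records.
* Activity is sequence-level only: expression, regulation and
  transposition rates are out of scope.
* The translated-search score floor trades sensitivity to *short* (< ~60
  aa) distant transposase fragments for a clean noise margin; such
  fragments are normally also visible at the nucleotide level.
* Insertion calling uses soft-clip evidence only; discordant read pairs
  are not consulted, and the caller reports flank-pair spans rather than
  attempting to reconstruct wider printed interval conventions used in
  published site tables.
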