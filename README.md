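# issweep

Insertion sequences (ISs) are the smallest autonomous mobile genetic
elements in bacteria: 0.7–6 kb segments encoding only a transposase,
usually flanked by short terminal inverted repeats (IRs) and, after
insertion, by a target-site duplication (TSD) of host DNA. In thermophiles
such as *Thermus thermophilus* they are unusually abundant and
concentrated on megaplasmids, and their truncated remnants ("scars")
litter the genome as substrates for homologous recombination. `issweep`
is a tidyverse-native R package for annotating and quantifying this
mobilome, written for microbial genomicists who want every step — from raw
similarity search to cross-strain insertion calling — reproducible in one
place without external aligners or web services.

## What it does

* **Homology search, re-implemented.** Each catalog consensus is searched
  against every replicon with a self-contained seed-and-extend local
  aligner (exact k-mer seeds, ungapped x-drop triage, banded gapped
  extension), at both the nucleotide level (identity ≥ 80%) and in
  six-frame translation against reference transposases (BLOSUM62,
  identity ≥ 30%, translation table 11). An exact Smith–Waterman oracle
  (`sw_oracle()`, Waterman–Eggert enumeration) backs the heuristic in the
  test suite. Identity is defined as matches / aligned columns, with gap
  columns counting as mismatches and N never matching.
* **Locus building.** Hits merge into loci; a locus is *complete* when it
  covers ≥ 95% of the consensus and its length falls within
  [0.9·min, 1.1·max] of the family's size range, otherwise *partial* (an
  IS scar). TSDs are called from identical `dr_len`-bp flanks; IR evidence
  from the locus termini.
* **Activity assessment.** A complete copy is *putatively active* when its
  ORFs restore ≥ 90% of a reference transposase — either as one ORF or,
  for split-ORF-tolerant types such as ISTth7, as a same-strand N-/C-
  terminal ORF pair. DDE/DEDD catalytic-motif content is annotated but
  never decides the verdict.
* **CRISPR filtering.** Tandem copies of a 32 bp IS-derived repeat
  separated by 30–40 bp spacers are CRISPR arrays, not transposition
  scars; they are detected, excluded from partial-IS counts and logged.
  Isolated copies of the same repeat stay in the census as IS fragments.
* **Insertion calling from soft clips.** Soft-clipped read ends against a
  reference genome are clustered per side; clusters whose clip consensus
  matches an IS terminus become flanks, flank pairs become insertion
  calls (the flank overlap is the inferred TSD length), and calls from
  many samples merge into a presence/absence matrix with novel and
  shared-novel counts per replicon.
* **Census statistics.** Per-replicon complete/partial/active counts,
  density in copies per Mbp, occupancy (fraction of replicon bp inside IS
  loci) and IS-vs-host GC.
* **A ground-truthed simulator.** Multi-replicon genomes at host-like GC
  (68.1%) with planted complete copies (IRs + TSDs), scars, CRISPR-like
  arrays, derived strains carrying novel insertions, and coordinate-sorted
  SAM alignments synthesised directly from the known junctions.

## Worked example

```r
library(issweep)

catalog <- simulate_catalog(seed = 1)   # ISTth7-, ISTth4-, IS1000B-like
plan_rep <- tibble::tibble(id = c("chr", "pTT"),
                           kind = c("chromosome", "megaplasmid"),
                           length_bp = c(80000L, 40000L))
plan_is <- tibble::tibble(
  replicon_id = c("chr", "chr", "chr", "pTT", "pTT"),
  is_name     = c("ISTth7", "ISTth7", "IS1000B", "ISTth7", "ISTth4"),
  status      = c("complete", "partial", "complete", "complete", "partial"),
  truncation  = c(NA, 0.4, NA, NA, 0.5),
  strand      = c("+", "-", "+", "-", "+"))
crispr_plan <- tibble::tibble(replicon_id = "chr", source = "IS1000B",
                              slice_start = 1165L, slice_end = 1196L,
                              n_copies = 5L, spacer_min = 30L,
                              spacer_max = 40L)
sim <- simulate_genome(catalog, plan_rep, plan_is, crispr_plan, seed = 2)
scan <- scan_genome(sim$replicons, catalog,
                    crispr = list(source = "IS1000B",
                                  slice_start = 1165, slice_end = 1196))
scan
#> <is_scan> 2 replicon(s), 5 IS loci ( 3 complete / 2 partial ), 3 active,
#>           1 CRISPR array(s) excluded
dplyr::select(tidy(scan), is_name, replicon_id, start, end, strand,
              coverage, status, tsd_seq, verdict)
#>   is_name replicon_id start   end strand coverage   status  tsd_seq verdict
#> 1 IS1000B         chr 12947 14202      +    1.000 complete     <NA>  active
#> 2  ISTth7         chr 33615 34639      +    1.000 complete GCGACGAG  active
#> 3  ISTth7         chr 79457 79866      -    0.400  partial     <NA>    <NA>
#> 4  ISTth7         pTT  6317  7341      -    1.000 complete AGCGGCCG  active
#> 5  ISTth4         pTT 19672 20448      +    0.589  partial     <NA>    <NA>
scan$summary
#>   replicon_id        kind complete partial active density occupancy gc_is gc_host
#> 1         chr  chromosome        2       1      2  36.146     0.032 0.660   0.679
#> 2         pTT megaplasmid        1       1      1  47.952     0.043 0.656   0.677
```

Every planted element is recovered with its planted status, strand and
TSD; the 5-copy repeat array on `chr` is recognised as a CRISPR array and
excluded from the partial count; densities are copies/Mbp and occupancy
the fraction of each replicon inside IS loci. `autoplot(scan)` draws the
per-replicon counts; `compare_samples()` + `autoplot()` do the same for
cross-strain presence matrices.

The package also ships the published *T. thermophilus* census and ISTth7
site tables (`thermus_is_census()`, `istth7_softclip_sites()`): feeding
them through `summarize_replicons()` and `compare_samples()` reproduces
the strain totals (25 and 27 complete copies in HB27 and HB8; 9 and 11
ISTth7 copies) and the domestication counts (7 chromosomal + 2
megaplasmid novel ISTth7 sites in HB27E, 6 + 1 of them shared with
HB27A).

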