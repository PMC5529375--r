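---
title: "Characterizing insect mitochondrial genomes with mitochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing insect mitochondrial genomes with mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

## The problem

An insect mitochondrial genome is a circular molecule of roughly 15–16 kb
carrying a nearly invariant gene complement: 13 protein-coding genes
(PCGs), 22 tRNAs, 2 rRNAs, and one long non-coding span, the A+T-rich
(control) region, which regulates replication and transcription. Once such
a genome has been sequenced and annotated, its characterization follows a
conventional recipe: a per-gene summary table (coordinates, sizes,
intergenic spacers, start and stop codons, tRNA anticodons), nucleotide
composition and strand-asymmetry statistics per region class, codon usage
of the pooled PCGs, the arrangement of the 37 genes around the circle
compared with reference arrangements, and a scan of the control region for
its conserved structural elements. `mitochar` implements that recipe as a
tested pipeline operating on annotated genomes (GenBank flat files, or
FASTA plus a feature TSV), and ships the published characterization tables
of two Bombycoidea moths — *Ampelophaga rubiginosa* (GenBank KT153024,
15,282 bp) and *Rondotia menciana* (GenBank KT258908, 15,636 bp) — as
desk-scale inputs against which every statistic can be recomputed.

## Coordinate conventions

Coordinates are 1-based and inclusive, the GenBank convention. The circle
is linearized at the position where the first annotated feature starts; a
feature with `end < start` spans that origin and its length is
`genome_length - start + 1 + end`. Strand `F` is the majority strand
(carrying 23 of the 37 genes in these moths), `R` the minority strand.
The intergenic spacer after a feature is `next_start - end - 1`; negative
values are genuine overlaps (e.g. the 7-nt atp8/atp6 overlap), and the
last feature's spacer closes the circle back to the first. These
definitions make the telescoping identity

```
sum(size + intergenic) == genome length
```

hold exactly on any circular annotation, which the tests verify both on
synthetic genomes and on the two shipped coordinate sets.

## Start and stop codons

Mitochondrial PCGs start on ATN codons, with the conserved exception of
*cox1*, which initiates on CGA; `classifyStartCodon()` flags anything
outside {ATA, ATT, ATC, ATG, CGA} as non-canonical. Stops may be complete
(TAA/TAG) or incomplete — a terminal T, TA, or A completed to UAA by
polyadenylation of the transcript. `classifyStopCodon()` is driven purely
by the CDS length modulo 3: remainder 0 expects TAA/TAG, remainder 1
accepts T or A, remainder 2 accepts TA; everything else is reported as
`OTHER` and flagged. The terminal-A form is accepted because the shipped
*A. rubiginosa* table annotates *nad5* that way; note that the same table
prints *nad5* as 1,722 nt — a multiple of three — which is internally
inconsistent with a single-base incomplete stop. The classifier reports
what the sequence shows and raises a flag rather than trusting an
annotation; `runCharacterize()` collects such flags into `flags.tsv`
without failing the run.

## Composition and skews

For one region the statistics are the A/T/G/C counts, percentages, A+T
content, and the two skews

    AT skew = (A - T) / (A + T)        GC skew = (G - C) / (G + C)

`compositionByClass()` computes them for the whole genome (counted once on
the majority strand) and for each gene class, where a class is the
concatenation of its members' *sense-strand* sequences. Taking the reading
orientation rather than the majority strand is deliberate: it reproduces
the characteristic negative AT skew of the pooled PCGs (-0.133 in
*A. rubiginosa*), which reflects the T-richness of the coding strands.
Overlapping features are counted per feature, not deduplicated, matching
how such tables are conventionally built. The ambiguity code N counts as
neither AT nor GC. Raw fractions are kept at full precision; report
writers round percentages to 1 decimal and skews to 3 decimals, and a
`raw` flag disables rounding.

One cell of the shipped composition table is worth flagging: the printed
PCG GC skew of *A. rubiginosa* is 0.038, while its own printed counts give
(1135 - 1056)/2191 = 0.036. The package reports the recomputed value; the
discrepancy is treated as a printing slip, as are a handful of percentage
cells that appear to have been rounded half-up.

## Codon usage and RSCU

Codon counting reads each sense-strand CDS as non-overlapping triplets
from position 1, discarding a trailing 1–2 nt (the incomplete stops) and
counting complete stop codons; counts pool across all 13 PCGs. Whether
published counts excluded start codons or incomplete tails is generally
unstated, so this discard-trailing rule is the package's fixed convention,
validated against family-internal arithmetic rather than against
regenerating any specific published table from sequence.

Translation uses the invertebrate mitochondrial code (transl_table 5):
AGA/AGG encode serine (an eight-codon Ser family), AUA encodes methionine,
UGA tryptophan, and the only stops are UAA/UAG — which form a two-codon
family of their own for RSCU purposes, mirroring how published tables
assign the stop pair an RSCU of 2 when only UAA is used. For codon *i* in
a family of size *k* with family total *n*,

    RSCU_i = count_i * k / n

so within any family with nonzero total the RSCU values sum to *k*; a
zero-total family reports 0 for every member. Computation is in the DNA
alphabet; reports transliterate to RNA at the I/O boundary.
`aaComposition()` excludes stops and can split Leu and Ser into the
conventional two-box categories (UUR/CUN, AGN/UCN), under which the three
most common residues in both shipped genomes are Leu(UUR), Ile and Phe.

## Gene order and rearrangement

A `GeneOrder` is a circular sequence of signed labels (sign = strand),
anchored for display at the A+T-rich region; rotation never changes the
adjacency structure. Two reference arrangements are built in: the
ancestral-insect order, whose tRNA cluster downstream of the control
region reads trnI, -trnQ, trnM, nad2, and the derived lepidopteran order,
trnM, trnI, -trnQ, nad2, with the remaining 33 genes in the shared
pancrustacean arrangement.

Rearrangement is quantified by the breakpoint distance: the number of
signed adjacencies (circular closure included) present in one order but
absent from the other. Signs participate in adjacency identity so that
inversions register; whole-molecule reflections are not normalized away,
since inputs are assumed to follow the majority-strand convention. The
source study describes the rearrangement qualitatively; breakpoint
distance is this package's choice of metric, selected because it is the
standard elementary measure and is checkable against an independent
brute-force oracle, which the test suite does exhaustively for small
orders and on randomized instances up to 8 labels. More elaborate measures
(inversion/DCJ distance, tandem-duplication–random-loss reconstruction)
are deliberately out of scope.

`detectTranslocatedGenes()` returns the smallest set of genes whose
removal from both orders makes the remaining adjacency sets identical,
searching subsets of the genes involved in differing adjacencies in order
of increasing size. On the two built-in references it returns exactly
`trnM` — the single-tRNA translocation that separates the derived
lepidopteran arrangement from the ancestral one.

## The control region

`locateATRichRegion()` returns the annotated control feature when present,
and otherwise the longest unannotated span of the circle (warning if that
span does not abut rrnS, where the region sits in these genomes; spans
under 50 nt are rejected). Two element scans run on the region in
majority-strand orientation:

* **ATAGA + poly-T.** Every ATAGA occurrence followed, starting within
  `window` nt of its last base, by a run of at least `min_polyT`
  consecutive T — the conserved lepidopteran motif associated with the
  origin of minority-strand replication. The full run length is reported.
* **Exact tandem repeats.** A self-alignment scan: for each period *p*
  the region is compared against itself shifted by *p*; maximal runs of
  agreement give arrays with fractional final copies allowed. An array
  whose span also has a smaller period is reported only at its smallest
  period, and arrays contained in longer reported arrays are suppressed.

Defaults — `min_polyT = 5`, `window = 20`, `min_period = 2`,
`max_period = 200`, `min_copies = 2.0`, `min_span = 10` — are the
package's own choices (no thresholds are published for these genomes),
set wide enough to detect the described structures; all are exposed as
arguments and command-line flags. Only exact-match repeats are detected:
published repeat counts for these genomes come from a mismatch-tolerant
external tool whose parameters are not printed, so approximate repeats
are out of scope and repeat *counts* are not treated as reproducible
targets. Note that in a 90%+ AT region short period-2 arrays arise by
chance; stricter `min_span`/`min_copies` values isolate long planted or
biological arrays.

## The synthetic generator

`syntheticSpec()`/`generateGenome()` produce annotated genomes whose every
downstream statistic is known by construction. Defaults mirror the
structure of the shipped genomes: 38 features in the lepidopteran
arrangement with gene lengths taken from the *A. rubiginosa* table
(except *nad5*, which uses the self-consistent 1,739 nt / TA stop pair
from *R. menciana*), per-gene start codons as published (CGA for *cox1*),
incomplete stops for nad2/cox1/cox2/nad3, codon weights proportional to
the published *A. rubiginosa* codon counts, class base frequencies from
the published composition percentages, and a control region of 450 nt
carrying an ATAGA + 12-nt poly-T at offset 10 and an aperiodic 23-nt unit
repeated 3.5 times at offset 120. The default genome is ~15.2 kb.

The generator records *realized* counts — the codons actually sampled, the
start/stop codons actually planted — so recovery tests are exact equality,
not statistical. Per-class base counts are tallied from the assembled
circle so that configured overlaps are counted exactly as the extraction
path will see them. Overlapping neighbours are supported only when the
downstream feature is a tRNA or rRNA: its overlapped prefix simply reuses
the bases already laid down. A PCG (or the control region) downstream of
an overlap would have its planted codons overwritten, so such a spec is
rejected as infeasible rather than silently degrading the ground truth.
Boundary bases around planted repeats are adjusted so the planted array is
maximal exactly as recorded, and repeat units are resampled until
aperiodic so the array is reported at its planted period.

What the generator does *not* emulate: real tRNA secondary structure,
substitution processes along a phylogeny, approximate repeats,
heteroplasmy, or sequencing error. Passing recovery tests therefore
demonstrates the correctness of the measurement pipeline, not robustness
to annotation error in real data — that is what the flags report is for.

## Numerical and degenerate-input choices

* Skews are undefined (NA) when the relevant base pair sums to zero;
  empty region classes report size 0 and NA skews.
* A lone feature's intergenic spacer closes the circle onto itself
  (`genome_length - size`).
* `OTHER` stop codons are values with a flag, not errors, so one
  inconsistent gene cannot abort a batch run.
* Report rounding (1-decimal percentages, 3-decimal skews, 2-decimal
  RSCU) matches the conventional print format of such tables.
* The generator seeds R's RNG with the spec's seed on entry, making every
  fixture byte-reproducible from its spec alone.

## Problem sizes used by the test suite

The suite runs entirely on generated or shipped desk-scale data: the two
38-row published coordinate sets, 64-cell codon tables, 20 synthetic
genomes (~15.2 kb each) for full-pipeline recovery, exhaustive
breakpoint-oracle comparison over all signed circular orders of up to 4
labels plus 150 randomized pairs up to 8 labels, and 1,000 random strings
of 10–200 nt (periods up to 25) for the tandem-repeat oracle. These sizes
keep the whole suite under two minutes while exercising every code path;
the statistics themselves are size-independent.

## A worked example

```{r example, eval = FALSE}
library(mitochar)

## reproduce the published whole-genome skews of A. rubiginosa
comp <- publishedComposition("A_rubiginosa")
wg <- comp[comp$region == "whole_genome", ]
atSkew(wg$A, wg$T)    # 0.0167 -> prints as 0.017
gcSkew(wg$G, wg$C)    # -0.189

## and the headline rearrangement
detectTranslocatedGenes(lepidopteranOrder(), ancestralInsectOrder())
#> [1] "trnM"

## run the whole pipeline on a synthetic fixture
fix <- runSimulate(outdir = tempdir(), seed = 7)
runCharacterize(fix[["genbank"]], outdir = file.path(tempdir(), "reports"))
```

## Known limitations

* No de-novo annotation: gene boundaries are inputs, and no attempt is
  made to re-derive them (the software that produced the shipped
  annotations is not stated in the source records).
* Only exact tandem repeats; no approximate-repeat or
  origin-of-replication prediction beyond the motif scan.
* No per-codon-position composition breakdown, no codon-adaptation
  indices, and no phylogenetic inference — the characterization ends
  where alignment-based comparative analysis begins.
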