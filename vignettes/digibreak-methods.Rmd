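---
title: "Digital break mapping with digibreak: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital break mapping with digibreak: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digibreak)
```

## The digital readout

PCR-free double-strand break (DSB) sequencing attaches a sequencing
adapter directly to each blunted break end in fixed cells and puts the
labelled fragments on the flow cell without amplification. The
consequence is a *digital* readout: one retained sequencing read
corresponds to exactly one labelled break end, so the number of reads
whose 5' terminus maps to a genomic position is the number of cells in
the sample broken at that position. All quantification in digibreak
rests on that identity — there is no UMI collapsing, no spike-in
calibration, and no amplification-bias correction, because the data
model has nothing to correct.

A DSB produces two ends. A blunt cut between reference positions $k$
and $k+1$ yields a plus-strand read starting at $k+1$ and a minus-strand
read ending at $k$; staggered cutters shift these offsets according to
their overhang chemistry. digibreak therefore represents a **breakend**
as a width-1 stranded genomic interval, and a break as the (implicit)
pair of its two ends.

## Breakend calling

`call_breakends()` runs a fixed four-stage pipeline:

1. **Alignment filtering.** Alignments with MAPQ < 30 (default) are
   removed as ambiguous, and any read with a soft-clip (`S` in the
   CIGAR) is removed entirely — a clipped 5' end makes single-nucleotide
   break assignment unreliable. The whole read is dropped, not just the
   clipped bases.
2. **Breakend assignment.** The breakend is the 5'-terminal *aligned*
   base of the read: `start` for a plus-strand read, `end` for a
   minus-strand read; the breakend inherits the read's strand. The
   phrase "first 5' nucleotide upstream of the read" admits a second
   reading — the base immediately *preceding* the read — and we keep it
   available as `convention = "preceding_base"`. The terminal-base
   convention is the default because it is the only one consistent with
   the AsiSI site reduction below: AsiSI cuts GCGAT^CGC with a 2-nt 3'
   overhang, so after end blunting the plus-strand 5' terminus sits at
   in-site position 6 and the minus-strand terminus at position 3,
   which is exactly where the reduced site intervals are placed.
3. **Blacklist removal.** Breakends falling inside user-supplied regions
   (poor mappability, chromosome ends, incomplete contigs) are dropped.
   The test is strand-blind: nothing about mappability artifacts is
   strand-specific, and the data we remove here is noise, not signal.
4. **Optical duplicate removal.** Neighbouring flow-cell clusters can
   report the same library molecule twice. Among breakends identical in
   (sample, chromosome, position, strand, lane, tile), single-linkage
   clusters under Euclidean pixel distance ≤ 100 are collapsed to one
   representative — the lexicographically smallest $(x, y)$, so output
   is bit-reproducible. The distance threshold is configurable; 100 px
   mirrors common duplicate-marking practice. Everything else at the
   same position is *kept*: reads from different tiles or lanes, or
   farther apart on the same tile, are recurrent breaks from different
   cells, which is precisely the signal. Reads whose names do not carry
   flow-cell fields are kept and exempted from deduplication (their
   count is reported) — we never silently drop data.

Coordinates are 1-based closed inside R (the Bioconductor convention)
and 0-based half-open in every BED file read or written; the conversion
happens only at the parser/writer boundary.

## Site prediction

`locate_motif()` reports every genomic window within Hamming distance
`max_mm` of a recognition motif, on both strands, with no indels.
Windows containing `N` (or any ambiguity code) never match, which keeps
assembly gaps and chromosome ends out of the site census. For
palindromic motifs such as AAGCTT (HindIII) and GCGATCGC (AsiSI) the
two orientations match at identical loci with identical distances, so
each locus is reported once in forward orientation; per-site break
counts then aggregate the breakends of both strands, which is what
"breaks per site" means for a double-strand cut.

Two site-reduction geometries are provided:

* **AsiSI** (`reduce_asisi_site()`): each 8-bp site becomes two 1-bp
  stranded intervals, at in-site positions 6 (+) and 3 (−). Breakends
  are intersected against these with *strand matching* — a stringent
  test that a break is enzyme-induced.
* **CRISPR** (`crispr_cut_window()`): each protospacer+PAM site becomes
  the unstranded 2-bp window flanking the blunt cut 3 bp upstream of
  the PAM (between protospacer bases 17 and 18 for a 20-nt spacer).
  The overlap here is strand-blind: both ends of a blunt cut fall in
  the window, and requiring strand agreement would halve sensitivity
  for no specificity gain.

HindIII quantification, by contrast, intersects breakends with the full
6-bp site interval, strand-blind: the benchmark digestion question is
"was this site cut", not "which end is this", and the filled-in 5'
overhang spreads ends across the site.

## CRISPR off-target discovery

Candidates are every 23-bp window (both strands) whose combined
spacer+PAM mismatch count is within budget; the PAM's `N` matches
anything, and each non-G at the two fixed PAM positions counts one
mismatch, the most direct reading of "mismatches in the spacer and
canonical PAM combined". Bulges are not modelled — the search is
fixed-length. Candidate enumeration and motif search are built on
`Biostrings::matchPattern`, and the test suite holds both to exact
agreement with a naive all-windows Hamming scan.

Discovery then runs a 2 × 4 × 4 grid of filter conditions: total
mismatch budget ∈ {6, 7}, seed mismatch budget ∈ {2, 3, 4, 5} (the seed
being the 12 nt proximal to the PAM), and recurrence threshold
n ∈ {2, 3, 4, 5}. Under one condition, a candidate with at least one
breakend in its cut window is called if it has at most n total
mismatches *or* more than one breakend: high-mismatch sites must show
independent recurrence to be believed. Breaks are counted per sample,
not pooled across replicates (a pooled mode would inflate recurrence
with sample count; the per-sample rule is the conservative reading).
Call sets are provably monotone along each relaxation axis of the grid,
and the tests assert this on simulated data.

The empirical FDR uses untreated control samples as the noise estimate:
per condition, $T$ is the number of distinct sites called across the
treated group and $F$ across the control group, combined by union over
replicates (an intersection mode is available), and
$\mathrm{FDR} = F/(T+F)$, defined as 0 when both are 0. The
complementary form $F/T$ is exposed via `formula = "F/T"`. The union
reading and the $F/(T+F)$ form are design choices: with control ≡
treated the formula yields exactly 1/2, a boundary behaviour the test
suite documents. `select_condition()` picks the condition maximising
treated yield subject to FDR ≤ α (default α = 0.05), breaking ties
toward the stricter condition (smaller total budget, then seed budget,
then recurrence threshold) so the default choice is reproducible and
conservative.

## Quantification

Ranking sorts sites by break count with deterministic tie-breaking
(chromosome, then start); the cumulative break frequency is computed on
exact integer counts and converted to percentages only at output, so
the curve is monotone and ends at exactly 100%. A breakend overlapping
two predicted sites counts toward both, and the double-counted total is
reported so users can audit it. Normalisations are exact ratios:
breaks per cell (total breaks / cells assayed) and nuclease-induced
breaks per million reads. In-silico subsampling is per-breakend
Bernoulli thinning (an exact-count mode exists); because reads are
breaks, per-site counts scale linearly with the retained fraction up to
binomial noise, and the tests verify the regression of subsampled
counts on the fraction has the original count as slope and zero
intercept.

`recurrent_break_table()` collapses breakends by position (strand-aware
by default; Fig.-style strand-blind collapsing is a flag) and flags
positions that also break in the control — endogenous fragile sites
rather than induced cuts.

## The simulator

`simulate_breakseq()` generates the full data path with known truth:

* **Genome**: i.i.d. bases at a configurable GC fraction (default 0.41,
  human-like), with planted site copies that are exact,
  non-overlapping, and rejection-checked so no spurious exact copy of a
  planted sequence exists anywhere else — planted-truth bookkeeping is
  therefore exact, not approximate.
* **Break events**: per-site cutting efficiencies drawn from
  Beta(0.5, 2) by default — a strongly right-skewed distribution chosen
  to reproduce the orders-of-magnitude spread of per-site cutting seen
  in cell populations (a few near-saturated sites, a long tail of
  rarely cut ones); each of the `n_cells` cells (default 5000) cuts
  each site independently with its efficiency; every cut emits exactly
  two ends at chemistry-determined offsets (AsiSI 6/+ and 3/−; HindIII
  modelled with filled-in 5' overhangs at in-site positions 2/+ and
  5/−, a modelling choice since the exact offsets are not standardised;
  Cas9 blunt 3 bp upstream of the PAM; generic blunt at the motif
  midpoint). Endogenous background breaks arrive as
  Poisson(`background_rate` × cells) blunt cuts at uniform positions,
  default 2 per cell — the endogenous level of untreated human cells.
* **Reads**: one error-free, fully mapped (MAPQ 60) read per break end,
  truncated at contig boundaries, with Illumina-convention names. Reads
  sharing (position, strand, lane, tile) are placed on a sparse 300-px
  grid (jitter ≤ 20 px), so distinct break events are never within the
  duplicate radius of one another, directly or through a chain via an
  injected duplicate; injected optical duplicates sit within ±50 px of
  their parent on the same tile. This separation is a *generator
  guarantee that makes exact truth recovery a well-posed test*, not a
  claim about real flow cells, where unrelated clusters can
  occasionally sit close enough to be collapsed.

All randomness flows from one master seed; the three stages use
`seed`, `seed + 1`, `seed + 2` so each stage is individually
reproducible. Identical configurations give byte-identical outputs.

What the simulator deliberately omits: sequencing errors, partial
alignability, PCR amplification (the assay is PCR-free by construction),
chromatin accessibility and methylation effects on cutting, and indel
repair outcomes. Passing the end-to-end identity tests therefore shows
the pipeline's bookkeeping is exact under the stated model; it does not
show robustness to alignment noise, which the real pipeline delegates
to the upstream aligner and MAPQ/soft-clip filters.

## Problem sizes and test design

The shipped test suite runs the full digital-identity check on a 1 Mb
genome with 20 AsiSI sites, 5000 cells, Beta(0.5, 2) efficiencies and 2
background breaks per cell (≈ 60,000 reads end-to-end, with and without
10% injected optical duplicates); oracle-equivalence checks compare the
motif and candidate scans against a brute-force all-windows Hamming
scan on one hundred 100-kb random sequences; the grid-monotonicity,
subsampling-proportionality and FDR-recovery properties run on smaller
seeded simulations. These sizes were chosen so the whole suite
exercises every pipeline stage at realistic per-site break counts while
remaining a desk-scale computation. Genome-scale site censuses (e.g.
the 1211 AsiSI loci on human chr1–X after excluding chrY for a female
cell line) use the same `locate_motif()` + `exclude_chromosomes()`
path, which the suite validates on synthetic multi-chromosome genomes
with planted counts.

## Known limitations

* Mismatch search is pure Hamming; bulged protospacers are invisible.
* The optical-duplicate radius is a heuristic; with real data the lane
  and tile fields must be parseable from read names, or deduplication
  is silently skipped for those reads (with a reported count).
* The empirical FDR depends on control sample depth: a shallow control
  underestimates $F$.
* `breaks_per_cell` assumes every labelled end is sequenced; capture
  losses bias it downward uniformly, cancelling in comparisons but not
  in absolute terms.
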