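---
title: "Mining EST-derived microsatellite markers: models and methods"
author: "SSRmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining EST-derived microsatellite markers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Simple sequence repeats (SSRs, microsatellites) are tandem repetitions of
a 2--6 bp DNA motif. They are popular co-dominant markers in plant
population genetics, but classical marker development -- library
enrichment, cloning, sequencing -- is slow and expensive. Expressed
sequence tag (EST) collections offer a shortcut: mine public EST sets for
perfect repeats with enough flanking sequence to design PCR primers, and
the markers come for free, with the bonus that EST-borne repeats sit in
transcribed regions and often transfer across congeneric species.

SSRmine implements that pipeline end to end:

1. **Redundancy reduction** -- collapse a genus's ESTs into unique
   sequences (contigs and singletons), since EST libraries are highly
   redundant and the same transcript would otherwise be counted many
   times.
2. **Perfect-SSR detection** -- find all maximal perfect tandem repeats
   of period 2--6, group them into canonical motif families, and apply
   Class-I thresholds.
3. **Primer design** -- select flanking primer pairs under hard length /
   melting-temperature / GC / product-size constraints; a repeat without
   a compliant pair never enters the marker catalog.
4. **Genomic-context classification** -- align SSR-bearing sequences to
   an annotated reference and classify each repeat as exon (CDS), UTR,
   intron or genomic.
5. **Summaries** -- repeat-type and family frequencies by taxonomic
   group, location distributions, and empirical amplification /
   transferability rates.
6. **Synthetic data** -- a seeded generator producing annotated toy
   genomes and redundant, error-bearing EST sets with repeats planted at
   known positions, so every stage is testable against ground truth with
   no downloads.

## Definitions and conventions

A repeat run is *perfect* when it is an uninterrupted concatenation of
one motif. A motif is *primitive* when it is not a whole-number power of
a shorter motif (ATAT is not primitive; an (ATAT)~5~ region is reported
as (AT)~10~). A run is *maximal* when neither adjacent motif-length
window continues it. Two motifs name the same *canonical family* when
one is a cyclic rotation of the other or of its reverse complement --
the same locus read in a different register or from the other strand.
The family is named by the lexicographic minimum of that equivalence
class; a fixed lookup supplies the conventional display alias used in
the plant EST-SSR literature where it differs from the minimum (the
family containing CCG is written GGC, ATC is written TGA, ACT is written
AGT, CG is written GC).

*Class I* repeats are runs of at least 20 bp, operationalized as at
least 10 di-, 7 tri-, 5 tetra- and 4 penta-/hexanucleotide units. The
relaxed profile (`MiningParams(relaxed = TRUE)`) requires 4 units at
every period. Mononucleotide runs are never reported: their polymorphism
is hard to interpret, and primitivity prevents them from masquerading as
higher periods. Only unique sequences longer than 100 bp are mined
("larger than 100 bp" read strictly), so that flanks of usable quality
exist for primers.

All internal coordinates are 1-based closed intervals, the convention of
the IRanges/GenomicRanges/Biostrings containers this package is built
on; GFF3 and 12-column tabular alignments use the same convention at
file boundaries, so only the minus-strand subject flip needs conversion
on ingest.

## Redundancy reduction

The reduction emulates an assembler's redundancy-removal step without
being a full assembler, which the problem does not need: records are
processed in (length-descending, id-ascending) order; each sequence
joins the first existing cluster whose representative shares at least
one exact 12-mer and aligns at $\ge$ 95 % identity over $\ge$ 80 % of
the shorter sequence (ends-free alignment, via
`Biostrings::pairwiseAlignment`; substitution-only containment is
detected first with a fast C-level scan). Sequences may join through
their reverse complement, because EST libraries mix orientations, and
are stored re-oriented. Contig consensus is the per-column majority over
the star alignment to the representative, ties keeping the
representative's base. Low-complexity 12-mers (periodic with period
$\le$ 6 -- i.e. the repeats themselves) are excluded from candidate
pairing, otherwise every sequence carrying an AG-repeat would be paired
with every other.

The defaults (identity 0.95, overlap 0.80, k = 12) are deliberate,
conservative choices for EST-scale redundancy; the upstream tool the
field used for this step does not document its internal thresholds, so
cluster counts from it are not exact reproduction targets.

## Perfect-SSR detection

For each period $p \in \{2..6\}$ the scanner compares the sequence with
itself shifted by $p$: a maximal run of equalities of length $L$ marks a
periodic span of $L + p$ bases, which yields $\lfloor (L+p)/p \rfloor$
complete units. Runs are broken at non-ACGT characters, non-primitive
motifs are discarded (their primitive period is found at a smaller
$p$), and when runs of different periods overlap, the longer run wins
with ties going to the smaller period -- each repeat is reported once
with one motif. The scan is equivalent to a brute-force
position-by-position oracle; the test suite asserts that equivalence on
200 random 2 kb sequences with planted runs, and strand symmetry (the
reverse complement yields the same multiset of families, periods and
counts).

## Primer design

The designer enumerates every candidate forward window ending before
the run and reverse window starting after it (primers never overlap the
repeat: a primer inside the run could not size alleles), discards
candidates violating any hard constraint, and ranks survivors by

$$\mathrm{penalty} = w_l(|l_f-20| + |l_r-20|) + w_t(|T_f-60| + |T_r-60|)
 + w_g(|GC_f-50| + |GC_r-50|) + w_p|T_f-T_r|$$

with lengths in nt, temperatures in degC, GC in percentage points and
default weights 1, 1, 0.5, 1. Hard constraints: length 18--23 nt
(optimum 20), melting temperature 55--65 degC (optimum 60), GC 30--70 %
(optimum 50), product size 90--320 bp, pair Tm difference at most 3 degC,
longest self-complementary stretch at most 8 nt, no ambiguity codes.
The Tm-difference and self-complementarity caps are this package's own
robustness defaults (configurable and reported); full hairpin
thermodynamics and mispriming libraries of a production primer picker
are deliberately out of scope, since only the four constraint windows
are prescribed for this analysis.

Two melting-temperature models are provided. The default
`nearest_neighbor` model is the standard two-state duplex estimate from
the SantaLucia (1998) unified nearest-neighbor set with terminal
initiation terms, entropic salt correction
($\Delta S + 0.368\,(L-1)\ln[\mathrm{Na}^+]$) and
$T_m = 1000\,\Delta H / (\Delta S + R \ln(C/4)) - 273.15$, at 50 mM
monovalent salt and 500 nM oligo. The `gc_linear` model,
$64.9 + 41\,(n_{GC} - 16.4)/L$, exists because it is hand-checkable:
the exhaustive-oracle tests run under it so every expected value is
closed-form. Both the model and its conditions are recorded in the
output.

`catalogWithPrimers()` keeps exactly the loci with at least one
compliant pair -- the catalog counts primer-bearing repeats, matching
how such marker catalogs are reported. The best-only search is a
penalty-ordered scan with a lower-bound cutoff; the tests assert it
returns the same pair as the full enumeration.

## Genomic-context classification

SSR-bearing unique sequences are aligned to the annotated reference.
Externally computed alignments in the 12-column tabular convention are
accepted as-is (E-values honored, `evalue` significance mode); at toy
scale the built-in seed-and-extend aligner is used instead: exact
11-mer seeds (low-complexity seeds excluded), diagonal merging, X-drop
extension (match +1, mismatch -2, drop 6), and colinear chaining with
bounded gaps (query gaps $\le$ 60 bp, subject gaps $\le$ 20 kb --
intron scale) and small-overlap trimming, because neighbouring exon
extensions overrun splice junctions by a few bases of micro-homology.
The internal aligner has no E-value model -- Karlin--Altschul
calibration would be out of proportion for toy references -- so its
significance rule is identity $\ge$ 0.90 over $\ge$ 50 aligned bp,
declared and configurable.

A repeat on a sequence with no significant hit is `no_hit` and is
excluded from context tables (reported as an exclusion fraction).
Otherwise the best hit (lowest E-value; ties and E-value-free hits by
identity x aligned length) projects the repeat interval onto the
reference through the alignment blocks; the projection is absent when
fewer than half the repeat's bases are aligned. The projected interval
is intersected with gene features: CDS counts as exon, 5'/3' UTRs as
UTR (merged in reports, split retained internally), introns as intron.
The category is the majority-overlap feature type, ties broken
exon > UTR > intron -- a fixed rule, since no convention is prescribed
for repeats spanning feature boundaries; a projection overlapping no
feature is `genomic`. Classification uses the best hit only, mirroring
how a single matching gene model would be inspected by hand.

## The synthetic-data generator

`simulateGenome()` builds one chromosome of `nGenes` genes (5'UTR --
exons/introns -- 3'UTR on the plus strand) separated by intergenic
spacers on an i.i.d. background of the configured GC fraction (default
0.42, a typical plant exome neighbourhood). Per transcript, with
probability `ssrPlantRate`, one repeat is planted: context drawn from
`contextMix` (default CDS 0.45, UTR 0.33, intron 0.12, intergenic 0.10,
mirroring the location distribution reported for annotated control
genomes), family from a context-conditional table (trinucleotide
families enriched in CDS, AG-type dinucleotides in UTRs and other
non-coding contexts), motif uniformly from the family's rotations and
reverse-complement rotations, and repeat count uniformly from
per-period ranges that start at the Class-I minima. Repeats are
*inserted* (flanks displaced, junction bases adjusted to preserve
maximality), so ground-truth counts are exact by construction; the
miner is additionally run on each pre-insertion transcript so
spontaneous background runs are recorded rather than mistaken for
planted ones. Identical parameters and seed give byte-identical output;
the EST stage seeds its own stream at `seed + 1` so either stage can be
rerun independently.

`simulateEsts()` draws Poisson(`coveragePerTranscript`, default 3)
fragments per transcript. Fragments come from the spliced mRNA, from
unspliced pre-mRNA with probability `intronRetentionRate` (0.10) -- the
only route by which intron-context repeats enter an EST set -- or from
intergenic genome with probability `genomicFragmentRate` (0.05),
emulating the contamination that shows up as repeats without a
transcript context. A fraction `shortFragmentRate` (0.05) is truncated
below 100 bp to exercise the length filter; fragments are duplicated
with probability `duplicateRate` (0.20); each copy gets an independent
random strand and i.i.d. substitutions at `errorRate` (default 0.002).
The default fragment length range (1500--2500 bp, truncated at the
source length) makes most fragments full-length cDNA-style clones, so
that planted repeats are covered together with their flanks.

What the generator does *not* emulate: realistic expression-level
variation (coverage is homogeneous), platform-specific error profiles
or quality strings, chimerism, vector contamination, and paralogy.
Passing tests therefore demonstrate the pipeline's correctness under
clean, known conditions -- not its robustness to every artifact of
historical EST archives.

## Verification strategy and problem sizes

Every operation with a tractable alternative implementation is tested
against an independent oracle: the miner against a brute-force
position/period scan (200 random 2 kb sequences, half with planted
runs); motif canonicalization against a union-find closure over
rotation and reverse-complement edges for all motifs of periods 2--6;
the primer designer against an exhaustive window-pair enumeration under
the closed-form melting model (12 random 600 bp templates); the context
classifier against a plain interval-arithmetic reimplementation on a
100-gene synthetic genome, where the planted-context cross-tab must be
recovered exactly at zero error. The full pipeline runs on a 200-gene
genome at zero error: recall of covered planted Class-I repeats must be
1.0, the stage funnel monotone, reruns byte-identical, and planted
family frequencies recovered at sampling precision (per-context
chi-square goodness of fit, plus a median per-family deviation within
two standard errors -- a joint test rather than per-cell 2-SE bounds,
which would false-alarm under multiplicity). These sizes keep the whole
suite within a few minutes on one core while leaving each property
statistically meaningful.

The packaged transcriptions of the published summary tables are
validated on load (every stored total must equal the sum of its parts)
and the summarize module reproduces the published percentages from
them at printed precision. Two printed cells are known to be truncated
rather than rounded (30.76/39.03 vs the computed 30.77/39.04) and one
published rate (58.3 %) is inconsistent with its own printed counts
(8/12 = 66.7 %); these are asserted at one-unit-in-the-last-digit
tolerance or reported as computed, never chased.

## Degenerate inputs and numerical choices

Empty inputs propagate as empty results everywhere (an empty EST set
gives a zero-count funnel, not an error). Ambiguity codes are retained
in storage but break repeat runs and disqualify primer windows.
Percentages are rounded half away from zero at printed precision (2
decimals for shares, 1 for rates). Penalty ties in primer design break
by smaller product, then leftmost forward start; mining overlap ties
break by smaller period, then position. A stutter-profile locus counts
as amplified for the amplification rate but is discarded from the
transferability denominator; when both congeneric species show a single
allele, the locus is polymorphic only if the two sizes differ. These
are the only readings under which the published 54.2 % and 75 % rates
are simultaneously reproducible, and they are fixed as package
behavior.

## Known limitations

- The redundancy step is a greedy star-consensus reducer, not an
  overlap-layout assembler; complex paralogous families may over- or
  under-merge.
- The internal aligner is for toy references (up to ~10 Mb); real
  genome-scale classification should ingest external tabular
  alignments.
- The genus-to-group taxonomy table ships with the handful of genera
  used in the worked examples and is user-extensible; it is not a
  complete taxonomy.
- Compound or interrupted repeats are out of scope by design: only
  perfect runs are reported.
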