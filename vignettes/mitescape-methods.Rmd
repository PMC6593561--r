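---
title: "Models and methods behind mitescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitescape)
library(dplyr)
```

`mitescape` analyses annotated miniature inverted-repeat transposable
elements (MITEs): short, non-autonomous DNA transposon derivatives bounded
by terminal inverted repeats (TIRs) and flanked by a target-site duplication
(TSD) that the host repair machinery creates on insertion. The package
deliberately starts *after* discovery — it consumes a copy annotation
(BED-like TSV) rather than re-implementing discovery heuristics — and
covers classification, amplification dating, genomic context, small-RNA
profiling, alternative-splicing association, and a synthetic-data generator
with planted ground truth. This vignette records the models, the defaults,
and the reasoning behind the genuinely open design choices.

## Coordinates and data shapes

Every coordinate inside the package is 0-based, half-open. GFF3 input and
output converts from/to the standard's 1-based inclusive convention at the
I/O boundary; BED-like annotations pass through unchanged. All analysis
tables are tibbles with one record per row (element, exon, match, event),
so stages compose with ordinary `dplyr` pipelines.

MITE sequences are stored as the plus strand of their scaffold. Strand is
allowed to be unknown (`*`): MITE strand is rarely annotated and none of
the analyses require it, but family clustering compares unknown-strand
sequences in both orientations and keeps the better one. `N` bases are
permitted; each operation states its handling (they never match in TIR/TSD
comparison, and K2P drops those columns).

## Structure detection and superfamilies

`detect_tir()` returns the longest `L ≥ min_tir` (default 10) for which the
first `L` bases and the reverse complement of the last `L` bases disagree
at no more than `max_mismatch` positions (default 2), capped at half the
element so the termini cannot overlap. The defaults are configuration, not
biology: surveys rarely publish their TIR tolerance, so both knobs are
exposed and the brute-force-checked semantics are what matters.

`detect_tsd()` compares the `k` bases immediately 5′ of the element with
the `k` bases immediately 3′ of it, exactly and case-insensitively, for
`k ∈ {2, 3, 8, 9}` — the signature lengths of the four superfamilies
handled here. When several `k` match, the largest wins: an 8-bp duplication
that happens to end in `TA` is an hAT signature, not a Tc1/Mariner one.
Elements too close to a scaffold edge are flagged rather than guessed.

The superfamily call uses the TSD alone: `TA` → Tc1/Mariner, `T[AT]A`
(IUPAC `TWA`) → PIF/Harbinger, any 8-mer → hAT, any 9-mer → Mutator,
everything else → Unknown ("DTx"). TIR presence is reported but not
discriminative between these four.

## Families: the 80–80–80 rule, naming, full length

Copies are clustered greedily: visit sequences by decreasing length (ties
broken lexicographically so the order is total), join the first existing
family whose representative you match, else found a new family. A match
requires length coverage ≥ 80 % (shorter/longer ratio — this is what keeps
a 90-bp fragment of a 200-bp element out of its family) and global-alignment
identity ≥ 80 % (identical columns over all alignment columns; alignment by
Needleman–Wunsch with match +1, mismatch −1, gap open 4, extend 1, fixed so
decisions are reproducible). Sequences under 80 bp are set aside
unclassified. The scheme is deterministic and idempotent: representatives
re-cluster to themselves. Published pipelines typically apply the rule
through an external clustering tool whose tie-breaking is opaque; this
greedy operationalisation trades a little optimality for exact
reproducibility, and the planted-family tests show it recovers cleanly
separated families exactly.

Families are named `Mn` + superfamily code (`T`, `P`, `h`, `M`, `N` for
unknown) + a serial assigned by decreasing family size within the
superfamily. The family-level superfamily is the modal per-element call,
ignoring Unknown votes unless there is nothing else — individual elements
lose their TSD to flank erosion, and the modal vote is robust to that.

An element is *full length* when a global alignment against the family
representative leaves at most 3 unaligned representative bases at each
terminus — i.e. copies up to 3 bp short at an end still count, 4 bp does
not.

## Pairwise diversity, modality, and dating

Pairwise nucleotide diversity K between two aligned rows is mismatching
columns over counted columns, where a column with a gap in exactly one row
counts as one mismatch (a g-column gap run costs g), and dual-gap columns
are excluded entirely. The alternative gap accounting (one mismatch per gap
*run*) cannot be distinguished from the per-column rule using published
per-family means alone; the per-column rule is the default because it is
the literal reading of "every gap is a single mismatch" applied
column-wise, and the run-wise variant would interact badly with the
center-star aligner's tendency to split long gaps.

Each family's full-length members are aligned once. The default aligner is
a deterministic center-star progressive scheme (align everything to the
longest member, merge on center coordinates); equal-length inputs — the
common case for burst-simulated families without indels — pass through
unchanged. The aligner is pluggable (`aligner =` any function from
sequences to equal-length rows), and `align_sequences(method = "mafft")`
delegates to mafft when it is on the PATH. A dedicated external aligner
will out-align center-star on gappy families; the built-in exists so that
no decision in the package depends on an external binary.

Modality of the K distribution is read from a Gaussian KDE over [0, 1]
with Silverman's rule-of-thumb bandwidth: peaks are local maxima with
topographic prominence at least 10 % of the global maximum; one peak is
unimodal (a single amplification burst), two bimodal, three or more
multimodal. Below 30 pairwise values the call is "insufficient" — KDE
modality on fewer points is noise. Both thresholds are exposed.

Dating uses **T = K / r** with r = 1.3 × 10⁻⁸ substitutions · site⁻¹ ·
year⁻¹ by default, reported in millions of years. This is the convention
that reproduces the published worked examples this package targets
(K = 0.160 → 12.3 Mya, K = 0.312 → 24 Mya); the population-genetic
convention T = K / 2r, appropriate when K measures divergence along two
independent lineages, is available via `convention = "K/2r"`. Users should
note the factor-of-two subtlety: in the burst simulator two copies diverge
independently from the master, so E[K] ≈ 2·r·t and T = K/r recovers twice
the burst age. The default follows the printed convention rather than the
simulator's geometry.

## Trees

Kimura two-parameter distances count transitions (P) and transversions (Q)
over columns where both rows have an unambiguous base (pairwise deletion),
then d = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q). Saturated pairs (non-positive
log arguments) are returned as `NA` with a `saturated` attribute rather
than an error, because one saturated pair should not kill a family matrix.
The implementation is cross-checked against `ape::dist.dna(model = "K80")`
in the tests. Neighbor joining itself is delegated to `ape::nj()` — it is a
standard step, and additive-matrix recovery (the property that matters) is
verified over random topologies. `star_score()` — the fraction of total
branch length on leaf-adjacent edges — operationalises the "star-shaped
tree ⇒ single rapid amplification from one master" reading: 1 for a
perfect star, lower as clade structure accumulates.

## Genomic context

`partition_genome()` builds the GS/IS decomposition: each gene contributes
its body widened by `flank` (default 2000 bp) on both sides, clipped to the
scaffold; blocks are merged, and IS is the complement, so GS and IS tile
every scaffold exactly — a property asserted on every input. Merging
automatically absorbs short intergenic gaps, which is the published
treatment of genes closer than the flank. Gene anchors are the gene-model
extremes; start/stop codons would be marginally more faithful but require
CDS records the input may lack.

Elements are assigned GS or IS by midpoint, not any-overlap: midpoint
assignment conserves per-family counts exactly (gs + is + unplaced = family
size) and is insensitive to boundary-straddling, which the any-overlap rule
would double-count. The per-family IS-on-GS ordinary least squares fit
(`gs_is_regression()`) flags families with standardized residual > 2 on the
IS-excess side — the operationalisation of "more intergenic copies than the
trend predicts"; the threshold is configurable.

Near-gene enrichment compares each superfamily's share among all elements
with its share among elements whose midpoint falls in the *flank-only*
zones (gene bodies excluded, since the question is about insertion next to
genes, not into them). Expression coupling counts genes with a MITE
overlapping any exon of any isoform and RPKM ≥ 1 in the tissue — the RPKM
gate and the exon-overlap reading are both exposed as parameters.

## Small RNAs

A read is MITE-derived when it matches an element sequence exactly; both
orientations count, because plant siRNA biogenesis proceeds through
double-stranded RNA and a sequence-level match cannot distinguish the
strands. Multi-mapping reads count once in read-level statistics (length
distribution, GS/IS origin) and once per element in positional profiles —
positions are per-element properties, abundances are per-read. Relative
positions are percent-of-element, half-open: a 20-nt read starting at
0-based position 30 of a 100-bp element spans the 30–50 % region and
increments bins 30–49 of the 100-bin profile.

Per-family profiles are only computed for families whose members have
nearly identical lengths (coefficient of variation ≤ 0.05 — otherwise
"relative position" mixes incomparable coordinates) and more than 100
distinct matched reads. A family is "central" when ≥ 50 % of profile mass
falls in the 30–69 % bins, "terminal" when ≥ 50 % falls in the 0–19 % and
80–99 % bins, else "mixed". A matched read is attributed to GS when any of
its matched elements is GS — the generous attribution errs toward the
gene-proximal origin that transcription makes more plausible.

## Alternative splicing

Events are called from all isoform pairs of a gene and deduplicated by
(mode, interval, splice sites). Exon skipping requires the flanking
junctions to form a direct junction in the excluding isoform; intron
retention requires a single exon spanning the intron plus both flanking
exons exactly; alternative 5′/3′ events require one shared boundary, a
shifted boundary that is an internal splice site in *both* isoforms, and a
shared junction partner on the shifted side — the last condition is what
keeps an intron-retention pair from also surfacing as a spurious
alternative-donor event. Labels are strand-aware (donor = 5′). Mutually
exclusive exons and complex events are out of scope: they are not among the
four basic modes.

An event is MITE-associated when either (a) one of its splice-site
positions lies within an element interval — "the spliced sites are on
MITEs" — or (b) some element overlaps exonic sequence of at least one
isoform and none of at least one other isoform of the gene, the
exonization signature. A splice-site position is the boundary coordinate
itself, read as the first base 3′ of the junction. Tissue summaries gate
genes on RPKM ≥ 1 per tissue (configurable off); numerators count genes,
not events, with event-level counts also reported for the site-on-MITE
ratio.

## The synthetic generator

`simulate_genome()` emulates the study conditions end to end: i.i.d.
uniform ACGT background (no isochore structure), non-overlapping multi-exon
genes, and per-family amplification from a single TIR-bearing master. A
copy from a burst of age t receives independent per-site substitutions with
probability p = r·t under a two-parameter scheme (transition fraction
κ/(κ+2), default κ = 2, so K2P estimation is exercised meaningfully),
optional geometric indels (off by default so exact-recovery tests stay
exact), and optional terminal truncation producing partial copies. A run is
rejected beyond p ≥ 0.75 (saturation). Truncation removes 4 bases to 10 %
of one terminus: enough to fail the 3-bp full-length rule, small enough
that the 80–80–80 coverage requirement keeps partials inside their family —
heavier decay would also defeat real clustering, which is a statement about
the rule, not the generator.

Insertions are written into the genome flanked by the superfamily's TSD
(`TA`, sampled `TWA`, random 8-mer, random 9-mer), drawn near genes, inside
introns, or in intergenic space with configurable probabilities. The
generator then *enforces* that the planted TSD is the maximal flank
duplication, resampling a flank base when background sequence accidentally
extends the duplication — with dozens of insertions a spurious 8-mer
duplication is otherwise a once-per-run event. Planted-TSD recovery is
therefore a property of the generator's ground truth, by construction.

Two-burst simulations default to asymmetric burst sizes (few old copies,
many young). This is deliberate: in a master-copy model with comparable
burst sizes the pairwise-K histogram has *three* modes (within-old,
between, within-young) and is correctly called multimodal; the classic
bimodal signature arises when the old burst contributes few surviving
copies, so its within-burst mode is negligible and the histogram shows the
young mode plus the between mode.

Small-RNA simulation samples reads from configured relative regions
(central 40–60 %, terminal 0–20 %/80–100 %, …) with the read-length mass at
24 nt (23–25 nt window), matching the dominant size class of plant
heterochromatic siRNAs. Isoform simulation plants one event per eligible
gene inside an intronic MITE: a new exon within the element (exon
skipping), a retained intron, or a boundary shifted to a position inside
the element (alternative 5′/3′), recording exact truth for recovery tests.

What the generator does **not** emulate: real base composition, nested or
fragmented insertions, element families related to one another, selection
or drift, tissue-specific transcription of elements, and sequencing error.
Passing the pipeline-on-truth tests therefore demonstrates algorithmic
correctness under the stated generative model, not performance on real
genomes — on real data the discovery annotation, aligner choice and
density thresholds will dominate.

## Problem sizes and numerical notes

The test-suite study conditions are sized for a desk run: simulated genomes
of two scaffolds (180 kb total) with ~60 insertions across four families,
burst-recovery experiments of 100 seeded replicates with 25–30 copies of a
300-bp master (300–435 pairwise values per replicate), and neighbor-joining
recovery over 100 random additive matrices with up to 8 taxa. Modality
calls use 512-point KDE grids; an all-identical K vector short-circuits to
unimodal (zero bandwidth is undefined). Degenerate inputs are first-class:
families with fewer than two full-length members report absent diversity
rather than erroring, zero-partial superfamilies report an absent
full/partial ratio, saturated K2P pairs are flagged, and an exact GS/IS
regression fit reports no outliers (standardized residuals are undefined
there).

## Known limitations

* Greedy centroid clustering depends on the visit order (fixed and
  documented) and can split borderline families that a global method would
  merge; identity uses one fixed scoring scheme.
* The center-star aligner is adequate for low-divergence, low-indel
  families; heavily gapped families deserve mafft.
* KDE modality with a fixed prominence threshold replaces visual histogram
  reading; near-threshold peaks flip with the bandwidth, and small families
  (tens of pairs) are noisy — the README example shows one such
  misclassification deliberately.
* The exonization bookkeeping reports variant-specific MITEs at the gene
  level; it does not attempt to reconstruct pseudo-splice-site evolution.
* RPKM values are consumed, never computed; expression gating is only as
  good as the supplied table.
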