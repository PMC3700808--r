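---
title: "Testing whether alternative splicing avoids protein-protein interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing whether alternative splicing avoids protein-protein interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the model

Alternative splicing (AS) can delete part of a protein's sequence. When the
deleted stretch overlaps a protein-protein binding site, the isoform may lose
the ability to interact. `spliceshield` asks, for a collection of proteins
with structurally known interfaces, whether such partial removals happen
*more*, *less*, or *as often as* expected under a random model of splicing
that respects each isoform's own splicing pattern.

The analysis objects are:

* a **semi-interface**: the interface residues contributed by one chain of a
  dimer, expressed in canonical-protein numbering. Heterodimers are analysed
  per semi-interface; homodimers per whole interface (either of the two
  semi-interfaces being lost counts as removal).
* an **isoform mask**: a two-bit string over the canonical protein, bit 1
  where the isoform lacks the residue. Masks are built purely from the
  genomic coordinates of coding exons: a residue is missing when *any* of
  its three codon bases is absent from the alternative transcript. The
  rationale for the any-base rule is that a partial codon cannot encode the
  canonical residue; this is a package convention, since coordinate-level
  comparison does not define the behaviour of split codons by itself.
* **missing stretches** (maximal runs of 1s), **non-missing stretches**
  (runs of 0s strictly between missing stretches), and the **variable
  region** (from the first to the last missing position).

## The null model: pulsed decoys

A decoy isoform preserves the number, approximate sizes, and order of an
isoform's missing and non-missing stretches while randomizing everything
else: each stretch size is redrawn from a Poisson distribution with mean
equal to its real size (zero draws are allowed — rejecting them would bias
sizes upward, and the Poisson mean preservation is exactly what makes the
decoy sizes comparable), the pulsed stretches are concatenated in their
original order, and the new variable region start is drawn uniformly over
all placements that keep it inside the protein. A draw whose pulsed
variable region is empty or longer than the protein is redrawn entirely,
so a decoy mask always has the canonical length.

For the **all-isoforms** null, one control is a whole group of decoy
isoforms. Isoforms are first partitioned into *overlap groups* (connected
components under missing-stretch position overlap); the union span of a
group is split into segments at every junction between a missing and a
non-missing stretch, each segment carrying the vector of which isoforms
miss it. Per group, segment sizes are pulsed and a fresh uniform start is
drawn; a control is accepted only if

1. pulsed missing-derived segments of *different* groups occupy no common
   protein position, and
2. with more than one group, the total pulsed missing size is at least 90 %
   of the real total (constraint 1 favours shrinkage; this bound counters
   it).

Constraint 1 is applied across groups only (within a group the segment
structure already fixes relative positions); and a decoy variable region
may extend over formerly constant territory, since only in-bounds placement
is required. Both readings were genuinely open; these are the package's
choices. The joint constraints can be very selective: when one isoform's
variable region spans most of the protein, the acceptance rate drops below
a percent, so the all-isoforms sampler draws candidates in vectorized
batches and its attempt bound defaults to `1e5` (the orchestration layer
skips, with a warning, a protein whose controls cannot be built at all
rather than aborting a whole run).

## The test

For each (semi-)interface/isoform pair and a removal threshold *t* (percent
of interface residues that must be missing; the comparison is inclusive), a
2×2 stratum counts real versus decoy isoforms against removed versus not
removed. The Cochran-Mantel-Haenszel chi-square statistic combines strata
as `(|Σa − ΣE| − c)² / ΣV` with the usual hypergeometric mean and variance
per stratum. Stratification is essential: decoys are only ever compared
with the isoform from which they derive. Degenerate strata (a zero row or
column margin) carry no information and are skipped, with their count
reported. The continuity correction `c = 0.5` is on by default and follows
the convention of R's stock implementation (`mantelhaen.test`), including
its rule of applying the correction only when the absolute deviation is at
least 0.5; the uncorrected statistic is one flag away. P-values are
two-sided; the direction of any effect is conveyed by the reported real and
control removal frequencies.

The removal threshold is swept over a grid (default 10–100 % in steps of
10); both frequency curves are necessarily non-increasing in the threshold.
A second sweep dimension filters isoforms by *coverage* (fraction of the
canonical protein retained), to restrict the analysis to isoforms similar
enough to the canonical protein to plausibly fold and interact.

## Interface extraction and redundancy reduction

Residue contacts use the van der Waals criterion (sum of the two atoms'
radii plus a 0.5 Å margin). The radii table ships as a configuration file
(C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Å); unknown elements fall
back to 1.80 Å with a warning, or to an error if the fallback is disabled.
Alternate locations keep the highest-occupancy conformer (ties by first
letter); hydrogens are used when present. Records are kept when both sides
contribute at least five residues, both chains cover at least 30 % of their
protein, and the chain pair passed the biological-unit orientation check —
consumed as a precomputed flag, since parsing assembly remarks is out of
scope. These inclusion filters are monotone: tightening them never turns a
drop into a keep.

Because the same interface recurs across structures and across paralogous
proteins, the analysis set is deduplicated: proteins are grouped by greedy
single-linkage over pairwise global alignments (join when identity ≥ 30 %
over aligned columns covering ≥ 90 % of each sequence; identity is defined
as matches over columns where neither sequence is gapped — the denominator
choice is a documented package convention). Within a protein group,
interface residues are compared through the columns of a multiple
alignment (a built-in center-star progressive alignment; externally
computed alignments can be supplied and take precedence). Semi-interfaces
are scored with the overlap `O = |shared identifiers| / |smaller side|`
(for homodimeric interface pairs, the side pairing maximizing the shared
count is used and the denominator is the smaller whole interface), and
clustered by complete linkage on `1 − O` cut at 0.5, which guarantees
`O ≥ 0.5` for every within-cluster pair. One representative per cluster is
elected by largest coverage (product of both chains' coverages for
homodimers), then best resolution (a missing resolution sorts last), then
most residues, then a seeded random choice.

## Reference transcripts and isoform enumeration

The canonical protein is matched to a transcript by preferring an identical
translated sequence, otherwise the most similar candidate with at most five
non-contiguous differences (maximal runs of gap or substitution columns in
a global alignment), otherwise none — proteins without a reference drop
out. Alignment scoring is an identity matrix (+1/−1) with affine gaps
(open 5, extend 1); since it only ranks reference candidates, the exact
scheme is non-critical and is documented as configuration. Ties go to the
lexicographically smallest transcript id, making runs reproducible.
Alternative isoforms are all other full-length coding transcripts of the
gene, excluding transcripts flagged for nonsense-mediated decay and
transcripts encoding the reference protein itself; transcripts that share
one alternative coding sequence are all retained as distinct isoforms.
Without transcript sequences, "encodes the same protein" is decided by CDS
interval identity; translated sequences, when supplied, take precedence.

## Selectivity scores and enrichment

At each threshold, a spliced pair's *selectivity score* is the fraction of
its single-isoform decoys that also remove the interface — low values mean
the real removal is unusual against the isoform's own splicing background.
Interfaces never removed in any isoform are scored with the all-isoforms
controls instead — high values mean removal would have been easy and was
avoided. Proteins with a spliced pair scoring strictly below 0.5 form the
selectively-removed class, proteins with a never-spliced interface scoring
strictly above 0.5 the selectively-protected class; scores exactly at the
cutoff join neither (the inequalities are read strictly, and one qualifying
pair suffices to place a protein in a class). Annotation enrichment of
either class against the analysis background uses an upper-tail
hypergeometric test per term with Benjamini-Hochberg correction across
terms; ontology-graph propagation is intentionally out of scope — a
flat gene-to-term map (optionally pre-propagated) is the input.

# The synthetic generator

`sim_config()` / `simulate_study()` generate a study with known truth:
multi-exon genes (default 6–10 coding exons), a canonical protein, 1–4
alternative isoforms per gene formed by skipping internal exons
independently (baseline skip probability 0.25), interfaces of 5–60
residues placed uniformly on the protein with a contiguous run of hot
spots (25 % of interface residues), and toy two-chain structures whose
contact residues equal the prescribed interface exactly (one pseudo-atom
per residue; intended contacts at 3.0 Å, everything else across chains at
8 Å or more). A quarter of genes get homodimeric interfaces. The splicing
**bias** multiplies the skip probability of interface-overlapping exons:
1 is neutral, 0.2 protects interfaces, values above 1 target them. Bias
acts at the exon level because real AS removes exon-delimited stretches.

Two design choices matter for the statistical validity of the neutral
condition. The decoy null places variable regions uniformly over the whole
protein, so the neutral generator must make the real mask exchangeable
with its decoys: terminal coding exons are never skipped, hence they are
kept short (2–6 codons) so splicing can reach essentially the whole
canonical sequence, and interfaces are placed uniformly. Were the
constitutive termini long, interfaces falling there could never be removed
by real splicing but often by decoys, and the neutral condition would show
spurious "protection" unrelated to any selective effect.

What the generator does *not* emulate: real exon length and splice-site
statistics, sequence-dependent splicing regulation, correlated isoform
structures beyond shared exon skipping, NMD prevalence (an NMD-flagged
transcript is injected for roughly one gene in five purely to exercise the
exclusion), crystallographic noise, or realistic protein geometry. Passing
tests therefore demonstrate the correctness and calibration of the
machinery under controlled conditions, not biological conclusions about
any real proteome.

# Numerical and testing choices

* Exact arithmetic is asserted where exact answers exist (mask round trips,
  contact threshold boundaries, overlap ratios); the CMH statistic is
  checked against an independently coded formula to `1e-9` and against
  `stats::mantelhaen.test`.
* The calibration experiment uses 200 replicates of a 50-gene neutral study
  with 200 decoys per pair at a 30 % threshold, and accepts a rejection
  rate inside the 99 % binomial band around 0.05. The protection
  experiment uses 100 runs of a bias-0.2 study, 60 heterodimeric pairs with
  1000 decoys each, thresholds 10–50 %. These sizes keep the full suite in
  the tens of minutes on one CPU while leaving the Monte-Carlo error well
  inside the asserted bands.
* Decoy placement is validated against an exact enumeration oracle (sum
  over Poisson sizes and uniform starts) with a 0.01 bound on the maximum
  per-position deviation at 10⁴ decoys.
* Degenerate inputs: all-zero masks have no decoys (an error), zero-margin
  strata are skipped with a count, empty position sets and empty interface
  sides are errors, fully degenerate stratifications return a flagged
  `NA` statistic rather than a number.
* Random tie-breaks (representative election) consume the session RNG, so
  a seeded run is fully deterministic end to end; `run_full_analysis()`
  records seed and configuration hash in its provenance block.

# Interfaces and limitations

The package surface is the exported functions plus `run_full_analysis()`;
workflows are driven from R (or `Rscript`), which is the natural interface
for an analysis package of this kind — no separate shell CLI is shipped.
File formats: PDB coordinate files (ATOM records; mmCIF is out of scope),
SIFTS-style mapping TSV, FASTA, GTF/GFF3 CDS features or a simplified exon
TSV dialect, run-length-encoded mask TSVs, and plain TSV/JSON outputs.

Known limitations: the center-star alignment is a crude MSA (adequate
because only column identifiers are consumed; supply a real MSA for
distant homologs); hot-spot labels are consumed as input, never predicted;
the CMH residue-level hot-spot test inherits the usual caveat that
residues within a stratum are not independent under block-wise splicing;
exact conditional CMH p-values and homogeneity tests are not implemented;
frame-shift consequences downstream of a lost region are not modelled at
mask level — masks record genomic absence only, and the coverage filter is
the blunt instrument that removes drastically altered isoforms.
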