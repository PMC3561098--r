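---
title: "Methods: comparative structural analysis of cybrid mitogenomes"
author: "cybridmt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative structural analysis of cybrid mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`cybridmt` compares one focal circular plant mitochondrial genome —
typically a somatic-hybrid ("cybrid") mitogenome of 200–360 kb —
against comparator mitotypes and a plastid genome.  Plant mitogenomes
are conventionally described as a single *master circle* that coexists
with *subgenomic circles* generated by intramolecular homologous
recombination across repeated sequence; a cybrid additionally carries
donor-derived introgressions, extensive block rearrangement, and
chloroplast-derived insertions (MTPT).

Coordinates are 1-based and inclusive everywhere; this matches the
arithmetic of published feature tables in this field (a region printed
as `145578-147797` has length `147797 - 145578 + 1 = 2220`).  The BED
exporter converts to 0-based half-open at the file boundary only.  An
interval with `start > end` wraps the circle's origin; its span is
`L - start + 1 + end`.  Wrapping is represented natively rather than by
permanently doubling sequences; operations that scan a circular genome
use a doubled view internally and deduplicate features whose start lies
beyond `L`.

`N` bases are excluded from GC content and treated as mismatches (never
seeds) in alignment.

# One aligner for every similarity question

The original analyses of this kind mix several alignment programs
(pairwise BLAST variants for synteny and repeats, a percent-identity
plotter for uniqueness), whose identity definitions differ.  This
package instead routes *every* similarity search — synteny, repeats,
unique regions, chloroplast segments, ORF sharedness, CDS anchoring —
through one seeded local aligner, so a "95% similarity" threshold means
the same thing in every stage.  Exact published percentages produced by
those heterogeneous tools are therefore not reproduced bit-for-bit,
and are not attempted.

The aligner (`find_local_matches`):

1. collects exact `seed_k`-mer matches (default `seed_k = 12`; seeds
   occurring more than `max_occ = 256` times in the target are skipped
   as low-complexity),
2. merges seeds along diagonals, refusing a merge when the running
   match/mismatch score dips more than `xdrop = 20` below its maximum,
3. extends segments ungapped under the same X-drop,
4. chains co-linear segments whose query and target gaps are at most
   `chain_gap` (default 100 bp) — this is what lets a multi-kb syntenic
   region survive isolated substitution clusters and small indels,
5. rescores each chain by banded global alignment over its full span
   (band = observed diagonal range ± 16).

Identity is defined as identical columns divided by alignment columns,
with gap columns counting against — the most common convention, chosen
because the source analyses never state theirs.  Scores are unit
match/mismatch/gap = +1/−1/−2.  Output order is deterministic
(query start, target start, strand).  `align_pair` exposes the exact
quadratic DP (capped at 20 kb) with deterministic tie-breaking
(diagonal over gap, gap-in-b over gap-in-a); the test suite uses it as
the oracle for the seeded path, and cross-checks it against an
independent DP implementation.

In a *self*-comparison the trivial identity diagonal is suppressed.
Because two distinct genomes can legitimately be identical, callers
state their intent: repeat detection passes `self = TRUE`, synteny and
unique-region calling pass `self = FALSE`, and the default infers
self-comparison from object identity.

# Synteny

`detect_syntenic_regions` keeps chained matches with span ≥ 1 kb and
identity ≥ 95% (the conventional thresholds for mitotype comparison),
resolves overlaps on the focal genome by keeping the higher-scoring
region and trimming the other (overlaps ≤ 50 bp are tolerated — repeat
copies legitimately share flanks), and labels regions S1… in focal
coordinate order.  Labels are *not* intended to match any published
S-numbering, which is not reconstructible without the original focal
sequence.  Region identity is the alignment-column-weighted identity of
the banded rescoring.  Coverage is the union span of regions divided by
genome length, wraparound-aware, computed with `IRanges`.

# Repeats and recombination

Repeats are found by self-comparison and reported as canonical *pairs*
of disjoint copies (copy 1 precedes copy 2; tandem, self-overlapping
hits are excluded because they are a different phenomenon from the
recombination repeats of interest).  Whether published repeat counts
tally pairs or copies is usually unstated; this package counts pairs —
the recombination substrate — and documents it.  The short class is
30–500 bp at ≥ 90% identity; the large class is ≥ 1 kb at ≥ 95%,
a floor chosen to separate the multi-kb recombination repeats (9.7 kb,
6.6 kb, 2.4 kb in the genomes this models) from the short class.
`short_repeat_fraction` is the union of all copy intervals over `L`.

A direct repeat pair resolves the master circle into two subgenomic
circles.  Sizes are measured start-of-copy to start-of-copy, so each
product keeps exactly one full fused copy and the sizes sum to `L`
exactly — the accounting that makes 56,610 + 201,863 = 258,473 work.
An inverted pair instead yields an equal-length isomer with the
inter-copy arc reverse-complemented; applying the operation twice is
the identity.  Circle equality is tested rotation-normalised
(`canonical_rotation`, lexicographically minimal rotation).

`explain_junctions_by_repeats` walks adjacent region pairs in
comparator order; when their focal-side images are non-adjacent
(circular gap > 200 bp) it is a rearrangement junction, and every
repeat pair is tested for copies within `flank_window = 500` bp of both
focal-side breakpoints.  The window default covers the scale of the
published example in which a ~600 bp gap vanished in a repeat-mediated
swap, while keeping explanations tight.  Junctions with no candidate
are still reported, flagged not plausible.

# Unique regions and chloroplast-derived segments

A focal position is *unique* only when no comparator covers it.
Coverage thresholds are deliberately permissive — any match ≥ 50 bp at
≥ 70% identity covers — because "unique" means no appreciable homology
at all, a far weaker standard than synteny's 95%.  Unique regions are
maximal uncovered runs ≥ `min_unique_len = 400` bp (the smallest
published unique region in this system is 445 bp), labelled U1… in
coordinate order; runs separated by any covered stretch stay separate,
and the two runs flanking the origin merge on a circular genome.  The
reported fraction is the sum of lengths over `L`.

Chloroplast-derived segments are matches of the mitogenome against the
plastid genome at ≥ 95% identity and ≥ 100 bp, de-overlapped on the
mitochondrial side, labelled H1… by length descending.

ORF sharedness: an ORF is *shared* when one comparator carries a
near-full-length (≥ 90% of its length) copy at ≥ 99% identity,
*partial* when ≥ 30% of its length is matched at ≥ 90% identity without
a full-length high-identity copy, *unique* otherwise; unique ORFs are
intersected with the unique regions to flag candidate introgressions.

# Gene-level typing

SNP calling (`call_gene_snps`) is substitution-only on pre-trimmed,
equal-length orthologous CDSs; length differences are routed to the
boundary-shift detector.  Translation uses the standard genetic code
(table 1), which plant mitochondria use.  A codon hit by several
substitutions is translated jointly and each site reports that joint
effect.  Transitions are purine↔purine or pyrimidine↔pyrimidine
exchanges.  An internal stop triggers a warning, not an error, so
pseudogenised orthologs can still be typed.

Boundary shifts: the reference CDS is anchored in the alternate genome
by a local match of its core (≥ 90% identity).  A 3′ extension is
called when the orthologous stop codon is disrupted and the next
in-frame stop lies k codons downstream (`shift_len = 3k`).  A 5′
extension is called when the alternate genome has a longer maximal
in-frame ATG-initiated upstream extension (scanning to the first
in-frame stop) than the reference genome does at the same locus; the
reference-side comparison is what keeps an unmodified ortholog silent.
On noisy real data a chance upstream ATG/stop difference between the
genomes could still produce a spurious small 5′ call; the detector is
designed for curated gene models, where the published cases are clean
multi-codon extensions (+27 bp 3′, +498 bp 5′).

ORF finding scans all six frames ATG-to-stop, reports lengths
*including* the stop codon (under this convention the conventional
300 bp minimum and the published shortest ORF of 303 bp are both
multiples of three), keeps only the longest ORF per (stop, frame), and
includes origin-crossing ORFs once on circular molecules.  Start codons
are strictly ATG.

Transmembrane segments are maximal runs of 19-residue windows whose
mean Kyte–Doolittle hydropathy exceeds 1.6 — the classic
window/threshold pair for membrane-spanning helix detection.  CMS
screening ranks ORFs by three binary criteria characteristic of known
CMS genes: unique to the focal mitotype, carrying a predicted
membrane-spanning segment, and lying within 2 kb of an annotated
functional gene.

# The simulator

`simulate_cybrid` builds a complete, fully ground-truthed system:
recipient, comparators, donor, plastid genome, and cybrid.  Its
defaults *are* the study conditions this package models: recipient
221,853 bp at GC 0.4521; a duplicated 9,731 bp large repeat; mediating
short repeats of 310 and 232 bp; eleven donor segments with the
published unique-region lengths (2×2220, 2×469, 5130, 1052, 445, 3572,
2700, 3828, 879 — 22,984 bp, i.e. 8.89% of a 258,473 bp genome when
`final_len` pins the cybrid at that size); six chloroplast segments of
2196, 1880, 1362, 1159, 673, 178 bp (2.88%) planted at 97% identity;
40 coding SNPs at a 29/40 transition bias; and 5′/3′ boundary shifts of
498 and 27 bp.

Construction order: a random recipient backbone (per-base independent
draws at the target GC — no higher-order composition structure, a
documented simplification) with non-overlapping planted protein genes;
comparators as the recipient plus ~0.5% substitutions and up to three
neutral block moves, with *no* donor or plastid content, giving
uniqueness calling a clean negative set; the cybrid as the recipient
carrying the planted SNPs and boundary shifts, cut into blocks at
gene-free breakpoints, permuted and partly inverted, then insertions
spliced in at gene-free points ≥ 600 bp apart.  Mediating short
repeats are placed so both copies of one repeat flank the two
cybrid-side breakpoints of a single separated recipient adjacency —
the geometry under which a repeat genuinely "explains" a rearrangement
junction; the permutation is redrawn until every configured repeat can
be placed that way.  Mediating repeats are novel random sequence
rather than recipient-derived, so the planted pair is the only copy
pair (a recipient-derived source would leave a third background copy);
at 310/232 bp they fall below `min_unique_len` and do not surface as
unique regions.  The 5′ gene extension is donor-style novel sequence
bounded upstream by a planted in-frame stop, making the planted length
exactly recoverable; as exogenous sequence ≥ 400 bp it legitimately
surfaces as one extra called unique region, which is why recovery is
scored by recall against the planted donor catalogue.  The large
repeat duplicates a gene-free stretch of the (recipient-derived)
cybrid backbone, so it is covered by comparators and never called
unique.  All randomness flows from the single mandatory seed; the
caller's RNG state is restored on exit, and the same seed reproduces
every genome and truth table byte-identically.

What the simulator does **not** emulate: realistic mutation-rate
phylogenetics among comparators, substoichiometric shifting, RNA
editing, tRNA/rRNA genes, genomic composition structure beyond GC, or
read-level sequencing artefacts.  Passing recovery tests on simulated
data therefore demonstrates correctness of the interval logic,
detection thresholds and bookkeeping — not robustness to every
property of real mitogenomes.

`score_recovery` matches a called feature to a truth feature when
reciprocal overlap ≥ 0.8 and both boundary errors ≤ `boundary_tol`
(100 bp in the shipped checks), each called feature matching at most
one truth feature.

# Numerical and engineering choices

* The DP core, seed scan and banded rescoring are in C++ (Rcpp); all
  results are exact integer scores, so there are no floating-point
  reproducibility concerns beyond identity ratios.
* Degenerate inputs: empty sequences are rejected at construction;
  all-`N` sequences have undefined GC (error); a wrapping interval on
  a linear molecule is a domain error; `align_pair` refuses inputs
  over its 20 kb cap and points to the seeded aligner.
* Tie-breaks are fixed everywhere (alignment traceback priority;
  deterministic output ordering; overlap resolution by score then
  coordinate), so re-running any stage on identical inputs is
  byte-identical.
* Reported percentages use two decimals with R's round-half-even.

The shipped test suite runs the recovery checks at two scales: a 60 kb
system exercised by most unit tests, and one full-scale 258,473 bp
system for the planted-recovery checks; both finish in minutes on one
CPU.  `scripts/acceptance.R` regenerates the subgenomic-circle
prediction from scratch at full scale.

# Known limitations

* Synteny labels and exact coverage percentages are not comparable to
  numbers produced by other aligners with other identity definitions.
* The junction-explanation model tests one repeat pair per junction; it
  does not search multi-step rearrangement histories (deliberately out
  of scope — with ~20 syntenic regions the minimum-event history is
  not identifiable anyway).
* Only single-exon gene models are supported by the boundary-shift
  detector; trans-spliced genes must be typed exon-wise.
* The unique-region caller reports repeat-contained regions once per
  copy only if both copies independently fail coverage; no repeat-aware
  deduplication is attempted.
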