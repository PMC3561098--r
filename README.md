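# cybridmt

Comparative structural analysis of cybrid plant mitochondrial genomes.

## The problem

Somatic hybridisation (protoplast fusion) mixes the cytoplasms of two
parents, and the resulting "cybrid" mitochondrial genome is a mosaic: a
recipient-like backbone carrying introgressed donor segments, extensive
block rearrangement, chloroplast-derived insertions (MTPT), duplicated
large repeats that drive a multipartite genome structure, and scattered
coding changes.  Typing such a genome against its relatives answers
concrete questions: which regions are exogenous?  which repeats can
resolve the master circle into subgenomic circles?  which rearrangement
junctions are repeat-mediated?  which open reading frames are candidate
cytoplasmic-male-sterility (CMS) genes?

`cybridmt` is an R package for this analysis.  It is aimed at plant
organelle researchers comparing one focal circular mitogenome (typically
~220-360 kb) against a handful of comparator mitotypes and a plastid
genome.

## What it computes

All similarity searches go through one seeded local aligner (exact
k-mer seeds, X-drop ungapped extension, co-linear chaining, banded
gapped rescoring), so "similarity" means the same thing in every stage:
identical columns / alignment columns.

* **Syntenic regions** `detect_syntenic_regions(A, B, min_len = 1000,
  min_identity = 0.95)` — labelled S1..Sn in focal coordinate order,
  with per-genome coverage fractions and dot-plot export.
* **Repeats** `find_repeats` (30-500 bp, identity >= 0.90, direct and
  inverted, counted as pairs) and `find_large_repeats` (>= 1 kb,
  identity >= 0.95); `short_repeat_fraction` gives the genome fraction.
* **Recombination** `predict_subgenomic_circles` — a direct repeat pair
  on a master circle of length L yields two circles whose sizes sum to
  L (size measured start-of-copy to start-of-copy, each product keeping
  one fused copy); `predict_inverted_isomer` reverses the inter-copy
  arc; `explain_junctions_by_repeats` tests every repeat pair against
  the breakpoints of each rearrangement junction.
* **Unique regions** `call_unique_regions` — maximal runs of focal
  positions with no qualifying match in *any* comparator (coverage
  thresholds deliberately permissive: 50 bp at 70% identity), labelled
  U1.. and reported with their genome fraction.
* **Chloroplast-derived segments** `find_cp_segments` (>= 95% identity,
  labelled H1.. by length).
* **Gene-level typing** `call_gene_snps` (synonymous /
  non-synonymous x transition / transversion, standard genetic code),
  `detect_boundary_shift` (in-frame 5'/3' CDS extensions),
  `find_orfs` (six frames, circular wraparound), `predict_tm_segments`
  (Kyte-Doolittle hydropathy), `classify_orf_sharedness` and
  `screen_cms_candidates` (unique + membrane-spanning + near a
  functional gene).
* **Simulator** `simulate_cybrid(sim_config(seed))` — a ground-truthed
  synthetic cybrid system (recipient, six comparators, donor, plastid,
  cybrid) whose defaults encode the study conditions; `score_recovery`
  compares calls against the truth catalogue.

## Worked example

```r
library(cybridmt)

sim <- simulate_cybrid(sim_config(seed = 7, recipient_len = 60000L,
  n_blocks = 5L, n_inversions = 2L, large_repeat_len = 3000L,
  donor_segments = c(2220L, 469L, 5130L, 1052L),
  cp_segments = c(2196L, 673L, 178L),
  n_genes = 8L, n_coding_snps = 15L, cp_len = 40000L, donor_len = 40000L))

detect_syntenic_regions(sim$cybrid, sim$recipient)
#> <SyntenyMap> cybrid vs recipient: 14 regions, coverage 81.09% / 97.70%

u <- call_unique_regions(sim$cybrid, sim$comparators)
head(u, 3)
#>   label start   end length wraps
#> 1    U1  3881  4927   1047 FALSE
#> 2    U2  5823  8010   2188 FALSE
#> 3    U3 13317 13989    673 FALSE

lr <- find_large_repeats(sim$cybrid)[1, ]
predict_subgenomic_circles(sim$cybrid, lr, emit_seq = FALSE)[[1]]
#> <SubgenomicCircle> 27940 bp (copy 1; arc 38275..66214)
```

The synteny map says 14 chained regions at >= 95% identity cover 81.1%
of the cybrid (the remainder is exogenous or repeat-divergent).  U1 is
the planted 1,052 bp donor segment, recovered to within a few bases; U2
and U3 are chloroplast insertions (2,196 and 673 bp planted at 97%
identity), called unique because these comparators carry no plastid
content.  The two subgenomic circle sizes always sum to the master
length.

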