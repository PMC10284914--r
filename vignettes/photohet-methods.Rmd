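---
title: "Methods: alignment, abundance and rhodopsin screening in photohet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment, abundance and rhodopsin screening in photohet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photohet)
```

photohet implements the computational core of a sequence-based survey of
photoheterotrophic marine bacteria: where close relatives of two cultivated
*Verrucomicrobiota* isolates occur (a 16S rRNA amplicon stage), how abundant
the target taxon is worldwide and how often it carries its
proteorhodopsin/retinal operon (a gene-catalog coverage stage), and which
rhodopsin subfamilies occur across a genome cohort (a protein screening
stage). This vignette describes the models behind each stage, the tunable
parameters, the synthetic-data generators used to validate them, and the
design choices made where the methods literature leaves the details open.

## Pairwise alignment and the identity statistic

All stages share one pairwise aligner: Needleman–Wunsch with affine gap
costs (Gotoh's three-state recursion), implemented in C++. The default
nucleotide scheme is match 5, mismatch −4, gap open 16, gap extension 4.
Two conventions had to be fixed explicitly because the four numbers alone
do not determine them:

* **Gap cost.** A gap run of length $L$ costs
  $\mathrm{open} + (L-1)\,\mathrm{extend}$: the opening column carries the
  whole opening penalty. Switching between a gap in one sequence and a gap
  in the other opens a new run.
* **Traceback ties.** Diagonal is preferred over vertical over horizontal,
  so the reported alignment (not only its score) is deterministic.

Percent identity is the number of matched columns divided by matches plus
mismatches; gap columns enter neither numerator nor denominator. Because
gaps are excluded, the identity statistic is insensitive to the gap-cost
convention; only the alignment path depends on it. Ambiguity codes (N and
the other IUPAC degeneracies, and B/J/Z/X for proteins) always score as
mismatches — a conservative, deterministic choice that avoids giving
unknown residues credit for matching.

Protein comparisons reuse the same match/mismatch scheme rather than a
substitution matrix. The quantity consumed downstream is always the
gap-excluded identity, for which a BLOSUM-style matrix would change the
alignment path only marginally at the identity levels that matter here
(≥ 25%); a biological similarity score is never used as a statistic.

The aligner is validated two ways: against exhaustive enumeration of all
gapped alignments for short pairs (an oracle that shares no code with the
dynamic program), and against `Biostrings::pairwiseAlignment`, whose
`gapOpening = 12, gapExtension = 4` parameterisation is algebraically
identical to the open-16/extend-4 convention used here.

One classical-sounding invariant turned out to be false and was
deliberately *not* asserted in its naive form: mutating a matched residue
of an optimally aligned pair can *raise* the optimal score, because the
replacement residue may match a different partner under an alternative
alignment (by at most match − mismatch). The test suite asserts the sound
restricted form, replacing a residue with one absent from the partner
sequence, which provably cannot create new matches.

## Semiglobal mode and read recruitment

Amplicon reads are matched against window-trimmed reference fragments
with a semiglobal alignment: terminal overhangs of the *longer* sequence
are free, so a 200-nt read is recruited inside a 424-nt fragment without
penalising the unaligned fragment ends. Identity is computed over the
aligned columns of that semiglobal alignment. The original survey used a
local aligner (BLAST) for this step and did not state whether its 98%
threshold applied to the local HSP or the whole read; defining identity
over the semiglobal alignment covers the full read, is deterministic, and
keeps a single aligner for every stage. The recruitment threshold
defaults to 0.98; a read is assigned to at most one reference (its best
hit, ties to the lexicographically smallest id), which is appropriate for
reference fragments that are mutually far more divergent than the
threshold. Reads shorter than 50 nt are rejected with a warning — the
source methods are silent on a minimum length, and 50 nt is short enough
to keep any plausibly informative amplicon fragment.

Reference fragments are produced by aligning each full-length 16S gene
against an anchor sequence (E. coli numbering convention) and mapping the
anchor window, by default positions 515–938 (1-based inclusive, 424
anchor positions), through the alignment columns. Relative abundance per
sample is matched reads over all reads searched, with the denominator
counting every read supplied for the sample, matched or not (the
quality-filtered per-sample pool is taken as "the reads searched").

## Marker-based abundance and copy numbers

The coverage stage consumes a genes × samples matrix of per-base read
coverage with orthogroup annotations; computing coverage from raw reads
is out of scope. Catalog records are first recruited to the target taxon:
a record is kept when its best-identity hit over the whole supplied
reference set is a target protein at ≥ 95% identity — a best hit to any
competitor disqualifies the record regardless of its identity to the
target.

Taxon abundance in a sample is the arithmetic mean, over selected marker
orthogroups, of recruited per-orthogroup coverage (the sum over a marker's
recruited genes; summing rather than averaging keeps the estimate correct
when an orthogroup fragments into several catalog records). Zeros are
included in the mean so that a sample lacking the taxon scores near zero
rather than NaN. The community fraction divides this by the mean total
community coverage of the *selected* orthogroups — the denominator set is
configurable, but defaulting to the selected markers keeps numerator and
denominator on the same genes. Fractions above 1 are reported and flagged
rather than silently clipped.

"Mutual correlation and outlier detection" for marker selection is a
one-line description in the methods literature with no published
algorithm, so the package documents one admissible instantiation:

1. drop orthogroups whose total coverage is a high outlier
   (> median + 3 MAD of per-orthogroup totals; multi-copy or contaminated
   markers recruit systematically too much coverage);
2. iteratively drop the orthogroup with the lowest median Spearman
   correlation of log(coverage + 10⁻⁶) to the remaining candidates, while
   that median falls below the overall median minus 3 MAD of the
   median-correlation vector.

Rank correlation makes the rule insensitive to the lognormal noise scale;
the pseudocount (10⁻⁶, far below any real coverage) only shields the log
at exact zeros; the MAD multiplier 3 is the conventional robust-outlier
cut. All three are configuration values. Selection fails loudly
("marker selection collapsed") if fewer than three orthogroups survive.

Accessory-gene copy number per genome is the gene's coverage divided by
the marker-based taxon abundance, defined only in samples where at least
90% of the selected markers have non-zero coverage — below that gate the
taxon is too marginal for the ratio to be meaningful, and the estimate is
reported as undefined rather than as a number. The two-gene operon
estimate is the mean of the per-gene copy numbers, defined only where
both are. Copy numbers are scale-invariant: multiplying all coverages of
a sample by a constant cancels in the ratio. Cohort-level counting (the
<3-assembly contamination rule below) is likewise applied only after all
per-query calls are made.

## Rhodopsin screening

Candidate rhodopsin proteins (the upstream HMM search that produces
candidates, with its E < 10⁻⁵ gate, is out of scope — candidates are
inputs) are classified by best-identity hit against a curated reference
set in which every reference carries a subfamily label, the position of
the retinal-binding lysine, and the helix-7 interval. Ties are broken by
longer alignment, then lexicographic reference id. Queries whose best
identity falls below 0.25 are rejected as having no confident hit — a
screening step standing where the HMM gate would be, with a configurable
threshold.

The functional filter maps the reference's retinal-lysine position
through the global alignment onto the query: `present` requires a lysine
at the mapped position *and* that position inside the query region
aligned to the reference's helix 7; a non-lysine residue is `absent`; a
position mapping into a gap (e.g. helix 7 deleted) is `unalignable`.
Helix-7 membership is defined purely by the reference annotation mapped
through the alignment — no de novo topology prediction.

Retained sequences are deduplicated at 100% identity and then clustered
sequentially at 90/80/70/60%, each level clustering the representatives
of the previous one, with the lineage recorded so every query maps to its
60% cluster. Clustering is greedy and longest-first (the cd-hit
convention), with *best-hit* representative assignment rather than
first-hit: a sequence joins the representative with the highest identity
above the level, which makes the outcome independent of the insertion
order of equal-length sequences. Contamination flags are cohort-level: a
subfamily seen in fewer than three distinct assemblies is `likely`
contamination for all its calls; otherwise a call whose 60% cluster
contains a single assembly is `potential`; everything else is `none`.
The assembly-count rule is applied after the retinal-lysine filter (the
source description does not fix the order; counting only functional
sequences is the conservative choice for flagging).

## Synthetic data and what passing tests mean

Each stage has a seeded generator producing inputs with exactly the
statistical structure the stage assumes, plus a ground-truth table:

* `simulate_coverage`: latent taxon abundance $a_s \sim$ lognormal
  (meanlog $\log 5$, sdlog 1 — a heavy-tailed, always-positive abundance
  typical of coverage data), 10% of samples with the taxon absent,
  marker coverage $a_s \varepsilon$ with $\varepsilon$ lognormal of sd
  0.2 on the log scale, corrupted markers drawn independently of $a_s$,
  accessory coverage $c \, a_s \varepsilon$ for $c \in \{0,1,2\}$, and
  total community coverage $a_s \varepsilon / \text{share}$ (default
  share 2%, a realistic fraction for a moderately common marine clade).
* `simulate_reads`: uniformly placed windows with i.i.d. substitutions
  (never back to the original base), realised counts recorded; the
  defaults (200-nt reads, 0.5% on-target vs 5% decoy substitution rates)
  bracket the 98% identity threshold from both sides.
* `simulate_rhodopsins`: queries derived from per-subfamily consensi
  (random 240-mers, pairwise identity ≈ 5%, asserted ≤ 50%) at 10%
  mutation load, with controlled lysine knockouts, helix-7 deletions and
  per-family assembly counts.

A single integer seed fans out to independent substreams, so adding
draws to one block cannot perturb another, and all generators are
byte-reproducible under a fixed seed.

The validation suite runs at deliberately desk-sized problems — 500
alignment oracle pairs of length ≤ 6, 1000 reads, 30 samples × 20
markers, 60 query proteins — chosen so the whole suite completes in well
under a minute per stage while the noise floors still allow tight
assertions (community fraction recovered to ≈ 5% relative error, copy
numbers to < 0.1 absolute). What these tests demonstrate is the
*estimators*: correct marker exclusion, unbiased ratio recovery, exact
threshold behaviour. What they cannot demonstrate is robustness to
features the generators deliberately omit: indel sequencing errors and
quality structure in reads, phylogenetically correlated sequence
evolution (random consensi are farther apart than real subfamilies),
compositional correlations between community members, and catalog-scale
redundancy. Results on real data therefore depend on the usual upstream
controls (read QC, catalog curation) that are out of scope here.

## Degenerate inputs and numerical notes

Empty sequences, mixed alphabets, negative or ragged coverage tables,
duplicate ids and non-IUPAC residues all fail fast with messages naming
the offending record or position. An alignment consisting only of gap
columns has undefined identity and raises an error rather than returning
0/0. Anchor windows that map entirely into a deletion yield `NULL` from
`map_region` (an error in `trim_reference`, `unalignable` in the lysine
check). Constant (e.g. all-zero) marker rows have undefined rank
correlation; they are treated as correlation 0, i.e. maximally
implausible markers. All result tables are written deterministically
(sorted by primary key) and every pipeline run writes a timestamp-free
manifest of config hash and input checksums, so byte-identical inputs
and configuration produce byte-identical outputs.

## Genome accessions

`genome_length` sums residue counts over the records of an assembly
FASTA; for the two deposited isolate genomes (GenBank CP076041.1 and
CP076039.1) the expected totals are 4,815,746 bp and 4,086,264 bp. The
FASTA files are several megabytes and are not shipped; the corresponding
test fetches them from `extdata/genomes/` or NCBI and fails when neither
is available.
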