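---
title: "Methods: structure, repeats, divergence and phylogeny of plastomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure, repeats, divergence and phylogeny of plastomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastome)
```

This vignette records the models, algorithms and numerical choices behind
the package, the study conditions built into the synthetic-plastome
generator, and what the passing test suite does and does not demonstrate
about real data.

## The quadripartite model

A plastome is modelled as a circular string over the IUPAC alphabet with a
feature table of CDS/tRNA/rRNA genes (exon lists; introns are the gaps
between consecutive exons; features may wrap the origin). All internal
coordinates are 0-based and half-open with arithmetic modulo the genome
length `L`; report files and GenBank output use 1-based inclusive
coordinates, as those formats require.

The structural model is the canonical angiosperm layout LSC–IRa–SSC–IRb:
two long inverted repeats (IRs) that are exact or near-exact reverse
complements of each other, separating a large and a small single-copy
region. Because intramolecular recombination between the IRs inverts the
SSC, a species' plastome exists as two orientation isomers; which one an
assembly reports is arbitrary unless a read spans an entire IR. Orientation
must therefore be *called against a reference*, never read off a single
assembly.

## IR detection and partition

`find_inverted_repeat_pair()` seeds exact `k`-mer matches (default
`k = 21`) between the doubled sequence (doubling handles circularity) and
its reverse complement, groups seeds on common diagonals into maximal exact
runs, merges runs on one diagonal when the implied internal mismatches keep
the overall mismatch fraction within `max_mismatch` (default 0.001), and
finally extends both end pairs over exactly matching bases.

Two boundary conventions were possible. A literal "extend while the
mismatch fraction stays below the ceiling" rule would always push one junk
base past an exact repeat whenever `1/(len+1) <= max_mismatch`, i.e. for
every IR longer than 1 kb — boundaries would then systematically overshoot
the biological repeat. We instead place boundaries on the outermost
*matching* base pair and reserve the mismatch budget for internal
mismatches; detected boundaries of an exact planted IR then equal the
planted truth base-for-base, which is what the truth-record tests assert.

Defaults: `min_len = 1000` bp (plastid IRs are >20 kb; anything shorter is
the business of the repeat scanner, not the structure caller) and
`max_mismatch = 0.001` (real IR copies are kept near-identical by gene
conversion). Ties between equal-length candidate pairs break to the lowest
start coordinate. Absence of any qualifying pair is a distinguishable
"no-IR" result, not an error.

`partition_genome()` assigns the longer inter-IR arc to the LSC and errors
on exactly equal arcs rather than guessing. IRa is defined as the IR copy
first encountered clockwise from the LSC end — a pure labelling convention.
The partition always satisfies `len(LSC) + len(SSC) + 2·len(IR) = L`.
`canonicalize()` rotates (optionally reflects) the genome so the layout
reads LSC, IRa, SSC, IRb from coordinate 0, remaps features, and records
the applied transformation; it is idempotent.

## SSC orientation calling

`call_ssc_orientation()` canonicalizes both genomes, first aligns the LSC
frames (if the query LSC matches the reference LSC better in reverse
complement, the whole molecule is reflected — a whole-molecule reflection
is not an SSC isomer), then scores the query SSC against the reference SSC
forward (`fwd_identity`) and reverse-complemented (`rev_identity`).

Identity is alignment identity (matching columns over all columns) when
the two sequences share at least five unique 21-mer anchors; otherwise —
reverse-oriented or unrelated sequences, where a global alignment is
meaningless garbage — a Mash-style estimate is used: per-base identity is
recovered from 12-mer containment as `containment^(1/12)`, floored at the
random-sequence expectation of 0.25, with containment at the level expected
by chance treated as zero. This keeps both evidence numbers on the same
interpretable scale at a tiny fraction of the cost of dynamic programming.

The call is `+` iff `fwd_identity > rev_identity`; when the two identities
are within `tol = 0.02` the result is `indeterminate` — on strongly
diverged genomes a coin-flip would otherwise masquerade as evidence. When
annotations exist, the strands of SSC-resident genes shared with the
reference (ndhF, ccsA and the ndh cluster in practice) are reported as a
second, independent channel. `orientation_survey()` applies the caller to
a batch, records per-genome failures as rows, and totals the calls.

## Repeat scanning

**SSRs.** `find_ssrs()` reports every maximal perfect tandem repeat of a
*primitive* motif of 1–6 nt whose tract reaches `min_tract` bases. Tracts
count whole motif copies only (a trailing partial copy neither counts nor
extends); a run whose motif is a power of a shorter motif is reported only
under the shortest motif (poly-A is mono, never di-"AA"); homopolymer runs
of N are ignored; motifs are canonicalized to the lexicographic minimum
over rotations and reverse-complement rotations, so both strands of a
genome yield the same loci. Scanning is rle-based on the lag-m
self-comparison vector, with origin-spanning tracts found via the doubled
sequence and deduplicated.

The flat default `min_tract = 10` is the loosest reading of a "10 nt"
tract threshold. Under it, 2-copy penta- and hexanucleotide tracts are
abundant in random background sequence (a 12-base exact tandem occurs every
few kb by chance), so a census of *informative* SSRs needs per-class
thresholds, as microsatellite search tools conventionally apply.
`ssr_class_thresholds()` provides the set used throughout the package's
own analyses: 10/12/15/16/20/18 bases for mono…hexa, i.e. at least 10, 6,
5, 4, 4 and 3 copies. The generator's planted census is designed against
these thresholds, which is why planted-versus-found comparisons are exact.

**Long repeats.** `find_long_repeats()` reports all maximal exact direct
and inverted repeat pairs of at least `min_len` bases (default 30 bp, the
common exact-match default in repeat surveys; the choice is exposed).
Detection seeds on `min_len`-mers, merges diagonal runs, excludes
self-overlapping pairs, and — when an IR pair is supplied — removes
matches lying on the genome-scale IR diagonal, so the structural IR does
not drown the biologically interesting dispersed repeats. Output ordering
is deterministic (length descending, then position).

## Alignment and divergence statistics

`align_pair()` produces a deterministic global pairwise alignment: k-mers
unique within both sequences become anchors, the longest strictly
increasing chain is kept, collinear anchors merge into exact blocks, and
the unanchored segments between blocks are aligned by Needleman–Wunsch
(via Biostrings; match 1, mismatch −1, gap open 4, extend 1). Equal-length
segments of up to 3 bases are paired directly — gapless is DP-optimal
there under this scoring, and it avoids thousands of tiny DP calls on
SNP-dense pairs. With no anchors at all, sequences up to 20 kb fall back
to full DP; longer ones raise an error advising external alignment.
Inputs are expected pre-canonicalized (same frame and orientation).

`sliding_pi()` computes nucleotide diversity in windows of `window`
alignment columns advanced by `step`: π per window is the average over row
pairs of (mismatching usable sites)/(usable sites), where usable means
unambiguous, ungapped bases in both rows — gaps and ambiguity codes leave
both numerator and denominator. Windows with no usable site are `NA`, and
a window longer than the alignment degrades to a single truncated window
with a warning. With `window = step = n_cols` this is exactly the global
p-distance. The defaults are window 800 / step 50; 600/100 is another
setting in circulation for the same kind of analysis, and both are plain
arguments — profiles record their parameters as attributes.

`substitution_spectrum()` pools the mismatching usable columns of a
pairwise alignment into the six unordered base-pair classes A:C, A:G, A:T,
C:G, C:T, G:T, with transitions ts = A:G + C:T. Note the genuine symmetry
property: reading both rows on the opposite strand maps each class to its
complement (A:G↔C:T, A:C↔G:T, A:T and C:G fixed), preserving ts, tv and
the total — the class vector itself is *not* strand-invariant, and the
tests assert exactly this.

`call_hypervariable()` merges maximal runs of windows with
`pi >= threshold` into regions and names them by overlapping genes, or by
the flanking gene pair when intergenic. The default threshold 0.7 follows
the convention of flagging only near-saturated windows; it is far above
anything two congeneric plastomes produce (mean π ~0.02), so for real
screening work a threshold a few-fold above the profile's own mean is the
sensible setting — the parameter is exposed for that reason.

`per_gene_divergence()` maps each annotated gene (exons only, IR copies
pooled) to alignment columns on the first row's frame and reports usable
sites, differences and percent identity, ranked most-variable first with
alphabetical tie-breaks; genes outside the aligned span are flagged, not
dropped.

## Distances and neighbor joining

`pairwise_distance()` implements p, JC69 (`−3/4·ln(1−4p/3)`), K2P
(`−ln(1−2P−Q)/2 − ln(1−2Q)/4`) and a composite-likelihood-style `mcl`
model: Tamura–Nei with base frequencies pooled across all sequences
(parameters shared by every pair) and per-pair purine-transition,
pyrimidine-transition and transversion proportions. Deletion is
`pairwise` (gap/ambiguous columns removed per pair — the default, matching
how published plastome trees state their site handling) or `complete`
(removed across all rows, with the pooled usable-site count reported).
Undefined corrections (log of a non-positive argument under saturation)
yield `NA` with a diagnostic and mark the matrix unusable for tree
building — never a silent 0. The p/JC69/K2P models are cross-checked
against an independent reference implementation (ape::dist.dna) in the
tests; `mcl` follows its published description but no bit-exact claim is
made for it, since composite estimators differ across implementations.

`nj_tree()` is a standard Q-criterion neighbor-joining agglomeration with
two determinism rules: ties in Q break to the lexicographically lowest
active index pair, and a negative intermediate branch length is clamped to
zero with the deficit moved to its sibling edge so the joined pair's path
length is preserved. The result is an unrooted `phylo` tree (trifurcating
root). On an additive matrix NJ provably reconstructs the generating tree;
the tests verify this exhaustively for every 4- and 5-taxon topology
against a least-squares-over-all-topologies oracle, and check
order-invariance and agreement with ape's NJ. Newick output quotes labels
containing spaces (doubling internal quotes) and writes branch lengths to
10 significant digits; the reader restores quoted labels and reports the
position of unbalanced parentheses in malformed input.

## The synthetic-plastome generator

`simulate_plastome()` is first-class, tested code — the package's
no-download substrate with exact ground truth. It emulates:

* the quadripartite architecture, with IRb the exact reverse complement of
  IRa; the `test` preset uses LSC 9,000 / SSC 2,000 / IR 1,500 bp (every
  brute-force oracle runs in seconds at this scale), `fullscale` uses
  90,351 / 19,486 / 26,533 bp — the dimensions of a real Malvaceae
  plastome, totalling 162,903 bp;
* a canonical 113-gene complement (79 CDS, 30 tRNA, 4 rRNA) with 18 genes
  duplicated in the IRs (4 rRNA, 8 tRNA, rpl2, rpl23, rps7, rps12, ndhB,
  ycf2), 11 SSC-resident genes, 15 single-intron genes and 2 double-intron
  genes (ycf3, clpP). Gene sequences are composition-matched placeholders;
  at full scale intron lengths are set so the mean intron is 907 bp with
  trnK-UUU the longest at 2,599 bp, matching the reference architecture;
* planted SSR tracts and direct/inverted repeat pairs. The fullscale
  census is 86 SSRs in classes 28/11/13/15/10/9 (mono…hexa; mono
  frequency 32.56%) and 49 repeat pairs (30 direct, 19 inverted, five
  exceeding 50 bp). Guard bases at every plant boundary break one-base
  extensions, so each plant is *exactly* maximal and scanners must recover
  it coordinate-for-coordinate;
* i.i.d. background at GC 36.65% (a typical plastome value, and the
  reference genome's);
* mutation (`mutate_genome()`): per-site substitutions with transition
  probability `tstv/(tstv+1)` given a substitution (default ratio 2), so
  the realized spectrum's transition fraction estimates `tstv/(tstv+1)`;
  geometric-length indels confined to intergenic spacers. When the genome
  carries a partition, IRa substitutions are mirrored (complemented) into
  IRb rather than drawn independently — the concerted evolution that keeps
  real IRs near-identical, without which no mutated genome would retain a
  detectable IR at the 0.001 mismatch ceiling. Per-site rates are
  unchanged by the mirroring;
* SSC flips (`flip_ssc()`, an exact involution touching only the SSC) and
  families (`simulate_family()`): a root genome evolved along a `phylo`
  tree with per-branch substitution rates equal to branch lengths, with
  optional per-leaf flips.

Determinism: every generator function takes a seed and uses it through an
isolated RNG scope, so identical seeds give byte-identical genomes across
sessions.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: codon structure and selection (placeholder
genes), compositional heterogeneity along the genome, interrupted/compound
SSRs, nested or degenerate repeat families, rate variation across sites,
rearrangements other than the SSC flip, and sequencing error. Tests
establish algorithmic correctness against exact truth and independent
oracles, not biological calibration.

## Problem sizes used by the tests

The suite validates each scanner against naive brute-force oracles
(all-cells dynamic programming for repeats, per-position motif walks for
SSRs, per-window recounts for π) at sizes where those oracles are
feasible: 200 planted-IR genomes of 3.0–4.5 kb, 200 random 2 kb sequences
for both repeat scanners, 100 seeded SSC flips at test scale, a 100 kb
mutation run for the transition-fraction check, every 4- and 5-taxon
topology for NJ exactness, and twenty 6-taxon families of ~20 kb genomes
(internal branches 0.005–0.02 substitutions/site) for topology recovery.
The acceptance script runs the fullscale generator once and reruns every
detector on it in well under a minute.

## Known limitations

* GenBank I/O is deliberately minimal: single-record flat files, gene-level
  CDS/tRNA/rRNA features with `join`/`complement` locations. Trans-spliced
  genes (rps12 in real annotations) are not modelled.
* An exon split exactly at the origin is indistinguishable in GenBank
  notation from an origin-wrapping exon; the reader merges such span pairs.
* `align_pair()` is for closely related, co-oriented genomes; for distant
  or rearranged pairs use an external aligner and `load_alignment()`.
* The `mcl` distance shares parameters across pairs via pooled base
  frequencies, which approximates but does not replicate any specific
  composite-likelihood implementation.
* Orientation identity numbers from the k-mer estimate path are
  calibrated approximations; decisions near the indeterminacy band should
  be checked with the marker-gene channel.
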