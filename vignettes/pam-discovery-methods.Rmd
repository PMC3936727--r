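---
title: "PAM discovery and Cas9 ortholog grouping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PAM discovery and Cas9 ortholog grouping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispam)
```

## The problem

Type II CRISPR-Cas interference requires two sequence signals on the
invading DNA: a protospacer matching the crRNA spacer, and a short
protospacer adjacent motif (PAM) immediately 3' of the protospacer, read
on the non-target strand (the strand whose sequence equals the spacer).
Because Cas9 orthologs recognise different PAMs, transplanting a Cas9
into a new editing context requires inferring its PAM.  `crispam`
implements the comparative-genomics route to that inference: collect the
spacers of a host's CRISPR array, find matching protospacers in phage,
plasmid and related genomic sequence, stack the 10-nt flanks 3' of every
protospacer, and read the PAM off the resulting frequency matrix.  The
package also provides the companion computations used to organise Cas9
diversity — ortholog clustering under coverage thresholds, a
distance-based grouping tree with column bootstrap, and a simplified
repeat:anti-repeat duplex score — together with a fully reproducible
synthetic-data generator that stands in for public-database searches.

## Protospacer matching

`find_protospacers()` scans each target on both strands for windows that
align to a spacer at or above a configurable identity threshold
(default 0.90).  Two choices deserve emphasis:

* **Identity is anchored to the spacer length**: `matches /
  nchar(spacer)` under a semi-global alignment in which the spacer is
  aligned end to end and window overhangs are free.  Database search
  tools usually report identity over the local alignment span, which can
  shorten the denominator; anchoring to the spacer makes "90%
  similarity" unambiguous and slightly conservative.
* **Scoring** is megaBLAST-like: match +1, mismatch −2, affine gaps with
  open −5 and extend −2 (a gap of length L costs `−5 − 2L`).  Because
  identity is a match count, the scores matter only for ranking
  alternative spans; tie-breaks are deterministic (leftmost span, then
  `+` strand).

The scan is seed-and-extend: the spacer is split into
`mismatch_budget + max_gaps + 1` contiguous pieces, each piece is
matched exactly against the target, and every seed neighbourhood is
verified by the full dynamic program.  By the pigeonhole principle an
alignment with at most `mismatch_budget + max_gaps` edit operations must
conserve one piece exactly, so no hit above threshold can be missed.
(A seed length of `ceil(len / (max_mismatches + 1))` would be sound only
for ungapped hits; since up to 2 gap columns are admitted by default,
the piece count includes the gap budget.)  Overlapping hits of one
spacer are reduced greedily: best score first, discarding spans that
overlap an accepted one.  Hits falling inside declared CRISPR-array
intervals can be masked out, since a spacer trivially matches its own
array.

## Flanks, frequency matrix, and consensus

For a `+`-strand hit ending at position `e` (0-based half-open
coordinates), the PAM evidence is `target[e, e+10)`; for a `−`-strand
hit starting at `s` it is the reverse complement of `target[s-10, s)`.
Flanks shorter than the configured width (contig edges) are dropped, not
padded — padding would bias terminal positions.  Identical
(protospacer, flank) pairs are deduplicated by default so that a
protospacer inherited by a family of near-identical phages is counted
once; `dedupe = FALSE` keeps all copies.

Flanks are fixed-width, so "alignment" is positional stacking.  The
position frequency matrix counts A/C/G/T per position; ambiguous bases
go to a per-position `skipped` tally, preserving `counts + skipped = n`.
Information content is the standard logo quantity `IC = 2 − H` bits with
`H` the base-2 Shannon entropy of the position's base fractions.  The
Schneider small-sample correction (`3/(2 ln 2 · n)`) is available but
off by default: protospacer counts in this kind of survey are small
(tens, sometimes fewer), and the correction can erase weak but real
signals; enabling it is a single flag.

The consensus rule is deliberately simple and deterministic: per
position, admit bases in descending frequency until their cumulative
fraction reaches `coverage` (default 0.8), including all bases tied with
the last admitted one, and emit the IUPAC letter of the admitted set.
A 50/50 position therefore yields a two-letter code (e.g. `M` for A/C)
— the caller surfaces ambiguity that only an experiment can resolve —
and an even position yields `N`.  Reading a PAM off a logo by eye has no
canonical rule; this cumulative-coverage rule is the package's own
declared convention, not a reconstruction of any published one.  A
consensus is refused below `min_support = 3` flanks; the practical
remedy, pooling targets found with the arrays of closely related strains
of the same species, is what the pipeline's `groups` mapping implements.
With a degenerate truth such as `NNNNACA`, recovery claims concern the
informative positions (here 5–7): at realistic support an exactly
uniform position will often be called as a 3-base code rather than
literal `N`, because finite-sample frequencies rarely cross the coverage
threshold four ways; the synthetic-recovery tests therefore require the
non-N truth positions exactly and a near-uniform (≥ 3-base) call where
the truth is `N`.

Per-source partitions (`partition_by_source()`) profile phage-, plasmid-
and genome-class hits separately.  Chromosomal protospacers are retained
but flagged: a self-derived protospacer can carry a deviant flank
(self-protection against autoimmunity), and contrasting the partitions
is precisely how such cases become visible.

## Ortholog clustering

`greedy_cluster()` reimplements coverage-threshold clustering: proteins
shorter than 800 aa are discarded; every remaining pair is aligned
locally (BLOSUM62, gap open 11 / extend 1, `X` scored 0); an edge joins
two sequences when the alignment covers ≥ 0.8 of *both* lengths and the
score coverage — bit score divided by alignment length — is ≥ 0.8.  Bit
scores use the gapped Karlin–Altschul transformation with the standard
protein constants λ = 0.267, K = 0.041; these are declared package
constants, and the full edge table (scores, coverages) is exported as an
audit TSV so the thresholds' sensitivity to them is visible rather than
hidden.  Clusters are single-linkage connected components, which is the
effective semantics of the classical coverage-threshold clusterers.
Coverage is applied to both sequences symmetrically; users can relax
this by supplying their own edge table.  All-vs-all alignment is O(n²)
and intended for desk scale (hundreds of sequences).

## Grouping tree

The package's tree is an explicit stand-in for maximum-likelihood
reconstruction, which is out of scope: what is claimed and tested is
grouping concordance (which sequences fall together, and whether
clusters are monophyletic), not branch-length fidelity.  The chain is:
informative-column selection (gap fraction ≤ 0.5 and ≥ 2 distinct
residues per column — a declared approximation to curated alignment
blocks, with thresholds exposed and no claim of reproducing any curated
column count), pairwise p-distances with pairwise deletion, Poisson
correction `d = −ln(1 − p)` (p capped at 0.99 with a warning to keep the
correction finite), neighbor joining, and column bootstrap with
per-bipartition supports mapped onto the point tree.  NJ is exact on
additive matrices, which the test suite exploits as an oracle; labels
are sorted before joining so identical matrices give byte-identical
newick output, and negative branch lengths are clamped to zero.
Monophyly of a leaf set is unrooted: some edge bipartition must separate
exactly that set.  Singletons, sets of size n−1 and the full leaf set
are monophyletic by convention (leaf edges and the trivial bipartition).

## Duplex scoring

`hybridize()` scores repeat:anti-repeat pairing with an inter-strand
dynamic program: pair weights GC = 3, AU = 2, G:U wobble = 1, mismatch
−1, per-base gap −2, local semantics (the empty duplex scores 0).  It is
*not* energy-calibrated and ignores intra-strand structure; it exists to
compare the extent and architecture of repeat:anti-repeat
complementarity across loci with a transparent, dependency-free score.
Thermodynamic co-folding belongs to dedicated RNA packages.

## The synthetic generator and what it does (not) show

`synth_corpus()` plants spacer copies into an i.i.d. background genome
at a per-base mutation rate, each followed on its strand by a concrete
flank drawn uniformly within the IUPAC base sets of a ground-truth PAM
(padded with `N` to the flank width) and mutated at the same rate.
Placements are rejected rather than overlapped; the manifest records
coordinates, strands, mutation counts and realized flanks, and fully
determines the corpus given the seed.  Each generator operation draws
from its own derived seed stream, so adding placements does not perturb
the background bases.

The default corpus — 50 protospacers, per-base mutation rate 0.02,
4-kb background, 20-nt spacers from a 5-spacer array — mirrors the
modest evidence scale of real protospacer surveys, where a species
typically yields tens of usable flanks.  These sizes (and the test
batteries: 20 recovery replicates, 100 randomized oracle cases, 100
additive matrices, bootstrap B = 50–100) are the package's chosen
problem sizes; they keep the full validation suite in the minutes range
on a single core.

What passing these tests shows: the matcher finds exactly what is above
threshold, coordinates and strand conventions are consistent end to end,
and the consensus caller recovers a known PAM at realistic noise and
support.  What they do not show: performance on real phage corpora with
repeats, codon structure, horizontal transfer and uneven phylogenetic
sampling; robustness of the 0.90 identity threshold to real spacer
divergence; or any thermodynamic validity of the duplex score.  Database
retrieval (which sequences count as "related to the host species") is
likewise an input here — a metadata table — not an inference.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open on the forward strand internally;
  BED output keeps them, GFF3 output converts to 1-based inclusive.
* `U` is normalized to `T` in DNA inputs; spacers must be unambiguous
  A/C/G/T (ambiguity codes in a spacer make the identity denominator
  ill-defined and are rejected with a clear error), while targets may
  carry IUPAC codes.
* Empty target sets warn and return an empty hit table; an empty spacer
  set is a usage error.  A position with zero usable counts has IC 0 and
  consensus `N`, each with a warning.
* All randomness (generators, bootstrap) is seed-derived;  reports carry
  a config digest, package version and seed, and rerunning a config
  reproduces every consensus byte for byte.
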