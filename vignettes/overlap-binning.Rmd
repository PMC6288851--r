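---
title: "Reference-free read binning with exact-overlap graphs"
author: "overbin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free read binning with exact-overlap graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overbin)
```

## The model

Shotgun metagenomic sequencing mixes reads from every organism in a sample.
`overbin` groups those reads by source organism *before* assembly and without
any reference database, using a single, deliberately strict signal: two reads
are considered related if and only if they share an **exact common substring
of at least `b` bases**, in forward or reverse-complement orientation. Reads
become nodes of an undirected graph, shared-substring pairs become edges, and
in the ideal case each chromosome in the sample appears as one connected
subgraph. Binning is then just connected-component extraction.

Two biological realities break the ideal case, and the pipeline has one stage
for each:

* **Conserved regions** (classically the rRNA operon) are nearly identical
  across taxa and occur in several copies per genome. Reads carrying at least
  `b` conserved bases match reads at *every* copy in *every* carrier genome,
  so their node degree is several times the typical degree of a single-copy
  locus. These hub nodes fuse otherwise-disjoint species subgraphs.
* **Chimeric reads** join fragments of two molecules and tend to show
  atypically low, split-affiliation connectivity.

Because a node's degree approximates the local abundance of its sequence,
the reads of one genome sequenced at one depth produce a roughly
normal-shaped peak in the **degree histogram**; hubs sit far right of the
peak and chimera-suspect reads far left. The tool therefore runs in two
passes: first build the graph and inspect the histogram (`hist`), then choose
an inclusive degree band `[lower, upper]` and re-run (`bin`). Nodes outside
the band are removed in a single pass — the band always refers to the degrees
of the *unfiltered* graph, i.e. to the histogram the user actually looked at —
and the connected components of the remainder, found by breadth-first
search, are reported as bins, largest first. Components smaller than
`min_bin_size` are set aside rather than reported.

## Edge semantics and the window construction

An edge requires a shared exact substring of length at least `b` located
anywhere in both reads — substring matching, not suffix–prefix dovetail
overlap, and no scoring or mismatches. The implementation indexes every
length-`b` window of every read in a hash table, keyed on the lexicographic
minimum of the window and its reverse complement so that both orientations
collapse onto one key. This is complete: any shared substring of length
`>= b` contains a shared window of length exactly `b`. The test suite checks
that completeness claim against two independent oracles — a per-pair
brute-force substring enumeration and, on tiny inputs, a
longest-common-substring dynamic program.

Further contracts of the graph stage:

* Windows containing `N` are skipped, so `N` never matches anything,
  including another `N`; ambiguous bases break matches instead of inventing
  them. IUPAC ambiguity codes are mapped to `N` on load, with a warning.
* A pair of reads counts as **one** edge no matter how many substrings it
  shares; degree therefore means "number of distinct neighboring reads",
  which is the abundance reading the histogram stage relies on.
* Duplicate reads stay distinct nodes joined by an edge — duplication is
  abundance signal, not an artifact to collapse.
* A read never neighbors itself, even via a palindromic window.
* Reads shorter than `b` cannot carry a window and are isolated by
  construction; they end up in the `small_or_singleton` set.
* Matches can never span two reads (each window comes from exactly one
  read), and the construction is deterministic in the file order of reads.

`b` trades sensitivity against specificity: 70 suits 454-style or merged
long reads, 100 merged Illumina pairs, and a small value such as 15 a
low-coverage residual pass over previously unbinned reads. Raising `b` can
only remove edges (tested as a monotonicity property).

## The synthetic benchmark generator

Real metagenomes come with no per-read truth, so the package ships a
generator that emulates the structure the algorithm assumes, with truth
labels for every read:

* i.i.d. random genomes at chosen GC and length — across independent random
  genomes of tens of kilobases, cross-genome exact 70-mers essentially never
  occur, and the tests *verify* their absence with the substring oracle
  rather than relying on the probability;
* uniform read starts, uniform strands, normal read lengths truncated below
  (default mean 300 bp, emulating length-variable merged long reads);
* per-genome target depth, with read count `round(depth * G / mean_len)`;
* substitution-only errors (an exact-match graph is blind to the difference
  between a substitution and an indel — either breaks windows);
* optional chimeras: additional reads joining the first half of one read to
  the second half of a read from a different genome, labelled `chimera`;
* an optional **shared conserved region** spliced verbatim into designated
  carrier genomes.

The shared region is inserted as **tandem multi-copies (default 4 per
carrier) at the genome tail**. Both choices are deliberate. Multiplicity
mirrors rRNA-operon biology and is what actually produces the
"several-times-the-mean" hub degrees the threshold mechanism needs: with a
single copy in each of two genomes, a read straddling the region boundary
with barely `b` conserved bases gains only a handful of cross-edges, its
degree lands inside the normal peak, and *no* upper threshold can remove
every cross-linked read without also removing ordinary reads — single-copy
pairwise shared regions are a documented limitation of degree-threshold
rescue, not something the generator should hide. With 4 tandem copies in 2
carriers every conserved window occurs at 8 sites, so every conserved-carrier
read sits far right of the peak and a wide band of thresholds separates the
genomes cleanly. Tail placement means that removing the hub reads cuts
nothing out of the middle of a genome, so each genome still yields a single
flank component rather than fragmenting into several bins.

Genomes are linear and reads never wrap; circularity would add nothing to
edge semantics. Chimeras are additive (donor reads are kept) so that read
counts obey `per-genome reads + chimeras = truth rows = FASTA records`.

What the generator does **not** emulate: quality-score-dependent error
profiles, homopolymer indels, strain-level mixtures, paired-end structure
(pair merging is assumed upstream), and real phylogenetic sequence
similarity between genomes. Passing tests on these benchmarks therefore
demonstrate the graph/threshold mechanics, not robustness to real
cross-species homology beyond the explicitly modelled conserved regions.

## Choice of benchmark scale and depth

The bundled benchmarks use 20–50 kb genomes and a few thousand reads so that
the whole suite, including brute-force oracles, runs in minutes. Depth for
the two-genome benchmarks is 25×, matching the regime of a deeply sequenced
isolate mixture. The choice is driven by coverage statistics: a genome stays
one connected component only where consecutive read starts are closer than
`L − b` bases, so the expected number of component breaks is about
`N · exp(−c(1 − b/L))` (Lander–Waterman). At 10× with 300 bp reads and
`b = 70` that is ~0.3 breaks per 20 kb genome — occasional fragmentation of
a genome into two bins is *expected behavior* at that depth, while at 25× the
expectation is ~10⁻⁴. The five-genome benchmark keeps the unequal-depth
design (11.7×, 17.41×, 2.4×, 2.4×, 1.7×): its low-depth genomes *do*
fragment into many small components, which is exactly the
abundance-dependent behavior the degree histogram exposes, and the test
asserts only what survives it — the deepest genome forms the largest bin at
purity 1, and per-genome mean degree rank-correlates with depth.

## Evaluation conventions

`score_bins()` builds the exact integer contingency of bins against truth
labels. Purity is the dominant label's share of a bin; ties are broken
lexicographically and flagged. Per-genome recall counts reads recovered in
bins *dominated* by that genome, against the denominator of reads long
enough to be binnable (`length >= b`), with the all-reads denominator
reported alongside — reads shorter than `b` are unbinnable by construction,
and both views are informative. The `chimera` label participates like a
genome.

## Numerical and degenerate-input conventions

* Thresholds are inclusive on both ends; `lower > upper` is a configuration
  error; the default band is `[0, Inf]` (identity).
* `min_bin_size` defaults to 2: singletons are never reported as bins.
* Bin order is size-descending, ties broken by smallest member ordinal; bin
  files are numbered from `bin0`. Re-running on identical input yields
  byte-identical outputs; shuffling the input read order permutes bin
  *membership labels* but never membership itself.
* Empty read sets give an empty graph; `b` larger than every read length
  gives an edge-free graph with a warning.
* The excluded sets (`excluded_low`, `excluded_high`, `small_or_singleton`)
  partition the input together with the bins, and can be written out for
  residual passes — re-running with a smaller `b` on the leftovers is the
  supported workflow for low-abundance organisms.
* All randomness in the generator flows from one integer seed, and the
  generator restores the caller's RNG state.

## Known limitations

* Exact matching is deliberately strict: at realistic error rates,
  per-base errors thin the edge set, and sensitivity must come from
  coverage. The substitution-error generator exists to exercise exactly
  this thinning.
* Degree thresholds are chosen by the user from the histogram; the package
  exposes the data but no automatic threshold rule.
* Single-copy conserved regions shared by exactly two genomes cannot be
  cleanly removed by any degree threshold (see above).
* The core is single-threaded; determinism is unconditional rather than
  achieved by order-normalizing parallel output.
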