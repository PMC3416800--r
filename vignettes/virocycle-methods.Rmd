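---
title: "Methods: iterative kmer-optimized assembly and cassette discovery"
author: "virocycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative kmer-optimized assembly and cassette discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virocycle)
```

## The problem

A virome sample — the DNA viruses and bacteriophages of a community such as
the human gut — mixes tens of genomes of very different sizes (a few kb up
to hundreds of kb) at abundances spanning orders of magnitude, with rapid
sequence evolution within and between hosts. Short-read de Bruijn graph
assembly of such a mixture is sensitive to the choice of kmer in a way that
single-genome assembly is not, because the optimal kmer depends on the kind
of polymorphism in the mixture:

* **Short kmers resolve point polymorphism.** A population of near-identical
  genomes differing at isolated sites produces, at a small kmer, one simple
  *bubble* per site (two internally disjoint paths between a shared start
  and end node). When the kmer length exceeds the spacing between sites, the
  variant kmers overlap several sites at once and the bubbles braid into a
  tangle that no longer resolves into a consensus. `count_bubbles()` makes
  this diagnosable: four haplotypes differing at three sites spaced 25 bp
  apart show exactly 3 bubbles at k = 23 and a non-bubble tangle at k = 27.
* **Long kmers separate unrelated genomes.** Two unrelated genomes sharing
  one short segment are fused into a single connected component whenever
  the segment is at least k-1 long, and fall apart into two components
  otherwise. `connected_components()` shows a 25 bp shared segment joining
  two genomes at k = 23 and separating at k = 27.

No single kmer is right for the whole mixture, which motivates the iterative
design below.

## The iterative assembly loop

`run_iterative_assembly()` repeats four steps until the data are exhausted:

1. **Kmer scan.** Trial assemblies are run over a descending ladder of odd
   kmers (default 63, 59, ..., 19). If any trial closes a *circular contig*
   of at least `circular_min_len` (default 2 kb) — a maximal non-branching
   cycle in the graph, the signature of a completely assembled circular
   viral genome — the **largest** such kmer wins. Otherwise each trial is
   scored by the cumulative length of its `top_n` (default 20) contigs of at
   least `min_contig_len` (default 1 kb), ranked by read support, and the
   kmer with the longest score wins; ties break to the larger kmer. When
   more than `trial_subsample` reads (default 10^6) are present, the scan
   runs on a seeded pair-preserving subsample.
2. **Assembly.** All current reads are assembled at the winning kmer:
   graph construction on canonical kmers, then simplification (below), then
   contig extraction.
3. **Retention.** The `top_n` contigs of at least `min_contig_len`, ranked
   by read support, are retained, plus *every* circular contig of at least
   `circular_min_len`; circles do not count against `top_n`.
4. **Subtraction.** The full current read set (never the scan subsample) is
   mapped to the retained contigs, and each pair with at least one mapped
   mate is removed — the unmapped mate of a mapped read usually spans a
   circular junction or an assembly gap and would only obstruct the next
   round. The loop ends when zero reads map or no contig reaches 1 kb;
   whatever reads remain then get one final assembly at the last winning
   kmer, reported in full.

Read counts obey an exact conservation law — input reads equal the sum of
per-iteration mapped reads plus the reads left unassembled — which the test
suite asserts on every simulation.

### Graph machinery and numerical choices

* Kmers are packed two bits per base into 128-bit integers (k up to 63) and
  collapsed with their reverse complements onto the lexicographically
  smaller *canonical* form, with strand handled during traversal; shotgun
  reads come from both strands, and the canonical graph is invariant to
  reverse-complementing any read (a tested property). Kmers containing N
  are skipped.
* **Simplification** repeats three steps to a fixed point (hence it is
  idempotent, also tested): edges observed fewer than `min_edge_coverage`
  times (default 2) are removed; dead-end branches of at most
  `max_tip_length` edges (default 2k) are clipped, but only when a sibling
  branch at the attachment node beats them on mean coverage (then on
  length) — this competitive rule prevents the genuine end of a linear
  path from being mistaken for a tip; two-path bubbles of at most
  `bubble_max_len` edges (default 2k) collapse onto the higher-coverage
  branch (ties to the lexicographically smaller sequence), the removed
  branch's mean coverage being added to the kept one. The 2k tip/bubble
  limits are conventional; they are exposed as configuration.
* **Contigs** are maximal non-branching paths. A non-branching cycle is
  emitted as circular without repeating its closing (k-1)-mer and is
  normalized to the lexicographically smallest rotation of the smaller
  strand; linear contigs are normalized to the smaller strand. All scans
  iterate sorted edge sets, so output is byte-for-byte deterministic.
* **The mapper** is a seed-and-extend aligner: a read maps where it shares
  an exact seed (`seed_length`, defaulting to the current assembly kmer)
  with a contig, verified by mismatch counting and, when that fails, a
  banded gapped alignment (band 5); the identity floor is 0.95. Each read
  keeps its best contig only. Circular contigs are virtually extended by
  one read length minus one so junction-spanning reads map — extending by
  only a seed length would truncate those alignments. A long seed makes
  the mapper conservative: an error in the middle of a read can leave no
  exact seed at large k, and such reads simply stay in the remaining pool.

## The synthetic community testbed

`community_spec()` / `generate_community()` / `simulate_reads()` emulate the
study conditions this package targets: 5-50 circular or linear genomes of a
few to tens of kb, skewed abundances (rank-power-law, default exponent 1.5),
100 bp paired-end reads from opposite strands of insert-length fragments
(default 300 +/- 30 bp), and uniform per-base substitution errors (default
0.005, an Illumina-like rate). Circular genomes are sampled across the
origin. Genomes are i.i.d. uniform ACGT, screened so no 62-mer (the largest
node size in the ladder) repeats within a genome; assembly ground truth is
then unambiguous. What the simulator deliberately does *not* model: indel
errors, quality-score structure, amplification bias, and genuine repeat
structure within and between genomes. Passing tests on this testbed
therefore demonstrate the pipeline's bookkeeping and its kmer/circularity
logic, not robustness to repeat-rich real viromes.

### The spike-in recovery benchmark

`spike_recovery_benchmark()` mixes reads of one 8 kb circular target genome
into a background community at fixed counts (500, 1000, 1500, 1798 of
40,000 reads — 6.25 to 22.5-fold target coverage at 100 bp), runs the full
loop on each mixture, and reports the recovered fraction of the target (the
longest contig aligning to it at >= 95% identity over >= 500 bp, divided by
the genome length, capped at 1). Reads are error-free so the curve isolates
the effect of coverage ("clean coverage").

The background design deserves its own account. The benchmark's premise is
that a low-abundance genome is protected from premature, fragmented
assembly by rank competition: a fragment of the target that forms at a
background-driven kmer must *lose* the race into the per-iteration retained
set, so its reads survive until an iteration whose kmer suits the target
(ideally closing its circle). On full-scale data this protection is
automatic — abundant background contigs recruit thousands of reads each,
orders of magnitude more than any fragment of a rare genome. At a
40,000-read benchmark scale it must be engineered: (i) at least 20
non-circular background contigs must exist, because circular contigs are
retained outside the `top_n` cap and do not saturate it; and (ii) every
background contig must out-rank every possible target fragment at every
kmer of the ladder, which requires every background genome to assemble
contiguously rather than fragment (at k = 63 that needs roughly 30-fold
coverage or more). The default background is therefore 24 genomes of
2-2.5 kb (22 linear, 2 circular) at mildly skewed rank^-0.3 abundances,
putting every genome at 50-130-fold coverage with over a thousand
supporting reads per contig. A strongly skewed large-genome background —
more visually faithful to a real virome — silently voids the retention cap
at this scale and makes recovery non-monotone in coverage, which is a
property of the scale-down, not of the method. With the saturating
background, recovery is monotone in coverage and reaches 1.0 from about
19-fold coverage; at 6-fold the target assembles only partially, as
expected for a kmer ladder whose smallest value still needs about 5-fold
effective kmer coverage against a 2-per-edge coverage floor.

Problem sizes used throughout the tests and the acceptance script — 2-8 kb
genomes, 2,500-40,000 reads, 10^5-contig Monte-Carlo draws — are the scales
at which every property of interest is already exercised; they keep a full
run of the suite in the minutes range on a single core.

## ORFs, families, cassettes

* `call_orfs()` is a deterministic six-frame caller: every maximal
  start-to-stop span of at least `min_orf_len` nucleotides (default 100,
  stop included; ATG starts only by default). It deliberately does not
  re-implement an interpolated-Markov gene finder: the downstream cassette
  mathematics is independent of the gene caller, and planted-ORF tests need
  determinism more than sensitivity. Circular contigs are scanned across
  the junction (a wrapped ORF is reported with its end past the contig
  length); minus-strand ORFs are reported on the forward axis.
* `cluster_families()` groups ORF translations into protein-coding families
  by greedy centroid clustering, processing ORFs by length (descending,
  ties by id) and joining the first centroid at or above 30% global
  alignment identity (BLOSUM62; identity is identical columns over all
  alignment columns, gaps included — stated exactly because clustering
  thresholds are meaningless without the identity definition). The 30%
  default sits near the limit of detectable homology, deliberately
  inclusive. A cluster becomes a family only if its members sit on at least
  two distinct contigs; recurrence across genomes, not paralogy within
  one, is the signal of interest.
* `discover_cassettes()` agglomerates families into cassettes: repeatedly
  merge the pair of units with the highest shared-contig overlap — shared
  contigs over the size of the *smaller* unit — at or above 0.8,
  recalculating all overlaps after each merge; merged units take the
  *intersection* of their parts' contig sets (the conservative reading of
  "found on the same contigs"; union is available as a configuration).
  Ties break by larger smaller-set, then ids, making the result invariant
  to input order (tested). Units with at least two families are reported.
* `co_orientation_score()`: a gene pair on a contig has exactly four
  relative orientations (two strands each; gene order is not part of the
  state). For each family pair the score is the proportion of shared
  contigs showing the modal orientation — one representative ORF per
  family per contig, the longest — and a cassette scores the mean over its
  pairs. Under uniform random orientations the score tends to 0.25, the
  chance level against which conserved cassette architecture is judged;
  the Monte-Carlo check at 10^5 contigs lands within half a percentage
  point of it. `cassette_span_stats()` reports covered bases per contig as
  interval unions, so overlapping ORFs are not double counted.

## The annotation network

`build_bipartite()` consumes an externally produced hit table (ORF against
a reference protein database; this package never runs the search) and draws
an edge between a contig and a reference protein when any of the contig's
ORFs hits it with e-value strictly below 10^-50. Contigs shorter than 3 kb
or with fewer than five distinct qualifying protein partners are dropped,
then orphan proteins; the two filters commute because hit counts are
computed on qualifying edges only. "Five hits" counts distinct proteins,
not alignment segments. Exports are sorted SIF or GraphML (via igraph) for
Cytoscape; GraphML round-trips through `import_network()`.

## Known limitations

* No paired-end scaffolding, gap filling, or repeat resolution beyond
  unitig extraction: repeat-bearing genomes assemble fragmented.
* The mapper requires one exact seed of the current kmer length; at large
  k it under-recruits error-bearing reads, leaving them for later
  iterations (conservative, but it can delay termination slightly).
* Substitution-only error model; indels in real data would break the
  exact-seed assumption more often.
* The co-orientation chance level of 0.25 is asymptotic; on a handful of
  shared contigs the modal proportion is biased upward simply because a
  maximum over four cells is taken from few draws.
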