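---
title: "Methods: pairwise organellar genome comparison in orgvar"
author: "orgvar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise organellar genome comparison in orgvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgvar)
```

`orgvar` compares pairs of complete chloroplast (cp) and mitochondrial
(mt) genomes at base resolution and censuses their repeat structure. This
vignette documents the models and procedures, the parameters that matter,
the numerical choices, and what the simulator-based validation does and
does not establish.

## Coordinates and sequence model

All internal coordinates are 0-based half-open; report writers convert
per table (variant and SSR tables are 1-based inclusive, repeat tables
0-based, plastid-segment tables 1-based BLAST-style), and every output
file names its convention in a header comment. Sequences are uppercase
over `{A,C,G,T,N}`; `U` is mapped to `T` and all other IUPAC ambiguity
codes are collapsed to `N` on input (with a warning) so that real GenBank
records always load. `N` matches nothing — not even another `N` — in
every scanner, so ambiguity never fabricates exact matches, repeats or
SSR copies. Circular genomes are stored linearised at their deposited
origin; `rotate_genome()` relocates the origin, and `align_pair()` uses a
single query rotation to undo origin differences between two circular
genomes.

## Pairwise alignment: anchor, chain, close

1. **Anchoring.** All maximal exact matches (MEMs) of length at least
   `min_match` are found in both orientations. The default of 50 bp is
   the conventional anchor size for organellar-scale comparisons; tests
   go down to 8 bp, where the finder is checked against an exhaustive
   diagonal-enumeration oracle. Internally, seeds are 2-bit-packed
   k-mers (`k = min(min_match, 31)`) extended maximally, with a
   per-diagonal coverage map so that a long match is derived once rather
   than once per contained seed.
2. **Chaining.** Per orientation, a maximum-total-anchor-length collinear
   chain is computed by weighted longest-increasing-subsequence. A
   successor anchor must advance strictly in start and end on both
   genomes; bounded overlap between consecutive anchors is tolerated
   because the two anchors flanking an InDel both extend into the shared
   flanking base. Ties prefer the chain with the smallest reference
   start, making output deterministic. After the heaviest chain is
   accepted, anchors overlapping its footprint by more than 20 % of
   their length are discarded and the remainder is re-chained; secondary
   chains are kept while they span at least `min_chain_span`
   (default 200 bp). This is how a planted inversion surfaces: its
   reverse-complement anchors survive the overlap filter and form their
   own reverse chain.
3. **Gap closing.** Anchors are copied into the transcript as match runs
   after trimming any residual overlap (the same amount on both
   coordinates, preserving the diagonal). Inter-anchor gaps are aligned
   globally under unit edit costs — match 0, mismatch 1, gap 1 per
   base — with deterministic tie-breaking (diagonal, then query-gap).
   Unit costs make the bookkeeping identity *insertion bp − deletion bp
   = query length − reference length* exact on colinear pairs, which the
   tests assert on every simulated pair. Gaps larger than `max_gap`
   (default 50 kb), or gaps claimed by another accepted chain (an
   inversion interior), split the block instead of being aligned.

## Variant model

Within a block transcript, a maximal run of substituted columns is one
variant: length 1 is a SNP; longer runs whose alternate allele equals the
reverse complement of the reference allele are reverse complementary
variations (RCVs); all other runs are multi-nucleotide substitutions
(MNS), reported as co-segregating SNPs. RCV takes precedence, and a run
whose reference allele is its own reverse complement (such as `CG→GC`)
is by construction an MNS — the RCV identity cannot hold when the
alternate differs from the reference. Transition/transversion tallies
cover isolated SNPs only by default, so that their sum equals the SNP
count; `explode_runs = TRUE` adds the per-column contributions of runs.

Gap runs become insertions or deletions and are left-normalised: shifted
to the lowest reference coordinate that preserves the alignment, without
crossing a neighbouring variant. Positions inside homopolymer runs are
inherently ambiguous, which is why comparisons (and the simulator's
truth) use normalised coordinates. Per-class rates are
`100 × count / reference length`, printed to three decimals.

## Quadripartite structure, SSRs, repeats

`detect_ir_partition()` takes the longest maximal inverted-repeat pair of
at least `min_ir` (default 1 kb) as IRA/IRB; of the two interstitial
intervals the longer is the LSC, the shorter the SSC, and the four
regions tile the genome exactly (an error is raised when no qualifying
pair exists).

`find_ssrs()` reports perfect tandem repeats of primitive 1–6 bp motifs.
Candidates are the left-maximal phases of every periodic run; selection
is greedy by span (ties: smaller start, then smaller unit), so reported
loci never overlap and only complete copies count. Thresholds default to
three copies for di- through hexanucleotides — the conventional census
rule — and five copies for mononucleotides; the mononucleotide threshold
is a tool-specific choice with no authoritative published value, so
genome-wide SSR totals should be read as indicative, not comparable
across tools.

`find_maximal_repeats()` reports maximal pairs under the four classical
relations (forward, reverse, complemented, palindromic). Circular genomes
are scanned on the doubled sequence with pairs deduplicated modulo the
genome length, so origin-spanning repeats are found. The large-repeat
table suppresses pairs wholly contained in a longer same-direction pair
(`nonredundant = FALSE` restores the full list), and coverage is the true
interval union, so nested pairs are not double-counted.

## Plastid-derived segments

`find_cp_derived()` is a seeded local homology search: exact 12-mer seeds
in both orientations are clustered along near-constant diagonals
(inter-seed gap ≤ 200 bp, diagonal drift ≤ 40 bp), each cluster's padded
window is aligned globally under unit costs, and the alignment is trimmed
to its maximal-scoring window under the BlastN-style scheme +1/−2/−2 — a
Kadane scan over the run-length transcript, giving local-alignment
semantics without a separate X-drop pass. Segments overlapping on the
mitochondrial genome are merged keeping the higher-scoring span (score,
not raw identity, so a short perfect sliver cannot displace a long
slightly diverged segment), and the identity ≥ 0.80 / length ≥ 50 /
E ≤ 1e−5 filters are applied after merging. E-values use ungapped
Karlin–Altschul statistics with λ ≈ 1.28, K ≈ 0.46 for this scheme over
the search space `|mt| × |cp|`. This approximates, but does not promise
to equal, any specific BLAST build, so genome-wide plastid-derived
percentages are soft numbers; segment-level behaviour is what the tests
pin down (planted fragments recovered within ±0.03 identity, recall
≥ 0.95 for ≥ 200 bp fragments at 85 % identity, empty output on unrelated
random genomes over 20 seeds).

## The simulator and what passing tests mean

`generate_cp_pair()` builds an ancestor as
`LSC ++ IRA ++ SSC ++ revcomp(IRA)` with random interior and pins the IR
boundary bases so the planted inverted-repeat pair is maximal at exactly
its planted length; `generate_mt_pair()` interleaves random backbone
fillers with planted large direct repeats (flank-pinned for the same
reason) and plastid fragments copied from a donor cp genome and mutated
to a configured identity (default 0.97), sized to hit the configured
plastid-derived fraction. The derived genome applies sampled,
non-overlapping events; the manifest records every event, and replaying
it must reproduce the derived genome byte-exactly — a conservation
invariant the tests assert.

Event placement is designed so that planted truth is unambiguous under
the package's own alignment model:

- events are separated by at least 60 bp of untouched sequence (30 bp of
  padding on each side), so each event sits between exact stretches at
  least as long as the default anchor and occupies its own alignment
  gap. Ten-base separation would be enough to keep events distinct, but
  events closer than the anchor length share one gap, where unit-cost
  alignment can legitimately mix their representations;
- homopolymer runs of four or more near an event are avoided, and InDel
  flanks are chosen so the event is neither left- nor right-shiftable,
  making left-normalised coordinates exact;
- a substitution run is planted only where the alignment of its alleles
  resolves to a single substitution run; otherwise (for example an RCV
  whose reverse-complement allele shares a shifted palindromic substring
  with the reference, like `CCAATT→AATTGG`) a gapped decomposition is
  equally or more parsimonious and any aligner would be entitled to
  report it.

The profiles encode the three study conditions used throughout the
validation: `cp-hybrid` (11 insertions and 5 deletions with length
composition 9×1+2×4 and 4×1+1×2, hence a +11 bp cumulative difference,
and no substitutions), `cp-intersubspecific` (110 SNPs, 13 co-segregating
runs of lengths 12×2+1×3, 4 RCVs of lengths 2/4/6/8, 40 insertions, 71
deletions on a 134 kb quadripartite genome with 2 × 20.8 kb IRs and a
12.3 kb SSC), and `mt-hybrid` (26 SNPs split 13 transitions / 13
transversions, 39 insertions including one of 44 bp and 9 single-base
deletions for a +74 bp difference, six large direct repeats of
96 000 / 6 120 / 6 030 / 4 080 / 2 990 / 2 990 bp, and 5.9 %
plastid-derived content on 455 kb). Unspecified InDel lengths follow a
geometric distribution with mean 1.4 bp, matching the observed dominance
of single-base events. The mitochondrial generator offsets its random
stream by a fixed constant relative to the seed so that a cp genome
generated from the same seed shares no random draws with the mt backbone.

What passing recovery tests establish: on genomes whose divergence
consists of well-separated, unambiguous events at realistic rates
(0.006–0.08 % per class), the pipeline recovers every planted event with
exact position and alleles (precision = recall = 1 over 20 seeds at full
genome size). What they do not establish: behaviour on clustered variants
sharing an alignment gap, on homopolymer-interior InDels (where no
coordinate is canonical beyond normalisation), on biologically structured
(non-random) sequence backgrounds, or on genomes whose true alignment is
itself ambiguous due to recombination — there the package still produces
a deterministic, parsimonious answer, but no unique truth exists to
recover.

## Validation problem sizes

The property suites run the scanners against brute-force oracles on 100
seeded random strings each (up to 200 bp for exact matches, 300 bp for
repeat pairs, 1 kb for SSRs) and the gap-closing distance against the
textbook dynamic-programming oracle; recovery suites run 20 full-size
chloroplast pairs (134 kb) across both divergence profiles and one
full-size mitochondrial pair (455 kb). These sizes keep the default suite
in the low minutes on a single core while exercising every code path at
the scale the method targets.

## Known limitations

- Alignment assumes genome pairs that are colinear up to isolated
  inversions; extensively recombined mt genomes produce multiple blocks
  whose boundaries are reported but not interpreted.
- Unit (non-affine) gap costs are deliberate — they make InDel counting
  exact — but they fragment long divergent insertions less economically
  than affine costs would.
- The intravarietal flag on variants is pass-through metadata: calling it
  requires raw sequencing reads, which are outside this package's scope.
- SSR totals, repeat-coverage percentages and plastid-derived percentages
  depend on conventions (monomer threshold, coverage definition, BLAST
  build) that published tables rarely state; `orgvar` documents its own
  conventions and treats cross-tool comparisons of those aggregates as
  indicative only.
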