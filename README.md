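# orgvar: comparative variant analysis of organellar genome pairs

Plant chloroplast (cp) and mitochondrial (mt) genomes are small, largely
uniparental and slowly evolving, which makes complete-genome comparisons
between closely related cultivars a sensitive way to trace maternal
ancestry and to design diagnostic markers. `orgvar` implements that
comparison end to end for pairs of assembled organellar genomes:

- **Base-level pairwise alignment** by maximal-exact-match (MEM) anchoring
  (default minimum anchor 50 bp), collinear chaining by weighted
  longest-increasing-subsequence, and gap closing by global alignment under
  unit edit costs — the anchor-and-chain strategy of whole-genome aligners
  such as nucmer, resolved to single-base precision.
- **Variant extraction and classification.** Maximal runs of substituted
  columns become SNPs (length 1, tallied as transitions A↔G, C↔T vs
  transversions), co-segregating multi-nucleotide substitutions (MNS), or
  **reverse complementary variations (RCVs)** — runs whose alternate allele
  is exactly the reverse complement of the reference allele, a distinct
  class of organellar polymorphism. Gap runs become insertions/deletions,
  left-normalised. Summaries report per-class rates as
  `100 × count / reference length`.
- **Microsatellite (SSR) census** of perfect 1–6 bp motif repeats with
  genic/intergenic classification and frequency/density statistics.
- **Maximal repeat pairs** (forward, reverse, complemented, palindromic),
  non-redundant large-repeat tables (>1 kb) and repeat coverage.
- **Quadripartite structure detection**: the longest inverted-repeat pair
  defines IRA/IRB; the longer single-copy interval is the LSC, the shorter
  the SSC.
- **Plastid-derived segment detection** in mt genomes by seeded local
  homology search with BlastN-style filters (identity ≥ 80 %, length
  ≥ 50 bp, E ≤ 1e−5).
- **A seeded simulator** of cp/mt genome pairs with planted,
  manifest-recorded structure and divergence, so every stage is testable
  against exact truth without downloading anything.

## Worked example

Simulate a chloroplast pair whose divergence matches an
indica-vs-japonica-style comparison (110 SNPs, 13 co-segregating runs, 4
RCVs, 111 InDels on 134 kb), then recover everything:

```r
library(orgvar)

sim <- generate_cp_pair(sim_config("cp-intersubspecific", seed = 1))
blocks   <- align_pair(sim$ancestor, sim$derived)        # one forward block
variants <- extract_variants(blocks, sim$ancestor, sim$derived)
part     <- detect_ir_partition(sim$ancestor)
variants <- annotate_variants(variants, sim$features, part)

summarize_variants(variants, sim$ancestor$length)
#> <VariantSummary> reference length 134000 bp
#>   SNP          110 (0.082%)
#>   MNS           13 (0.010%)
#>   RCV            4 (0.003%)
#>   insertion     40 (0.030%)
#>   deletion      71 (0.053%)
#>   InDel        111 (0.083%)
#>   transitions 53, transversions 57
#>   insertion bp 56, deletion bp 103, cumulative delta -47 bp

score_recovery(variants, sim$manifest)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1

part
#> <RegionPartition> LSC 80100 bp, SSC 12300 bp, IRA 20800 bp, IRB 20800 bp (genome 134000 bp)
```

The SNP and InDel rates (0.082 % and 0.083 %) are the intersubspecific
polymorphism rates this configuration emulates; `precision = recall = 1`
says every planted event was recovered with exact position and alleles.
The partition recovers the planted 2 × 20.8 kb inverted repeats.

For a mitochondrial pair, `generate_mt_pair(sim_config("mt-hybrid"))`
plants six large direct repeats (led by a 96 kb duplication) and ~5.9 %
plastid-derived content; `find_maximal_repeats()` + `large_repeat_table()`
and `find_cp_derived()` + `cp_derived_fraction()` recover them.

A thin command-line wrapper is installed at
`system.file("cli", "orgvar.R", package = "orgvar")` with subcommands
`compare | ssr | repeats | cpderived | ir | simulate` (exit codes: 0 ok,
2 usage, 3 format, 4 no homology / no quadripartite structure).

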