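#' Census perfect microsatellites (SSRs)
#'
#' Scans for perfect tandem repeats of primitive 1-6 bp motifs. Candidate
#' runs at or above the per-unit copy thresholds are selected greedily,
#' longest span first (ties: smaller start, then smaller unit length), and
#' overlapping candidates are discarded, so reported loci never overlap.
#' Only complete copies count: the reported interval length is exactly
#' `unit_len * copies`. Runs containing `N` are excluded.
#'
#' @param g `Genome` or DNA string (scanned as stored, i.e. linearised).
#' @param min_copies Named copy-number thresholds by unit length `"1"`-`"6"`.
#'   The default follows the census convention of at least three repeat
#'   units for di- through hexanucleotides; the mononucleotide threshold is
#'   a tool-specific choice (five copies here) and is not authoritative.
#' @return Data frame of `SSRLocus` records: `start`, `end` (0-based
#'   half-open), `unit_len`, `copies`, `motif` (unit as it occurs),
#'   `canonical_motif` (lexicographically smallest rotation) and `context`
#'   (`NA` until [classify_ssr_context()]).
#' @export
find_ssrs <- function(g, min_copies = c(`1` = 5L, `2` = 3L, `3` = 3L,
                                        `4` = 3L, `5` = 3L, `6` = 3L)) {
  s <- as_seq(g)
  stopifnot(all(as.character(1:6) %in% names(min_copies)))
  if (any(min_copies[as.character(2:6)] < 2L))
    stop_format("copy thresholds for unit lengths 2-6 must be >= 2")
  cand <- cpp_find_ssr_runs(s)
  cand <- cand[cand$copies >= min_copies[as.character(cand$unit_len)], , drop = FALSE]
  sel <- select_ssr_candidates(cand)
  if (nrow(sel) == 0L)
    return(data.frame(start = integer(), end = integer(), unit_len = integer(),
                      copies = integer(), motif = character(),
                      canonical_motif = character(), context = character(),
                      stringsAsFactors = FALSE))
  motif <- substr(rep(s, nrow(sel)), sel$start + 1L, sel$start + sel$unit_len)
  data.frame(start = sel$start, end = sel$start + sel$unit_len * sel$copies,
             unit_len = sel$unit_len, copies = sel$copies,
             motif = motif,
             canonical_motif = vapply(motif, canonical_rotation, ""),
             context = NA_character_, stringsAsFactors = FALSE)
}

## Greedy non-overlap selection shared by scanner and documentation of the
## rule: longest span first, ties by smaller start, then smaller unit.
select_ssr_candidates <- function(cand) {
  if (nrow(cand) == 0L) return(cand)
  span <- cand$unit_len * cand$copies
  cand <- cand[order(-span, cand$start, cand$unit_len), , drop = FALSE]
  sel_start <- integer(0); sel_end <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- s + cand$unit_len[i] * cand$copies[i]
    if (!any(s < sel_end & e > sel_start)) {
      keep[i] <- TRUE
      sel_start <- c(sel_start, s); sel_end <- c(sel_end, e)
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

canonical_rotation <- function(motif) {
  n <- nchar(motif)
  if (n == 1L) return(motif)
  rots <- vapply(seq_len(n) - 1L, function(k)
    paste0(substr(motif, k + 1L, n), substr(motif, 1L, k)), "")
  min(rots)
}

#' Classify SSR loci as genic or intergenic
#'
#' A locus overlapping any gene/tRNA/rRNA feature by at least one base is
#' genic (feature spans include introns; no sub-feature resolution).
#'
#' @param loci SSR data frame from [find_ssrs()].
#' @param features Feature data frame ([read_features()]).
#' @return The loci with the `context` column set.
#' @export
classify_ssr_context <- function(loci, features) {
  if (nrow(loci) == 0L) return(loci)
  if (is.null(features) || nrow(features) == 0L) {
    loci$context <- NA_character_
    return(loci)
  }
  fx <- features[features$kind %in% c("gene", "tRNA", "rRNA"), , drop = FALSE]
  genic <- vapply(seq_len(nrow(loci)), function(i)
    any(fx$start < loci$end[i] & fx$end > loci$start[i]), TRUE)
  loci$context <- ifelse(genic, "genic", "intergenic")
  loci
}

#' SSR frequency and density statistics
#'
#' `frequency = 1000 * count / genome_len` (loci per kb),
#' `density = 1000 * ssr_bp / genome_len` (bases per kb) and
#' `percent = density / 10` (per-cent of the genome in SSRs).
#'
#' @param loci SSR data frame.
#' @param genome_len Genome length in bases.
#' @return List with `count`, `frequency_per_kb`, `density_bp_per_kb`,
#'   `percent`.
#' @export
ssr_statistics <- function(loci, genome_len) {
  stopifnot(genome_len > 0)
  total_bp <- sum(loci$end - loci$start)
  list(count = nrow(loci),
       frequency_per_kb = 1000 * nrow(loci) / genome_len,
       density_bp_per_kb = 1000 * total_bp / genome_len,
       percent = 100 * total_bp / genome_len)
}
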