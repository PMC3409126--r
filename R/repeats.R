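#' Find maximal repeat pairs within a genome
#'
#' Reports all maximal pairs of substrings related by one of four
#' transforms: `F` forward (identical copies), `P` palindromic
#' (reverse-complement), `R` reverse, `C` complement-only. A pair is maximal
#' when simultaneous extension by one base on both ends breaks the relation
#' or hits a boundary. Circular genomes are scanned on the doubled sequence
#' and pairs deduplicated modulo the genome length, so origin-spanning
#' repeats are found.
#'
#' @param g A `Genome` (or DNA string, treated as linear).
#' @param min_len Minimum repeat length in bases (default 50).
#' @param types Subset of `c("F","P","R","C")`.
#' @param allow_tandem Keep forward pairs whose copies overlap
#'   (`start1 + length > start2`); dropped by default.
#' @return Data frame with columns `length`, `start1`, `start2` (0-based,
#'   `start1 <= start2`) and `direction`, ordered by decreasing length, then
#'   `start1`, `start2`.
#' @export
find_maximal_repeats <- function(g, min_len = 50L, types = c("F", "P", "R", "C"),
                                 allow_tandem = FALSE) {
  types <- match.arg(types, c("F", "P", "R", "C"), several.ok = TRUE)
  s <- as_seq(g)
  n <- nchar(s)
  circular <- inherits(g, "Genome") && g$topology == "circular"
  ss <- if (circular) paste0(s, s) else s
  n2 <- nchar(ss)
  min_len <- as.integer(min_len)

  res <- list()
  for (dir in types) {
    if (dir == "F") {
      excl <- if (circular) c(0L, n, -n) else 0L
      m <- cpp_find_mems(ss, ss, min_len, excl)
      s2 <- m$pos_qry
    } else if (dir == "P") {
      m <- cpp_find_mems(ss, revcomp(ss), min_len, integer(0))
      s2 <- n2 - m$pos_qry - m$length
    } else if (dir == "R") {
      m <- cpp_find_mems(ss, reverse_seq(ss), min_len, integer(0))
      s2 <- n2 - m$pos_qry - m$length
    } else {  # C
      m <- cpp_find_mems(ss, complement_seq(ss), min_len, integer(0))
      s2 <- m$pos_qry
    }
    if (nrow(m) == 0L) next
    df <- data.frame(length = m$length, start1 = m$pos_ref, start2 = s2,
                     direction = dir, stringsAsFactors = FALSE)
    if (circular) {
      df <- df[df$length <= n, , drop = FALSE]
      df$start1 <- df$start1 %% n
      df$start2 <- df$start2 %% n
    }
    swap <- df$start2 < df$start1
    tmp <- df$start1[swap]; df$start1[swap] <- df$start2[swap]; df$start2[swap] <- tmp
    df <- unique(df)
    res[[length(res) + 1L]] <- df
  }
  if (!length(res))
    return(data.frame(length = integer(), start1 = integer(),
                      start2 = integer(), direction = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  if (!allow_tandem)
    out <- out[!(out$direction == "F" & out$start1 + out$length > out$start2), ,
               drop = FALSE]
  out <- out[order(-out$length, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Table of large repeats
#'
#' Rows `(length, start1, direction, start2)` for pairs longer than `cutoff`
#' (default 1 kb), longest first. By default pairs wholly contained (both
#' intervals) inside a longer reported pair of the same direction are
#' suppressed, giving a non-redundant census; `nonredundant = FALSE`
#' restores the full list.
#'
#' @param pairs Repeat pairs from [find_maximal_repeats()].
#' @param cutoff Minimum length (exclusive) in bases.
#' @param nonredundant Suppress contained sub-pairs.
#' @return Data frame with columns `length`, `start1`, `direction`, `start2`.
#' @export
large_repeat_table <- function(pairs, cutoff = 1000L, nonredundant = TRUE) {
  big <- pairs[pairs$length > cutoff, , drop = FALSE]
  big <- big[order(-big$length, big$start1, big$start2), , drop = FALSE]
  if (nonredundant && nrow(big) > 1L) {
    keep <- rep(TRUE, nrow(big))
    contained <- function(s, l, S, L) s >= S & s + l <= S + L
    for (i in seq_len(nrow(big))[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (!keep[j] || big$direction[j] != big$direction[i]) next
        if (contained(big$start1[i], big$length[i], big$start1[j], big$length[j]) &&
            contained(big$start2[i], big$length[i], big$start2[j], big$length[j])) {
          keep[i] <- FALSE; break
        }
      }
    }
    big <- big[keep, , drop = FALSE]
  }
  rownames(big) <- NULL
  big[, c("length", "start1", "direction", "start2")]
}

#' Fraction of a genome covered by repeat pairs
#'
#' `100 *` (bases covered by the union of all pair intervals) `/` genome
#' length.
#'
#' @param g `Genome` or DNA string.
#' @param pairs Repeat pairs from [find_maximal_repeats()].
#' @return Percentage.
#' @export
repeat_fraction <- function(g, pairs) {
  n <- nchar(as_seq(g))
  if (nrow(pairs) == 0L) return(0)
  iv <- IRanges::IRanges(
    start = c(pairs$start1, pairs$start2) + 1L,
    width = rep(pairs$length, 2L)
  )
  iv <- IRanges::restrict(iv, start = 1L, end = n)  # wrap tails clipped
  100 * sum(IRanges::width(IRanges::reduce(iv))) / n
}
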