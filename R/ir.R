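#' Detect the quadripartite partition of a chloroplast genome
#'
#' The longest maximal inverted-repeat (reverse-complement) pair of length
#' at least `min_ir` defines IRA and IRB; of the two interstitial
#' single-copy intervals the longer is the LSC and the shorter the SSC.
#'
#' @param cp A circular chloroplast `Genome`.
#' @param min_ir Minimum inverted-repeat length in bases (default 1000).
#' @return A `RegionPartition`: list with elements `lsc`, `ssc`, `ira`,
#'   `irb`, each a two-column matrix of 0-based half-open sub-intervals
#'   (two rows when a region spans the origin), plus `genome_length`.
#' @export
detect_ir_partition <- function(cp, min_ir = 1000L) {
  stopifnot(inherits(cp, "Genome"))
  if (cp$topology != "circular")
    stop_format("quadripartite detection expects a circular genome")
  pairs <- find_maximal_repeats(cp, min_len = min_ir, types = "P")
  ## the two IR copies must not overlap
  pairs <- pairs[pairs$start1 + pairs$length <= pairs$start2, , drop = FALSE]
  if (nrow(pairs) == 0L)
    stop_no_quadripartite(sprintf(
      "no inverted repeat of length >= %d in %s: no quadripartite structure",
      min_ir, cp$id))
  top <- pairs[1L, ]
  n <- cp$length
  as_sub <- function(s, len) {
    if (len == 0L) return(matrix(integer(), ncol = 2L))
    e <- s + len
    if (e <= n) matrix(as.integer(c(s, e)), ncol = 2L)
    else matrix(as.integer(c(s, n, 0L, e - n)), ncol = 2L, byrow = TRUE)
  }
  ira_end <- (top$start1 + top$length) %% n
  irb_end <- (top$start2 + top$length) %% n
  gap1_len <- (top$start2 - ira_end) %% n   # between IRA end and IRB start
  gap2_len <- (top$start1 - irb_end) %% n   # may wrap past the origin
  g1 <- as_sub(ira_end, gap1_len)
  g2 <- as_sub(irb_end, gap2_len)
  if (gap1_len >= gap2_len) { lsc <- g1; ssc <- g2 } else { lsc <- g2; ssc <- g1 }
  part <- structure(
    list(lsc = lsc, ssc = ssc,
         ira = as_sub(top$start1, top$length),
         irb = as_sub(top$start2, top$length),
         genome_length = n),
    class = "RegionPartition"
  )
  if (sum(region_lengths(part)) != n)
    stop_format("internal error: region partition does not tile the genome")
  part
}

region_lengths <- function(partition) {
  vapply(partition[c("lsc", "ssc", "ira", "irb")],
         function(m) sum(as.numeric(m[, 2L] - m[, 1L])), numeric(1))
}

#' @export
print.RegionPartition <- function(x, ...) {
  len <- region_lengths(x)
  cat(sprintf("<RegionPartition> LSC %d bp, SSC %d bp, IRA %d bp, IRB %d bp (genome %d bp)\n",
              len[["lsc"]], len[["ssc"]], len[["ira"]], len[["irb"]],
              x$genome_length))
  invisible(x)
}

#' Region containing a position
#'
#' @param pos 0-based position(s).
#' @param partition A `RegionPartition`.
#' @return Character vector over `"LSC"`, `"SSC"`, `"IRA"`, `"IRB"`.
#' @export
region_of <- function(pos, partition) {
  out <- rep(NA_character_, length(pos))
  for (nm in c("lsc", "ssc", "ira", "irb")) {
    m <- partition[[nm]]
    for (k in seq_len(nrow(m)))
      out[pos >= m[k, 1L] & pos < m[k, 2L]] <- toupper(nm)
  }
  out
}
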