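#' Detect chloroplast-derived segments in a mitochondrial genome
#'
#' Seed-and-extend homology search: exact k-mer seeds (both orientations)
#' are clustered along near-constant diagonals, each cluster's spanning
#' windows are aligned globally under unit edit costs and trimmed to their
#' terminal match columns, and the resulting segments are scored with the
#' BlastN-style scheme match +1 / mismatch -2 / gap -2. E-values use
#' ungapped Karlin-Altschul statistics for that scheme (lambda ~ 1.28,
#' K ~ 0.46) against search space `|mt| x |cp|`; agreement with any
#' particular BLAST build is approximate, so genome-wide plastid-derived
#' percentages are soft numbers. Overlapping hits on the mitochondrial
#' genome are merged keeping the higher-identity span; the identity,
#' length and E-value filters are applied after merging.
#'
#' @param mt,cp `Genome` objects (mitochondrial target, chloroplast query).
#' @param min_identity Minimum fraction of matching alignment columns
#'   (default 0.80).
#' @param min_len Minimum aligned length in columns (default 50).
#' @param max_e Maximum E-value (default 1e-5).
#' @param seed_k Exact seed length (default 12).
#' @return Data frame of segments: `mt_start`, `mt_end`, `cp_start`,
#'   `cp_end` (0-based half-open), `orientation`, `aligned_len`, `identity`,
#'   `score`, `e_value`; the per-segment alignments are attached as the
#'   `alignments` attribute (run-length `ops`/`lens`).
#' @export
find_cp_derived <- function(mt, cp, min_identity = 0.80, min_len = 50L,
                            max_e = 1e-5, seed_k = 12L) {
  ms <- as_seq(mt); cs <- as_seq(cp)
  nm <- nchar(ms); nc <- nchar(cs)
  segs <- list(); alns <- list()
  for (orient in c("F", "R")) {
    co <- if (orient == "F") cs else revcomp(cs)
    seeds <- cpp_find_mems(ms, co, as.integer(seed_k), integer(0))
    if (nrow(seeds) == 0L) next
    cl <- cluster_seeds(seeds, max_gap = 200L, max_drift = 40L)
    pad <- 2L * seed_k   # seeds need k clean bases; the homologous run
    for (w in cl) {      # usually continues past the outermost seeds
      w$mt_start <- max(0L, w$mt_start - pad)
      w$mt_end <- min(nm, w$mt_end + pad)
      w$cp_start <- max(0L, w$cp_start - pad)
      w$cp_end <- min(nc, w$cp_end + pad)
      if (w$mt_end - w$mt_start < min_len) next
      a <- substr(ms, w$mt_start + 1L, w$mt_end)
      b <- substr(co, w$cp_start + 1L, w$cp_end)
      if ((as.numeric(nchar(a)) + 1) * (nchar(b) + 1) > 8e7) next
      al <- cpp_edit_align(a, b)
      tr <- trim_alignment(al)
      if (is.null(tr) || tr$cols < 2L) next
      n_match <- tr$match; n_mis <- tr$mismatch; n_gap <- tr$gapcols
      score <- n_match - 2L * n_mis - 2L * n_gap
      e <- karlin_altschul_evalue(score, nm, nc)
      mt_s <- w$mt_start + tr$lead_a
      mt_e <- w$mt_end - tr$trail_a
      co_s <- w$cp_start + tr$lead_b
      co_e <- w$cp_end - tr$trail_b
      if (orient == "F") { cp_s <- co_s; cp_e <- co_e }
      else { cp_s <- nc - co_e; cp_e <- nc - co_s }
      segs[[length(segs) + 1L]] <- data.frame(
        mt_start = mt_s, mt_end = mt_e, cp_start = cp_s, cp_end = cp_e,
        orientation = orient, aligned_len = tr$cols,
        identity = n_match / tr$cols, score = score, e_value = e,
        stringsAsFactors = FALSE)
      alns[[length(segs)]] <- tr[c("ops", "lens")]
    }
  }
  empty <- data.frame(mt_start = integer(), mt_end = integer(),
                      cp_start = integer(), cp_end = integer(),
                      orientation = character(), aligned_len = integer(),
                      identity = numeric(), score = integer(),
                      e_value = numeric(), stringsAsFactors = FALSE)
  if (!length(segs)) return(structure(empty, alignments = list()))
  out <- do.call(rbind, segs)
  ## merge overlapping mt spans, keeping the better span: ranked by
  ## alignment score (which weighs identity by length, so a short perfect
  ## sliver cannot displace a long slightly diverged segment), then identity
  ord <- order(-out$score, -out$identity, out$mt_start)
  out <- out[ord, , drop = FALSE]; alns <- alns[ord]
  keep <- logical(nrow(out))
  ks <- integer(0); ke <- integer(0)
  for (i in seq_len(nrow(out))) {
    if (!any(out$mt_start[i] < ke & out$mt_end[i] > ks)) {
      keep[i] <- TRUE
      ks <- c(ks, out$mt_start[i]); ke <- c(ke, out$mt_end[i])
    }
  }
  out <- out[keep, , drop = FALSE]; alns <- alns[keep]
  ## filters after merging
  pass <- out$identity >= min_identity & out$aligned_len >= min_len &
    out$e_value <= max_e
  out <- out[pass, , drop = FALSE]; alns <- alns[pass]
  ord <- order(out$mt_start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, alignments = alns[ord])
}

## Greedy single-linkage clustering of seeds sorted by target position.
## A seed joins an open cluster when it starts within max_gap of the
## cluster's end and its diagonal drifts by at most max_drift from the
## cluster's opening diagonal; unrelated seeds on distant diagonals open
## their own clusters instead of interrupting a homologous run. Clusters
## that fall more than max_gap behind the scan are closed.
cluster_seeds <- function(seeds, max_gap = 200L, max_drift = 40L) {
  seeds$diag <- seeds$pos_ref - seeds$pos_qry
  seeds <- seeds[order(seeds$pos_ref, seeds$pos_qry), , drop = FALSE]
  closed <- list()
  open <- list()
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    if (length(open)) {
      stale <- vapply(open, function(cl) cl$mt_end + max_gap < s$pos_ref, TRUE)
      closed <- c(closed, open[stale])
      open <- open[!stale]
    }
    hit <- 0L
    for (k in seq_along(open)) {
      if (abs(s$diag - open[[k]]$diag) <= max_drift &&
          s$pos_qry + s$length > open[[k]]$cp_start) { hit <- k; break }
    }
    if (hit > 0L) {
      cl <- open[[hit]]
      cl$mt_end <- max(cl$mt_end, s$pos_ref + s$length)
      cl$cp_start <- min(cl$cp_start, s$pos_qry)
      cl$cp_end <- max(cl$cp_end, s$pos_qry + s$length)
      open[[hit]] <- cl
    } else {
      open[[length(open) + 1L]] <- list(
        mt_start = s$pos_ref, mt_end = s$pos_ref + s$length,
        cp_start = s$pos_qry, cp_end = s$pos_qry + s$length, diag = s$diag)
    }
  }
  c(closed, open)
}

## Trim a run-length transcript to its maximal-scoring window under the
## +1/-2/-2 scheme (local-alignment semantics: flanking noise from the
## padded search window scores negatively and is excluded). Runs are
## homogeneous, so the optimum starts and ends at run boundaries and a
## Kadane scan over run scores suffices. Returns NULL when no match column
## survives.
trim_alignment <- function(al) {
  ops <- al$ops; lens <- al$lens          # 0 M, 1 X, 2 gap-in-b, 3 gap-in-a
  if (!any(ops == 0L)) return(NULL)
  score <- ifelse(ops == 0L, lens, -2L * lens)
  best <- -Inf; best_i <- 1L; best_j <- 0L
  cur <- 0; cur_i <- 1L
  for (k in seq_along(score)) {
    if (cur <= 0) { cur <- 0; cur_i <- k }
    cur <- cur + score[k]
    if (cur > best) { best <- cur; best_i <- cur_i; best_j <- k }
  }
  consumed <- function(idx) {
    c(a = sum(lens[idx][ops[idx] != 3L]), b = sum(lens[idx][ops[idx] != 2L]))
  }
  lead <- seq_len(best_i - 1L)
  trail <- if (best_j < length(ops)) (best_j + 1L):length(ops) else integer(0)
  lead_c <- consumed(lead); trail_c <- consumed(trail)
  keep <- best_i:best_j
  ops <- ops[keep]; lens <- lens[keep]
  list(ops = ops, lens = lens,
       cols = sum(lens),
       match = sum(lens[ops == 0L]),
       mismatch = sum(lens[ops == 1L]),
       gapcols = sum(lens[ops %in% c(2L, 3L)]),
       lead_a = lead_c[["a"]], lead_b = lead_c[["b"]],
       trail_a = trail_c[["a"]], trail_b = trail_c[["b"]])
}

## Ungapped Karlin-Altschul expectation for the +1/-2 scoring scheme.
karlin_altschul_evalue <- function(score, m, n, lambda = 1.28, K = 0.46) {
  K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

#' Fraction of a mitochondrial genome covered by cp-derived segments
#'
#' `100 *` union of `mt` interval lengths `/ mt_len`.
#'
#' @param segments Segment data frame from [find_cp_derived()].
#' @param mt_len Mitochondrial genome length.
#' @return Percentage.
#' @export
cp_derived_fraction <- function(segments, mt_len) {
  stopifnot(mt_len > 0)
  if (nrow(segments) == 0L) return(0)
  iv <- IRanges::reduce(IRanges::IRanges(start = segments$mt_start + 1L,
                                         end = segments$mt_end))
  100 * sum(IRanges::width(iv)) / mt_len
}
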