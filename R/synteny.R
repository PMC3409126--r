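#' Find maximal exact matches between two genomes
#'
#' All maximal exact matches (MEMs) of length at least `min_match`, in both
#' orientations. A MEM cannot be extended by one base on either side without
#' breaking the match or hitting a sequence boundary; `N` never matches.
#'
#' @param ref,qry `Genome` objects or DNA strings.
#' @param min_match Minimum match length in bases (>= 8 for genome-scale
#'   use; smaller values are accepted for toy inputs).
#' @return A data frame of anchors with columns `pos_ref`, `pos_qry` (0-based
#'   starts on the respective genome; for reverse-complement anchors
#'   `pos_qry` is the leftmost base of the matching query interval),
#'   `length` and `orientation` (`"F"` forward, `"R"` reverse-complement),
#'   sorted by `pos_ref` then `pos_qry`.
#' @export
find_mems <- function(ref, qry, min_match = 50L) {
  r <- as_seq(ref); q <- as_seq(qry)
  if (!nzchar(r) || !nzchar(q)) stop_format("cannot anchor an empty genome")
  min_match <- as.integer(min_match)
  fwd <- cpp_find_mems(r, q, min_match, integer(0))
  fwd$orientation <- rep("F", nrow(fwd))
  qrc <- revcomp(q)
  rev <- cpp_find_mems(r, qrc, min_match, integer(0))
  nq <- nchar(q)
  rev$pos_qry <- nq - rev$pos_qry - rev$length
  rev$orientation <- rep("R", nrow(rev))
  out <- rbind(fwd, rev)
  out <- out[order(out$pos_ref, out$pos_qry, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Anchor coordinates in "oriented query space": for reverse anchors the
## query start re-expressed on the reverse complement of the full query, so
## that a collinear reverse chain is increasing in both coordinates.
oriented_qpos <- function(anchors, nq) {
  ifelse(anchors$orientation == "R",
         nq - anchors$pos_qry - anchors$length,
         anchors$pos_qry)
}

## Weighted longest increasing subsequence over anchors of one orientation.
## Successor anchors must advance strictly in both start and end coordinates;
## bounded overlap is tolerated (anchors flanking an InDel overshoot into the
## shared flank base) and trimmed away during gap closing. Ties in total
## weight prefer the chain with the smallest ref start.
best_chain_dp <- function(pr, pq, len) {
  n <- length(pr)
  if (n == 0L) return(integer(0))
  ord <- order(pr, pq)
  pr <- pr[ord]; pq <- pq[ord]; len <- len[ord]
  score <- as.numeric(len)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (pr[j] < pr[i] && pq[j] < pq[i] &&
          pr[j] + len[j] < pr[i] + len[i] && pq[j] + len[j] < pq[i] + len[i]) {
        cand <- score[j] + len[i]
        if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
      }
    }
  }
  ends <- which(score == max(score))
  end <- ends[1L]   # smallest index = smallest ref start among ties
  chain <- integer(0)
  while (end != 0L) { chain <- c(end, chain); end <- prev[end] }
  ord[chain]
}

#' Chain anchors into collinear subsets
#'
#' Per orientation, a maximum-total-anchor-length collinear subset (strictly
#' increasing in both genome coordinates) is computed by weighted
#' longest-increasing-subsequence. The heaviest chain over both orientations
#' is accepted first; anchors overlapping an accepted chain's footprint on
#' either genome are discarded and the remainder is chained again, greedily,
#' until no chain of reference span at least `min_chain_span` remains.
#'
#' @param anchors Anchor data frame from [find_mems()].
#' @param nq Query genome length (needed to orient reverse anchors).
#' @param min_chain_span Minimum reference span of a secondary chain.
#' @return A list of chains ordered by decreasing weight; each chain is an
#'   anchor data frame with attributes `orientation` and `weight`.
#' @export
chain_anchors <- function(anchors, nq, min_chain_span = 200L) {
  chains <- list()
  if (is.null(anchors) || nrow(anchors) == 0L) return(chains)
  remaining <- anchors
  remaining$.qor <- oriented_qpos(remaining, nq)
  repeat {
    if (nrow(remaining) == 0L) break
    best <- NULL
    for (orient in unique(remaining$orientation)) {
      sub <- remaining[remaining$orientation == orient, , drop = FALSE]
      idx <- best_chain_dp(sub$pos_ref, sub$.qor, sub$length)
      if (!length(idx)) next
      ch <- sub[idx, , drop = FALSE]
      w <- sum(ch$length)
      if (is.null(best) || w > attr(best, "weight") ||
          (w == attr(best, "weight") && ch$pos_ref[1L] < best$pos_ref[1L])) {
        attr(ch, "weight") <- w
        attr(ch, "orientation") <- orient
        best <- ch
      }
    }
    if (is.null(best)) break
    span <- max(best$pos_ref + best$length) - min(best$pos_ref)
    if (length(chains) > 0L && span < min_chain_span) break
    rownames(best) <- NULL
    chains[[length(chains) + 1L]] <- best
    ## drop anchors substantially overlapping the accepted chain's footprint
    ref_iv <- cbind(best$pos_ref, best$pos_ref + best$length)
    qry_iv <- cbind(best$pos_qry, best$pos_qry + best$length)
    ov <- function(s, e, iv) {
      tot <- rep(0L, length(s))
      for (k in seq_len(nrow(iv)))
        tot <- tot + pmax(0L, pmin(e, iv[k, 2L]) - pmax(s, iv[k, 1L]))
      tot
    }
    ov_r <- ov(remaining$pos_ref, remaining$pos_ref + remaining$length, ref_iv)
    ov_q <- ov(remaining$pos_qry, remaining$pos_qry + remaining$length, qry_iv)
    keep <- (pmax(ov_r, ov_q) / remaining$length) <= 0.2
    ## anchors of the accepted chain are always consumed
    in_chain <- interaction(remaining$pos_ref, remaining$pos_qry, remaining$orientation) %in%
      interaction(best$pos_ref, best$pos_qry, attr(best, "orientation"))
    remaining <- remaining[keep & !in_chain, , drop = FALSE]
  }
  lapply(chains, function(ch) { ch$.qor <- NULL; ch })
}

OP_CODES <- c("M", "X", "D", "I")  # match, substitution, qry-gap, ref-gap

new_block <- function(ref_start, ref_end, q_start, q_end, orientation, ops, lens, nq) {
  ## merge adjacent equal ops
  if (length(ops) > 1L) {
    grp <- cumsum(c(TRUE, ops[-1L] != ops[-length(ops)]))
    lens <- as.integer(tapply(lens, grp, sum))
    ops <- ops[!duplicated(grp)]
  }
  if (orientation == "F") {
    qs <- q_start; qe <- q_end
  } else {           # oriented coords live on revcomp(qry); map back
    qs <- nq - q_end; qe <- nq - q_start
  }
  structure(
    list(ref_start = ref_start, ref_end = ref_end,
         qry_start = qs, qry_end = qe,
         orientation = orientation, ops = ops, lens = as.integer(lens)),
    class = "SyntenyBlock"
  )
}

#' @export
print.SyntenyBlock <- function(x, ...) {
  cat(sprintf("<SyntenyBlock> ref [%d, %d) ~ qry [%d, %d) %s, %d runs\n",
              x$ref_start, x$ref_end, x$qry_start, x$qry_end,
              if (x$orientation == "F") "forward" else "reverse-complement",
              length(x$ops)))
  invisible(x)
}

#' Close inter-anchor gaps of a chain into synteny blocks
#'
#' Anchors are copied into the transcript as match runs; the sequence gaps
#' between consecutive anchors are aligned globally under unit edit costs
#' (match 0, mismatch 1, gap 1 per base). A gap larger than `max_gap`, or one
#' claimed by another chain (`claimed` intervals), splits the block with a
#' warning instead of being aligned.
#'
#' @param chain One chain from [chain_anchors()].
#' @param ref,qry `Genome` objects or DNA strings.
#' @param max_gap Largest gap (bases, on either genome) closed by alignment.
#' @param extend_to_ends Align the terminal gaps before the first and after
#'   the last anchor (used for the primary chain of a global comparison).
#' @param claimed Optional matrix of reference intervals (0-based half-open)
#'   owned by other chains; gaps mostly covered by them are not aligned.
#' @return A list of `SyntenyBlock` objects (one, unless the block was split).
#' @export
close_gaps <- function(chain, ref, qry, max_gap = 50000L,
                       extend_to_ends = FALSE, claimed = NULL) {
  r <- as_seq(ref); q <- as_seq(qry)
  nq <- nchar(q)
  orient <- attr(chain, "orientation")
  if (is.null(orient)) orient <- chain$orientation[1L]
  qo <- if (orient == "F") q else revcomp(q)
  ch <- chain
  ch$qor <- oriented_qpos(ch, nq)
  ch <- ch[order(ch$pos_ref), , drop = FALSE]

  claimed_frac <- function(s, e) {
    if (is.null(claimed) || nrow(claimed) == 0L || e <= s) return(0)
    sum(pmax(0L, pmin(e, claimed[, 2L]) - pmax(s, claimed[, 1L]))) / (e - s)
  }

  blocks <- list()
  ops <- character(0); lens <- integer(0)
  blk_r0 <- NA_integer_; blk_q0 <- NA_integer_
  cur_r <- NA_integer_; cur_q <- NA_integer_

  flush <- function() {
    if (length(ops))
      blocks[[length(blocks) + 1L]] <<- new_block(blk_r0, cur_r, blk_q0, cur_q,
                                                  orient, ops, lens, nq)
    ops <<- character(0); lens <<- integer(0)
  }
  append_runs <- function(o, l) { ops <<- c(ops, o); lens <<- c(lens, l) }

  align_gap <- function(rs, re, qs, qe) {
    ## returns TRUE when the gap was aligned, FALSE when the block must split
    if (re - rs > max_gap || qe - qs > max_gap ||
        (as.numeric(re - rs + 1) * (qe - qs + 1)) > 4e7) {
      warning(sprintf("gap of %d x %d bases exceeds max_gap; block split",
                      re - rs, qe - qs), call. = FALSE)
      return(FALSE)
    }
    if (claimed_frac(rs, re) > 0.5) return(FALSE)
    if (re == rs && qe == qs) return(TRUE)
    al <- cpp_edit_align(substr(r, rs + 1L, re), substr(qo, qs + 1L, qe))
    append_runs(OP_CODES[al$ops + 1L], al$lens)
    TRUE
  }

  n <- nrow(ch)
  for (i in seq_len(n)) {
    rs <- ch$pos_ref[i]; qs <- ch$qor[i]; L <- ch$length[i]
    if (i > 1L) {
      ## trim overlap with the consumed prefix (same amount on both
      ## coordinates, so the anchor stays on its diagonal)
      d <- max(0L, cur_r - rs, cur_q - qs)
      if (d >= L) next
      rs <- rs + d; qs <- qs + d; L <- L - d
    }
    if (i == 1L) {
      blk_r0 <- rs; blk_q0 <- qs
      if (extend_to_ends && (rs > 0L || qs > 0L)) {
        blk_r0 <- 0L; blk_q0 <- 0L
        if (!align_gap(0L, rs, 0L, qs)) { blk_r0 <- rs; blk_q0 <- qs }
      }
    } else {
      ok <- align_gap(cur_r, rs, cur_q, qs)
      if (!ok) { flush(); blk_r0 <- rs; blk_q0 <- qs }
    }
    append_runs("M", L)
    cur_r <- rs + L; cur_q <- qs + L
  }
  if (extend_to_ends) {
    nr <- nchar(r)
    if ((cur_r < nr || cur_q < nchar(qo)) &&
        align_gap(cur_r, nr, cur_q, nchar(qo))) {
      cur_r <- nr; cur_q <- nchar(qo)
    }
  }
  flush()
  blocks
}

#' Align a pair of genomes into synteny blocks
#'
#' Anchors with [find_mems()], chains with [chain_anchors()], then resolves
#' each accepted chain to base level with [close_gaps()]. For circular
#' genomes the query is first rotated so that the heaviest chain starts at
#' reference offset 0 (positions reported for the query then refer to the
#' rotated sequence; the applied offset is stored in the `rotation`
#' attribute). Anchor coordinates are attached as the `anchors` attribute
#' for dot-plot export.
#'
#' @param ref,qry `Genome` objects.
#' @param min_match Minimum exact-match anchor length (default 50 bases).
#' @param min_chain_span Minimum reference span of a secondary chain.
#' @param max_gap Largest inter-anchor gap closed by alignment.
#' @return A list of `SyntenyBlock`s sorted by reference interval, of class
#'   `SyntenyBlocks`.
#' @export
align_pair <- function(ref, qry, min_match = 50L, min_chain_span = 200L,
                       max_gap = 50000L) {
  stopifnot(inherits(ref, "Genome"), inherits(qry, "Genome"))
  rotation <- 0L
  anchors <- find_mems(ref, qry, min_match)
  if (nrow(anchors) == 0L)
    stop_no_homology(sprintf("no exact match of length >= %d between %s and %s",
                             min_match, ref$id, qry$id))
  chains <- chain_anchors(anchors, qry$length, min_chain_span)
  primary <- chains[[1L]]
  if (ref$topology == "circular" && qry$topology == "circular" &&
      attr(primary, "orientation") == "F") {
    delta <- (primary$pos_qry[1L] - primary$pos_ref[1L]) %% qry$length
    if (delta != 0L) {
      rotation <- as.integer(delta)
      qry <- rotate_genome(qry, delta)
      anchors <- find_mems(ref, qry, min_match)
      chains <- chain_anchors(anchors, qry$length, min_chain_span)
    }
  }

  spans <- lapply(chains, function(ch)
    cbind(min(ch$pos_ref), max(ch$pos_ref + ch$length)))
  blocks <- list()
  global <- attr(chains[[1L]], "orientation") == "F"
  for (i in seq_along(chains)) {
    claimed <- if (length(chains) > 1L)
      do.call(rbind, spans[-i]) else NULL
    blocks <- c(blocks, close_gaps(chains[[i]], ref, qry, max_gap = max_gap,
                                   extend_to_ends = (i == 1L && global),
                                   claimed = claimed))
  }
  ord <- order(vapply(blocks, function(b) b$ref_start, 0L))
  blocks <- blocks[ord]
  structure(blocks, class = "SyntenyBlocks",
            ref_id = ref$id, qry_id = qry$id,
            ref_len = ref$length, qry_len = qry$length,
            rotation = rotation, anchors = anchors)
}

#' Reconstruct the two interval sequences spelled by a block transcript
#'
#' Conservation check used by tests: the transcript must consume exactly the
#' reference and query intervals of the block.
#'
#' @param block A `SyntenyBlock`.
#' @param ref,qry `Genome` objects or DNA strings.
#' @return List with elements `ref` and `qry` (query in alignment
#'   orientation).
#' @export
block_sequences <- function(block, ref, qry) {
  r <- as_seq(ref); q <- as_seq(qry)
  rlen <- sum(block$lens[block$ops != "I"])
  qlen <- sum(block$lens[block$ops != "D"])
  ref_seg <- substr(r, block$ref_start + 1L, block$ref_start + rlen)
  qseg <- substr(q, block$qry_start + 1L, block$qry_end)
  if (block$orientation == "R") qseg <- revcomp(qseg)
  list(ref = ref_seg, qry = qseg, ref_len = rlen, qry_len = qlen)
}
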