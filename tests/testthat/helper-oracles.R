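# Independent brute-force oracles used by the property suites. These are
# deliberately naive (diagonal run-length scans, exhaustive subset search,
# per-start sliding windows) and share no code with the package's
# seed-and-extend / DP implementations.

DNA <- c("A", "C", "G", "T")
COMP_TAB <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

rand_seq <- function(n, with_n = FALSE) {
  pool <- if (with_n) c(DNA, "N") else DNA
  prob <- if (with_n) c(rep(0.24, 4), 0.04) else NULL
  paste(sample(pool, n, replace = TRUE, prob = prob), collapse = "")
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
rc_chars <- function(cv) unname(COMP_TAB[rev(cv)])

# all maximal match runs >= mm between two character vectors, forward sense
oracle_runs <- function(rc, qc, mm) {
  nr <- length(rc); nq <- length(qc)
  out <- list()
  for (d in (-(nq - 1L)):(nr - 1L)) {
    i0 <- max(0L, d); j0 <- i0 - d
    len <- min(nr - i0, nq - j0)
    if (len < mm) next
    m <- rc[(i0 + 1L):(i0 + len)] == qc[(j0 + 1L):(j0 + len)] &
      rc[(i0 + 1L):(i0 + len)] != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= mm))
      out[[length(out) + 1L]] <- c(i0 + starts[k] - 1L, j0 + starts[k] - 1L,
                                   r$lengths[k])
  }
  if (!length(out))
    return(data.frame(pos_ref = integer(), pos_qry = integer(),
                      length = integer()))
  m <- do.call(rbind, out)
  data.frame(pos_ref = m[, 1L], pos_qry = m[, 2L], length = m[, 3L])
}

oracle_mems <- function(ref, qry, mm) {
  rc <- chars(ref); qc <- chars(qry)
  fwd <- oracle_runs(rc, qc, mm)
  fwd$orientation <- rep("F", nrow(fwd))
  rev <- oracle_runs(rc, rc_chars(qc), mm)
  rev$pos_qry <- length(qc) - rev$pos_qry - rev$length
  rev$orientation <- rep("R", nrow(rev))
  out <- rbind(fwd, rev)
  out <- out[order(out$pos_ref, out$pos_qry, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# maximal repeat pairs within a linear string, REPuter's four relations
oracle_repeats <- function(s, min_len, types = c("F", "P", "R", "C"),
                           allow_tandem = FALSE) {
  cv <- chars(s); n <- length(cv)
  res <- list()
  for (dir in types) {
    tc <- switch(dir, F = cv, P = rc_chars(cv), R = rev(cv),
                 C = unname(COMP_TAB[cv]))
    runs <- oracle_runs(cv, tc, min_len)
    if (dir %in% c("P", "R")) runs$pos_qry <- n - runs$pos_qry - runs$length
    if (dir == "F") runs <- runs[runs$pos_ref != runs$pos_qry, , drop = FALSE]
    if (nrow(runs) == 0L) next
    df <- data.frame(length = runs$length,
                     start1 = pmin(runs$pos_ref, runs$pos_qry),
                     start2 = pmax(runs$pos_ref, runs$pos_qry),
                     direction = dir, stringsAsFactors = FALSE)
    res[[length(res) + 1L]] <- unique(df)
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

# exhaustive SSR candidates by per-start window counting, then the same
# published selection rule (longest span, then start, then unit)
oracle_ssrs <- function(s, min_copies) {
  cv <- chars(s); n <- length(cv)
  cand <- list()
  for (u in 1:6) {
    if (n < 2L * u) next
    for (i in 0:(n - 2L * u)) {
      motif <- cv[(i + 1L):(i + u)]
      if (any(motif == "N")) next
      # primitive motif?
      prim <- TRUE
      for (d in seq_len(u - 1L))
        if (u %% d == 0L && all(motif == motif[((seq_len(u) - 1L) %% d) + 1L]))
          prim <- FALSE
      if (!prim) next
      # left-maximal: no full unit immediately before
      if (i >= u && all(cv[(i - u + 1L):i] == motif)) next
      cp <- 1L
      while (i + (cp + 1L) * u <= n &&
             all(cv[(i + cp * u + 1L):(i + (cp + 1L) * u)] == motif))
        cp <- cp + 1L
      if (cp >= min_copies[[as.character(u)]])
        cand[[length(cand) + 1L]] <- c(i, u, cp)
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(), unit_len = integer(),
                      copies = integer()))
  m <- do.call(rbind, cand)
  cand <- data.frame(start = m[, 1L], unit_len = m[, 2L], copies = m[, 3L])
  span <- cand$unit_len * cand$copies
  cand <- cand[order(-span, cand$start, cand$unit_len), , drop = FALSE]
  sel_s <- integer(0); sel_e <- integer(0); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s0 <- cand$start[i]; e0 <- s0 + cand$unit_len[i] * cand$copies[i]
    if (!any(s0 < sel_e & e0 > sel_s)) {
      keep[i] <- TRUE; sel_s <- c(sel_s, s0); sel_e <- c(sel_e, e0)
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive maximum-weight collinear subset of forward anchors
oracle_chain_weight <- function(anchors) {
  n <- nrow(anchors)
  best <- 0
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (!length(idx)) next
    a <- anchors[idx, , drop = FALSE]
    a <- a[order(a$pos_ref), , drop = FALSE]
    ok <- TRUE
    if (nrow(a) > 1L)
      for (i in seq_len(nrow(a) - 1L))
        if (a$pos_ref[i] >= a$pos_ref[i + 1L] ||
            a$pos_qry[i] >= a$pos_qry[i + 1L] ||
            a$pos_ref[i] + a$length[i] >= a$pos_ref[i + 1L] + a$length[i + 1L] ||
            a$pos_qry[i] + a$length[i] >= a$pos_qry[i + 1L] + a$length[i + 1L]) {
          ok <- FALSE; break
        }
    if (ok) best <- max(best, sum(a$length))
  }
  best
}

# small default thresholds used across tests
TEST_MIN_COPIES <- c(`1` = 5L, `2` = 3L, `3` = 3L, `4` = 3L, `5` = 3L, `6` = 3L)

# scaled-down simulator configs (30 kb chloroplast) for fast unit tests
small_cp_config <- function(seed, ...) {
  sim_config("cp-intersubspecific", seed = seed, cp_len = 30000L,
             ir_len = 4000L, ssc_len = 3000L, n_snp = 20L, n_mns = 4L,
             n_rcv = 3L, n_ins = 8L, n_del = 10L, n_features = 25L, ...)
}
small_mt_config <- function(seed, ...) {
  sim_config("mt-hybrid", seed = seed, mt_len = 70000L, cp_len = 25000L,
             ir_len = 3000L, ssc_len = 2500L,
             repeat_lens = c(9000L, 2500L), cp_derived_fraction = 0.05,
             n_snp = 8L, n_ts = 4L, n_ins = 6L, n_del = 4L,
             ins_lens = NULL, del_lens = NULL, n_features = 20L, ...)
}

# verify a block transcript spells both sequences (conservation check)
check_block_transcript <- function(block, ref, qry) {
  seqs <- orgvar::block_sequences(block, ref, qry)
  rs <- chars(seqs$ref); qs <- chars(seqs$qry)
  ri <- 0L; qi <- 0L
  for (k in seq_along(block$ops)) {
    op <- block$ops[k]; l <- block$lens[k]
    if (op == "M") {
      if (!all(rs[(ri + 1L):(ri + l)] == qs[(qi + 1L):(qi + l)])) return(FALSE)
      ri <- ri + l; qi <- qi + l
    } else if (op == "X") {
      if (any(rs[(ri + 1L):(ri + l)] == qs[(qi + 1L):(qi + l)])) return(FALSE)
      ri <- ri + l; qi <- qi + l
    } else if (op == "D") ri <- ri + l
    else qi <- qi + l
  }
  ri == length(rs) && qi == length(qs)
}

# The published RCV calls (accepted) and co-segregating substitution runs
# (rejected as RCV) used to pin down the classifier.
RCV_CALLS <- list(c("TC", "GA"), c("GAAAAA", "TTTTTC"),
                  c("CTTGGTCT", "AGACCAAG"), c("AAGC", "GCTT"))
MNS_CALLS <- list(c("TA", "CC"), c("GG", "AA"), c("CG", "GC"), c("GC", "CG"),
                  c("GC", "CG"), c("ACT", "GAA"), c("TT", "AG"), c("CT", "AA"),
                  c("CG", "GC"), c("CG", "GC"), c("GC", "CG"), c("AG", "GA"),
                  c("CG", "AC"))

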