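BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

random_dna <- function(n) sample(BASES, n, replace = TRUE)

#' Simulation configuration
#'
#' Parameters of the synthetic organellar genome-pair generator. The
#' profiles encode the three study conditions the package is validated
#' against: a chloroplast pair diverging like two closely related cultivars
#' of the same subspecies (`"cp-hybrid"`: 11 insertions, 5 deletions with
#' the 1/1/1/1/1/1/1/1/1/4/4 and 1/1/1/1/2 length composition, no
#' substitutions), a chloroplast pair diverging across subspecies
#' (`"cp-intersubspecific"`: 110 SNPs, 13 co-segregating substitution runs,
#' 4 RCVs of lengths 2/4/6/8, 40 insertions and 71 deletions on a ~134 kb
#' genome), and a mitochondrial pair (`"mt-hybrid"`: 26 SNPs split 13
#' transitions / 13 transversions, 39 insertions and 9 deletions summing to
#' a +74 bp length difference, six planted large direct repeats led by a
#' 96 kb duplication, and ~5.9% plastid-derived content).
#'
#' @param profile One of `"cp-intersubspecific"`, `"cp-hybrid"`,
#'   `"mt-hybrid"`.
#' @param seed Integer seed; the generator is deterministic given the
#'   configuration.
#' @param ... Overrides for any configuration field (see Details in the
#'   package vignette): `cp_len`, `ir_len`, `ssc_len`, `mt_len`, `n_snp`,
#'   `n_ts`, `n_mns`, `n_rcv`, `n_ins`, `n_del`, `ins_lens`, `del_lens`,
#'   `indel_mean_len`, `mns_lens`, `rcv_lens`, `n_features`,
#'   `feature_len_range`, `repeat_lens`, `cp_derived_fraction`,
#'   `cp_fragment_identity`, `inversion_count`, `inversion_len`.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(profile = c("cp-intersubspecific", "cp-hybrid", "mt-hybrid"),
                       seed = 1L, ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile, seed = as.integer(seed),
    cp_len = 134000L, ir_len = 20800L, ssc_len = 12300L,
    mt_len = 455000L,
    n_snp = 0L, n_ts = NULL, n_mns = 0L, n_rcv = 0L,
    n_ins = 0L, n_del = 0L,
    ins_lens = NULL, del_lens = NULL, indel_mean_len = 1.4,
    mns_lens = c(2L, 3L), rcv_lens = c(2L, 4L, 6L, 8L),
    n_features = 130L, feature_len_range = c(100L, 1200L),
    repeat_lens = integer(0), cp_derived_fraction = 0,
    cp_fragment_identity = 0.97, inversion_count = 0L, inversion_len = 8000L
  )
  if (profile == "cp-intersubspecific") {
    cfg$n_snp <- 110L; cfg$n_mns <- 13L; cfg$n_rcv <- 4L
    cfg$n_ins <- 40L; cfg$n_del <- 71L
    cfg$mns_lens <- c(rep(2L, 12L), 3L)
  } else if (profile == "cp-hybrid") {
    cfg$n_ins <- 11L; cfg$n_del <- 5L
    cfg$ins_lens <- c(rep(1L, 9L), 4L, 4L)
    cfg$del_lens <- c(rep(1L, 4L), 2L)
  } else {   # mt-hybrid
    cfg$n_snp <- 26L; cfg$n_ts <- 13L
    cfg$n_ins <- 39L; cfg$n_del <- 9L
    cfg$ins_lens <- c(rep(1L, 37L), 2L, 44L)
    cfg$del_lens <- rep(1L, 9L)
    cfg$n_features <- 100L
    cfg$repeat_lens <- c(96000L, 6120L, 6030L, 4080L, 2990L, 2990L)
    cfg$cp_derived_fraction <- 0.059
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_format(paste("unknown sim_config field(s):", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  for (f in c("seed", "cp_len", "ir_len", "ssc_len", "mt_len", "n_snp",
              "n_mns", "n_rcv", "n_ins", "n_del", "n_features",
              "inversion_count", "inversion_len"))
    cfg[[f]] <- as.integer(cfg[[f]])
  if (!is.null(cfg$n_ts)) cfg$n_ts <- as.integer(cfg$n_ts)
  for (f in c("ins_lens", "del_lens", "mns_lens", "rcv_lens", "repeat_lens",
              "feature_len_range"))
    if (!is.null(cfg[[f]])) cfg[[f]] <- as.integer(cfg[[f]])
  validate_sim_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_snp, cfg$n_mns, cfg$n_rcv, cfg$n_ins, cfg$n_del,
              cfg$inversion_count)
  if (any(counts < 0)) stop_format("event counts must be >= 0")
  if (2L * cfg$ir_len + cfg$ssc_len >= cfg$cp_len)
    stop_format("cp structure unsatisfiable: 2*ir_len + ssc_len must be < cp_len")
  if (length(cfg$repeat_lens) &&
      2L * sum(cfg$repeat_lens) + round(cfg$cp_derived_fraction * cfg$mt_len) >
      cfg$mt_len - 500L * (2L * length(cfg$repeat_lens) + 3L))
    stop_format("repeat lengths exceed the mitochondrial genome size")
  invisible(cfg)
}

## ---- event machinery ----------------------------------------------------

max_homopolymer <- function(chars) {
  if (!length(chars)) return(0L)
  max(rle(chars)$lengths)
}

## Events are separated by at least 2 * EVENT_PAD bases of untouched
## sequence, so every event sits between exact stretches at least as long
## as the default 50 bp anchor: the flanking anchors reach exactly to the
## event boundaries (guaranteed by the per-type flank conditions below) and
## the inter-anchor gap the aligner closes contains nothing but the event's
## own alleles. A substitution run is additionally accepted only when the
## gap alignment of its alleles resolves to a single substitution run --
## otherwise a gapped decomposition is equally or more parsimonious (e.g.
## an alternate allele sharing shifted substrings with the reference run)
## and the planted representation would be ambiguous.
EVENT_PAD <- 30L

substitution_run_unambiguous <- function(ra, aa) {
  al <- cpp_edit_align(ra, aa)
  identical(al$ops, 1L) && identical(al$lens, nchar(ra))
}

## Draw non-overlapping events on the ancestor (0-based positions), each at
## least 10 bp from its neighbours and away from homopolymer runs >= 4, with
## flanks pinned so that left-normalised calls are coordinate-exact.
sample_variant_events <- function(sv, cfg, forbidden = NULL) {
  L <- length(sv)
  specs <- list()
  add <- function(type, lens) for (l in lens)
    specs[[length(specs) + 1L]] <<- list(type = type, len = as.integer(l))
  geo_lens <- function(n) {
    if (n == 0L) return(integer(0))
    pmin(1L + stats::rgeom(n, min(1, 1 / cfg$indel_mean_len)), 60L)
  }
  snp_cls <- character(0)
  if (cfg$n_snp > 0L) {
    n_ts <- if (is.null(cfg$n_ts)) NA_integer_ else cfg$n_ts
    snp_cls <- if (is.na(n_ts)) sample(c("ts", "tv"), cfg$n_snp, replace = TRUE)
    else sample(c(rep("ts", n_ts), rep("tv", cfg$n_snp - n_ts)))
    add("SNP", rep(1L, cfg$n_snp))
  }
  add("MNS", rep_len(cfg$mns_lens, cfg$n_mns))
  add("RCV", rep_len(cfg$rcv_lens, cfg$n_rcv))
  add("insertion", if (is.null(cfg$ins_lens)) geo_lens(cfg$n_ins)
      else rep_len(cfg$ins_lens, cfg$n_ins))
  add("deletion", if (is.null(cfg$del_lens)) geo_lens(cfg$n_del)
      else rep_len(cfg$del_lens, cfg$n_del))
  if (!length(specs))
    return(data.frame(type = character(), ref_pos = integer(),
                      ref_allele = character(), alt_allele = character(),
                      length = integer(), stringsAsFactors = FALSE))

  occ_s <- if (is.null(forbidden)) integer(0) else forbidden[, 1L]
  occ_e <- if (is.null(forbidden)) integer(0) else forbidden[, 2L]
  rows <- vector("list", length(specs))
  snp_i <- 0L
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  for (k in seq_along(specs)) {
    type <- specs[[k]]$type; l <- specs[[k]]$len
    placed <- FALSE
    for (try in seq_len(20000L)) {
      p <- sample.int(L - l - 100L, 1L) + 50L      # 0-based
      if (any(p - EVENT_PAD < occ_e & p + l + EVENT_PAD > occ_s)) next
      win <- sv[max(1L, p - 3L):min(L, p + l + 4L)]
      if (max_homopolymer(win) >= 4L) next
      seg <- sv[(p + 1L):(p + l)]
      if (type == "SNP") {
        snp_i <- snp_i + 1L
        alt <- if (snp_cls[snp_i] == "ts") transition_of[[seg]]
        else sample(setdiff(BASES, c(seg, transition_of[[seg]])), 1L)
        ra <- seg; aa <- alt
      } else if (type == "MNS") {
        aa_ch <- vapply(seg, function(b) sample(setdiff(BASES, b), 1L), "")
        if (paste(aa_ch, collapse = "") ==
            paste(COMP[rev(seg)], collapse = "")) next  # would be an RCV
        ra <- paste(seg, collapse = ""); aa <- paste(aa_ch, collapse = "")
        if (!substitution_run_unambiguous(ra, aa)) next
      } else if (type == "RCV") {
        aa_ch <- unname(COMP[rev(seg)])
        if (any(aa_ch == seg)) next   # must differ at every position
        ra <- paste(seg, collapse = ""); aa <- paste(aa_ch, collapse = "")
        if (!substitution_run_unambiguous(ra, aa)) next
      } else if (type == "insertion") {
        aa_ch <- random_dna(l)
        if (aa_ch[l] == sv[p] || aa_ch[1L] == sv[p + 1L]) {
          if (l == 1L) aa_ch <- sample(setdiff(BASES, c(sv[p], sv[p + 1L])), 1L)
          else next
        }
        if (max_homopolymer(c(sv[max(1L, p - 3L):p], aa_ch, sv[(p + 1L):(p + 4L)])) >= 4L) next
        ra <- ""; aa <- paste(aa_ch, collapse = "")
      } else {  # deletion
        if (sv[p] == sv[p + l] || sv[p + 1L] == sv[p + l + 1L]) next
        ra <- paste(seg, collapse = ""); aa <- ""
      }
      rows[[k]] <- list(type = type, ref_pos = p,
                        ref_allele = ra, alt_allele = aa, length = l)
      occ_s <- c(occ_s, p - EVENT_PAD); occ_e <- c(occ_e, p + l + EVENT_PAD)
      placed <- TRUE
      break
    }
    if (!placed) stop_format("could not place all events; genome too small for config")
  }
  out <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  out[order(out$ref_pos), , drop = FALSE]
}

## Apply manifest events to the ancestor character vector; returns the
## derived vector and the derived coordinate of every event.
apply_events_chars <- function(sv, events) {
  if (nrow(events) == 0L) return(list(seq = sv, derived_pos = integer(0)))
  events <- events[order(events$ref_pos), , drop = FALSE]
  pieces <- list()
  derived_pos <- integer(nrow(events))
  cursor <- 0L   # 0-based position in ancestor
  offset <- 0L
  for (i in seq_len(nrow(events))) {
    p <- events$ref_pos[i]; l <- events$length[i]; type <- events$type[i]
    if (p > cursor) pieces[[length(pieces) + 1L]] <- sv[(cursor + 1L):p]
    derived_pos[i] <- p + offset
    if (type %in% c("SNP", "MNS", "RCV")) {
      pieces[[length(pieces) + 1L]] <- strsplit(events$alt_allele[i], "")[[1L]]
      cursor <- p + l
    } else if (type == "insertion") {
      pieces[[length(pieces) + 1L]] <- strsplit(events$alt_allele[i], "")[[1L]]
      cursor <- p
      offset <- offset + l
    } else if (type == "deletion") {
      cursor <- p + l
      offset <- offset - l
    } else if (type == "inversion") {
      seg <- sv[(p + 1L):(p + l)]
      pieces[[length(pieces) + 1L]] <- unname(COMP[rev(seg)])
      cursor <- p + l
    } else stop_format(paste("unknown event type:", type))
  }
  if (cursor < length(sv)) pieces[[length(pieces) + 1L]] <- sv[(cursor + 1L):length(sv)]
  list(seq = unlist(pieces), derived_pos = derived_pos)
}

#' Replay a truth manifest
#'
#' Applies every planted event to the ancestor; the result must reproduce
#' the derived genome byte-exactly (the simulator's conservation
#' invariant).
#'
#' @param ancestor Ancestor `Genome`.
#' @param manifest `TruthManifest`.
#' @return The derived `Genome`.
#' @export
apply_manifest <- function(ancestor, manifest) {
  sv <- strsplit(ancestor$sequence, "")[[1L]]
  res <- apply_events_chars(sv, manifest$events)
  genome(paste0(ancestor$id, "_replayed"), paste(res$seq, collapse = ""),
         topology = ancestor$topology)
}

place_features <- function(n, L, len_range) {
  if (n == 0L)
    return(make_features(character(), character(), integer(), integer(), character()))
  starts <- integer(0); ends <- integer(0)
  rows <- vector("list", n)
  kinds <- sample(c("gene", "tRNA", "rRNA"), n, replace = TRUE,
                  prob = c(0.8, 0.12, 0.08))
  for (i in seq_len(n)) {
    for (try in seq_len(5000L)) {
      l <- sample(len_range[1L]:len_range[2L], 1L)
      if (kinds[i] != "gene") l <- sample(60:150, 1L)
      s <- sample.int(L - l - 1L, 1L)
      if (any(s < ends + 20L & s + l + 20L > starts)) next
      starts <- c(starts, s); ends <- c(ends, s + l)
      rows[[i]] <- list(name = sprintf("%s%03d", ifelse(kinds[i] == "gene", "gene", tolower(kinds[i])), i),
                        kind = kinds[i], start = s, end = s + l,
                        strand = sample(c("+", "-"), 1L))
      break
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  out <- out[order(out$start), , drop = FALSE]
  make_features(out$name, out$kind, out$start, out$end, out$strand)
}

new_manifest <- function(cfg, genome_type, events, derived_pos, features,
                         partition = NULL, repeats = NULL, cp_segments = NULL) {
  events$derived_pos <- derived_pos
  events <- events[, c("type", "ref_pos", "derived_pos", "ref_allele",
                       "alt_allele", "length")]
  structure(
    list(seed = cfg$seed, profile = cfg$profile, genome_type = genome_type,
         events = events, features = features, partition = partition,
         repeats = repeats, cp_segments = cp_segments, config = cfg),
    class = "TruthManifest"
  )
}

#' @export
print.TruthManifest <- function(x, ...) {
  cat(sprintf("<TruthManifest> %s pair, profile '%s', seed %d: %d events\n",
              x$genome_type, x$profile, x$seed, nrow(x$events)))
  if (nrow(x$events)) print(table(x$events$type))
  invisible(x)
}

## ---- chloroplast pair ---------------------------------------------------

#' Generate a chloroplast genome pair with planted divergence
#'
#' The ancestor is assembled as LSC ++ IRA ++ SSC ++ reverse_complement(IRA)
#' with random interior, giving an exact quadripartite structure whose IR
#' boundaries are pinned (flanking bases chosen so the inverted-repeat pair
#' cannot extend by chance). Features are placed without overlap; the
#' derived genome applies the configured non-overlapping events. All output
#' is deterministic given the configuration.
#'
#' @param cfg A [sim_config()] (a `cp-*` profile).
#' @return List with elements `ancestor`, `derived` (both `Genome`),
#'   `features` and `manifest` (`TruthManifest`).
#' @export
generate_cp_pair <- function(cfg = sim_config("cp-intersubspecific")) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    lsc_len <- cfg$cp_len - 2L * cfg$ir_len - cfg$ssc_len
    lsc <- random_dna(lsc_len)
    ira <- random_dna(cfg$ir_len)
    ssc <- random_dna(cfg$ssc_len)
    irb <- unname(COMP[rev(ira)])
    sv <- c(lsc, ira, ssc, irb)
    ## pin IR boundaries: the planted pair must be maximal exactly
    if (sv[lsc_len] == COMP[[sv[1L]]])
      sv[lsc_len] <- sample(setdiff(BASES, COMP[[sv[1L]]]), 1L)
    ssc_last <- lsc_len + cfg$ir_len + cfg$ssc_len
    ssc_first <- lsc_len + cfg$ir_len + 1L
    if (sv[ssc_last] == COMP[[sv[ssc_first]]])
      sv[ssc_last] <- sample(setdiff(BASES, COMP[[sv[ssc_first]]]), 1L)
    n <- length(sv)
    partition <- structure(
      list(lsc = matrix(c(0L, lsc_len), ncol = 2L),
           ssc = matrix(c(lsc_len + cfg$ir_len, lsc_len + cfg$ir_len + cfg$ssc_len), ncol = 2L),
           ira = matrix(c(lsc_len, lsc_len + cfg$ir_len), ncol = 2L),
           irb = matrix(c(n - cfg$ir_len, n), ncol = 2L),
           genome_length = n),
      class = "RegionPartition")
    features <- place_features(cfg$n_features, n, cfg$feature_len_range)
    events <- sample_variant_events(sv, cfg)
    res <- apply_events_chars(sv, events)
    ancestor <- genome(sprintf("cp_anc_s%d", cfg$seed), paste(sv, collapse = ""))
    derived <- genome(sprintf("cp_der_s%d", cfg$seed), paste(res$seq, collapse = ""))
    manifest <- new_manifest(cfg, "cp", events, res$derived_pos, features,
                             partition = partition)
    list(ancestor = ancestor, derived = derived, features = features,
         manifest = manifest)
  })
}

## ---- mitochondrial pair -------------------------------------------------

#' Generate a mitochondrial genome pair with planted divergence
#'
#' The ancestor is assembled from random backbone fillers interleaved with
#' planted structure: large direct repeats (segmental duplications of
#' backbone pieces, flanks pinned so each pair is maximal at its planted
#' length) and chloroplast-derived fragments copied from a supplied or
#' co-generated cp genome, mutated to the configured identity, sized to hit
#' `cp_derived_fraction`. The derived genome applies the configured
#' variants and optional segment inversions.
#'
#' @param cfg A [sim_config()] (typically the `mt-hybrid` profile).
#' @param cp Optional chloroplast `Genome` to draw plastid fragments from;
#'   a random one of `cfg$cp_len` is generated when absent.
#' @return List with elements `ancestor`, `derived`, `features`, `manifest`;
#'   the manifest records the planted repeats (`repeats`) and plastid
#'   segments (`cp_segments`) alongside the event ledger.
#' @export
generate_mt_pair <- function(cfg = sim_config("mt-hybrid"), cp = NULL) {
  validate_sim_config(cfg)
  ## offset the stream so that a cp genome generated from the same seed
  ## shares no random draws with the mt backbone
  with_seed((cfg$seed + 1500450271) %% .Machine$integer.max, {
    cs <- if (is.null(cp)) paste(random_dna(cfg$cp_len), collapse = "") else as_seq(cp)
    nc <- nchar(cs)
    cp_bp <- round(cfg$cp_derived_fraction * cfg$mt_len)

    ## plastid fragments
    frags <- list()
    if (cp_bp > 0L) {
      n_frag <- max(1L, round(cp_bp / 2500))
      while (cp_bp / n_frag < 200 && n_frag > 1L) n_frag <- n_frag - 1L
      lens <- rep(cp_bp %/% n_frag, n_frag)
      lens[1L] <- lens[1L] + cp_bp - sum(lens)
      src_s <- integer(0); src_e <- integer(0)
      for (l in lens) {
        repeat {
          s <- sample.int(nc - l - 1L, 1L)
          if (!any(s < src_e & s + l > src_s)) break
        }
        src_s <- c(src_s, s); src_e <- c(src_e, s + l)
        seq <- strsplit(substr(cs, s + 1L, s + l), "")[[1L]]
        nmut <- round((1 - cfg$cp_fragment_identity) * l)
        if (nmut > 0L) {
          at <- sample.int(l, nmut)
          seq[at] <- vapply(seq[at], function(b) sample(setdiff(BASES, b), 1L), "")
        }
        orient <- sample(c("F", "R"), 1L)
        if (orient == "R") seq <- unname(COMP[rev(seq)])
        frags[[length(frags) + 1L]] <- list(kind = "cpfrag", seq = seq,
                                            cp_start = s, cp_end = s + l,
                                            orientation = orient)
      }
    }

    ## large direct repeats: source + identical copy
    reps <- lapply(seq_along(cfg$repeat_lens), function(i)
      list(kind = "repsrc", seq = random_dna(cfg$repeat_lens[i]), partner = i))
    pieces <- c(reps, frags)
    for (i in seq_along(reps))
      pieces[[length(pieces) + 1L]] <- list(kind = "repcopy", seq = reps[[i]]$seq,
                                            partner = i)
    np <- length(pieces)
    if (np > 0L) {
      repeat {   # keep each copy away from its own source
        ord <- sample.int(np)
        src_at <- match(seq_along(reps), ord)
        copy_at <- match(length(reps) + length(frags) + seq_along(reps), ord)
        if (!length(reps) || all(abs(src_at - copy_at) > 1L)) break
      }
      pieces <- pieces[ord]
    }
    piece_bp <- sum(vapply(pieces, function(p) length(p$seq), 0L))
    filler_total <- cfg$mt_len - piece_bp
    nf <- np + 1L
    if (filler_total < 500L * nf)
      stop_format("mt config unsatisfiable: planted content leaves too little backbone")
    extra <- filler_total - 500L * nf
    w <- runif(nf); add <- floor(extra * w / sum(w))
    add[1L] <- add[1L] + (extra - sum(add))
    flens <- 500L + as.integer(add)

    parts <- list(random_dna(flens[1L]))
    coords <- vector("list", np)
    pos <- flens[1L]
    for (i in seq_len(np)) {
      coords[[i]] <- c(start = pos, end = pos + length(pieces[[i]]$seq))
      parts[[length(parts) + 1L]] <- pieces[[i]]$seq
      pos <- pos + length(pieces[[i]]$seq)
      parts[[length(parts) + 1L]] <- random_dna(flens[i + 1L])
      pos <- pos + flens[i + 1L]
    }
    sv <- unlist(parts)
    stopifnot(length(sv) == cfg$mt_len)

    kinds <- vapply(pieces, function(p) p$kind, "")
    repeats <- NULL
    if (length(reps)) {
      src_idx <- which(kinds == "repsrc")
      copy_idx <- which(kinds == "repcopy")
      src_of <- vapply(pieces[src_idx], function(p) p$partner, 0L)
      partner <- vapply(pieces[copy_idx], function(p) p$partner, 0L)
      rows <- lapply(seq_along(reps), function(i) {
        a <- coords[[src_idx[match(i, src_of)]]][["start"]]
        b <- coords[[copy_idx[match(i, partner)]]][["start"]]
        data.frame(length = length(reps[[i]]$seq),
                   start1 = min(a, b), start2 = max(a, b),
                   direction = "F", stringsAsFactors = FALSE)
      })
      repeats <- do.call(rbind, rows)
      ## pin flanks so planted pairs are maximal at their planted length
      for (i in seq_len(nrow(repeats))) {
        a <- repeats$start1[i]; b <- repeats$start2[i]; l <- repeats$length[i]
        if (a > 0L && sv[a] == sv[b])
          sv[b] <- sample(setdiff(BASES, sv[a]), 1L)
        if (b + l < cfg$mt_len && sv[a + l + 1L] == sv[b + l + 1L])
          sv[b + l + 1L] <- sample(setdiff(BASES, sv[a + l + 1L]), 1L)
      }
      repeats <- repeats[order(-repeats$length), , drop = FALSE]
      rownames(repeats) <- NULL
    }

    cp_segments <- NULL
    if (length(frags)) {
      frag_idx <- which(kinds == "cpfrag")
      rows <- lapply(frag_idx, function(i) {
        p <- pieces[[i]]
        data.frame(mt_start = coords[[i]][["start"]], mt_end = coords[[i]][["end"]],
                   cp_start = p$cp_start, cp_end = p$cp_end,
                   orientation = p$orientation,
                   identity = cfg$cp_fragment_identity, stringsAsFactors = FALSE)
      })
      cp_segments <- do.call(rbind, rows)
      cp_segments <- cp_segments[order(cp_segments$mt_start), , drop = FALSE]
      rownames(cp_segments) <- NULL
    }

    ## inversions go into filler regions, clear of planted structure
    inv_events <- NULL
    if (cfg$inversion_count > 0L) {
      occ <- do.call(rbind, coords)
      placed <- list()
      inv_iv <- matrix(integer(), ncol = 2L)
      for (i in seq_len(cfg$inversion_count)) {
        for (try in seq_len(20000L)) {
          s <- sample.int(cfg$mt_len - cfg$inversion_len - 200L, 1L) + 100L
          e <- s + cfg$inversion_len
          busy <- rbind(if (is.null(occ)) NULL else occ, inv_iv)
          if (!is.null(busy) && nrow(busy) &&
              any(s - 100L < busy[, 2L] & e + 100L > busy[, 1L])) next
          placed[[i]] <- data.frame(type = "inversion", ref_pos = s,
                                    ref_allele = "", alt_allele = "",
                                    length = cfg$inversion_len,
                                    stringsAsFactors = FALSE)
          inv_iv <- rbind(inv_iv, c(s, e))
          break
        }
      }
      inv_events <- do.call(rbind, placed)
      if (is.null(inv_events) || nrow(inv_events) < cfg$inversion_count)
        stop_format("could not place inversions; mt genome too crowded")
    }

    forbidden <- if (is.null(inv_events)) NULL
    else cbind(inv_events$ref_pos - 50L, inv_events$ref_pos + inv_events$length + 50L)
    events <- sample_variant_events(sv, cfg, forbidden = forbidden)
    events <- rbind(events, inv_events)
    events <- events[order(events$ref_pos), , drop = FALSE]

    features <- place_features(cfg$n_features, cfg$mt_len, cfg$feature_len_range)
    res <- apply_events_chars(sv, events)
    ancestor <- genome(sprintf("mt_anc_s%d", cfg$seed), paste(sv, collapse = ""))
    derived <- genome(sprintf("mt_der_s%d", cfg$seed), paste(res$seq, collapse = ""))
    manifest <- new_manifest(cfg, "mt", events, res$derived_pos, features,
                             repeats = repeats, cp_segments = cp_segments)
    list(ancestor = ancestor, derived = derived, features = features,
         manifest = manifest,
         cp = genome(sprintf("cp_donor_s%d", cfg$seed), cs))
  })
}

#' Score recovered variants against a truth manifest
#'
#' A call is a true positive when its type, reference position and both
#' alleles equal a planted event's. Inversions are excluded (they are
#' recovered as reverse-orientation blocks, not variant records).
#'
#' @param variants Variant data frame from [extract_variants()].
#' @param manifest `TruthManifest`.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
score_recovery <- function(variants, manifest) {
  truth <- manifest$events
  truth <- truth[truth$type != "inversion", , drop = FALSE]
  tkey <- paste(truth$type, truth$ref_pos, truth$ref_allele, truth$alt_allele)
  ckey <- paste(variants$kind, variants$ref_pos, variants$ref_allele,
                variants$alt_allele)
  tp <- sum(ckey %in% tkey)
  list(tp = tp, fp = length(ckey) - tp, fn = length(tkey) - tp,
       precision = if (length(ckey)) tp / length(ckey) else NA_real_,
       recall = if (length(tkey)) tp / length(tkey) else NA_real_)
}

#' Write a truth manifest to disk
#'
#' A TSV event table preceded by a JSON header block in `#`-prefixed lines
#' (seed, profile, configuration, planted structure).
#'
#' @param manifest `TruthManifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  hdr <- list(seed = manifest$seed, profile = manifest$profile,
              genome_type = manifest$genome_type,
              config = unclass(manifest$config),
              repeats = manifest$repeats, cp_segments = manifest$cp_segments)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", strsplit(jsonlite::toJSON(hdr, auto_unbox = TRUE,
                                                   null = "null", digits = NA),
                                  "\n")[[1L]]), con)
  utils::write.table(manifest$events, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
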