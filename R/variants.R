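#' Classify a substitution run
#'
#' A length-1 run is a SNP. A run of length >= 2 whose alternate allele is
#' the exact reverse complement of the reference allele is a reverse
#' complementary variation (RCV); any other run is a multi-nucleotide
#' substitution (MNS), reported as co-segregating SNPs. RCV takes precedence
#' over MNS; a run whose reverse complement equals the reference itself
#' (e.g. `CG -> GC`, since revcomp(`CG`) is `CG`) is therefore an MNS.
#'
#' @param ref_allele,alt_allele Equal-length DNA strings differing at every
#'   position.
#' @return `"SNP"`, `"RCV"` or `"MNS"`.
#' @examples
#' classify_substitution_run("TC", "GA")        # RCV
#' classify_substitution_run("CG", "GC")        # MNS
#' @export
classify_substitution_run <- function(ref_allele, alt_allele) {
  if (nchar(ref_allele) != nchar(alt_allele))
    stop_format("substitution run alleles must have equal length")
  if (nchar(ref_allele) < 1L) stop_format("empty allele")
  ra <- strsplit(ref_allele, "", fixed = TRUE)[[1L]]
  aa <- strsplit(alt_allele, "", fixed = TRUE)[[1L]]
  if (any(ra == aa))
    stop_format("substitution run alleles must differ at every position")
  if (nchar(ref_allele) == 1L) return("SNP")
  if (alt_allele == revcomp(ref_allele)) "RCV" else "MNS"
}

#' Classify a SNP as transition or transversion
#'
#' Purine-purine (`A<->G`) and pyrimidine-pyrimidine (`C<->T`) exchanges are
#' transitions; all other exchanges are transversions.
#'
#' @param ref_base,alt_base Single differing bases.
#' @return `"transition"` or `"transversion"`.
#' @export
classify_snp <- function(ref_base, alt_base) {
  if (nchar(ref_base) != 1L || nchar(alt_base) != 1L)
    stop_format("classify_snp expects single bases")
  if (ref_base == alt_base) stop_format("identical bases are not a SNP")
  pair <- paste0(sort(c(ref_base, alt_base)), collapse = "")
  if (pair %in% c("AG", "CT")) "transition" else "transversion"
}

empty_variants <- function() {
  data.frame(kind = character(), label = character(),
             ref_pos = integer(), qry_pos = integer(),
             ref_allele = character(), alt_allele = character(),
             length = integer(), orientation = character(),
             gene_context = NA_character_[0], region = NA_character_[0],
             intravarietal = NA_character_[0],
             stringsAsFactors = FALSE)
}

variant_label <- function(kind, len) {
  switch(kind,
         SNP = "SNP",
         MNS = paste0("S-", len),
         RCV = paste0("R-", len),
         insertion = paste0("I-", len),
         deletion = paste0("D-", len))
}

#' Extract variants from synteny blocks
#'
#' Walks every block transcript and emits one variant per maximal run of
#' substituted columns (classified SNP / MNS / RCV) and one InDel per gap
#' run. InDels are left-normalised: shifted to the lowest reference
#' coordinate that preserves the alignment, without crossing a neighbouring
#' variant. Positions are 0-based; for variants on reverse-complement blocks
#' `qry_pos` is the leftmost query base of the affected interval and the
#' alternate allele is given in alignment (reference) orientation.
#'
#' @param blocks `SyntenyBlocks` from [align_pair()] (or a list of
#'   `SyntenyBlock`s).
#' @param ref,qry `Genome` objects or DNA strings.
#' @return Variant data frame sorted by `ref_pos` with columns `kind`
#'   (`SNP|MNS|RCV|insertion|deletion`), `label` (short table code such as
#'   `I-4`, `D-2`, `S-2`, `R-6`), `ref_pos`, `qry_pos`, `ref_allele`,
#'   `alt_allele`, `length`, `orientation`, and the annotation columns
#'   `gene_context`, `region`, `intravarietal` (filled by
#'   [annotate_variants()]; `intravarietal` is pass-through metadata, never
#'   computed here).
#' @export
extract_variants <- function(blocks, ref, qry) {
  r <- as_seq(ref); q <- as_seq(qry)
  nq <- nchar(q)
  if (inherits(blocks, "SyntenyBlock")) blocks <- list(blocks)
  if (length(blocks) > 1L) {
    ivs <- cbind(vapply(blocks, function(b) b$ref_start, 0L),
                 vapply(blocks, function(b) b$ref_end, 0L))
    ivs <- ivs[order(ivs[, 1L]), , drop = FALSE]
    if (any(ivs[-1L, 1L] < ivs[-nrow(ivs), 2L]))
      stop_format("overlapping synteny blocks on the reference; deoverlap first")
  }
  rows <- list()
  for (b in blocks) {
    qo <- if (b$orientation == "F") q else revcomp(q)
    qoff <- if (b$orientation == "F") b$qry_start else nq - b$qry_end
    rp <- b$ref_start; qp <- qoff
    prev_end <- b$ref_start   # ref end of the previous variant in this block
    for (k in seq_along(b$ops)) {
      op <- b$ops[k]; l <- b$lens[k]
      if (op == "M") { rp <- rp + l; qp <- qp + l; next }
      if (op == "X") {
        ra <- substr(r, rp + 1L, rp + l)
        aa <- substr(qo, qp + 1L, qp + l)
        kind <- classify_substitution_run(ra, aa)
        rows[[length(rows) + 1L]] <- list(kind = kind, ref_pos = rp, qpos_or = qp,
                                          ref_allele = ra, alt_allele = aa, length = l)
        prev_end <- rp + l
        rp <- rp + l; qp <- qp + l
      } else if (op == "D") {           # qry-gap: deletion in qry
        pos <- rp
        qpos <- qp
        while (pos > prev_end &&
               substr(r, pos, pos) == substr(r, pos + l, pos + l)) {
          pos <- pos - 1L; qpos <- qpos - 1L
        }
        rows[[length(rows) + 1L]] <- list(kind = "deletion", ref_pos = pos, qpos_or = qpos,
                                          ref_allele = substr(r, pos + 1L, pos + l),
                                          alt_allele = "", length = l)
        prev_end <- rp + l
        rp <- rp + l
      } else {                          # ref-gap: insertion in qry
        pos <- rp
        qpos <- qp
        aa <- substr(qo, qp + 1L, qp + l)
        while (pos > prev_end &&
               substr(aa, l, l) == substr(r, pos, pos)) {
          aa <- paste0(substr(aa, l, l), substr(aa, 1L, l - 1L))
          pos <- pos - 1L; qpos <- qpos - 1L
        }
        rows[[length(rows) + 1L]] <- list(kind = "insertion", ref_pos = pos, qpos_or = qpos,
                                          ref_allele = "", alt_allele = aa, length = l)
        prev_end <- rp
        qp <- qp + l
      }
      ## record block context on the variant just added
      rows[[length(rows)]]$orientation <- b$orientation
      rows[[length(rows)]]$qoff_map <- if (b$orientation == "F") NA_integer_ else nq
    }
  }
  if (!length(rows)) return(empty_variants())
  out <- do.call(rbind, lapply(rows, function(v) {
    qry_pos <- if (v$orientation == "F") v$qpos_or
    else v$qoff_map - (v$qpos_or + nchar(v$alt_allele))
    data.frame(kind = v$kind,
               label = variant_label(v$kind, v$length),
               ref_pos = v$ref_pos, qry_pos = qry_pos,
               ref_allele = v$ref_allele, alt_allele = v$alt_allele,
               length = v$length, orientation = v$orientation,
               gene_context = NA_character_, region = NA_character_,
               intravarietal = NA_character_, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$ref_pos, out$qry_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate variants with gene context and genomic region
#'
#' A variant inside a feature is labelled with that feature's name; an
#' intergenic variant is labelled `"upstreamGene/downstreamGene"` from the
#' nearest flanking features in genome order, wrapping around the circular
#' origin. When a `RegionPartition` is supplied the `region` column is set
#' to LSC/SSC/IRA/IRB.
#'
#' @param variants Variant data frame from [extract_variants()].
#' @param features Optional feature data frame ([read_features()]).
#' @param partition Optional `RegionPartition` from [detect_ir_partition()].
#' @return The variant data frame with `gene_context` and `region` filled.
#' @export
annotate_variants <- function(variants, features = NULL, partition = NULL) {
  if (nrow(variants) == 0L) return(variants)
  if (!is.null(partition))
    variants$region <- region_of(variants$ref_pos, partition)
  if (!is.null(features) && nrow(features) > 0L) {
    fx <- features[order(features$start), , drop = FALSE]
    ctx <- character(nrow(variants))
    for (i in seq_len(nrow(variants))) {
      s <- variants$ref_pos[i]
      e <- s + max(variants$length[i] * (variants$kind[i] != "insertion"), 1L)
      hit <- which(fx$start < e & fx$end > s)
      if (length(hit)) {
        ctx[i] <- fx$name[hit[1L]]
      } else {
        up <- which(fx$end <= s)
        dn <- which(fx$start >= e)
        up_i <- if (length(up)) up[length(up)] else nrow(fx)   # circular wrap
        dn_i <- if (length(dn)) dn[1L] else 1L
        ctx[i] <- paste0(fx$name[up_i], "/", fx$name[dn_i])
      }
    }
    variants$gene_context <- ctx
  }
  variants
}

#' Summarise variants into count and rate statistics
#'
#' Rates are `100 * count / ref_len` (per-cent of reference positions,
#' reported to three decimals in the printed tables). Transition and
#' transversion tallies cover isolated SNPs only unless `explode_runs` is
#' set, in which case every MNS/RCV column is counted as a SNP as well.
#'
#' @param variants Variant data frame.
#' @param ref_len Reference genome length (rate denominator).
#' @param explode_runs Count MNS/RCV columns in the Ts/Tv tally.
#' @return A `VariantSummary` list: per-kind counts, `transitions`,
#'   `transversions`, `insertion_bp`, `deletion_bp`, `cumulative_delta`
#'   (`insertion_bp - deletion_bp`) and a `rates` vector.
#' @export
summarize_variants <- function(variants, ref_len, explode_runs = FALSE) {
  stopifnot(ref_len > 0)
  cnt <- function(k) sum(variants$kind == k)
  snps <- variants[variants$kind == "SNP", , drop = FALSE]
  ts <- tv <- 0L
  if (nrow(snps)) {
    cls <- mapply(classify_snp, snps$ref_allele, snps$alt_allele)
    ts <- sum(cls == "transition"); tv <- sum(cls == "transversion")
  }
  if (explode_runs) {
    runs <- variants[variants$kind %in% c("MNS", "RCV"), , drop = FALSE]
    for (i in seq_len(nrow(runs))) {
      ra <- strsplit(runs$ref_allele[i], "")[[1L]]
      aa <- strsplit(runs$alt_allele[i], "")[[1L]]
      cls <- mapply(classify_snp, ra, aa)
      ts <- ts + sum(cls == "transition"); tv <- tv + sum(cls == "transversion")
    }
  }
  ins_bp <- sum(nchar(variants$alt_allele[variants$kind == "insertion"]))
  del_bp <- sum(nchar(variants$ref_allele[variants$kind == "deletion"]))
  counts <- c(SNP = cnt("SNP"), MNS = cnt("MNS"), RCV = cnt("RCV"),
              insertion = cnt("insertion"), deletion = cnt("deletion"))
  counts["InDel"] <- counts[["insertion"]] + counts[["deletion"]]
  structure(
    list(counts = counts,
         transitions = ts, transversions = tv,
         insertion_bp = ins_bp, deletion_bp = del_bp,
         cumulative_delta = ins_bp - del_bp,
         rates = 100 * counts / ref_len,
         ref_len = ref_len),
    class = "VariantSummary"
  )
}

#' @export
print.VariantSummary <- function(x, ...) {
  cat(sprintf("<VariantSummary> reference length %d bp\n", x$ref_len))
  for (nm in names(x$counts))
    cat(sprintf("  %-10s %5d (%.3f%%)\n", nm, x$counts[[nm]], x$rates[[nm]]))
  cat(sprintf("  transitions %d, transversions %d\n", x$transitions, x$transversions))
  cat(sprintf("  insertion bp %d, deletion bp %d, cumulative delta %+d bp\n",
              x$insertion_bp, x$deletion_bp, x$cumulative_delta))
  invisible(x)
}

#' Count co-segregating SNP clusters
#'
#' The number of multi-nucleotide substitution runs (length >= 2 runs not
#' classified as RCV).
#'
#' @param variants Variant data frame.
#' @return Integer count.
#' @export
count_coseg_clusters <- function(variants) {
  sum(variants$kind == "MNS")
}
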