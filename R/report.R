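## Report writers. Coordinate dialects are fixed per table and named in a
## header comment: variant and SSR tables are 1-based inclusive, repeat
## tables 0-based, cp-derived tables 1-based inclusive (BLAST style),
## dot-plot tables 0-based half-open.

write_tsv_with_header <- function(df, path, comments) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a variant table (TSV, 1-based inclusive positions)
#'
#' Columns mirror the published variant tables: label, positions on both
#' genomes, the affected sequence, gene context and region.
#'
#' @param variants Variant data frame from [extract_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(variants, path) {
  seq_col <- ifelse(variants$kind %in% c("SNP", "MNS", "RCV"),
                    paste0(variants$ref_allele, "->", variants$alt_allele),
                    ifelse(variants$kind == "deletion",
                           variants$ref_allele, variants$alt_allele))
  df <- data.frame(label = variants$label, kind = variants$kind,
                   ref_pos = variants$ref_pos + 1L,
                   qry_pos = variants$qry_pos + 1L,
                   sequence = seq_col,
                   gene_context = variants$gene_context,
                   region = variants$region,
                   intravarietal = variants$intravarietal,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, "coordinates: 1-based inclusive")
}

#' Write variants as minimal VCF 4.2
#'
#' SNPs are plain records; MNS/RCV runs are multi-base REF/ALT records; all
#' records carry `CLASS=` in INFO. InDels are anchored on the preceding
#' reference base, VCF-style.
#'
#' @param variants Variant data frame.
#' @param ref Reference `Genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, ref, path) {
  r <- as_seq(ref)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>",
            if (inherits(ref, "Genome")) ref$id else "ref", nchar(r)),
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"SNP, MNS (co-segregating SNPs), RCV, insertion or deletion\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  chrom <- if (inherits(ref, "Genome")) ref$id else "ref"
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$kind %in% c("SNP", "MNS", "RCV")) {
      pos <- v$ref_pos + 1L; refa <- v$ref_allele; alta <- v$alt_allele
    } else if (v$kind == "deletion") {
      anchor <- substr(r, v$ref_pos, v$ref_pos)     # base before, 1-based
      if (v$ref_pos == 0L) { anchor <- substr(r, v$length + 1L, v$length + 1L)
        pos <- 1L; refa <- paste0(v$ref_allele, anchor); alta <- anchor
      } else { pos <- v$ref_pos; refa <- paste0(anchor, v$ref_allele); alta <- anchor }
    } else {                                        # insertion
      anchor <- substr(r, v$ref_pos, v$ref_pos)
      if (v$ref_pos == 0L) { anchor <- substr(r, 1L, 1L)
        pos <- 1L; refa <- anchor; alta <- paste0(v$alt_allele, anchor)
      } else { pos <- v$ref_pos; refa <- anchor; alta <- paste0(anchor, v$alt_allele) }
    }
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tCLASS=%s",
                       chrom, pos, v$label, refa, alta, v$kind), con)
  }
  invisible(path)
}

#' Write dot-plot coordinates (TSV, 0-based half-open)
#'
#' One row per anchor: `ref_start`, `ref_end`, `qry_start`, `qry_end`,
#' `orientation`.
#'
#' @param blocks `SyntenyBlocks` from [align_pair()] (anchors attribute) or
#'   an anchor data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dotplot_tsv <- function(blocks, path) {
  anchors <- if (is.data.frame(blocks)) blocks else attr(blocks, "anchors")
  df <- data.frame(ref_start = anchors$pos_ref,
                   ref_end = anchors$pos_ref + anchors$length,
                   qry_start = anchors$pos_qry,
                   qry_end = anchors$pos_qry + anchors$length,
                   orientation = anchors$orientation, stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, "coordinates: 0-based half-open")
}

#' Write an SSR table (TSV, 1-based inclusive)
#' @param loci SSR data frame from [find_ssrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ssr_tsv <- function(loci, path) {
  df <- data.frame(canonical_motif = loci$canonical_motif, motif = loci$motif,
                   start = loci$start + 1L, end = loci$end,
                   unit_len = loci$unit_len, copies = loci$copies,
                   context = loci$context, stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, "coordinates: 1-based inclusive")
}

#' Write a repeat table (TSV, 0-based starts)
#' @param tbl Table from [large_repeat_table()] or pairs from
#'   [find_maximal_repeats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_tsv <- function(tbl, path) {
  write_tsv_with_header(tbl, path, "coordinates: 0-based starts")
}

#' Write a cp-derived segment table (TSV, 1-based inclusive, BLAST style)
#' @param segments Segment data frame from [find_cp_derived()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpderived_tsv <- function(segments, path) {
  df <- data.frame(mt_start = segments$mt_start + 1L, mt_end = segments$mt_end,
                   cp_start = segments$cp_start + 1L, cp_end = segments$cp_end,
                   orientation = segments$orientation,
                   aligned_len = segments$aligned_len,
                   identity = round(segments$identity, 4L),
                   e_value = signif(segments$e_value, 3L),
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, "coordinates: 1-based inclusive (BLAST convention)")
}

write_summary_tsv <- function(summary, path) {
  df <- data.frame(
    statistic = c(names(summary$counts), "transitions", "transversions",
                  "insertion_bp", "deletion_bp", "cumulative_delta_bp"),
    value = c(unname(summary$counts), summary$transitions, summary$transversions,
              summary$insertion_bp, summary$deletion_bp, summary$cumulative_delta),
    rate_pct = c(sprintf("%.3f", summary$rates), rep("", 5L)),
    stringsAsFactors = FALSE)
  write_tsv_with_header(df, path,
                        sprintf("rates are 100 * count / %d (reference length)",
                                summary$ref_len))
}

run_log <- function(out_dir, subcommand, params, inputs) {
  lines <- c(
    sprintf("tool: orgvar %s", as.character(utils::packageVersion("orgvar"))),
    sprintf("subcommand: %s", subcommand),
    vapply(names(params), function(k) sprintf("param %s = %s", k,
                                              paste(params[[k]], collapse = ",")), ""),
    vapply(inputs, function(p) sprintf("input %s md5 %s", p,
                                       unname(tools::md5sum(p))), "")
  )
  writeLines(lines, file.path(out_dir, "run.log"))
}

#' Compare two genomes end to end
#'
#' Runs [align_pair()], [extract_variants()], classification, annotation and
#' [summarize_variants()], writing `variants.tsv`, `variants.vcf`,
#' `summary.tsv` and `dotplot.tsv` to `out_dir`. With `mode = "cp"` the
#' quadripartite partition of the reference is detected and variants are
#' tagged with their region.
#'
#' @param ref_path,qry_path FASTA paths (first record used).
#' @param out_dir Output directory (created if needed).
#' @param features_path Optional GFF3 annotation of the reference.
#' @param mode `"cp"` (detect IR partition) or `"mt"`.
#' @param min_match Minimum exact-match anchor length.
#' @return The `VariantSummary`, invisibly.
#' @export
cmd_compare <- function(ref_path, qry_path, out_dir, features_path = NULL,
                        mode = c("cp", "mt"), min_match = 50L) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- read_fasta(ref_path)[[1L]]
  qry <- read_fasta(qry_path)[[1L]]
  features <- if (!is.null(features_path)) read_features(features_path) else NULL
  blocks <- align_pair(ref, qry, min_match = min_match)
  variants <- extract_variants(blocks, ref, qry)
  partition <- if (mode == "cp") detect_ir_partition(ref) else NULL
  variants <- annotate_variants(variants, features, partition)
  summary <- summarize_variants(variants, ref$length)
  write_variant_tsv(variants, file.path(out_dir, "variants.tsv"))
  write_vcf(variants, ref, file.path(out_dir, "variants.vcf"))
  write_dotplot_tsv(blocks, file.path(out_dir, "dotplot.tsv"))
  write_summary_tsv(summary, file.path(out_dir, "summary.tsv"))
  run_log(out_dir, "compare",
          list(mode = mode, min_match = min_match),
          c(ref_path, qry_path, features_path))
  invisible(summary)
}

#' SSR census of a genome
#'
#' Writes `ssr.tsv` and `ssr_summary.tsv` to `out_dir`. Without an
#' annotation the genic/intergenic split is reported as `NA` with a
#' warning.
#'
#' @param fasta_path FASTA path (first record used).
#' @param out_dir Output directory.
#' @param features_path Optional GFF3 annotation.
#' @param min_copies Copy thresholds, see [find_ssrs()].
#' @return The SSR loci, invisibly.
#' @export
cmd_ssr <- function(fasta_path, out_dir, features_path = NULL,
                    min_copies = c(`1` = 5L, `2` = 3L, `3` = 3L, `4` = 3L,
                                   `5` = 3L, `6` = 3L)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- read_fasta(fasta_path)[[1L]]
  loci <- find_ssrs(g, min_copies)
  if (!is.null(features_path)) {
    loci <- classify_ssr_context(loci, read_features(features_path))
  } else {
    warning("no annotation supplied; SSR context reported as NA", call. = FALSE)
  }
  write_ssr_tsv(loci, file.path(out_dir, "ssr.tsv"))
  st <- ssr_statistics(loci, g$length)
  df <- data.frame(statistic = c("count", "frequency_per_kb", "density_bp_per_kb",
                                 "percent"),
                   value = c(st$count, round(st$frequency_per_kb, 1L),
                             round(st$density_bp_per_kb, 1L), round(st$percent, 1L)))
  write_tsv_with_header(df, file.path(out_dir, "ssr_summary.tsv"),
                        sprintf("genome length %d bp", g$length))
  run_log(out_dir, "ssr", list(min_copies = min_copies),
          c(fasta_path, features_path))
  invisible(loci)
}

#' Maximal-repeat census of a genome
#'
#' Writes `repeats.tsv` (all maximal pairs) and `large_repeats.tsv`
#' (non-redundant pairs above `cutoff`) to `out_dir`.
#'
#' @param fasta_path FASTA path.
#' @param out_dir Output directory.
#' @param min_len Minimum repeat length (default 50).
#' @param cutoff Large-repeat cutoff (default 1 kb).
#' @param types Repeat classes, see [find_maximal_repeats()].
#' @return The large-repeat table, invisibly.
#' @export
cmd_repeats <- function(fasta_path, out_dir, min_len = 50L, cutoff = 1000L,
                        types = c("F", "P", "R", "C")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- read_fasta(fasta_path)[[1L]]
  pairs <- find_maximal_repeats(g, min_len = min_len, types = types)
  write_repeat_tsv(pairs, file.path(out_dir, "repeats.tsv"))
  big <- large_repeat_table(pairs, cutoff = cutoff)
  write_repeat_tsv(big, file.path(out_dir, "large_repeats.tsv"))
  df <- data.frame(statistic = "repeat_fraction_pct",
                   value = round(repeat_fraction(g, pairs), 1L))
  write_tsv_with_header(df, file.path(out_dir, "repeat_summary.tsv"),
                        sprintf("genome length %d bp", g$length))
  run_log(out_dir, "repeats",
          list(min_len = min_len, cutoff = cutoff, types = types), fasta_path)
  invisible(big)
}

#' Detect plastid-derived segments of a mitochondrial genome
#'
#' Writes `cp_derived.tsv` and a coverage summary to `out_dir`.
#'
#' @param mt_path,cp_path FASTA paths.
#' @param out_dir Output directory.
#' @param min_identity,min_len,max_e Filters, see [find_cp_derived()].
#' @return The segment table, invisibly.
#' @export
cmd_cpderived <- function(mt_path, cp_path, out_dir, min_identity = 0.80,
                          min_len = 50L, max_e = 1e-5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mt <- read_fasta(mt_path)[[1L]]
  cp <- read_fasta(cp_path)[[1L]]
  segs <- find_cp_derived(mt, cp, min_identity, min_len, max_e)
  write_cpderived_tsv(segs, file.path(out_dir, "cp_derived.tsv"))
  df <- data.frame(statistic = "cp_derived_pct",
                   value = round(cp_derived_fraction(segs, mt$length), 1L))
  write_tsv_with_header(df, file.path(out_dir, "cp_derived_summary.tsv"),
                        sprintf("mt length %d bp", mt$length))
  run_log(out_dir, "cpderived",
          list(min_identity = min_identity, min_len = min_len, max_e = max_e),
          c(mt_path, cp_path))
  invisible(segs)
}

#' Detect and report the quadripartite partition
#'
#' Writes `regions.tsv` (0-based half-open intervals) to `out_dir`.
#'
#' @param fasta_path FASTA path of a circular chloroplast genome.
#' @param out_dir Output directory.
#' @param min_ir Minimum inverted-repeat length.
#' @return The `RegionPartition`, invisibly.
#' @export
cmd_ir <- function(fasta_path, out_dir, min_ir = 1000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- read_fasta(fasta_path)[[1L]]
  part <- detect_ir_partition(g, min_ir = min_ir)
  rows <- do.call(rbind, lapply(c("lsc", "ssc", "ira", "irb"), function(nm) {
    m <- part[[nm]]
    if (!nrow(m)) return(NULL)
    data.frame(region = toupper(nm), start = m[, 1L], end = m[, 2L],
               stringsAsFactors = FALSE)
  }))
  write_tsv_with_header(rows, file.path(out_dir, "regions.tsv"),
                        "coordinates: 0-based half-open")
  run_log(out_dir, "ir", list(min_ir = min_ir), fasta_path)
  invisible(part)
}

#' Simulate an organellar genome pair
#'
#' Writes `ancestor.fasta`, `derived.fasta`, `features.gff3`,
#' `manifest.tsv` and `config.json` to `out_dir`. Deterministic: the same
#' seed and profile produce byte-identical files.
#'
#' @param out_dir Output directory.
#' @param profile Simulation profile, see [sim_config()].
#' @param seed Integer seed.
#' @param ... Further [sim_config()] overrides.
#' @return The simulation list, invisibly.
#' @export
cmd_simulate <- function(out_dir, profile = "cp-intersubspecific", seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(profile, seed = seed, ...)
  sim <- if (startsWith(profile, "mt")) generate_mt_pair(cfg)
  else generate_cp_pair(cfg)
  write_fasta(sim$ancestor, file.path(out_dir, "ancestor.fasta"))
  write_fasta(sim$derived, file.path(out_dir, "derived.fasta"))
  write_gff3(sim$features, file.path(out_dir, "features.gff3"),
             seqid = sim$ancestor$id)
  write_manifest(sim$manifest, file.path(out_dir, "manifest.tsv"))
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(sim)
}
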