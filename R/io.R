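#' Read genomes from a FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T` and any other IUPAC symbol
#' is collapsed to `N` with a warning, so real GenBank records always load.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param topology Topology assigned to every record; organellar genomes are
#'   circular, which is the default.
#' @return A named list of [genome()] objects in file order.
#' @export
read_fasta <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    stop_format(sprintf("empty FASTA file: %s", path))
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop_format(sprintf("malformed FASTA header at line %d of %s", first, path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_format(
                    sprintf("FASTA parse error in %s: %s", path, conditionMessage(e))))
  if (length(set) == 0L) stop_format(sprintf("no records in %s", path))
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  if (any(!nzchar(ids)))
    stop_format(sprintf("empty record id in %s", path))
  out <- lapply(seq_along(set), function(i) {
    genome(ids[i], as.character(set[[i]]), topology = topology)
  })
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#'
#' @param genomes A `Genome` or list of `Genome` objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "Genome")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, function(g) g$sequence, ""))
  names(seqs) <- vapply(genomes, function(g) g$id, "")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

FEATURE_KINDS <- c(gene = "gene", trna = "tRNA", rrna = "rRNA")

feature_kind <- function(type) {
  k <- FEATURE_KINDS[tolower(type)]
  ifelse(is.na(k), "other", k)
}

make_features <- function(name, kind, start, end, strand) {
  data.frame(name = as.character(name), kind = as.character(kind),
             start = as.integer(start), end = as.integer(end),
             strand = as.character(strand), stringsAsFactors = FALSE)
}

#' Read gene annotations
#'
#' Supports GFF3 and GenBank flat-file feature tables. Both dialects use
#' 1-based inclusive coordinates in the file; they are converted to the
#' package's 0-based half-open convention. Compound (joined) locations, as
#' used for features spanning the circular origin, are emitted as one row
#' per sub-interval sharing the feature name.
#'
#' @param path Annotation file.
#' @param format `"gff3"` or `"genbank"`.
#' @return A data frame with columns `name`, `kind` (`gene`, `tRNA`, `rRNA`
#'   or `other`), `start`, `end` (0-based half-open) and `strand`.
#' @export
read_features <- function(path, format = c("gff3", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  if (format == "gff3") read_features_gff3(path) else read_features_genbank(path)
}

read_features_gff3 <- function(path) {
  lines <- grep("^[^#]", readLines(path, warn = FALSE), value = TRUE)
  if (length(lines)) {
    fld <- strsplit(lines, "\t", fixed = TRUE)
    for (i in seq_along(fld)) {
      if (length(fld[[i]]) < 9L)
        stop_format(sprintf("GFF3 record with fewer than 9 columns in %s", path))
      s <- suppressWarnings(as.integer(fld[[i]][4L]))
      e <- suppressWarnings(as.integer(fld[[i]][5L]))
      if (is.na(s) || is.na(e) || e < s)
        stop_format(sprintf("invalid GFF3 interval %s..%s in %s",
                            fld[[i]][4L], fld[[i]][5L], path))
    }
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop_format(
                   sprintf("GFF3 parse error in %s: %s", path, conditionMessage(e))))
  if (length(gr) == 0L)
    return(make_features(character(), character(), integer(), integer(), character()))
  mc <- as.data.frame(S4Vectors::mcols(gr))
  pick <- function(col) if (col %in% names(mc)) as.character(mc[[col]]) else rep(NA_character_, length(gr))
  name <- pick("gene")
  name <- ifelse(is.na(name), pick("Name"), name)
  name <- ifelse(is.na(name), pick("ID"), name)
  name <- ifelse(is.na(name), paste0("feature", seq_along(gr)), name)
  make_features(
    name = name,
    kind = feature_kind(as.character(mc$type)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+")
  )
}

## Minimal parser for the FEATURES block of a GenBank flat file. Only the
## location and the /gene (or /product) qualifier are consumed; no installed
## package reads this dialect directly.
read_features_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fstart <- grep("^FEATURES", lines)
  if (length(fstart)) lines <- lines[(fstart[1L] + 1L):length(lines)]
  stop_at <- grep("^(ORIGIN|CONTIG|//)", lines)
  if (length(stop_at)) lines <- lines[seq_len(stop_at[1L] - 1L)]

  is_key <- grepl("^ {1,10}\\S", lines) & !grepl("^ {11,}", lines)
  rows <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!is_key[i]) { i <- i + 1L; next }
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    key <- parts[1L]
    loc <- paste(parts[-1L], collapse = "")
    j <- i + 1L
    quals <- character()
    while (j <= length(lines) && !is_key[j]) {
      txt <- trimws(lines[j])
      if (startsWith(txt, "/")) quals <- c(quals, txt)
      else if (!length(quals)) loc <- paste0(loc, txt)  # continued location
      j <- j + 1L
    }
    name <- NA_character_
    for (q in quals) {
      m <- regmatches(q, regexec('^/(gene|product)="?([^"]+)"?$', q))[[1L]]
      if (length(m) == 3L) { name <- m[3L]; break }
    }
    if (key != "source") {
      ivs <- parse_genbank_location(loc)
      if (is.null(ivs))
        stop_format(sprintf("cannot parse GenBank location '%s'", loc))
      for (r in seq_len(nrow(ivs)))
        rows[[length(rows) + 1L]] <- list(
          name = if (is.na(name)) key else name,
          kind = feature_kind(key),
          start = ivs$start[r], end = ivs$end[r],
          strand = if (ivs$comp[r]) "-" else "+")
    }
    i <- j
  }
  if (!length(rows))
    return(make_features(character(), character(), integer(), integer(), character()))
  out <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  make_features(out$name, out$kind, out$start, out$end, out$strand)
}

## "a..b", "complement(...)", "join(a..b,c..d)" and nestings thereof.
## Returns 0-based half-open intervals; NULL when unparseable.
parse_genbank_location <- function(loc) {
  comp <- FALSE
  loc <- gsub("[<>]", "", loc)
  repeat {
    if (grepl("^complement\\(.*\\)$", loc)) {
      comp <- TRUE
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    } else if (grepl("^join\\(.*\\)$", loc) || grepl("^order\\(.*\\)$", loc)) {
      loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    } else break
  }
  pieces <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  out <- lapply(pieces, function(p) {
    m <- regmatches(p, regexec("^(\\d+)(\\.\\.(\\d+))?$", p))[[1L]]
    if (!length(m)) return(NULL)
    s <- as.integer(m[2L])
    e <- if (nzchar(m[4L])) as.integer(m[4L]) else s
    if (e < s) stop_format(sprintf("GenBank location end < start: '%s'", p))
    data.frame(start = s - 1L, end = e, comp = comp)
  })
  if (any(vapply(out, is.null, TRUE))) return(NULL)
  do.call(rbind, out)
}

#' Write features as GFF3
#'
#' @param features Feature data frame as returned by [read_features()]
#'   (0-based half-open coordinates).
#' @param path Output path.
#' @param seqid Sequence name for column 1.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, seqid = "genome") {
  if (nrow(features) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  type <- c(gene = "gene", tRNA = "tRNA", rRNA = "rRNA", other = "misc_feature")[features$kind]
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand,
    type = unname(type),
    Name = features$name,
    ID = make.unique(features$name)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
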