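#' Genome objects
#'
#' A `Genome` is a named DNA sequence over the alphabet `{A, C, G, T, N}`
#' together with its topology. Circular genomes are stored linearised at
#' their deposited origin; origin-spanning logic is handled by callers
#' through [rotate_genome()]. All coordinates in this package are 0-based
#' half-open; report writers convert to the 1-based dialects of the output
#' tables.
#'
#' @param id Character label for the sequence.
#' @param sequence DNA string. Lower case is accepted, `U` is mapped to `T`,
#'   and any other IUPAC symbol is collapsed to `N` with a warning.
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `Genome` with fields `id`, `sequence`,
#'   `topology` and `length`.
#' @examples
#' g <- genome("toy", "acgtACGT")
#' g$length
#' @export
genome <- function(id, sequence, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_format("genome id must be a non-empty string")
  sequence <- normalize_sequence(sequence)
  structure(
    list(id = id, sequence = sequence, topology = topology,
         length = nchar(sequence)),
    class = "Genome"
  )
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("<Genome> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","), x$topology))
  invisible(x)
}

## Uppercase, U -> T, and collapse every other IUPAC symbol to N (real
## GenBank records occasionally carry R/Y/W/... and should still load).
normalize_sequence <- function(s, warn = TRUE) {
  if (!is.character(s) || length(s) != 1L)
    stop_format("sequence must be a single character string")
  s <- chartr("u", "T", toupper(s))
  s <- chartr("U", "T", s)
  bad <- gsub("[ACGTN]", "", s)
  if (nzchar(bad)) {
    if (warn)
      warning(sprintf("%d non-ACGTN symbol(s) collapsed to N (e.g. '%s')",
                      nchar(bad), substr(bad, 1, 1)), call. = FALSE)
    s <- gsub("[^ACGTN]", "N", s)
  }
  s
}

## Coerce a Genome or plain string to the sequence string.
as_seq <- function(x) {
  if (inherits(x, "Genome")) x$sequence
  else if (is.character(x) && length(x) == 1L) x
  else stop_format("expected a Genome or a single DNA string")
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement of the reversed sequence; `N` maps to `N`.
#' An involution: applying it twice returns the input.
#'
#' @param x A `Genome` or a single DNA string over `{A,C,G,T,N}`.
#' @return A character string.
#' @examples
#' reverse_complement("TC")      # "GA"
#' reverse_complement("GAAAAA")  # "TTTTTC"
#' @export
reverse_complement <- function(x) {
  s <- as_seq(x)
  if (grepl("[^ACGTN]", s))
    stop_format("sequence contains symbols outside {A,C,G,T,N}")
  if (!nzchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## Internal fast variants on plain strings (already validated).
revcomp <- function(s) {
  if (!nzchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
complement_seq <- function(s) chartr("ACGTN", "TGCAN", s)
reverse_seq <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

#' GC content of a genome
#'
#' `100 * (#G + #C) / (length - #N)`, i.e. ambiguous positions are excluded
#' from the denominator.
#'
#' @param x A `Genome` or DNA string.
#' @return Percentage (numeric scalar, full precision; reports round to one
#'   decimal).
#' @examples
#' gc_content("GGCC")  # 50
#' @export
gc_content <- function(x) {
  s <- as_seq(x)
  if (!nzchar(s)) stop_format("cannot compute GC content of an empty sequence")
  f <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("G", "C", "N"))
  denom <- nchar(s) - f[["N"]]
  if (denom == 0) stop_format("GC content undefined: sequence is all N")
  100 * (f[["G"]] + f[["C"]]) / denom
}

#' Rotate a circular genome to a new origin
#'
#' Returns the same circular sequence linearised so that old position
#' `offset` becomes position 0.
#'
#' @param g A circular `Genome`.
#' @param offset 0-based position of the new origin.
#' @return A `Genome`.
#' @export
rotate_genome <- function(g, offset) {
  stopifnot(inherits(g, "Genome"))
  if (g$topology != "circular")
    stop_format("only circular genomes can be rotated")
  offset <- as.integer(offset %% g$length)
  if (offset == 0L) return(g)
  s <- paste0(substr(g$sequence, offset + 1L, g$length),
              substr(g$sequence, 1L, offset))
  out <- g
  out$sequence <- s
  out
}
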