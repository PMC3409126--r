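test_that("FASTA round-trips byte-identically and normalises symbols", {
  set.seed(101)
  g1 <- genome("alpha", rand_seq(300))
  g2 <- genome("beta", paste0(rand_seq(100), "N", rand_seq(50)))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(list(g1, g2), path)
  back <- read_fasta(path)
  expect_identical(names(back), c("alpha", "beta"))
  expect_identical(back$alpha$sequence, g1$sequence)
  expect_identical(back$beta$sequence, g2$sequence)
  expect_identical(back$alpha$length, 300L)

  # case and U normalisation
  p2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "acgu"), p2)
  expect_identical(read_fasta(p2)$x$sequence, "ACGT")

  # other IUPAC symbols collapse to N with a warning
  p3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">y", "ACRGT"), p3)
  expect_warning(g <- read_fasta(p3)$y, "collapsed to N")
  expect_identical(g$sequence, "ACNGT")
})

test_that("malformed FASTA input raises format errors naming the problem", {
  p <- withr::local_tempfile(fileext = ".fasta")
  file.create(p)
  expect_error(read_fasta(p), class = "orgvar_format_error")
  writeLines(c("ACGT", ">x"), p)
  expect_error(read_fasta(p), "line 1", class = "orgvar_format_error")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")),
               class = "orgvar_format_error")
})

test_that("GFF3 features convert 1-based inclusive to 0-based half-open", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\t.\tgene\t101\t200\t.\t+\t.\tID=g1;Name=rbcL",
    "chr\t.\ttRNA\t301\t372\t.\t-\t.\tID=t1;Name=trnS-GCU"
  ), p)
  fx <- read_features(p)
  expect_identical(fx$start, c(100L, 300L))
  expect_identical(fx$end, c(200L, 372L))
  expect_identical(fx$kind, c("gene", "tRNA"))
  expect_identical(fx$name, c("rbcL", "trnS-GCU"))
  expect_identical(fx$strand, c("+", "-"))

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\t.\tgene\t200\t101\t.\t+\t.\tID=g1"), bad)
  expect_error(read_features(bad), class = "orgvar_format_error")
})

test_that("GenBank feature tables parse, including origin-spanning joins", {
  p <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "FEATURES             Location/Qualifiers",
    "     source          1..1000",
    "     gene            101..200",
    '                     /gene="psbA"',
    "     gene            join(950..1000,1..40)",
    '                     /gene="ori_gene"',
    "     tRNA            complement(300..372)",
    '                     /product="trnC-GCA"',
    "ORIGIN"
  ), p)
  fx <- read_features(p, format = "genbank")
  expect_identical(fx$name[fx$kind == "tRNA"], "trnC-GCA")
  expect_identical(fx$strand[fx$kind == "tRNA"], "-")
  ori <- fx[fx$name == "ori_gene", ]
  expect_identical(nrow(ori), 2L)       # split into two sub-intervals
  expect_identical(ori$start, c(949L, 0L))
  expect_identical(ori$end, c(1000L, 40L))
  expect_identical(fx$start[fx$name == "psbA"], 100L)
})

test_that("feature round trip through GFF3 preserves intervals", {
  fx <- data.frame(name = c("rbcL", "trnX"), kind = c("gene", "tRNA"),
                   start = c(10L, 500L), end = c(400L, 572L),
                   strand = c("+", "-"), stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(fx, p, seqid = "toy")
  back <- read_features(p)
  expect_identical(back$start, fx$start)
  expect_identical(back$end, fx$end)
  expect_identical(back$kind, fx$kind)
  expect_identical(back$name, fx$name)
})

test_that("reverse complement matches published examples and is an involution", {
  expect_identical(reverse_complement("TC"), "GA")
  expect_identical(reverse_complement("GAAAAA"), "TTTTTC")
  expect_identical(reverse_complement("N"), "N")
  set.seed(7)
  for (i in 1:50) {
    s <- rand_seq(sample(1:80, 1), with_n = TRUE)
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(nchar(reverse_complement(s)), nchar(s))
  }
  expect_error(reverse_complement("ACGQ"), class = "orgvar_format_error")
})

test_that("GC content excludes N from the denominator", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("GGAT"), 50)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCNN"), 100)   # 2 GC over 2 informative bases
  expect_error(gc_content("NNN"), class = "orgvar_format_error")
  expect_error(gc_content(""), class = "orgvar_format_error")
})

test_that("circular rotation relocates the origin and is reversible", {
  g <- genome("c", "AACCGGTT")
  r <- rotate_genome(g, 3)
  expect_identical(r$sequence, "CGGTTAAC")
  expect_identical(rotate_genome(r, g$length - 3)$sequence, g$sequence)
  lin <- genome("l", "ACGT", topology = "linear")
  expect_error(rotate_genome(lin, 1), class = "orgvar_format_error")
})
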