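test_that("substitution-run classification separates SNP, MNS and RCV", {
  for (p in RCV_CALLS)
    expect_identical(classify_substitution_run(p[1], p[2]), "RCV")
  for (p in MNS_CALLS)
    expect_identical(classify_substitution_run(p[1], p[2]), "MNS")
  expect_identical(classify_substitution_run("A", "G"), "SNP")
  # palindromic reference: revcomp(CG) == CG, so CG->GC cannot be an RCV
  expect_identical(classify_substitution_run("CG", "GC"), "MNS")
  expect_error(classify_substitution_run("AC", "A"), class = "orgvar_format_error")
  expect_error(classify_substitution_run("AC", "AG"), class = "orgvar_format_error")
})

test_that("transition/transversion classification is exhaustive over base pairs", {
  cls <- outer(DNA, DNA, Vectorize(function(a, b)
    if (a == b) NA_character_ else classify_snp(a, b)))
  tab <- table(cls[!is.na(cls)])
  expect_identical(as.integer(tab[["transition"]]), 4L)
  expect_identical(as.integer(tab[["transversion"]]), 8L)
  expect_identical(classify_snp("A", "G"), "transition")
  expect_identical(classify_snp("C", "G"), "transversion")
  expect_error(classify_snp("A", "A"), class = "orgvar_format_error")
})

test_that("adjacent substituted columns merge into one run", {
  set.seed(71)
  left <- rand_seq(40); right <- rand_seq(40)
  ref <- genome("r", paste0(left, "TA", right), topology = "linear")
  qry <- genome("q", paste0(left, "CC", right), topology = "linear")
  bl <- align_pair(ref, qry, min_match = 20)
  v <- extract_variants(bl, ref, qry)
  expect_identical(nrow(v), 1L)
  expect_identical(v$kind, "MNS")
  expect_identical(v$ref_pos, 40L)
  expect_identical(v$ref_allele, "TA")
  expect_identical(v$alt_allele, "CC")
  expect_identical(v$label, "S-2")
})

test_that("an all-match alignment yields no variants", {
  set.seed(72)
  g <- genome("g", rand_seq(500), topology = "linear")
  bl <- align_pair(g, g)
  expect_identical(nrow(extract_variants(bl, g, g)), 0L)
})

test_that("planted InDel composition is recovered with exact alleles", {
  sim <- generate_cp_pair(sim_config("cp-hybrid", seed = 5, cp_len = 30000L,
                                     ir_len = 4000L, ssc_len = 3000L,
                                     n_features = 10L))
  bl <- align_pair(sim$ancestor, sim$derived)
  v <- extract_variants(bl, sim$ancestor, sim$derived)
  expect_identical(sum(v$kind == "insertion"), 11L)
  expect_identical(sum(v$kind == "deletion"), 5L)
  expect_identical(sum(v$kind == "SNP"), 0L)
  sc <- score_recovery(v, sim$manifest)
  expect_identical(c(sc$precision, sc$recall), c(1, 1))
  expect_setequal(v$label[v$length > 1], c("I-4", "I-4", "D-2"))
})

test_that("variant annotation resolves genic, intergenic and region context", {
  fx <- make_features <- data.frame(
    name = c("rbcL", "accD", "ccsA"), kind = "gene",
    start = c(100L, 500L, 900L), end = c(300L, 700L, 1100L),
    strand = "+", stringsAsFactors = FALSE)
  v <- data.frame(kind = c("SNP", "SNP", "SNP"), label = "SNP",
                  ref_pos = c(150L, 400L, 1200L), qry_pos = c(150L, 400L, 1200L),
                  ref_allele = "A", alt_allele = "G", length = 1L,
                  orientation = "F", gene_context = NA_character_,
                  region = NA_character_, intravarietal = NA_character_,
                  stringsAsFactors = FALSE)
  out <- annotate_variants(v, fx)
  expect_identical(out$gene_context,
                   c("rbcL", "rbcL/accD", "ccsA/rbcL"))  # last wraps circularly
  expect_identical(annotate_variants(v, NULL)$gene_context,
                   rep(NA_character_, 3))

  sim <- generate_cp_pair(small_cp_config(61))
  part <- detect_ir_partition(sim$ancestor, min_ir = 1000L)
  bl <- align_pair(sim$ancestor, sim$derived)
  va <- annotate_variants(extract_variants(bl, sim$ancestor, sim$derived),
                          sim$features, part)
  expect_true(all(va$region %in% c("LSC", "SSC", "IRA", "IRB")))
  expect_identical(va$region, region_of(va$ref_pos, part))
  expect_false(any(is.na(va$gene_context)))
})

test_that("summary rates reproduce the published percentage arithmetic", {
  mk <- function(kind, n, ref = "A", alt = "G") {
    if (n == 0) return(NULL)
    data.frame(kind = kind, label = kind, ref_pos = seq_len(n) * 100L,
               qry_pos = seq_len(n) * 100L, ref_allele = ref, alt_allele = alt,
               length = nchar(ref), orientation = "F",
               gene_context = NA_character_, region = NA_character_,
               intravarietal = NA_character_, stringsAsFactors = FALSE)
  }
  s1 <- summarize_variants(mk("SNP", 110L), 134448L)
  expect_identical(sprintf("%.3f", s1$rates[["SNP"]]), "0.082")
  s2 <- summarize_variants(mk("SNP", 26L), 454820L)
  expect_identical(sprintf("%.3f", s2$rates[["SNP"]]), "0.006")
  s0 <- summarize_variants(mk("SNP", 1L)[0, ], 1000L)
  expect_true(all(s0$counts == 0L) && all(s0$rates == 0))
  expect_identical(s0$cumulative_delta, 0L)

  # Ts + Tv equals the SNP count on isolated SNPs
  v <- rbind(mk("SNP", 3L, "A", "G"), mk("SNP", 2L, "A", "C"),
             mk("MNS", 1L, "TA", "CC"))
  s3 <- summarize_variants(v, 1000L)
  expect_identical(s3$transitions + s3$transversions,
                   as.integer(s3$counts[["SNP"]]))
  expect_identical(s3$transitions, 3L)
  # exploding runs conserves the substituted-base tally
  s4 <- summarize_variants(v, 1000L, explode_runs = TRUE)
  expect_identical(s4$transitions + s4$transversions, 5L + 2L)
})

test_that("co-segregating cluster count equals the planted MNS run count", {
  v0 <- data.frame(kind = c("SNP", "SNP"), stringsAsFactors = FALSE)
  expect_identical(count_coseg_clusters(v0), 0L)
  for (s in 1:3) {
    sim <- generate_cp_pair(small_cp_config(s))
    bl <- align_pair(sim$ancestor, sim$derived)
    v <- extract_variants(bl, sim$ancestor, sim$derived)
    expect_identical(count_coseg_clusters(v),
                     sum(sim$manifest$events$type == "MNS"))
  }
})

test_that("variant-level invariants hold on simulated pairs", {
  for (s in 4:6) {
    sim <- generate_cp_pair(small_cp_config(s))
    bl <- align_pair(sim$ancestor, sim$derived)
    v <- extract_variants(bl, sim$ancestor, sim$derived)
    # no identical alleles, no reference overlap
    expect_false(any(v$ref_allele == v$alt_allele))
    ends <- v$ref_pos + ifelse(v$kind == "insertion", 0L, v$length)
    expect_true(all(v$ref_pos[-1] >= head(ends, -1)))
    # every RCV satisfies the reverse-complement identity; every MNS violates it
    rcv <- v[v$kind == "RCV", ]
    expect_true(all(mapply(function(r, a) reverse_complement(r) == a,
                           rcv$ref_allele, rcv$alt_allele)))
    mns <- v[v$kind == "MNS", ]
    expect_false(any(mapply(function(r, a) reverse_complement(r) == a,
                            mns$ref_allele, mns$alt_allele)))
    # cumulative InDel difference equals the genome length difference
    sm <- summarize_variants(v, sim$ancestor$length)
    expect_identical(sm$cumulative_delta,
                     sim$derived$length - sim$ancestor$length)
  }
})

test_that("overlapping blocks are rejected", {
  set.seed(77)
  g <- genome("g", rand_seq(300), topology = "linear")
  bl <- align_pair(g, g)
  expect_error(extract_variants(c(bl, bl), g, g),
               class = "orgvar_format_error")
})
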