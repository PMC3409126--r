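test_that("maximal exact matches handle identity and reverse complement", {
  m <- find_mems("ACGTACGTAC", "ACGTACGTAC", min_match = 10)
  fwd <- m[m$orientation == "F", ]
  expect_identical(nrow(fwd), 1L)
  expect_identical(unlist(fwd[1, c("pos_ref", "pos_qry", "length")],
                          use.names = FALSE), c(0L, 0L, 10L))

  set.seed(11)
  r <- rand_seq(60)
  m2 <- find_mems(r, reverse_complement(r), min_match = 60)
  expect_identical(nrow(m2), 1L)
  expect_identical(m2$orientation, "R")
  expect_identical(m2$length, 60L)
  expect_identical(m2$pos_qry, 0L)

  expect_error(find_mems("", "ACGT"), class = "orgvar_format_error")
})

test_that("MEM finder agrees with the exhaustive diagonal oracle", {
  set.seed(202)
  for (i in 1:30) {
    nr <- sample(50:200, 1); nq <- sample(50:200, 1)
    # correlated pairs so matches actually occur
    base <- rand_seq(max(nr, nq), with_n = (i %% 3 == 0))
    ref <- substr(base, 1, nr)
    qry <- if (i %% 2) paste0(substr(base, 5, nq + 4)) else rand_seq(nq)
    got <- find_mems(ref, qry, min_match = 8)
    want <- oracle_mems(ref, qry, 8)
    expect_identical(got[, c("pos_ref", "pos_qry", "length", "orientation")],
                     want)
    # every anchor re-verifies oriented substring equality
    for (k in seq_len(nrow(got))) {
      a <- got[k, ]
      rs <- substr(ref, a$pos_ref + 1, a$pos_ref + a$length)
      qs <- substr(qry, a$pos_qry + 1, a$pos_qry + a$length)
      if (a$orientation == "R") qs <- reverse_complement(qs)
      expect_identical(rs, qs)
    }
  }
})

test_that("chaining keeps the maximum-weight collinear subset", {
  # three mutually collinear anchors form one chain
  a <- data.frame(pos_ref = c(0L, 100L, 220L), pos_qry = c(0L, 105L, 230L),
                  length = c(50L, 60L, 40L), orientation = "F")
  ch <- chain_anchors(a, nq = 300L)
  expect_identical(length(ch), 1L)
  expect_identical(nrow(ch[[1]]), 3L)
  expect_identical(attr(ch[[1]], "weight"), 150L)

  # two crossing anchors: the 60 bp anchor dominates
  b <- data.frame(pos_ref = c(0L, 10L), pos_qry = c(200L, 0L),
                  length = c(60L, 50L), orientation = "F")
  chb <- chain_anchors(b, nq = 300L, min_chain_span = 100L)
  expect_identical(attr(chb[[1]], "weight"), 60L)
  expect_identical(chb[[1]]$length[1], 60L)

  expect_identical(chain_anchors(a[0, ], nq = 300L), list())

  # exhaustive best-subset oracle on random anchor sets
  set.seed(303)
  for (i in 1:10) {
    n <- 12L
    anc <- data.frame(pos_ref = sample(0:500, n), pos_qry = sample(0:500, n),
                      length = sample(10:60, n, replace = TRUE),
                      orientation = "F")
    got <- attr(chain_anchors(anc, nq = 600L)[[1]], "weight")
    expect_identical(as.integer(got), as.integer(oracle_chain_weight(anc)))
  }
})

test_that("gap closing resolves InDels and matches the DP distance oracle", {
  set.seed(404)
  left <- rand_seq(30); right <- rand_seq(30)
  ref <- genome("r", paste0(left, "ACGTT", right), topology = "linear")
  qry <- genome("q", paste0(left, "ACGT", right), topology = "linear")
  anchors <- find_mems(ref, qry, min_match = 20)
  chains <- chain_anchors(anchors, qry$length)
  blocks <- close_gaps(chains[[1]], ref, qry)
  expect_identical(length(blocks), 1L)
  ops <- blocks[[1]]$ops
  expect_identical(sum(blocks[[1]]$lens[ops == "D"]), 1L)  # one 1-base qry-gap
  expect_true(check_block_transcript(blocks[[1]], ref, qry))

  # identical gap content gives an all-match transcript
  g <- genome("g", rand_seq(200), topology = "linear")
  bl <- close_gaps(chain_anchors(find_mems(g, g, 50), g$length)[[1]], g, g)
  expect_identical(bl[[1]]$ops, "M")

  # unit-cost alignment distance equals the textbook DP (Levenshtein) oracle
  for (i in 1:50) {
    a <- rand_seq(sample(10:100, 1)); b <- rand_seq(sample(10:100, 1))
    al <- orgvar:::cpp_edit_align(a, b)
    expect_identical(al$dist,
                     as.integer(utils::adist(a, b)))
    # transcript consumes both strings exactly
    expect_identical(sum(al$lens[al$ops != 3L]), nchar(a))
    expect_identical(sum(al$lens[al$ops != 2L]), nchar(b))
  }
})

test_that("aligning a genome against itself yields one all-match forward block", {
  set.seed(505)
  g <- genome("self", rand_seq(5000))
  bl <- align_pair(g, g)
  expect_identical(length(bl), 1L)
  expect_identical(bl[[1]]$orientation, "F")
  expect_identical(bl[[1]]$ops, "M")
  expect_identical(bl[[1]]$ref_start, 0L)
  expect_identical(bl[[1]]$ref_end, g$length)
})

test_that("colinear simulated pairs resolve to one block tiling both genomes", {
  for (s in 1:3) {
    sim <- generate_cp_pair(small_cp_config(s))
    bl <- align_pair(sim$ancestor, sim$derived)
    expect_identical(length(bl), 1L)
    expect_identical(bl[[1]]$orientation, "F")
    cov_ref <- sum(vapply(bl, function(b) b$ref_end - b$ref_start, 0L))
    cov_qry <- sum(vapply(bl, function(b) b$qry_end - b$qry_start, 0L))
    expect_gte(cov_ref / sim$ancestor$length, 0.999)
    expect_gte(cov_qry / sim$derived$length, 0.999)
    expect_true(all(vapply(bl, check_block_transcript, TRUE,
                           sim$ancestor, sim$derived)))
  }
})

test_that("a planted inversion is recovered as a reverse-complement block", {
  sim <- generate_mt_pair(small_mt_config(21, inversion_count = 1L,
                                          inversion_len = 4000L))
  bl <- align_pair(sim$ancestor, sim$derived)
  orients <- vapply(bl, function(b) b$orientation, "")
  expect_identical(sum(orients == "R"), 1L)
  inv <- sim$manifest$events[sim$manifest$events$type == "inversion", ]
  rb <- bl[[which(orients == "R")]]
  expect_lt(abs(rb$ref_start - inv$ref_pos), 10L)
  expect_lt(abs((rb$ref_end - rb$ref_start) - inv$length), 20L)
})

test_that("circular rotation of the query is undone before comparison", {
  sim <- generate_cp_pair(small_cp_config(31))
  ## cut where the cumulative InDel offset is zero and no event is nearby,
  ## so the restored linearisation is exactly the original one
  ev <- sim$manifest$events
  stopifnot(min(ev$derived_pos) > 1000L)
  rotated <- rotate_genome(sim$derived, min(ev$derived_pos) - 500L)
  bl0 <- align_pair(sim$ancestor, sim$derived)
  bl1 <- align_pair(sim$ancestor, rotated)
  v0 <- extract_variants(bl0, sim$ancestor, sim$derived)
  qry_back <- rotate_genome(rotated, attr(bl1, "rotation"))
  v1 <- extract_variants(bl1, sim$ancestor, qry_back)
  expect_identical(v0[, c("kind", "ref_pos", "ref_allele", "alt_allele")],
                   v1[, c("kind", "ref_pos", "ref_allele", "alt_allele")])
})

test_that("quadripartite detection recovers planted IRs and rejects random input", {
  sim <- generate_cp_pair(small_cp_config(41))
  part <- detect_ir_partition(sim$ancestor, min_ir = 1000L)
  truth <- sim$manifest$partition
  for (nm in c("lsc", "ssc", "ira", "irb"))
    expect_identical(part[[nm]], truth[[nm]])
  expect_identical(sum(part$ira[, 2] - part$ira[, 1]) +
                     sum(part$irb[, 2] - part$irb[, 1]),
                   2L * sim$manifest$config$ir_len)
  # region lookup
  expect_identical(region_of(0L, part), "LSC")
  expect_identical(region_of(part$ira[1, 1], part), "IRA")
  expect_identical(region_of(part$irb[1, 1] + 5L, part), "IRB")

  set.seed(99)
  rnd <- genome("rnd", rand_seq(20000))
  expect_error(detect_ir_partition(rnd), class = "orgvar_no_quadripartite_error")
})
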