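test_that("planted duplications are reported in the right direction", {
  set.seed(808)
  x <- rand_seq(100)
  filler <- rand_seq(150)
  lin <- function(s) genome("t", s, topology = "linear")

  f <- find_maximal_repeats(lin(paste0("T", x, filler, x, "G")), min_len = 50)
  ff <- f[f$direction == "F", ]
  expect_identical(nrow(ff), 1L)
  expect_gte(ff$length, 100L)
  expect_lte(abs(ff$start1 - 1L), 1L)

  p <- find_maximal_repeats(lin(paste0("T", x, filler, reverse_complement(x), "G")),
                            min_len = 50)
  expect_identical(p$direction[which.max(p$length)], "P")
  expect_gte(max(p$length), 100L)
})

test_that("the scanner agrees with the all-pairs oracle on random strings", {
  set.seed(809)
  for (i in 1:30) {
    n <- sample(100:300, 1)
    base <- rand_seq(n)
    # plant relations of each kind into some trials
    s <- base
    if (i %% 4 == 1) {
      x <- substr(base, 10, 49)
      s <- paste0(base, x)                                # forward
    } else if (i %% 4 == 2) {
      x <- substr(base, 10, 49)
      s <- paste0(base, reverse_complement(x))            # palindromic
    } else if (i %% 4 == 3) {
      x <- chars(substr(base, 10, 49))
      s <- paste0(base, paste(rev(x), collapse = ""),     # reverse
                  paste(COMP_TAB[chars(substr(base, 60, 99))], collapse = ""))  # complement
    }
    g <- genome("t", s, topology = "linear")
    got <- find_maximal_repeats(g, min_len = 12)
    want <- oracle_repeats(s, 12)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("every reported pair re-verifies its relation and maximality", {
  set.seed(810)
  base <- rand_seq(250)
  x <- substr(base, 20, 80)
  s <- paste0(base, x, rand_seq(30), reverse_complement(x))
  pairs <- find_maximal_repeats(genome("t", s, topology = "linear"), min_len = 15)
  cv <- chars(s); n <- length(cv)
  for (k in seq_len(nrow(pairs))) {
    p <- pairs[k, ]
    s1 <- cv[(p$start1 + 1L):(p$start1 + p$length)]
    s2 <- cv[(p$start2 + 1L):(p$start2 + p$length)]
    t2 <- switch(p$direction, F = s2, P = rc_chars(s2), R = rev(s2),
                 C = unname(COMP_TAB[s2]))
    expect_identical(s1, t2)
    # simultaneous extension by one base must break the relation or a boundary
    lo1 <- p$start1; hi1 <- p$start1 + p$length
    lo2 <- p$start2; hi2 <- p$start2 + p$length
    if (p$direction == "F") {
      can_left <- lo1 > 0L && lo2 > 0L && cv[lo1] == cv[lo2]
      can_right <- hi1 < n && hi2 < n && cv[hi1 + 1L] == cv[hi2 + 1L]
      expect_false(can_left || can_right)
    }
    if (p$direction == "P") {
      can_left <- lo1 > 0L && hi2 < n && cv[lo1] == COMP_TAB[[cv[hi2 + 1L]]]
      can_right <- hi1 < n && lo2 > 0L && cv[hi1 + 1L] == COMP_TAB[[cv[lo2]]]
      expect_false(can_left || can_right)
    }
  }
})

test_that("origin-spanning repeats are found on circular genomes", {
  set.seed(811)
  x <- rand_seq(60)
  # copy 2 wraps: last 30 bases of the genome followed by its first 30
  s <- paste0(substr(x, 31, 60), rand_seq(120), x, rand_seq(90), substr(x, 1, 30))
  g <- genome("circ", s)
  pairs <- find_maximal_repeats(g, min_len = 50, types = "F")
  expect_gte(max(pairs$length), 60L)
  lin <- find_maximal_repeats(genome("lin", s, topology = "linear"),
                              min_len = 50, types = "F")
  expect_true(nrow(lin) == 0L || max(lin$length) < 60L)
})

test_that("the large-repeat table is non-redundant and ordered by length", {
  pairs <- data.frame(
    length = c(5000L, 1200L, 900L, 2000L),
    start1 = c(100L, 150L, 200L, 9000L),
    start2 = c(20000L, 20050L, 25000L, 30000L),
    direction = c("F", "F", "F", "P"), stringsAsFactors = FALSE)
  tbl <- large_repeat_table(pairs, cutoff = 1000L)
  # the 1200 bp pair is contained in the 5000 bp pair on both intervals
  expect_identical(tbl$length, c(5000L, 2000L))
  expect_identical(names(tbl), c("length", "start1", "direction", "start2"))
  full <- large_repeat_table(pairs, cutoff = 1000L, nonredundant = FALSE)
  expect_identical(full$length, c(5000L, 2000L, 1200L))
  expect_identical(nrow(large_repeat_table(pairs, cutoff = 10000L)), 0L)
})

test_that("repeat coverage fraction is a true interval union", {
  set.seed(812)
  g <- genome("g", rand_seq(1000), topology = "linear")
  expect_identical(repeat_fraction(g, find_maximal_repeats(g, min_len = 50)), 0)
  # two identical halves: the whole genome is covered
  h <- rand_seq(500)
  g2 <- genome("g2", paste0(h, h), topology = "linear")
  pairs <- find_maximal_repeats(g2, min_len = 50)
  expect_equal(repeat_fraction(g2, pairs), 100)
  # planted coverage equals the union of planted intervals
  x <- rand_seq(200)
  g3 <- genome("g3", paste0(x, rand_seq(300), x, rand_seq(300)), topology = "linear")
  fr <- repeat_fraction(g3, find_maximal_repeats(g3, min_len = 50))
  expect_equal(fr, 100 * 400 / 1000, tolerance = 0.02)
})
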