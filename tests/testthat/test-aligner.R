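# internal aligner: scoring statistics, exact DP, seed-and-extend,
# filters, FPR table, homology graph

test_that("lambda solves the Karlin-Altschul identity (bisection oracle)", {
  sch <- scoring_scheme()
  f <- function(l) 0.25 * exp(2 * l) + 0.75 * exp(-3 * l) - 1
  lo <- 1e-6; hi <- 4
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  expect_lt(abs(sch$lambda - (lo + hi) / 2), 1e-6)
  expect_gt(sch$K, 0)
})

test_that("smith_waterman handles the elementary cases", {
  sch <- scoring_scheme()
  h <- smith_waterman("ACGTACGT", "ACGTACGT", sch)
  expect_equal(h$score, 16)
  expect_equal(h$identity, 1)
  expect_equal(h$aln_length, 8)
  expect_equal(nrow(smith_waterman("AAAA", "TTTT", sch)), 0)
  expect_equal(nrow(smith_waterman("", "ACGT", sch)), 0)
})

test_that("smith_waterman scores match an independent local aligner", {
  sch <- scoring_scheme()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  set.seed(20)
  for (i in 1:50) {
    a <- rseq(sample(20:60, 1))
    b <- rseq(sample(20:60, 1))
    pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    h <- smith_waterman(a, b, sch)
    expect_equal(if (nrow(h)) h$score else 0,
                 max(0, Biostrings::score(pa)))
  }
})

test_that("E-values scale linearly in search space and geometrically in score", {
  sch <- scoring_scheme()
  expect_equal(evalue(30, 100, 2000, sch), 2 * evalue(30, 100, 1000, sch))
  expect_equal(evalue(30, 200, 1000, sch), 2 * evalue(30, 100, 1000, sch))
  expect_equal(evalue(31, 100, 1000, sch) / evalue(30, 100, 1000, sch),
               exp(-sch$lambda))
  # non-positive scores report the nominal (large) value, never clamped
  expect_gte(evalue(0, 50, 50, sch), sch$K * 50 * 50)
})

test_that("seed_extend finds a planted exact copy in a large random target", {
  set.seed(21)
  sch <- scoring_scheme()
  q <- rseq(100)
  t <- paste0(rseq(50000), q, rseq(50000))
  h <- seed_extend_search(q, t, sch)
  expect_gte(nrow(h), 1)
  expect_equal(h$identity[1], 1)
  expect_gte(h$aln_length[1], 100)
  expect_lte(h$aln_length[1], 110)
  expect_lte(h$t_start[1], 50001)
  expect_gte(h$t_end[1], 50100)
})

test_that("reverse-complement targets hit on the minus strand, same score", {
  set.seed(22)
  sch <- scoring_scheme()
  q <- rseq(300)
  t <- paste0(rseq(2000), q, rseq(2000))
  hf <- seed_extend_search(q, t, sch)
  hr <- seed_extend_search(q, rc_dna(t), sch)
  expect_equal(hr$score[1], hf$score[1])
  expect_identical(hr$strand[1], "-")
})

test_that("seed_extend is symmetric in query and target best score", {
  set.seed(23)
  sch <- scoring_scheme()
  for (i in 1:5) {
    core <- rseq(150)
    a <- paste0(rseq(500), core, rseq(400))
    b <- paste0(rseq(300), core, rseq(600))
    h1 <- seed_extend_search(a, b, sch)
    h2 <- seed_extend_search(b, a, sch)
    expect_equal(h1$score[1], h2$score[1])
  }
})

test_that("filter_hits enforces the three survey cutoffs exactly", {
  # alignment length: 24 rejected, 25 kept, at otherwise perfect stats
  h <- rbind(synthetic_hit(24), synthetic_hit(25))
  expect_equal(filter_hits(h)$aln_length, 25L)
  # identity: 0.59 rejected, 0.60 kept
  h <- rbind(synthetic_hit(50, identity = 0.59),
             synthetic_hit(50, identity = 0.60))
  expect_equal(filter_hits(h)$identity, 0.60)
  # E-value: strict < 0.1
  h <- rbind(synthetic_hit(50, evalue = 0.1),
             synthetic_hit(50, evalue = 0.0999))
  expect_equal(filter_hits(h)$evalue, 0.0999)
})

test_that("hits touching the telomere mask by one position are excluded", {
  h <- synthetic_hit(50, t_start = 1000) # target interval 1000-1049
  mask1 <- data.frame(target_id = "t", start = 1049L, end = 1200L)
  mask0 <- data.frame(target_id = "t", start = 1050L, end = 1200L)
  expect_equal(nrow(filter_hits(h, telomere_mask = mask1)), 0)
  expect_equal(nrow(filter_hits(h, telomere_mask = mask0)), 1)
  # mask on another contig never applies
  mask2 <- data.frame(target_id = "other", start = 1L, end = 1e6)
  expect_equal(nrow(filter_hits(h, telomere_mask = mask2)), 1)
})

test_that("filter_hits is idempotent and order-preserving", {
  set.seed(24)
  h <- do.call(rbind, lapply(1:40, function(i)
    synthetic_hit(sample(10:80, 1), identity = runif(1, 0.4, 1),
                  evalue = 10^runif(1, -12, 1), t_start = i * 100)))
  f1 <- filter_hits(h)
  expect_identical(filter_hits(f1), f1)
  expect_true(!is.unsorted(match(f1$t_start, h$t_start)))
})

test_that("the FPR table matches hand counts and a brute-force recount", {
  truth <- data.frame(target_id = "t", start = 5000L, end = 6000L)
  h <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      synthetic_hit(100, t_start = 5100 + i))),   # true, length 100
    do.call(rbind, lapply(1:5, function(i)
      synthetic_hit(30, t_start = 100 * i))))     # false, length 30
  tab <- estimate_fpr_by_length(h, truth)
  expect_equal(tab$fpr[tab$length_threshold == 25], 0.5)
  expect_equal(tab$fpr[tab$length_threshold == 50], 0)
  # brute-force recount on a random hit set
  set.seed(25)
  h2 <- do.call(rbind, lapply(1:60, function(i)
    synthetic_hit(sample(25:150, 1), t_start = sample(1:20000, 1))))
  tab2 <- estimate_fpr_by_length(h2, truth)
  for (r in seq_len(nrow(tab2))) {
    L <- tab2$length_threshold[r]
    sel <- h2[h2$aln_length >= L, ]
    is_false <- !(sel$t_end >= 5000 & sel$t_start <= 6000)
    expect_equal(tab2$n_hits[r], nrow(sel))
    expect_equal(tab2$fpr[r], sum(is_false) / nrow(sel))
  }
  expect_equal(nrow(estimate_fpr_by_length(h[0, ], truth)), 0)
})

test_that("homology graph edges carry inverse-hit-length weights", {
  h <- synthetic_hit(50)
  h$query_id <- "A"; h$target_id <- "B"
  status <- c(A = "literature", B = "identified", C = "candidate")
  g <- build_homology_graph(h, status)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 1 / 50)
  expect_equal(igraph::vcount(g), 3)
  expect_false(igraph::are_adjacent(g, "A", "C"))
  expect_identical(igraph::V(g)$status[match("A", igraph::V(g)$name)],
                   "literature")
  # the best (longest) hit defines the weight when several link a pair
  h2 <- rbind(h, within(synthetic_hit(80), {
    query_id <- "A"; target_id <- "B"
  }))
  g2 <- build_homology_graph(h2, status)
  expect_equal(igraph::E(g2)$weight, 1 / 80)
})

test_that("chance hits on dinucleotide decoys are as rare as E predicts", {
  set.seed(26)
  sch <- scoring_scheme()
  pos <- replicate(6, rseq(400))
  dec <- make_decoy_set(pos, 2)
  n_search <- 0; n_sig <- 0
  for (p in pos) for (d in dec) {
    h <- seed_extend_search(p, d, sch, min_score = 15)
    n_search <- n_search + 1
    n_sig <- n_sig + sum(h$evalue < 0.02)
  }
  # expected about 0.02 per search; allow an order of magnitude
  expect_lte(n_sig, 10 * 0.02 * n_search)
})
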