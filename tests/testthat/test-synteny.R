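# synteny-anchored projection of a locus between genomes

two_gene_genome <- function(species = "A", n = 4000,
                            g1 = c(100, 500), g2 = c(3000, 3500),
                            strands = c("+", "-"), og = c("OG1", "OG2"),
                            seed = 30) {
  set.seed(seed)
  genome(species, setNames(rseq(n), paste0(species, "_c1")),
         data.frame(gene_id = paste0(species, c("_a", "_b")),
                    contig_id = paste0(species, "_c1"),
                    start = c(g1[1], g2[1]), end = c(g1[2], g2[2]),
                    strand = strands, ortholog_group = og,
                    stringsAsFactors = FALSE))
}

test_that("flanking_anchors returns the nearest ortholog-labelled genes", {
  gA <- two_gene_genome()
  a <- flanking_anchors(gA, c(1000, 2000), "A_c1")
  expect_identical(a$left$gene_id, "A_a")
  expect_identical(a$right$gene_id, "A_b")
})

test_that("a locus at the contig start is unanchored", {
  gA <- two_gene_genome()
  expect_error(flanking_anchors(gA, c(10, 50), "A_c1"), "unanchored")
})

test_that("a locus overlapping a gene is rejected", {
  gA <- two_gene_genome()
  expect_error(flanking_anchors(gA, c(400, 900), "A_c1"), "overlaps")
})

test_that("genes without ortholog groups are skipped with a message", {
  gA <- two_gene_genome()
  gA$genes$ortholog_group[2] <- NA
  gA$genes <- rbind(gA$genes,
                    data.frame(gene_id = "A_d", contig_id = "A_c1",
                               start = 3600, end = 3800, strand = "+",
                               ortholog_group = "OG3"))
  expect_message(a <- flanking_anchors(gA, c(1000, 2000), "A_c1"),
                 "without ortholog group")
  expect_identical(a$right$gene_id, "A_d")
})

test_that("projecting a locus into its own genome contains the locus", {
  gA <- two_gene_genome()
  a <- flanking_anchors(gA, c(1000, 2000), "A_c1")
  si <- project_interval(a, gA)
  expect_s3_class(si, "synteny_interval")
  expect_lte(si$start, 1000)
  expect_gte(si$end, 2000)
  expect_identical(si$orientation, "same")
})

test_that("anchors split across contigs break the projection", {
  gA <- two_gene_genome()
  a <- flanking_anchors(gA, c(1000, 2000), "A_c1")
  set.seed(31)
  gB <- genome("B", c(B_c1 = rseq(2000), B_c2 = rseq(2000)),
               data.frame(gene_id = c("B_a", "B_b"),
                          contig_id = c("B_c1", "B_c2"),
                          start = c(100, 100), end = c(500, 500),
                          strand = c("+", "-"),
                          ortholog_group = c("OG1", "OG2"),
                          stringsAsFactors = FALSE))
  expect_null(project_interval(a, gB))
})

test_that("too many intervening genes break the projection", {
  gA <- two_gene_genome()
  a <- flanking_anchors(gA, c(1000, 2000), "A_c1")
  gB <- two_gene_genome("B", seed = 32)
  extra <- do.call(rbind, lapply(1:4, function(i)
    data.frame(gene_id = paste0("B_x", i), contig_id = "B_c1",
               start = 600 + i * 300, end = 700 + i * 300, strand = "+",
               ortholog_group = paste0("OGX", i))))
  gB$genes <- rbind(gB$genes, extra)
  expect_null(project_interval(a, gB, max_intervening = 3))
  expect_s3_class(project_interval(a, gB, max_intervening = 4),
                  "synteny_interval")
})

test_that("flipped anchor order with flipped strands reads as inverted", {
  gA <- two_gene_genome()
  a <- flanking_anchors(gA, c(1000, 2000), "A_c1")
  # in B the segment is inverted: OG2 comes first and each strand flips
  # (A has OG1 on "+", OG2 on "-"; inverting flips both)
  gB <- two_gene_genome("B", strands = c("+", "-"), og = c("OG2", "OG1"),
                        seed = 33)
  si <- project_interval(a, gB)
  expect_identical(si$orientation, "inverted")
  # order flipped but strands unchanged: the signals disagree
  gC <- two_gene_genome("C", strands = c("-", "+"), og = c("OG2", "OG1"),
                        seed = 34)
  expect_warning(siC <- project_interval(a, gC), "disagree")
  expect_identical(siC$orientation, "inverted")
})

test_that("extract_region returns the sequence with its genomic offset", {
  g <- genome("Z", c(Z_c1 = strrep("A", 30)))
  si <- structure(list(species = "Z", contig = "Z_c1", start = 11L,
                       end = 20L, anchor_left = "x", anchor_right = "y",
                       orientation = "same", slack = 0L),
                  class = "synteny_interval")
  r <- extract_region(g, si)
  expect_equal(nchar(r$seq), 10)
  expect_equal(r$offset, 11L)
})

test_that("local/genomic coordinate mapping round-trips both orientations", {
  set.seed(35)
  for (i in 1:50) {
    L <- sample(50:500, 1)
    offset <- sample(1:10000, 1)
    s <- sample(seq_len(L - 5), 1)
    e <- s + sample(0:4, 1)
    for (strand in c("pos", "neg")) {
      gv <- local_to_genomic(s, e, offset, L, strand)
      back <- genomic_to_local(gv[1], gv[2], offset, L, strand)
      expect_equal(back, c(s, e))
      expect_true(gv[1] <= gv[2])
    }
  }
})

test_that("projected anchors and intervals match the simulator's truth", {
  for (seed in c(3, 7, 12)) {
    sim <- simulate_clade(clade_sim_config(seed = seed))
    tr <- as.data.frame(sim$truth)
    ref <- tr[1, ]
    a <- flanking_anchors(sim$genomes[[ref$species]],
                          c(ref$ter_start, ref$ter_end), ref$accession)
    expect_identical(a$left$gene_id, ref$anchor_left)
    expect_identical(a$right$gene_id, ref$anchor_right)
    for (i in 2:nrow(tr)) {
      tg <- tr[i, ]
      si <- project_interval(a, sim$genomes[[tg$species]])
      expect_false(is.null(si))
      expect_identical(c(si$anchor_left, si$anchor_right),
                       c(tg$anchor_left, tg$anchor_right))
      expect_lte(si$start, tg$ter_start)
      expect_gte(si$end, tg$ter_end)
    }
  }
})
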