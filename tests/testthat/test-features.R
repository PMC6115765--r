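# feature cascade: SM motif, 3'-end rule, hairpin surrogates, assembly

hairpin_seq <- function(arm_len, loop) {
  arm <- rseq(arm_len)
  paste0(arm, loop, rc_dna(arm))
}

test_that("scan_sm finds the motif and equals an exhaustive Hamming scan", {
  set.seed(40)
  s <- paste0(rseq(39), "AATTTTTGG", rseq(60))
  h <- scan_sm(s, 0)
  expect_equal(h$start[1], 40)
  expect_equal(h$end[1], 48)
  expect_equal(h$mismatches[1], 0)
  expect_equal(nrow(scan_sm(strrep("C", 200), 2)), 0)
  # oracle: brute-force Hamming distance at every offset
  for (mm in 0:2) {
    for (rep in 1:10) {
      s <- paste0(rseq(120), "AATTTTTGG", rseq(30), "AATTTATGG", rseq(50))
      got <- scan_sm(s, mm)
      motif <- strsplit("AATTTTTGG", "")[[1]]
      ch <- strsplit(s, "")[[1]]
      want <- integer(0)
      for (p in 1:(nchar(s) - 8))
        if (sum(ch[p:(p + 8)] != motif) <= mm) want <- c(want, p)
      expect_setequal(got$start, want)
    }
  }
})

test_that("N never matches a motif position", {
  s <- paste0(strrep("G", 20), "AATTTTTGN", strrep("G", 20))
  expect_equal(nrow(scan_sm(s, 0)), 0)
  expect_equal(nrow(scan_sm(s, 1)), 1)
})

test_that("the 3' end sits 10 nt downstream of SM on either strand", {
  expect_equal(assign_three_prime(c(991, 1000), "pos"), 1010L)
  expect_equal(assign_three_prime(c(1000, 1009), "neg"), 990L)
  expect_warning(p <- assign_three_prime(c(991, 1000), "pos",
                                         contig_length = 1005),
                 "clamped")
  expect_equal(p, 1005L)
})

test_that("find_ku_hairpin needs GCTA and recovers a planted hairpin", {
  set.seed(41)
  ku <- hairpin_seq(10, paste0("AT", "GCTA", "CC"))
  win <- paste0(rseq(150), ku, rseq(120))
  s <- paste0(win, "TTTTTT")
  tpl_start <- nchar(win) + 3
  h <- find_ku_hairpin(s, tpl_start)
  expect_false(is.null(h))
  expect_lte(abs(h$start - 151), 3)
  expect_lte(abs(h$end - (150 + nchar(ku))), 3)
  # a window with no GCTA at all is a negative call
  win2 <- gsub("GCTA", "GGGG", win, fixed = TRUE)
  expect_null(find_ku_hairpin(paste0(win2, "TTTTTT"), tpl_start))
})

test_that("shuffled Ku windows are rejected in at least 90% of trials", {
  set.seed(42)
  ku <- hairpin_seq(10, paste0("AT", "GCTA", "CC"))
  win <- paste0(rseq(150), ku, rseq(120))
  nulls <- 0
  for (i in 1:100) {
    shuf <- make_decoy_set(win, 1)
    if (is.null(find_ku_hairpin(paste0(shuf, "T"), nchar(win) + 2)))
      nulls <- nulls + 1
  }
  expect_gte(nulls, 90)
})

test_that("find_est1 recovers a planted P3-like hairpin within +-5 nt", {
  set.seed(43)
  est1 <- hairpin_seq(12, rseq(6))
  s <- paste0(rseq(60), est1, rseq(60))
  h <- find_est1(s, c(1, nchar(s)))
  expect_false(is.null(h))
  expect_lte(abs(h$start - 61), 5)
  expect_lte(abs(h$end - (60 + nchar(est1))), 5)
  expect_gte(h$score, 0.6)
  expect_null(find_est1(strrep("A", 200), c(1, 200)))
  expect_warning(expect_null(find_est1(rseq(30), c(1, 30))), "shorter")
})

test_that("find_twj distinguishes structural and sequence-only calls", {
  set.seed(44)
  block <- paste0(hairpin_seq(8, rseq(6)), rseq(12), "AATA", rseq(12),
                  hairpin_seq(8, rseq(6)))
  s <- paste0(rseq(80), block, rseq(80))
  h <- find_twj(s, c(1, nchar(s)))
  expect_false(is.null(h))
  expect_identical(h$evidence, "AATA with flanking hairpins")
  expect_lte(abs(h$start - 81), 5)
  expect_lte(abs(h$end - (80 + nchar(block))), 5)
  # no AATA anywhere: NULL
  s2 <- gsub("AATA", "GGCC", s, fixed = TRUE)
  expect_null(find_twj(s2, c(1, nchar(s2))))
  # AATA with destroyed flanking structure: sequence-only, score 0
  s3 <- paste0(strrep("ACG", 60), "AATA", strrep("CGA", 60))
  h3 <- find_twj(s3, c(1, nchar(s3)))
  expect_identical(h3$evidence, "sequence-only")
  expect_equal(h3$score, 0)
  expect_equal(h3$end - h3$start + 1, 4)
})

test_that("annotate_ter recovers all planted features near the truth", {
  sim <- simulate_clade(clade_sim_config(seed = 3))
  # exercise leaves whose planted template island is still unmutated (the
  # robustness of the whole pipeline to island drift is measured separately
  # by the clade-recovery suite)
  intact <- which(vapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- as.data.frame(sim$truth)[i, ]
    tpl <- substr(sim$genomes[[tr$species]]$contigs[[tr$accession]],
                  tr$template_start, tr$template_end)
    if (tr$strand == "neg") tpl <- rc_dna(tpl)
    tpl == rc_dna("TTAGGGTTA")
  }, logical(1)))
  expect_gte(length(intact), 2)
  for (i in intact[1:2]) {
    tr <- as.data.frame(sim$truth)[i, ]
    g <- sim$genomes[[tr$species]]
    off <- max(1L, tr$ter_start - 400L)
    cand <- list(seq = substr(g$contigs[[tr$accession]], off,
                              tr$ter_end + 400),
                 offset = off, contig = tr$accession, inverted = FALSE)
    ann <- suppressWarnings(annotate_ter(cand, "TTAGGG",
                                         species = tr$species))
    expect_false(is.null(ann))
    expect_identical(ann$strand, tr$strand)
    for (f in c("ku", "template", "est1", "twj", "sm1")) {
      expect_lte(abs(ann[[paste0(f, "_start")]] -
                       tr[[paste0(f, "_start")]]), 5)
      expect_lte(abs(ann[[paste0(f, "_end")]] - tr[[paste0(f, "_end")]]), 5)
    }
    # nesting invariant and transcript order on the annotation itself
    starts <- unlist(ann[paste0(c("ku", "template", "est1", "twj", "sm1"),
                                "_start")])
    ends <- unlist(ann[paste0(c("ku", "template", "est1", "twj", "sm1"),
                              "_end")])
    expect_true(all(starts >= ann$ter_start & ends <= ann$ter_end,
                    na.rm = TRUE))
    ord <- starts[!is.na(starts)]
    if (tr$strand == "neg") ord <- rev(ord)
    expect_true(!is.unsorted(ord))
  }
})

test_that("a candidate with template but no SM is flagged incomplete", {
  set.seed(45)
  cand <- list(seq = paste0(rseq(300), rc_dna("TTAGGGTTA"), rseq(300)),
               offset = 1000L, contig = "c1", inverted = FALSE)
  ann <- suppressWarnings(annotate_ter(cand, "TTAGGG"))
  expect_false(is.null(ann))
  expect_true(is.na(ann$sm1_start))
  expect_true("incomplete" %in% attr(ann, "flags"))
})

test_that("a candidate with neither template nor SM evidence is rejected", {
  expect_null(annotate_ter(list(seq = strrep("CG", 400), offset = 1L,
                                contig = "c1", inverted = FALSE), "TTAGGG"))
})
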