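# the synthetic-clade generator: reproducibility, Jukes-Cantor calibration,
# island conservation, truth bookkeeping under indels, decoy shuffles

test_that("identical config and seed reproduce the clade byte-for-byte", {
  cfg <- clade_sim_config(seed = 42)
  s1 <- simulate_clade(cfg)
  s2 <- simulate_clade(cfg)
  expect_identical(lapply(s1$genomes, `[[`, "contigs"),
                   lapply(s2$genomes, `[[`, "contigs"))
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
})

test_that("zero branch length is the identity", {
  set.seed(1)
  s <- rseq(500)
  cfg <- clade_sim_config(seed = 1)
  map <- data.frame(name = "x", start = 10L, end = 40L, island = TRUE)
  out <- evolve_sequence(s, 0, map, cfg)
  expect_identical(out$seq, s)
  expect_identical(out$map, map)
})

test_that("negative branch lengths are rejected", {
  cfg <- clade_sim_config(seed = 1)
  expect_error(evolve_sequence("ACGT", -0.1,
                               data.frame(name = character(),
                                          start = integer(), end = integer(),
                                          island = logical()), cfg),
               "negative")
})

test_that("substitution counts match the Jukes-Cantor expectation", {
  # rate 0.5, t = 1: per-site difference p = 3/4 (1 - exp(-4/3 * 0.5))
  set.seed(7)
  L <- 10000
  s <- rseq(L)
  cfg <- clade_sim_config(seed = 1, background_sub_rate = 0.5,
                          island_sub_rate = 0.001, indel_rate = 0)
  out <- evolve_sequence(s, 1, data.frame(name = character(),
                                          start = integer(),
                                          end = integer(),
                                          island = logical()), cfg)
  p <- 0.75 * (1 - exp(-4 / 3 * 0.5))
  obs <- sum(strsplit(s, "")[[1]] != strsplit(out$seq, "")[[1]])
  expect_lt(abs(obs - L * p), 3 * sqrt(L * p * (1 - p)))
})

test_that("a zero-rate island survives any branch verbatim", {
  set.seed(3)
  s <- rseq(4000)
  cfg <- clade_sim_config(seed = 1, background_sub_rate = 0.9,
                          island_sub_rate = 0, indel_rate = 0.05)
  map <- data.frame(name = "island", start = 1500L, end = 1600L,
                    island = TRUE)
  out <- evolve_sequence(s, 2, map, cfg)
  expect_identical(substr(out$seq, out$map$start, out$map$end),
                   substr(s, 1500, 1600))
})

test_that("islands stay closer to the ancestor than background", {
  cfg <- clade_sim_config(seed = 1, background_sub_rate = 0.6,
                          island_sub_rate = 0.03, indel_rate = 0)
  island_id <- numeric(0); back_id <- numeric(0)
  for (seed in 1:20) {
    set.seed(seed)
    s <- rseq(3000)
    map <- data.frame(name = c("a", "b"), start = c(501L, 2001L),
                      end = c(700L, 2200L), island = TRUE)
    out <- evolve_sequence(s, 0.5, map, cfg)
    v0 <- strsplit(s, "")[[1]]; v1 <- strsplit(out$seq, "")[[1]]
    isl <- c(501:700, 2001:2200)
    island_id <- c(island_id, mean(v0[isl] == v1[isl]))
    back_id <- c(back_id, mean(v0[-isl] == v1[-isl]))
  }
  expect_gt(mean(island_id), mean(back_id))
  expect_gt(mean(island_id), 0.97)
})

test_that("planted truth stays valid after evolution with indels", {
  for (seed in c(2, 5, 9)) {
    sim <- simulate_clade(clade_sim_config(seed = seed))
    tr <- as.data.frame(sim$truth)
    for (i in seq_len(nrow(tr))) {
      g <- sim$genomes[[tr$species[i]]]
      clen <- nchar(g$contigs[[tr$accession[i]]])
      expect_gte(tr$ter_start[i], 1)
      expect_lte(tr$ter_end[i], clen)
      for (f in c("ku", "template", "est1", "twj", "sm1")) {
        s <- tr[[paste0(f, "_start")]][i]
        expect_gte(s, tr$ter_start[i])
        expect_lte(tr[[paste0(f, "_end")]][i], tr$ter_end[i])
      }
      # the planted SM island is intact up to island-rate drift
      sm <- substr(g$contigs[[tr$accession[i]]], tr$sm1_start[i],
                   tr$sm1_end[i])
      if (tr$strand[i] == "neg") sm <- rc_dna(sm)
      expect_lte(adist(sm, "AATTTTTGG")[1, 1], 1)
      # 3' end sits 10 nt downstream of SM in transcript orientation
      off <- if (tr$strand[i] == "pos") tr$ter_end[i] - tr$sm1_end[i] else
        tr$sm1_start[i] - tr$ter_start[i]
      expect_equal(off, 10)
    }
  }
})

test_that("ancestor contigs carry telomeric arrays and the planted elements", {
  set.seed(11)
  cfg <- clade_sim_config(seed = 11, telomere_unit = "TTAGGG")
  anc <- generate_ancestor(cfg)
  c1 <- anc$contigs[[1]]
  expect_true(endsWith(c1$seq, strrep("TTAGGG", 3)))
  expect_true(startsWith(c1$seq, rc_dna(strrep("TTAGGG", 3))))
  sm <- c1$map[c1$map$name == "sm1", ]
  sm_seq <- substr(c1$seq, sm$start, sm$end)
  if (anc$meta$ter_strand == "neg") sm_seq <- rc_dna(sm_seq)
  expect_identical(sm_seq, "AATTTTTGG")
})

test_that("a contig too short for the planted elements is a hard error", {
  expect_error(simulate_clade(clade_sim_config(seed = 1,
                                               contig_length = 4000)),
               "too short")
})

test_that("decoy sets are dinucleotide-preserving shuffles", {
  set.seed(4)
  pos <- replicate(6, rseq(120))
  dec <- make_decoy_set(pos, 2)
  expect_length(dec, 12)
  for (i in seq_along(pos)) {
    for (j in c(2 * i - 1, 2 * i)) {
      expect_equal(nchar(dec[j]), nchar(pos[i]))
      expect_equal(dinuc_counts(dec[j]), dinuc_counts(pos[i]))
    }
  }
})

test_that("single-state sequences shuffle to themselves; short ones error", {
  expect_identical(make_decoy_set("AAAA", 1), "AAAA")
  expect_error(make_decoy_set("AC", 1), "shorter")
})
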