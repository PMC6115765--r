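# shared helpers: tiny fixtures built in code, independent count oracles

rseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")

dinuc_counts <- function(s) {
  v <- strsplit(s, "")[[1]]
  di <- paste0(v[-length(v)], v[-1])
  table(factor(di, levels = as.vector(outer(c("A", "C", "G", "T"),
                                            c("A", "C", "G", "T"),
                                            paste0))))
}

# one-row hit table with chosen stats (for filter probes)
synthetic_hit <- function(aln_length, identity = 1, evalue = 1e-12,
                          t_start = 1000, query_id = "q", target_id = "t") {
  data.frame(query_id = query_id, target_id = target_id,
             identity = identity, aln_length = as.integer(aln_length),
             mismatches = 0L, gaps = 0L,
             q_start = 1L, q_end = as.integer(aln_length),
             t_start = as.integer(t_start),
             t_end = as.integer(t_start + aln_length - 1L),
             strand = "+", score = 100L, evalue = evalue,
             stringsAsFactors = FALSE)
}

# write a minimal FASTA + GFF3 + ortholog TSV; returns the three paths
write_mini_genome <- function(dir, contig_seq = strrep("ACGTAC", 10),
                              gene_start = 10, gene_end = 30,
                              og = "OG1", contig = "chr1",
                              gene_id = "gene1", prefix = "mini") {
  fa <- file.path(dir, paste0(prefix, ".fa"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  tsv <- file.path(dir, paste0(prefix, "_og.tsv"))
  writeLines(c(paste0(">", contig), contig_seq), fa)
  writeLines(c("##gff-version 3",
               sprintf("%s\ttest\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       contig, gene_start, gene_end, gene_id)), gff)
  writeLines(c("gene_id\tortholog_group", paste0(gene_id, "\t", og)), tsv)
  list(fasta = fa, gff3 = gff, tsv = tsv)
}

# simulate a clade and survey it from one seeded leaf; rate_mult scales all
# divergence parameters together (the homology-decay axis)
run_sim_survey <- function(seed, rate_mult = 1, supply_unit = FALSE) {
  cfg <- clade_sim_config(seed = seed,
                          background_sub_rate = 0.6 * rate_mult,
                          island_sub_rate = 0.03 * rate_mult,
                          indel_rate = 0.02 * rate_mult)
  sim <- simulate_clade(cfg)
  known <- sim$truth[sim$truth$species == "sp1", ]
  class(known) <- c("ter_table", "data.frame")
  sv <- suppressWarnings(run_survey(
    sim$genomes, known, sim$tree,
    repeat_unit = if (supply_unit) cfg$telomere_unit else NULL,
    seed = seed))
  list(sim = sim, survey = sv,
       metrics = score_recovery(sv$annotations, sim$truth))
}
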