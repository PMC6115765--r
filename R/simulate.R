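# Synthetic clades with planted TER loci. The generator emulates the regime
# that makes TER hard to find: rapid background divergence with short
# conserved islands (the functional elements), telomeric tandem arrays at
# contig ends, and conserved protein-coding anchor genes delimiting the
# locus. Islands are indel-free so planted truth stays exact under
# coordinate remapping.

#' Configuration for a simulated clade
#'
#' Rates are substitutions per site per unit branch length under
#' Jukes-Cantor; indels are geometric with the given mean length and never
#' fall inside conserved islands (features, genes, telomere arrays).
#'
#' @param tree rooted newick string (or ape "phylo") with branch lengths
#' @param n_contigs,contig_length contigs per genome and their length (nt)
#' @param background_sub_rate,island_sub_rate substitution rates for fast
#'   background sequence and conserved islands (island < background)
#' @param indel_rate expected indel events per background site per unit
#'   branch length
#' @param mean_indel_len mean indel length (geometric)
#' @param ter_length_range planted TER length bounds (nt), within 200..5000
#' @param telomere_unit G-rich-strand telomeric repeat unit for the clade
#' @param anchor_gene_length length of each anchor gene (nt)
#' @param telomere_copies tandem copies planted at each contig end
#' @param seed integer seed; the whole simulation is reproducible from it
#' @return a list of class "clade_sim_config"
#' @export
clade_sim_config <- function(tree = default_clade_tree(),
                             n_contigs = 2, contig_length = 12000,
                             background_sub_rate = 0.6,
                             island_sub_rate = 0.03,
                             indel_rate = 0.02, mean_indel_len = 3,
                             ter_length_range = c(750, 2000),
                             telomere_unit = "TTAGGG",
                             anchor_gene_length = 500,
                             telomere_copies = 10,
                             seed = 1) {
  stopifnot(island_sub_rate < background_sub_rate,
            ter_length_range[1] >= 200, ter_length_range[2] <= 5000,
            ter_length_range[1] <= ter_length_range[2],
            indel_rate >= 0, mean_indel_len >= 1,
            n_contigs >= 1, grepl("^[ACGT]{2,30}$", telomere_unit))
  structure(list(tree = tree, n_contigs = n_contigs,
                 contig_length = contig_length,
                 background_sub_rate = background_sub_rate,
                 island_sub_rate = island_sub_rate,
                 indel_rate = indel_rate, mean_indel_len = mean_indel_len,
                 ter_length_range = ter_length_range,
                 telomere_unit = telomere_unit,
                 anchor_gene_length = anchor_gene_length,
                 telomere_copies = telomere_copies, seed = seed),
            class = "clade_sim_config")
}

#' Default 6-leaf guide tree for simulations
#' @return a newick string
#' @export
default_clade_tree <- function() {
  "((sp1:0.1,sp2:0.1):0.08,((sp3:0.1,sp4:0.1):0.08,(sp5:0.1,sp6:0.1):0.08):0.05);"
}

random_hairpin <- function(arm_len, loop) {
  arm <- random_dna(arm_len)
  paste0(arm, loop, rc_dna(arm))
}

# Build the planted TER cassette in transcript orientation.
# Layout (5'->3'): 200 nt flank | Ku hairpin | s1 | template | s2 |
# Est1 hairpin | s3 | TWJ block (hairpin-AATA-hairpin) | s4 | SM | 10 nt.
make_ter_cassette <- function(config) {
  unit <- config$telomere_unit
  k <- nchar(unit)
  ku <- random_hairpin(10, paste0(random_dna(2), "GCTA", random_dna(2)))
  tpl <- rc_dna(paste0(unit, substr(unit, 1, max(3, k %/% 2))))
  est1 <- random_hairpin(12, random_dna(6))
  twj <- paste0(random_hairpin(8, random_dna(6)),
                random_dna(sample(8:20, 1)), "AATA",
                random_dna(sample(8:20, 1)),
                random_hairpin(8, random_dna(6)))
  sm <- "AATTTTTGG"
  s1 <- sample(60:280, 1)
  s2 <- sample(60:250, 1)
  fixed <- 200 + nchar(ku) + s1 + nchar(tpl) + s2 + nchar(est1) +
    nchar(twj) + nchar(sm) + 10
  target <- sample(config$ter_length_range[1]:config$ter_length_range[2], 1)
  rem <- max(80, target - fixed)
  s3 <- sample(40:max(40, rem - 40), 1)
  s4 <- max(40, rem - s3)
  parts <- list(
    list(seq = random_dna(200), name = NA, island = FALSE),
    list(seq = ku, name = "ku", island = TRUE),
    list(seq = random_dna(s1), name = NA, island = FALSE),
    list(seq = tpl, name = "template", island = TRUE),
    list(seq = random_dna(s2), name = NA, island = FALSE),
    list(seq = est1, name = "est1", island = TRUE),
    list(seq = random_dna(s3), name = NA, island = FALSE),
    list(seq = twj, name = "twj", island = TRUE),
    list(seq = random_dna(s4), name = NA, island = FALSE),
    list(seq = sm, name = "sm1", island = TRUE),
    list(seq = random_dna(10), name = "ter3p", island = TRUE))
  seq <- paste(vapply(parts, `[[`, "", "seq"), collapse = "")
  pos <- 1L
  feats <- list()
  for (p in parts) {
    w <- nchar(p$seq)
    if (!is.na(p$name))
      feats[[p$name]] <- c(pos, pos + w - 1L)
    pos <- pos + w
  }
  list(seq = seq, feats = feats, length = nchar(seq))
}

# Assemble one contig from parts; returns seq plus a tracking map.
assemble_parts <- function(parts) {
  seq <- paste(vapply(parts, `[[`, "", "seq"), collapse = "")
  pos <- 1L
  rows <- list()
  for (p in parts) {
    w <- nchar(p$seq)
    if (!is.na(p$name))
      rows[[length(rows) + 1L]] <-
        data.frame(name = p$name, start = pos, end = pos + w - 1L,
                   island = p$island, stringsAsFactors = FALSE)
    pos <- pos + w
  }
  map <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), start = integer(), end = integer(),
               island = logical(), stringsAsFactors = FALSE)
  list(seq = seq, map = map)
}

#' Generate the ancestral genome with one planted TER locus
#'
#' Each contig carries telomeric tandem arrays at both ends; contig 1
#' additionally carries six anchor genes with unique ortholog groups and one
#' TER cassette between the designated anchor pair (genes 3 and 4). The TER
#' is inserted in inverted orientation with probability 0.5.
#'
#' Uses the session RNG; callers wanting reproducibility should
#' `set.seed()` first ([simulate_clade()] does).
#'
#' @param config a [clade_sim_config()]
#' @return a list with elements `contigs` (per contig: seq + tracking map)
#'   and `meta` (gene strands/groups, TER strand, anchor ids)
#' @export
generate_ancestor <- function(config) {
  unit <- config$telomere_unit
  tel_g <- strrep(unit, config$telomere_copies)
  tel_left <- rc_dna(tel_g) # C-rich strand reads forward at the left end
  glen <- config$anchor_gene_length
  cass <- make_ter_cassette(config)
  ter_strand <- if (runif(1) < 0.5) "pos" else "neg"
  cass_seq <- cass$seq
  cass_feats <- cass$feats
  if (ter_strand == "neg") {
    L <- cass$length
    cass_seq <- rc_dna(cass_seq)
    cass_feats <- lapply(cass_feats, function(iv) c(L - iv[2] + 1L,
                                                    L - iv[1] + 1L))
  }
  sp <- function() list(seq = random_dna(sample(250:400, 1)), name = NA,
                        island = FALSE)
  gene <- function(id) list(seq = random_dna(glen),
                            name = paste0("gene:", id), island = TRUE)
  big_sp <- function() list(seq = random_dna(600), name = NA, island = FALSE)
  parts1 <- list(
    list(seq = tel_left, name = "tel", island = TRUE), sp(),
    gene("g1"), sp(), gene("g2"), sp(), gene("g3"), big_sp())
  # TER cassette parts with cassette-local features re-anchored below
  parts1 <- c(parts1, list(list(seq = cass_seq, name = "tercass",
                                island = FALSE)))
  parts1 <- c(parts1, list(big_sp(), gene("g4"), sp(), gene("g5"), sp(),
                           gene("g6")))
  used <- sum(vapply(parts1, function(p) nchar(p$seq), numeric(1))) +
    nchar(tel_g)
  filler <- config$contig_length - used
  if (filler < 50)
    stop(sprintf("contig too short to host all elements (need >= %d nt)",
                 used + 50))
  parts1 <- c(parts1, list(list(seq = random_dna(filler), name = NA,
                                island = FALSE),
                           list(seq = tel_g, name = "tel", island = TRUE)))
  c1 <- assemble_parts(parts1)
  # replace the cassette placeholder by feature islands + ter span
  cass_row <- which(c1$map$name == "tercass")
  cass_off <- c1$map$start[cass_row]
  c1$map <- c1$map[-cass_row, ]
  feat_rows <- do.call(rbind, lapply(names(cass_feats), function(nm)
    data.frame(name = nm, start = cass_off + cass_feats[[nm]][1] - 1L,
               end = cass_off + cass_feats[[nm]][2] - 1L,
               island = TRUE, stringsAsFactors = FALSE)))
  ter_row <- data.frame(name = "ter", start = cass_off,
                        end = cass_off + cass$length - 1L, island = FALSE,
                        stringsAsFactors = FALSE)
  c1$map <- rbind(c1$map, feat_rows, ter_row)
  c1$map <- c1$map[order(c1$map$start), ]
  contigs <- list(c1)
  og <- 7L
  if (config$n_contigs > 1) {
    for (ci in 2:config$n_contigs) {
      parts <- list(list(seq = tel_left, name = "tel", island = TRUE), sp(),
                    gene(paste0("g", og)), sp(), gene(paste0("g", og + 1L)))
      used <- sum(vapply(parts, function(p) nchar(p$seq), numeric(1))) +
        nchar(tel_g)
      filler <- max(50, config$contig_length - used)
      parts <- c(parts, list(list(seq = random_dna(filler), name = NA,
                                  island = FALSE),
                             list(seq = tel_g, name = "tel", island = TRUE)))
      contigs[[ci]] <- assemble_parts(parts)
      og <- og + 2L
    }
  }
  n_genes <- og - 1L
  meta <- list(ter_strand = ter_strand,
               anchor_left = "g3", anchor_right = "g4",
               gene_strand = setNames(rep(c("+", "-"),
                                          length.out = n_genes),
                                      paste0("g", seq_len(n_genes))),
               ortholog = setNames(paste0("OG", seq_len(n_genes)),
                                   paste0("g", seq_len(n_genes))))
  list(contigs = contigs, meta = meta)
}

#' Evolve a sequence along a branch
#'
#' Jukes-Cantor substitutions at `background_sub_rate` outside islands and
#' `island_sub_rate` inside them; geometric indels (mean
#' `mean_indel_len`) in background only. All tracked intervals in the map
#' are remapped for upstream indels.
#'
#' @param seq nucleotide string
#' @param branch_length branch length (>= 0)
#' @param island_map data.frame with columns name, start, end, island;
#'   rows with `island = TRUE` are conserved and indel-free
#' @param config a [clade_sim_config()] supplying the rates
#' @return list(seq, map) with the evolved sequence and remapped intervals
#' @export
evolve_sequence <- function(seq, branch_length, island_map, config) {
  if (branch_length < 0) stop("negative branch length")
  if (branch_length == 0) return(list(seq = seq, map = island_map))
  ch <- s2c(seq)
  L <- length(ch)
  rate <- rep(config$background_sub_rate, L)
  isl <- island_map[island_map$island, , drop = FALSE]
  in_island <- rep(FALSE, L)
  for (k in seq_len(nrow(isl))) {
    rate[isl$start[k]:isl$end[k]] <- config$island_sub_rate
    in_island[isl$start[k]:isl$end[k]] <- TRUE
  }
  # JC69: per-site substitution probability over the branch
  p <- 0.75 * (1 - exp(-4 / 3 * rate * branch_length))
  mutable <- ch %in% c("A", "C", "G", "T")
  hit <- which(runif(L) < p & mutable)
  if (length(hit)) {
    alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                    "A", "C", "G"), nrow = 4, byrow = TRUE,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pick <- sample.int(3, length(hit), replace = TRUE)
    ch[hit] <- alt[cbind(match(ch[hit], rownames(alt)), pick)]
  }
  # indels in background only, mutually disjoint
  n_ind <- rpois(1, config$indel_rate * branch_length * sum(!in_island))
  ins_after <- integer(L)  # inserted length after original position i
  ins_seq <- vector("list", L)
  deleted <- rep(FALSE, L)
  blocked <- in_island
  for (e in seq_len(n_ind)) {
    for (try in 1:25) {
      len <- rgeom(1, 1 / config$mean_indel_len) + 1L
      if (runif(1) < 0.5) { # insertion after position p
        p0 <- sample.int(L - 1L, 1)
        if (blocked[p0] && blocked[p0 + 1L]) next
        if (ins_after[p0] > 0) next
        ins_after[p0] <- len
        ins_seq[[p0]] <- random_dna(len)
        break
      } else { # deletion [p0, p0+len-1]
        p0 <- sample.int(L, 1)
        p1 <- p0 + len - 1L
        if (p1 > L) next
        if (any(blocked[p0:p1]) || any(deleted[p0:p1])) next
        deleted[p0:p1] <- TRUE
        break
      }
    }
  }
  keep <- !deleted
  new_index <- cumsum(keep)          # new position of surviving base i
  cum_ins <- c(0L, cumsum(ins_after))[seq_len(L)] # insertions before pos i
  remap <- function(p, side = "start") {
    base <- new_index[p] + cum_ins[p]
    if (deleted[p]) {
      if (side == "start") base + 1L else base
    } else base
  }
  pieces <- character(0)
  # rebuild sequence with insertions
  out <- ch[keep]
  ins_at <- which(ins_after > 0)
  if (length(ins_at)) {
    # splice insertions by building segments between insertion points
    segs <- list()
    prev <- 1L
    for (q in ins_at) {
      segs[[length(segs) + 1L]] <- ch[prev:q][keep[prev:q]]
      segs[[length(segs) + 1L]] <- s2c(ins_seq[[q]])
      prev <- q + 1L
    }
    if (prev <= L) segs[[length(segs) + 1L]] <- ch[prev:L][keep[prev:L]]
    out <- unlist(segs)
  }
  map <- island_map
  if (nrow(map)) {
    map$start <- vapply(seq_len(nrow(map)),
                        function(i) remap(island_map$start[i], "start"),
                        integer(1))
    map$end <- vapply(seq_len(nrow(map)),
                      function(i) remap(island_map$end[i], "end"),
                      integer(1))
  }
  list(seq = c2s(out), map = map)
}

#' Simulate a clade of genomes with planted TER loci
#'
#' One genome per tree leaf, evolved from a single ancestor along the tree;
#' fully reproducible from `config$seed`.
#'
#' @param config a [clade_sim_config()]
#' @return a list with `genomes` (named list of [genome()] objects), `truth`
#'   (a "ter_table" data.frame with extra columns anchor_left/anchor_right
#'   giving the flanking anchor gene ids per leaf), `tree` (ape phylo), and
#'   `config`
#' @export
simulate_clade <- function(config) {
  tree <- if (inherits(config$tree, "phylo")) config$tree else
    ape::read.tree(text = config$tree)
  if (is.null(tree) || length(tree$tip.label) < 2)
    stop("tree must have at least 2 leaves")
  set.seed(config$seed)
  anc <- generate_ancestor(config)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- anc$contigs
  genomes <- list()
  truth_rows <- list()
  # preorder traversal: parents before children
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  ord <- reorder(tree, "cladewise")$edge
  for (ei in seq_len(nrow(ord))) {
    parent <- ord[ei, 1]; child <- ord[ei, 2]
    bl <- tree$edge.length[which(tree$edge[, 1] == parent &
                                   tree$edge[, 2] == child)]
    st <- states[[parent]]
    states[[child]] <- lapply(st, function(ct)
      evolve_sequence(ct$seq, bl, ct$map, config))
    if (child <= ntip) {
      sp_name <- tree$tip.label[child]
      res <- leaf_to_genome(sp_name, states[[child]], anc$meta, config)
      genomes[[sp_name]] <- res$genome
      truth_rows[[sp_name]] <- res$truth
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  class(truth) <- c("ter_table", "data.frame")
  list(genomes = genomes, truth = truth, tree = tree, config = config)
}

leaf_to_genome <- function(sp_name, contigs, meta, config) {
  contig_ids <- paste0(sp_name, "_c", seq_along(contigs))
  seqs <- setNames(vapply(contigs, `[[`, "", "seq"), contig_ids)
  gene_rows <- list()
  for (ci in seq_along(contigs)) {
    map <- contigs[[ci]]$map
    g <- map[startsWith(map$name, "gene:"), , drop = FALSE]
    if (!nrow(g)) next
    base <- sub("^gene:", "", g$name)
    gene_rows[[ci]] <- data.frame(
      gene_id = paste0(sp_name, "_", base),
      contig_id = contig_ids[ci], start = g$start, end = g$end,
      strand = unname(meta$gene_strand[base]),
      ortholog_group = unname(meta$ortholog[base]),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  gm <- genome(sp_name, seqs, genes)
  map1 <- contigs[[1]]$map
  iv <- function(nm) {
    r <- map1[map1$name == nm, , drop = FALSE]
    if (!nrow(r)) c(NA_integer_, NA_integer_) else c(r$start[1], r$end[1])
  }
  ter <- iv("ter"); sm <- iv("sm1")
  truth <- data.frame(species = sp_name, accession = contig_ids[1],
                      strand = meta$ter_strand, stringsAsFactors = FALSE)
  for (f in c("ter", TER_FEATURES)) {
    v <- iv(f)
    truth[[paste0(f, "_start")]] <- v[1]
    truth[[paste0(f, "_end")]] <- v[2]
  }
  truth$coord_citation <- FALSE
  truth$anchor_left <- paste0(sp_name, "_", meta$anchor_left)
  truth$anchor_right <- paste0(sp_name, "_", meta$anchor_right)
  list(genome = gm, truth = truth)
}

#' Dinucleotide-preserving shuffled decoys
#'
#' Each decoy is an Altschul-Erikson dinucleotide-preserving shuffle of one
#' positive sequence: identical length, mononucleotide and dinucleotide
#' composition. Uses the session RNG.
#'
#' @param positives character vector of sequences (each >= 3 nt)
#' @param decoys_per_positive decoys generated per positive (default 2)
#' @return character vector of length
#'   `length(positives) * decoys_per_positive`
#' @export
make_decoy_set <- function(positives, decoys_per_positive = 2) {
  stopifnot(length(positives) >= 1, decoys_per_positive >= 1)
  if (any(nchar(positives) < 3))
    stop("sequences shorter than 3 nt cannot be dinucleotide-shuffled")
  unlist(lapply(positives, function(p)
    vapply(seq_len(decoys_per_positive), function(i) dinuc_shuffle(p), "")))
}

# Altschul-Erikson shuffle: random Eulerian path in the dinucleotide
# multigraph, via the arborescence-of-last-edges construction.
dinuc_shuffle <- function(s) {
  ch <- s2c(s)
  n <- length(ch)
  verts <- unique(ch)
  if (length(verts) == 1L) return(s)
  first <- ch[1]; last <- ch[n]
  edges <- split(ch[-1], factor(ch[-n], levels = verts))
  inner <- setdiff(verts, last)
  for (attempt in 1:1000) {
    last_edge <- vapply(inner, function(v) {
      out <- edges[[v]]
      out[sample.int(length(out), 1)]
    }, "")
    # every inner vertex must reach `last` via chosen last-edges
    ok <- all(vapply(inner, function(v) {
      seen <- character(0)
      while (v != last) {
        if (v %in% seen) return(FALSE)
        seen <- c(seen, v)
        v <- last_edge[[v]]
      }
      TRUE
    }, logical(1)))
    if (ok) break
    if (attempt == 1000) stop("dinucleotide shuffle failed to converge")
  }
  lists <- lapply(verts, function(v) {
    out <- edges[[v]]
    if (v %in% inner) {
      # remove one instance of the chosen last edge, shuffle, re-append it
      i <- match(last_edge[[v]], out)
      rest <- out[-i]
      c(rest[sample.int(length(rest))], last_edge[[v]])
    } else {
      out[sample.int(length(out))]
    }
  })
  names(lists) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1] <- first
  v <- first
  for (i in 2:n) {
    nxt <- lists[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    res[i] <- nxt
    v <- nxt
  }
  c2s(res)
}

#' Write a simulated clade to disk
#'
#' Emits per-genome FASTA and GFF3, a combined ortholog TSV, and the truth
#' table in the survey-table schema (plus anchor columns), all consumable by
#' [load_genome()] and [load_ter_table()].
#'
#' @param sim result of [simulate_clade()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_clade <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  og_rows <- list()
  for (sp in names(sim$genomes)) {
    g <- sim$genomes[[sp]]
    ss <- Biostrings::DNAStringSet(g$contigs)
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(sp, ".fa")),
                                width = 80)
    lines <- "##gff-version 3"
    for (k in seq_len(nrow(g$genes)))
      lines <- c(lines, sprintf(
        "%s\ttersim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
        g$genes$contig_id[k], g$genes$start[k], g$genes$end[k],
        g$genes$strand[k], g$genes$gene_id[k]))
    writeLines(lines, file.path(dir, paste0(sp, ".gff3")))
    og_rows[[sp]] <- g$genes[, c("gene_id", "ortholog_group")]
  }
  og <- do.call(rbind, og_rows)
  write.table(og, file.path(dir, "orthologs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_truth_table(sim$truth, file.path(dir, "truth.tsv"))
  if (inherits(sim$tree, "phylo"))
    ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}

write_truth_table <- function(truth, path) {
  out <- data.frame(species = truth$species, accession = truth$accession,
                    strand = truth$strand, stringsAsFactors = FALSE)
  for (f in c("ter", TER_FEATURES))
    out[[f]] <- format_interval(truth[[paste0(f, "_start")]],
                                truth[[paste0(f, "_end")]])
  out$coord_citation <- truth$coord_citation
  if (!is.null(truth$anchor_left)) {
    out$anchor_left <- truth$anchor_left
    out$anchor_right <- truth$anchor_right
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
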