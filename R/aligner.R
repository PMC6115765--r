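# Internal BLAST-like local alignment: exact-word seeding, cluster-wise
# optimal extension, Karlin-Altschul E-values, the survey's hit filters,
# empirical FPR by alignment length, and the homology graph.

#' Scoring scheme with Karlin-Altschul parameters
#'
#' Defaults re-express blastn defaults: match +2, mismatch -3, gap
#' existence 5, gap extension 2 (a gap of length L costs 5 + 2L). `lambda`
#' is the unique positive root of
#' \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1} under a uniform
#' background, found numerically; `K` is calibrated once per scheme by a
#' deterministic Gumbel-median fit on random ungapped alignments (cached).
#'
#' @param match,mismatch,gap_open,gap_extend integer scoring parameters
#' @return a list of class "scoring_scheme" with the parameters plus
#'   `lambda` and `K`
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = 5,
                           gap_extend = 2) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend > 0)
  lambda <- ka_lambda(match, mismatch)
  K <- ka_K(match, mismatch, lambda)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

# positive root of (1/4) e^(lambda*match) + (3/4) e^(lambda*mismatch) = 1
ka_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(1e-8, hi), tol = 1e-12)$root
}

# K from the Gumbel location of max ungapped segment scores on random
# sequence pairs: P(M <= x) = exp(-K m n e^(-lambda x)), so
# K = ln 2 * e^(lambda * median(M)) / (m n). Deterministic private RNG.
ka_K <- function(match, mismatch, lambda, n_rep = 49, len = 800) {
  key <- paste(match, mismatch, sep = "/")
  hit <- .ters_cache$K[[key]]
  if (!is.null(hit)) return(hit)
  scores <- with_private_seed(990127, {
    vapply(seq_len(n_rep), function(i)
      cpp_max_segment(random_dna(len), random_dna(len), match, mismatch),
      integer(1))
  })
  K <- log(2) * exp(lambda * median(scores)) / (as.numeric(len)^2)
  if (is.null(.ters_cache$K)) .ters_cache$K <- list()
  .ters_cache$K[[key]] <- K
  K
}

#' Karlin-Altschul E-value
#'
#' \eqn{E = K m n e^{-\lambda S}}: strictly decreasing in the score and
#' linear in each search-space dimension. Non-positive scores report the
#' (large) nominal value rather than being clamped.
#'
#' @param score raw alignment score
#' @param m,n query and target lengths (> 0)
#' @param scheme a [scoring_scheme()]
#' @return the expected number of chance hits at or above `score`
#' @export
evalue <- function(score, m, n, scheme = scoring_scheme()) {
  stopifnot(m > 0, n > 0)
  scheme$K * as.numeric(m) * as.numeric(n) * exp(-scheme$lambda * score)
}

empty_hits <- function() {
  data.frame(query_id = character(), target_id = character(),
             identity = numeric(), aln_length = integer(),
             mismatches = integer(), gaps = integer(),
             q_start = integer(), q_end = integer(),
             t_start = integer(), t_end = integer(),
             strand = character(), score = integer(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Exact quadratic DP; intended for oracle-scale inputs (product of lengths
#' bounded) and for polishing seed clusters.
#'
#' @param a,b sequences
#' @param scheme a [scoring_scheme()]
#' @param query_id,target_id labels carried into the hit row
#' @return a one-row hit data.frame, or an empty frame if no
#'   positive-scoring alignment exists
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme(),
                           query_id = "query", target_id = "target") {
  if (!nzchar(a) || !nzchar(b)) return(empty_hits())
  r <- cpp_sw_align(a, b, scheme$match, scheme$mismatch, scheme$gap_open,
                    scheme$gap_extend)
  if (r$score <= 0) return(empty_hits())
  data.frame(query_id = query_id, target_id = target_id,
             identity = r$matches / r$length, aln_length = r$length,
             mismatches = r$length - r$matches - r$gaps, gaps = r$gaps,
             q_start = r$a_start, q_end = r$a_end,
             t_start = r$b_start, t_end = r$b_end, strand = "+",
             score = r$score,
             evalue = evalue(r$score, nchar(a), nchar(b), scheme),
             stringsAsFactors = FALSE)
}

#' Seed-and-extend local search
#'
#' Exact word seeds (default word 11) on both strands of the target are
#' chained by diagonal proximity; each cluster is then polished by an exact
#' local DP on a window spanning the cluster plus padding, and overlapping
#' hits are merged keeping the best score. E-values come from [evalue()].
#'
#' @param query,target sequences
#' @param scheme a [scoring_scheme()]
#' @param word_size exact-match seed length (>= 4)
#' @param min_score minimum raw score reported
#' @param pad window padding around a seed cluster (nt)
#' @param query_id,target_id labels for the hit table
#' @return a hit data.frame sorted by score (descending); target
#'   coordinates are always forward-strand, with `strand == "-"` marking
#'   reverse-complement matches
#' @export
seed_extend_search <- function(query, target, scheme = scoring_scheme(),
                               word_size = 11, min_score = 20, pad = 50,
                               query_id = "query", target_id = "target") {
  stopifnot(word_size >= 4)
  hits <- list()
  nt <- nchar(target)
  for (strand in c("+", "-")) {
    tseq <- if (strand == "+") target else rc_dna(target)
    seeds <- cpp_seed_positions(query, tseq, as.integer(word_size))
    if (!nrow(seeds)) next
    cl <- cluster_seeds(seeds, word_size)
    for (ci in seq_along(cl)) {
      s <- cl[[ci]]
      dspan <- max(s$d) - min(s$d)
      w <- pad + dspan
      q0 <- max(1L, min(s$q) - w); q1 <- min(nchar(query),
                                             max(s$q) + word_size - 1L + w)
      t0 <- max(1L, min(s$t) - w); t1 <- min(nchar(tseq),
                                             max(s$t) + word_size - 1L + w)
      r <- cpp_sw_align(substr(query, q0, q1), substr(tseq, t0, t1),
                        scheme$match, scheme$mismatch, scheme$gap_open,
                        scheme$gap_extend)
      if (r$score < min_score) next
      qs <- q0 + r$a_start - 1L; qe <- q0 + r$a_end - 1L
      ts <- t0 + r$b_start - 1L; te <- t0 + r$b_end - 1L
      if (strand == "-") { tmp <- ts; ts <- nt - te + 1L; te <- nt - tmp + 1L }
      hits[[length(hits) + 1L]] <- data.frame(
        query_id = query_id, target_id = target_id,
        identity = r$matches / r$length, aln_length = r$length,
        mismatches = r$length - r$matches - r$gaps, gaps = r$gaps,
        q_start = qs, q_end = qe, t_start = ts, t_end = te,
        strand = strand, score = r$score,
        evalue = evalue(r$score, nchar(query), nt, scheme),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty_hits())
  hits <- do.call(rbind, hits)
  dedupe_hits(hits)
}

# single-linkage chaining along the target: seeds stay in one cluster while
# the target gap and the diagonal jump remain small, so the segments of one
# gapped alignment (which drift across nearby diagonals) chain together
cluster_seeds <- function(seeds, word_size, max_diag_gap = 50,
                          max_pos_gap = 250) {
  d <- seeds[, "t"] - seeds[, "q"]
  o <- order(seeds[, "t"], seeds[, "q"])
  q <- seeds[o, "q"]; t <- seeds[o, "t"]; d <- d[o]
  brk <- c(TRUE, diff(t) > max_pos_gap | abs(diff(d)) > max_diag_gap)
  grp <- cumsum(brk)
  lapply(split(seq_along(q), grp), function(i)
    list(q = q[i], t = t[i], d = d[i]))
}

# keep best-scoring representative among hits overlapping >= 50% in both
# query and target on the same strand
dedupe_hits <- function(hits) {
  hits <- hits[order(-hits$score, hits$t_start, hits$q_start), ]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    dup <- FALSE
    for (j in which(keep)) {
      if (hits$strand[i] != hits$strand[j]) next
      qo <- reciprocal_overlap(hits$q_start[i], hits$q_end[i],
                               hits$q_start[j], hits$q_end[j])
      to <- reciprocal_overlap(hits$t_start[i], hits$t_end[i],
                               hits$t_start[j], hits$t_end[j])
      if (qo >= 0.5 && to >= 0.5) { dup <- TRUE; break }
    }
    keep[i] <- !dup
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search a query against every contig of a genome
#'
#' @inheritParams seed_extend_search
#' @param genome a [genome()] object
#' @return combined hit table with `target_id` = contig id
#' @export
seed_extend_genome <- function(query, genome, scheme = scoring_scheme(),
                               query_id = "query", ...) {
  res <- lapply(names(genome$contigs), function(cid)
    seed_extend_search(query, genome$contigs[[cid]], scheme,
                       query_id = query_id, target_id = cid, ...))
  out <- do.call(rbind, res)
  if (is.null(out)) empty_hits() else out[order(-out$score), , drop = FALSE]
}

#' Apply the survey's hit filters
#'
#' Keeps hits with E-value below `max_e`, alignment length at least
#' `min_len`, identity at least `min_id`, and no overlap (>= 1 shared
#' position) with masked telomeric intervals on the target. Order is
#' preserved and the operation is idempotent.
#'
#' @param hits a hit data.frame
#' @param max_e E-value cutoff (exclusive), default 0.1
#' @param min_len minimum alignment length (nt), default 25
#' @param min_id minimum identity fraction, default 0.60
#' @param telomere_mask optional data.frame (target_id, start, end) of
#'   telomeric intervals to exclude
#' @return the filtered hit data.frame
#' @export
filter_hits <- function(hits, max_e = 0.1, min_len = 25, min_id = 0.60,
                        telomere_mask = NULL) {
  if (!nrow(hits)) return(hits)
  keep <- hits$evalue < max_e & hits$aln_length >= min_len &
    hits$identity >= min_id - 1e-9
  if (!is.null(telomere_mask) && nrow(telomere_mask)) {
    masked <- vapply(seq_len(nrow(hits)), function(i) {
      m <- telomere_mask[telomere_mask$target_id == hits$target_id[i], ,
                         drop = FALSE]
      nrow(m) > 0 && any(intervals_overlap(hits$t_start[i], hits$t_end[i],
                                           m$start, m$end))
    }, logical(1))
    keep <- keep & !masked
  }
  hits[keep, , drop = FALSE]
}

#' Empirical false-positive rate by alignment length
#'
#' In genomes whose TER locus is known, every filtered hit can be labelled:
#' hits overlapping a known locus are true, the rest false. The table
#' reports, for each length threshold L in 25, 30, ..., 200, the number of
#' hits of length >= L and the fraction of those that are false; thresholds
#' with no hits are omitted.
#'
#' @param hits a (filtered) hit data.frame
#' @param truth_loci data.frame (target_id, start, end) of known TER loci
#' @return data.frame of class "fpr_table" with columns length_threshold,
#'   n_hits, n_false, fpr
#' @export
estimate_fpr_by_length <- function(hits, truth_loci) {
  if (!nrow(hits))
    return(structure(data.frame(length_threshold = integer(),
                                n_hits = integer(), n_false = integer(),
                                fpr = numeric()),
                     class = c("fpr_table", "data.frame")))
  is_true <- vapply(seq_len(nrow(hits)), function(i) {
    tl <- truth_loci[truth_loci$target_id == hits$target_id[i], ,
                     drop = FALSE]
    nrow(tl) > 0 && any(intervals_overlap(hits$t_start[i], hits$t_end[i],
                                          tl$start, tl$end))
  }, logical(1))
  rows <- lapply(seq(25, 200, by = 5), function(L) {
    sel <- hits$aln_length >= L
    if (!any(sel)) return(NULL)
    data.frame(length_threshold = L, n_hits = sum(sel),
               n_false = sum(sel & !is_true),
               fpr = sum(sel & !is_true) / sum(sel))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("fpr_table", "data.frame"))
}

#' Build the TER homology graph
#'
#' Undirected graph over TER loci; an edge joins two loci whenever a
#' filtered hit links them, weighted by the inverse of the length of the
#' best (longest) such hit, so closely similar loci sit close together.
#'
#' @param pairwise_best_hits filtered hit data.frame with `query_id` and
#'   `target_id` naming loci
#' @param node_status named character vector mapping each locus to
#'   "literature", "identified" or "candidate"
#' @return an igraph graph with vertex attribute `status` and edge
#'   attributes `weight` (1 / best hit length) and `aln_length`
#' @export
build_homology_graph <- function(pairwise_best_hits, node_status) {
  stopifnot(all(node_status %in% c("literature", "identified", "candidate")))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(node_status),
                            name = names(node_status),
                            status = unname(node_status))
  h <- pairwise_best_hits
  h <- h[h$query_id != h$target_id, , drop = FALSE]
  if (nrow(h)) {
    key <- vapply(seq_len(nrow(h)), function(i)
      paste(sort(c(h$query_id[i], h$target_id[i])), collapse = "\r"),
      "")
    best <- vapply(split(seq_len(nrow(h)), key), function(idx)
      idx[which.max(h$aln_length[idx])], integer(1))
    hb <- h[best, , drop = FALSE]
    el <- as.vector(rbind(hb$query_id, hb$target_id))
    g <- igraph::add_edges(g, el, weight = 1 / hb$aln_length,
                           aln_length = hb$aln_length)
  }
  g
}
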