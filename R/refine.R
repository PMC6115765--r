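# Iterative TER boundary refinement: a candidate region (with flanking
# slack) is repeatedly aligned to the closest known TER with free end gaps
# on the candidate, and trimmed to the aligned core, until the interval
# stabilizes. Also: flagging of boundary contamination by coding sequence.

#' Refine TER boundaries against a known reference TER
#'
#' Repeats { align the current candidate window to the reference with free
#' end gaps on the candidate; trim the candidate to the aligned core plus
#' `trim_slack` } until the interval changes by less than `tol` nt or
#' `max_iter` iterations. If no alignment reaches `score_floor` the input
#' interval is returned unconverged.
#'
#' @param candidate_seq candidate sequence including flanking slack
#' @param reference_ter_seq the closest known/annotated TER sequence
#'   (transcript orientation; both orientations are tried)
#' @param scheme a [scoring_scheme()]
#' @param max_iter maximum refinement iterations (default 5)
#' @param trim_slack nt kept on each side of the aligned core (default 25)
#' @param tol convergence tolerance on boundary movement (nt, default 10)
#' @param score_floor minimum acceptable alignment score
#' @return list(interval = c(start, end) in candidate-local coordinates,
#'   trace = list(iterations, converged, n_iter, orientation))
#' @export
refine_boundaries <- function(candidate_seq, reference_ter_seq,
                              scheme = scoring_scheme(), max_iter = 5,
                              trim_slack = 25, tol = 10, score_floor = 60) {
  L <- nchar(candidate_seq)
  cur <- c(1L, L)
  core <- c(1L, L)
  iterations <- list()
  converged <- FALSE
  orientation <- NA_character_
  for (it in seq_len(max_iter)) {
    sub <- substr(candidate_seq, cur[1], cur[2])
    af <- if (it == 1L || orientation == "same")
      cpp_overlap_align(sub, reference_ter_seq, scheme$match,
                        scheme$mismatch, scheme$gap_open,
                        scheme$gap_extend) else list(score = NA_integer_)
    ar <- if (it == 1L || orientation == "inverted")
      cpp_overlap_align(sub, rc_dna(reference_ter_seq), scheme$match,
                        scheme$mismatch, scheme$gap_open,
                        scheme$gap_extend) else list(score = NA_integer_)
    fwd <- !is.na(af$score) && (is.na(ar$score) || af$score >= ar$score)
    a <- if (fwd) af else ar
    if (is.na(a$score) || a$score < score_floor) {
      if (it == 1L)
        return(list(interval = c(1L, L),
                    trace = list(iterations = iterations, converged = FALSE,
                                 n_iter = it - 1L,
                                 orientation = orientation)))
      break
    }
    orientation <- if (fwd) "same" else "inverted"
    core_new <- c(cur[1] + a$a_start - 1L, cur[1] + a$a_end - 1L)
    iterations[[it]] <- list(interval = core_new, score = a$score)
    moved <- abs(core_new[1] - core[1]) + abs(core_new[2] - core[2])
    core <- core_new
    # working window keeps trim_slack around the core for the next pass
    cur <- c(max(1L, core[1] - trim_slack), min(L, core[2] + trim_slack))
    if (moved < tol) { converged <- TRUE; break }
  }
  list(interval = core,
       trace = list(iterations = iterations, converged = converged,
                    n_iter = length(iterations), orientation = orientation))
}

#' Flag boundary contamination of a query TER
#'
#' When a query's boundaries were chosen too generously and include
#' neighboring coding or regulatory sequence, searches against other
#' genomes produce recurrent hits confined to one end of the query that
#' land on annotated genes. A side is flagged when at least `min_genomes`
#' distinct genomes show such edge-confined, gene-overlapping hits.
#'
#' @param query_length length of the query TER (nt)
#' @param hit_lists named list (per target genome) of filtered hit
#'   data.frames of the query against that genome
#' @param coding_annotations named list (per target genome) of gene tables
#'   with columns contig_id, start, end
#' @param edge_window nt at each query end counted as "edge" (default 100)
#' @param min_genomes distinct genomes required to raise a flag (default 2)
#' @return list(left = logical, right = logical)
#' @export
flag_boundary_contamination <- function(query_length, hit_lists,
                                        coding_annotations,
                                        edge_window = 100, min_genomes = 2) {
  side_votes <- c(left = 0L, right = 0L)
  for (gname in names(hit_lists)) {
    h <- hit_lists[[gname]]
    if (is.null(h) || !nrow(h)) next
    genes <- coding_annotations[[gname]]
    on_gene <- vapply(seq_len(nrow(h)), function(i) {
      g <- genes[genes$contig_id == h$target_id[i], , drop = FALSE]
      nrow(g) > 0 && any(intervals_overlap(h$t_start[i], h$t_end[i],
                                           g$start, g$end))
    }, logical(1))
    left_edge <- h$q_end <= edge_window
    right_edge <- h$q_start >= query_length - edge_window + 1L
    if (any(on_gene & left_edge) && !any(on_gene & !left_edge))
      side_votes["left"] <- side_votes["left"] + 1L
    if (any(on_gene & right_edge) && !any(on_gene & !right_edge))
      side_votes["right"] <- side_votes["right"] + 1L
  }
  list(left = unname(side_votes["left"]) >= min_genomes,
       right = unname(side_votes["right"]) >= min_genomes)
}
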