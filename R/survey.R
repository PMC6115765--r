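# Clade-wide TER survey: breadth-first propagation of annotations from
# seeded species over a guide tree. For each unannotated genome the locus
# is projected by synteny from the nearest annotated relative, the
# candidate is refined against that reference TER, annotated by the feature
# cascade, and — when credible (template or SM evidence, the two features
# recoverable nearly everywhere) — joins the reference set.

#' Run the TER survey over a set of genomes
#'
#' @param genomes named list of [genome()] objects
#' @param known "ter_table" rows seeding the search (species must be in
#'   `genomes`)
#' @param tree guide tree: ape "phylo" or newick string over the species
#' @param repeat_unit telomeric repeat unit string, "telomere_repeat"
#'   object, or NULL to infer it from contig ends of the seed genomes
#' @param scheme a [scoring_scheme()]
#' @param slack nt of flanking slack around projected intervals
#' @param max_intervening tolerated genes between projected anchors
#' @param sm_max_mismatch mismatches tolerated in the SM motif
#' @param refine run boundary refinement against the reference TER
#' @param seed integer seed (the survey itself is deterministic; the seed
#'   fixes any downstream stochastic consumers)
#' @return list of class "ter_survey": `annotations` (ter_table including
#'   the seeds), `graph` (igraph homology graph), `summary`
#'   ([summarize_table()] result), `status` (named vector:
#'   literature/identified/candidate), and `log` (per-species outcomes and
#'   the parameters used)
#' @export
run_survey <- function(genomes, known, tree, repeat_unit = NULL,
                       scheme = scoring_scheme(), slack = 500,
                       max_intervening = 3, sm_max_mismatch = 1,
                       refine = TRUE, seed = 1) {
  set.seed(seed)
  if (!length(genomes))
    return(empty_survey())
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(nrow(known) >= 1, all(known$species %in% names(genomes)))
  if (is.null(repeat_unit)) {
    for (sp in unique(known$species)) {
      repeat_unit <- infer_repeat_unit(genomes[[sp]])
      if (!is.null(repeat_unit)) break
    }
    if (is.null(repeat_unit))
      stop("no telomeric repeat could be inferred; supply repeat_unit")
  }
  params <- list(slack = slack, max_intervening = max_intervening,
                 sm_max_mismatch = sm_max_mismatch, refine = refine,
                 unit = if (inherits(repeat_unit, "telomere_repeat"))
                   repeat_unit$unit else repeat_unit,
                 match = scheme$match, mismatch = scheme$mismatch,
                 gap_open = scheme$gap_open, gap_extend = scheme$gap_extend)
  annotations <- as.data.frame(known)[, c("species", "accession", "strand",
                                          ter_interval_cols(),
                                          "coord_citation")]
  status <- setNames(rep("literature", nrow(annotations)),
                     annotations$species)
  log <- list(params = params, species = list())
  dmat <- ape::cophenetic.phylo(tree)
  pending <- setdiff(names(genomes), annotations$species)
  while (length(pending)) {
    done <- annotations$species
    # nearest (target, reference) pair over the guide tree
    sub <- dmat[pending, done, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    target <- pending[ij[1]]
    ref_sp <- done[ij[2]]
    pending <- setdiff(pending, target)
    res <- survey_one(target, ref_sp, genomes, annotations, repeat_unit,
                      scheme, slack, max_intervening, sm_max_mismatch,
                      refine)
    log$species[[target]] <- res$log
    if (!is.null(res$annotation)) {
      annotations <- rbind(annotations, res$annotation)
      status[target] <- res$status
    }
  }
  class(annotations) <- c("ter_table", "data.frame")
  graph <- survey_graph(genomes, annotations, status, scheme)
  structure(list(annotations = annotations,
                 graph = graph,
                 summary = summarize_table(annotations),
                 status = status, log = log),
            class = "ter_survey")
}

empty_survey <- function() {
  structure(list(annotations = empty_ter_table(),
                 graph = igraph::make_empty_graph(0, directed = FALSE),
                 summary = summarize_table(empty_ter_table()),
                 status = character(0),
                 log = list(species = list())),
            class = "ter_survey")
}

# transcript-oriented TER sequence of an annotation row
ter_sequence <- function(genome, ann) {
  s <- substr(genome$contigs[[ann$accession]], ann$ter_start, ann$ter_end)
  if (ann$strand == "neg") rc_dna(s) else s
}

survey_one <- function(target, ref_sp, genomes, annotations, repeat_unit,
                       scheme, slack, max_intervening, sm_max_mismatch,
                       refine) {
  ref_ann <- annotations[annotations$species == ref_sp, ][1, ]
  ref_genome <- genomes[[ref_sp]]
  tgt_genome <- genomes[[target]]
  anchors <- tryCatch(
    flanking_anchors(ref_genome, c(ref_ann$ter_start, ref_ann$ter_end),
                     ref_ann$accession),
    error = function(e) e)
  if (inherits(anchors, "error"))
    return(list(annotation = NULL,
                log = paste("anchoring failed:", conditionMessage(anchors))))
  proj <- suppressWarnings(
    project_interval(anchors, tgt_genome, slack, max_intervening))
  if (is.null(proj))
    return(list(annotation = NULL, log = "synteny broken: no projection"))
  cand <- extract_region(tgt_genome, proj)
  hint <- NULL # refined core in genomic coordinates
  if (refine) {
    ref_seq <- ter_sequence(ref_genome, ref_ann)
    rb <- refine_boundaries(cand$seq, ref_seq, scheme)
    if (rb$trace$converged) {
      hint <- cand$offset + rb$interval - 1L
      margin <- 100L
      s0 <- max(1L, rb$interval[1] - margin)
      s1 <- min(nchar(cand$seq), rb$interval[2] + margin)
      cand <- list(seq = substr(cand$seq, s0, s1),
                   offset = cand$offset + s0 - 1L,
                   contig = cand$contig, inverted = cand$inverted)
    }
  }
  ann <- suppressWarnings(
    annotate_ter(cand, repeat_unit, species = target,
                 sm_max_mismatch = sm_max_mismatch))
  if (is.null(ann))
    return(list(annotation = NULL,
                log = "no credible TER (no template or SM evidence)"))
  if (!is.null(hint)) {
    # the aligned core against the reference TER is the better estimate of
    # the approximate 5' boundary (the 3' end stays on the SM + 10 rule)
    if (ann$strand == "pos") {
      ann$ter_start <- min(ann$ter_start, hint[1])
    } else {
      ann$ter_end <- max(ann$ter_end, hint[2])
    }
  }
  credible_both <- !is.na(ann$template_start) && !is.na(ann$sm1_start)
  list(annotation = as.data.frame(ann),
       status = if (credible_both) "identified" else "candidate",
       log = sprintf("annotated via %s (%s)", ref_sp,
                     if (credible_both) "template+SM" else "partial"))
}

survey_graph <- function(genomes, annotations, status, scheme) {
  n <- nrow(annotations)
  hits <- list()
  if (n >= 2) {
    seqs <- lapply(seq_len(n), function(i)
      ter_sequence(genomes[[annotations$species[i]]], annotations[i, ]))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      h <- seed_extend_search(seqs[[i]], seqs[[j]], scheme,
                              query_id = annotations$species[i],
                              target_id = annotations$species[j])
      h <- filter_hits(h)
      if (nrow(h)) hits[[length(hits) + 1L]] <- h[1, ]
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else empty_hits()
  build_homology_graph(hits, status[annotations$species])
}

#' Score survey predictions against planted truth
#'
#' @param predicted,truth "ter_table" data.frames over the same species set
#' @param tolerance_nt per-boundary tolerance for a feature to count as
#'   recovered (default 10)
#' @return list of class "recovery_metrics": `locus_recall` (fraction of
#'   truth loci recovered with reciprocal overlap >= 0.5), `false_loci`
#'   (predicted loci matching no truth locus), and `per_feature`
#'   (data.frame: kind, n_truth, n_matched, recall, mean_error — the mean
#'   absolute boundary error over matched features)
#' @export
score_recovery <- function(predicted, truth, tolerance_nt = 10) {
  predicted <- as.data.frame(predicted)
  truth <- as.data.frame(truth)
  locus_hit <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    p <- predicted[predicted$species == truth$species[i] &
                     predicted$accession == truth$accession[i], ,
                   drop = FALSE]
    if (nrow(p) && any(reciprocal_overlap(p$ter_start, p$ter_end,
                                          truth$ter_start[i],
                                          truth$ter_end[i]) >= 0.5))
      locus_hit[i] <- TRUE
  }
  false_loci <- 0L
  for (i in seq_len(nrow(predicted))) {
    t <- truth[truth$species == predicted$species[i] &
                 truth$accession == predicted$accession[i], , drop = FALSE]
    if (!nrow(t) || all(reciprocal_overlap(predicted$ter_start[i],
                                           predicted$ter_end[i],
                                           t$ter_start, t$ter_end) < 0.5))
      false_loci <- false_loci + 1L
  }
  rows <- lapply(TER_FEATURES, function(f) {
    ts <- paste0(f, "_start"); te <- paste0(f, "_end")
    have <- which(!is.na(truth[[ts]]))
    matched <- 0L
    errs <- numeric(0)
    for (i in have) {
      p <- predicted[predicted$species == truth$species[i], , drop = FALSE]
      if (!nrow(p) || is.na(p[[ts]][1])) next
      ds <- abs(p[[ts]][1] - truth[[ts]][i])
      de <- abs(p[[te]][1] - truth[[te]][i])
      if (ds <= tolerance_nt && de <= tolerance_nt) {
        matched <- matched + 1L
        errs <- c(errs, (ds + de) / 2)
      }
    }
    data.frame(kind = f, n_truth = length(have), n_matched = matched,
               recall = if (length(have)) matched / length(have) else NA,
               mean_error = if (length(errs)) mean(errs) else NA)
  })
  structure(list(locus_recall = if (nrow(truth)) mean(locus_hit) else NA,
                 false_loci = false_loci,
                 per_feature = do.call(rbind, rows)),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("locus recall %.3f, %d false locus/loci\n", x$locus_recall,
              x$false_loci))
  print(x$per_feature, row.names = FALSE)
  invisible(x)
}

#' @export
print.ter_survey <- function(x, ...) {
  print(x$summary)
  cat(sprintf("homology graph: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Write survey outputs to a run directory
#'
#' Emits the annotation table (TSV in the survey schema, GFF3, BED), the
#' homology graph as an edge-list TSV, a JSON summary, and a manifest.
#'
#' @param survey a "ter_survey" from [run_survey()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotations(survey$annotations, file.path(dir, "annotations.tsv"),
                    "TSV")
  write_annotations(survey$annotations, file.path(dir, "annotations.gff3"),
                    "GFF3")
  write_annotations(survey$annotations, file.path(dir, "annotations.bed"),
                    "BED")
  g <- survey$graph
  el <- igraph::as_data_frame(g, what = "edges")
  write.table(el, file.path(dir, "graph_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  nodes <- igraph::as_data_frame(g, what = "vertices")
  write.table(nodes, file.path(dir, "graph_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_species_with_ter = survey$summary$n_species_with_ter,
         n_novel = survey$summary$n_novel,
         per_feature_counts = as.list(survey$summary$per_feature_counts),
         status = as.list(survey$status),
         params = survey$log$params),
    file.path(dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  manifest <- list.files(dir)
  jsonlite::write_json(list(files = manifest),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
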