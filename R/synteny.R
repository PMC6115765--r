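# Synteny-anchored candidate delimitation: a TER locus is projected from an
# annotated reference species into a target species via the orthologous
# protein-coding genes flanking it. This shrinks the search space from a
# whole genome to a few kb between two anchors.

#' Flanking anchor genes of a locus
#'
#' The nearest ortholog-labelled gene entirely left of the locus and the
#' nearest entirely right of it; genes without an ortholog group are
#' skipped (with a message).
#'
#' @param genome a [genome()] object
#' @param locus_interval c(start, end), must not overlap a gene
#' @param contig contig id holding the locus
#' @return list(left, right): one-row gene data.frames
#' @export
flanking_anchors <- function(genome, locus_interval, contig) {
  g <- genome$genes[genome$genes$contig_id == contig, , drop = FALSE]
  if (any(intervals_overlap(locus_interval[1], locus_interval[2],
                            g$start, g$end)))
    stop("locus overlaps an annotated gene")
  skipped <- g[is.na(g$ortholog_group), , drop = FALSE]
  if (nrow(skipped))
    message(sprintf("skipping %d gene(s) without ortholog group",
                    nrow(skipped)))
  g <- g[!is.na(g$ortholog_group), , drop = FALSE]
  left <- g[g$end < locus_interval[1], , drop = FALSE]
  right <- g[g$start > locus_interval[2], , drop = FALSE]
  if (!nrow(left) || !nrow(right))
    stop("locus unanchored: no ortholog-labelled gene on ",
         if (!nrow(left)) "the left" else "the right")
  list(left = left[which.max(left$end), ],
       right = right[which.min(right$start), ])
}

#' Project an anchored interval into another genome
#'
#' Finds the orthologs of the two anchor genes in the target genome. If
#' both lie on one contig with at most `max_intervening` genes between
#' them, the inter-gene interval expanded by `slack` is returned; if the
#' anchors are split across contigs (synteny broken by rearrangement), NULL.
#'
#' @param anchors result of [flanking_anchors()] (anchors in the reference)
#' @param genomeB target [genome()]
#' @param slack nt added on each side of the inter-gene interval
#' @param max_intervening maximum genes tolerated between the two anchors
#' @return a list of class "synteny_interval" (species, contig, start, end,
#'   anchor_left, anchor_right, orientation, slack), or NULL
#' @export
project_interval <- function(anchors, genomeB, slack = 500,
                             max_intervening = 3) {
  gB <- genomeB$genes
  ogL <- anchors$left$ortholog_group
  ogR <- anchors$right$ortholog_group
  candL <- gB[!is.na(gB$ortholog_group) & gB$ortholog_group == ogL, ,
              drop = FALSE]
  candR <- gB[!is.na(gB$ortholog_group) & gB$ortholog_group == ogR, ,
              drop = FALSE]
  if (!nrow(candL) || !nrow(candR)) {
    warning("anchor ortholog group missing in target genome")
    return(NULL)
  }
  if (nrow(candL) > 1 || nrow(candR) > 1)
    warning("ambiguous ortholog mapping; taking the closest pair")
  best <- NULL
  for (i in seq_len(nrow(candL))) for (j in seq_len(nrow(candR))) {
    if (candL$contig_id[i] != candR$contig_id[j]) next
    d <- abs((candL$start[i] + candL$end[i]) -
               (candR$start[j] + candR$end[j])) / 2
    if (is.null(best) || d < best$d)
      best <- list(L = candL[i, ], R = candR[j, ], d = d)
  }
  if (is.null(best)) return(NULL) # anchors split across contigs
  L <- best$L; R <- best$R
  contig <- L$contig_id
  # order along the target contig
  if (L$start <= R$start) { g1 <- L; g2 <- R; flipped <- FALSE }
  else { g1 <- R; g2 <- L; flipped <- TRUE }
  between <- gB[gB$contig_id == contig & gB$start > g1$end &
                  gB$end < g2$start, , drop = FALSE]
  if (nrow(between) > max_intervening) return(NULL)
  # orientation: anchor order and strand pattern should agree
  strand_kept <- (L$strand == anchors$left$strand) &&
    (R$strand == anchors$right$strand)
  strand_inverted <- (L$strand != anchors$left$strand) &&
    (R$strand != anchors$right$strand)
  if (!flipped && strand_kept) {
    orientation <- "same"
  } else if (flipped && strand_inverted) {
    orientation <- "inverted"
  } else {
    warning("anchor order and strand signals disagree; treating as inverted")
    orientation <- "inverted"
  }
  clen <- nchar(genomeB$contigs[[contig]])
  start <- max(1L, g1$end + 1L - as.integer(slack))
  end <- min(clen, g2$start - 1L + as.integer(slack))
  structure(list(species = genomeB$species_id, contig = contig,
                 start = start, end = end,
                 anchor_left = g1$gene_id, anchor_right = g2$gene_id,
                 orientation = orientation, slack = as.integer(slack)),
            class = "synteny_interval")
}

#' Extract the candidate region sequence
#'
#' @param genomeB a [genome()]
#' @param synteny_interval a "synteny_interval" from [project_interval()]
#' @return list(seq, offset, contig, inverted): forward-strand sequence,
#'   the genomic position of its first base, and whether the projection was
#'   orientation-inverted (downstream code maps local coordinates back with
#'   [local_to_genomic()])
#' @export
extract_region <- function(genomeB, synteny_interval) {
  si <- synteny_interval
  seq <- substr(genomeB$contigs[[si$contig]], si$start, si$end)
  list(seq = seq, offset = si$start, contig = si$contig,
       inverted = identical(si$orientation, "inverted"))
}
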