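# Locating conserved TER elements inside a candidate region: the SM binding
# motif, the 3'-end rule it anchors, the Ku and Est1 hairpins and the
# three-way-junction surrogate, then assembly into a survey-table row.
# Hairpins are found by maximal complementary-arm search (Watson-Crick by
# default; GU optional), not by thermodynamic folding.

SM_MOTIF <- "AATTTTTGG"

#' Scan for the SM binding motif
#'
#' All positions matching AATTTTTGG with at most `max_mismatch` mismatches
#' (N never matches), sorted by mismatch count then position. One allowed
#' mismatch admits the known species-specific motif variants.
#'
#' @param seq sequence to scan
#' @param max_mismatch 0, 1 or 2 (default 1)
#' @return data.frame(start, end, mismatches)
#' @export
scan_sm <- function(seq, max_mismatch = 1) {
  stopifnot(max_mismatch %in% 0:2)
  m <- s2c(SM_MOTIF)
  w <- length(m)
  ch <- s2c(seq)
  n <- length(ch)
  empty <- data.frame(start = integer(), end = integer(),
                      mismatches = integer())
  if (n < w) return(empty)
  np <- n - w + 1L
  mm <- integer(np)
  for (k in seq_len(w))
    mm <- mm + as.integer(ch[(k):(np + k - 1L)] != m[k])
  hit <- which(mm <= max_mismatch)
  out <- data.frame(start = hit, end = hit + w - 1L, mismatches = mm[hit])
  out[order(out$mismatches, out$start), , drop = FALSE]
}

#' Assign the TER 3' end from an SM motif hit
#'
#' The mature 3' end is approximated as 10 nt downstream of the SM binding
#' motif, in transcript orientation: `sm_end + 10` on the plus strand,
#' `sm_start - 10` on the minus strand (genomic forward coordinates).
#'
#' @param sm_interval c(start, end), genomic forward-strand
#' @param strand "pos" or "neg"
#' @param contig_length optional; results outside the contig are clamped
#'   with a warning
#' @return the genomic 3'-end position
#' @export
assign_three_prime <- function(sm_interval, strand, contig_length = NULL) {
  stopifnot(strand %in% c("pos", "neg"))
  p <- if (strand == "pos") sm_interval[2] + 10L else sm_interval[1] - 10L
  if (!is.null(contig_length) && (p < 1L || p > contig_length)) {
    warning("3' end outside contig; clamped")
    p <- min(max(p, 1L), contig_length)
  }
  as.integer(p)
}

WC_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "X")

# All hairpin candidates in `seq`: maximal complementary runs along the
# anti-diagonals of the pairing matrix, optionally merged across up to
# `max_merges` interruptions of length <= merge_gap (bulges / internal
# loops). Returns start/end (outer pair), stem (paired bases on one arm),
# span (arm length including interruptions), pair_fraction, loop bounds.
best_hairpins <- function(seq, min_stem, max_merges = 2, merge_gap = 1,
                          gu = FALSE, min_loop = 3, max_loop = Inf) {
  ch <- s2c(seq)
  n <- length(ch)
  if (n > 5000) stop("hairpin search region too long (", n, " nt)")
  empty <- data.frame(start = integer(), end = integer(), stem = integer(),
                      span = integer(), pair_fraction = numeric(),
                      loop_start = integer(), loop_end = integer())
  if (n < 2 * min_stem + min_loop) return(empty)
  compl <- unname(WC_COMP[ch])
  compl[is.na(compl)] <- "X"
  M <- outer(ch, compl, "==")
  if (gu)
    M <- M | outer(ch == "G", ch == "T", "&") | outer(ch == "T", ch == "G", "&")
  # per anti-diagonal, keep the best merged complementary run
  d_start <- integer(0); d_stem <- integer(0); d_span <- integer(0)
  d_diag <- integer(0)
  for (d in (min_loop + 3L):(2L * n - 1L)) {
    i_min <- max(1L, d - n)
    i_max <- (d - min_loop - 1L) %/% 2L
    if (i_max - i_min + 1L < min_stem) next
    ii <- i_min:i_max
    v <- M[cbind(ii, d - ii)]
    # a bulge may only be bridged by a continuing stem segment (>= 3 bp),
    # so isolated chance pairs never stretch a hairpin's boundaries
    mr <- merge_true_runs(v, max_merges, merge_gap, min_merge_run = 3)
    sel <- which(mr$paired >= min_stem)
    if (!length(sel)) next
    best <- sel[order(-mr$paired[sel], mr$span[sel])[1]]
    d_start <- c(d_start, i_min + mr$start[best] - 1L)
    d_stem <- c(d_stem, mr$paired[best])
    d_span <- c(d_span, mr$span[best])
    d_diag <- c(d_diag, d)
  }
  if (!length(d_start)) return(empty)
  out <- data.frame(start = d_start, end = d_diag - d_start,
                    stem = d_stem, span = d_span,
                    pair_fraction = d_stem / d_span,
                    loop_start = d_start + d_span,
                    loop_end = d_diag - d_start - d_span)
  out <- out[out$loop_end - out$loop_start + 1L <= max_loop, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out[order(-out$stem, -out$pair_fraction, out$start), , drop = FALSE]
}

feature_hit <- function(kind, start, end, score, evidence) {
  data.frame(kind = kind, start = as.integer(start), end = as.integer(end),
             score = score, evidence = evidence, stringsAsFactors = FALSE)
}

#' Find the Ku binding hairpin
#'
#' Searches the window upstream of the template (transcript orientation)
#' for the strongest hairpin (stem >= 8 bp, up to two 1-nt interruptions)
#' whose loop-proximal nucleotides contain GCTA (GCUA in the RNA), the
#' conserved Ku anchor. A window containing no GCTA at all is a negative
#' call (the motif-absent reasoning), returning NULL.
#'
#' @param seq candidate sequence in transcript orientation
#' @param template_local_start template start in `seq` (NA searches the
#'   whole candidate, with a warning)
#' @param window nt upstream of the template searched (default 600)
#' @param max_loop maximum hairpin loop length considered (nt); the Ku
#'   hairpin loop is short, and the cap keeps long-range chance pairings
#'   from masquerading as Ku sites
#' @return a one-row feature-hit data.frame, or NULL
#' @export
find_ku_hairpin <- function(seq, template_local_start, window = 600,
                            max_loop = 12) {
  if (is.na(template_local_start)) {
    warning("template position unknown; searching entire candidate for Ku")
    r0 <- 1L; r1 <- nchar(seq)
  } else {
    r0 <- max(1L, template_local_start - as.integer(window))
    r1 <- template_local_start - 1L
  }
  if (r1 - r0 + 1L < 20L) return(NULL)
  sub <- substr(seq, r0, r1)
  if (!grepl("GCTA", sub, fixed = TRUE)) return(NULL)
  hp <- best_hairpins(sub, min_stem = 8, max_merges = 2, merge_gap = 1,
                      max_loop = max_loop)
  for (i in seq_len(nrow(hp))) {
    lp0 <- max(1L, hp$loop_start[i] - 2L)
    lp1 <- min(nchar(sub), hp$loop_end[i] + 2L)
    if (lp1 >= lp0 && grepl("GCTA", substr(sub, lp0, lp1), fixed = TRUE))
      return(feature_hit("KU", r0 + hp$start[i] - 1L, r0 + hp$end[i] - 1L,
                         hp$stem[i], "GCUA in hairpin loop"))
  }
  NULL
}

#' Find the Est1 binding hairpin
#'
#' The Est1 site forms a P3-like hairpin; the surrogate here is the
#' strongest hairpin with a stem of at least 10 paired bases, allowing one
#' internal loop of up to 3 nt, scored by its paired fraction (NULL below
#' 0.6).
#'
#' @param seq candidate sequence in transcript orientation
#' @param search_region c(start, end) in `seq`, between template and SM
#' @param min_fraction paired-fraction acceptance threshold
#' @return a one-row feature-hit data.frame, or NULL
#' @export
find_est1 <- function(seq, search_region, min_fraction = 0.6) {
  r0 <- max(1L, search_region[1]); r1 <- min(nchar(seq), search_region[2])
  if (r1 - r0 + 1L < 40L) {
    warning("Est1 search region shorter than 40 nt")
    return(NULL)
  }
  hp <- best_hairpins(substr(seq, r0, r1), min_stem = 10, max_merges = 1,
                      merge_gap = 3)
  if (!nrow(hp)) return(NULL)
  if (hp$pair_fraction[1] < min_fraction) return(NULL)
  feature_hit("EST1", r0 + hp$start[1] - 1L, r0 + hp$end[1] - 1L,
              hp$pair_fraction[1], "P3-like hairpin")
}

#' Find the three-way-junction region
#'
#' A minimal TWJ surrogate: an occurrence of the conserved AATA flanked
#' within 120 nt on both sides by hairpins with stems of at least 6 bp. If
#' AATA occurs but no such flanking structure exists, the call is reported
#' with evidence "sequence-only" and score 0 (the aberrant-structure case);
#' if AATA is absent the result is NULL.
#'
#' @param seq candidate sequence in transcript orientation
#' @param search_region c(start, end) in `seq`
#' @param flank_window nt on each side of AATA searched for hairpins
#' @return a one-row feature-hit data.frame, or NULL
#' @export
find_twj <- function(seq, search_region, flank_window = 120) {
  r0 <- max(1L, search_region[1]); r1 <- min(nchar(seq), search_region[2])
  if (r1 < r0) return(NULL)
  sub <- substr(seq, r0, r1)
  occ <- gregexpr("AATA", sub, fixed = TRUE)[[1]]
  if (occ[1] == -1) return(NULL)
  w <- nchar(sub)
  best <- NULL
  for (p in as.integer(occ)) {
    up0 <- max(1L, p - flank_window); up1 <- p - 1L
    dn0 <- p + 4L; dn1 <- min(w, p + 3L + flank_window)
    if (up1 - up0 + 1L < 15L || dn1 - dn0 + 1L < 15L) next
    hu <- best_hairpins(substr(sub, up0, up1), min_stem = 6,
                        max_merges = 1, merge_gap = 1)
    hd <- best_hairpins(substr(sub, dn0, dn1), min_stem = 6,
                        max_merges = 1, merge_gap = 1)
    if (!nrow(hu) || !nrow(hd)) next
    score <- hu$stem[1] + hd$stem[1]
    if (is.null(best) || score > best$score)
      best <- list(score = score,
                   start = up0 + hu$start[1] - 1L,
                   end = dn0 + hd$end[1] - 1L)
  }
  if (!is.null(best))
    return(feature_hit("TWJ", r0 + best$start - 1L, r0 + best$end - 1L,
                       best$score, "AATA with flanking hairpins"))
  feature_hit("TWJ", r0 + as.integer(occ[1]) - 1L,
              r0 + as.integer(occ[1]) + 2L, 0, "sequence-only")
}

#' Annotate a candidate region as a TER locus
#'
#' Runs the full feature cascade in transcript order: template search
#' (which also resolves the reading direction), SM motif and the 3'-end
#' rule, Ku hairpin upstream of the template, Est1 hairpin and TWJ between
#' template and SM. Features are reported in forward-strand genomic
#' coordinates; the approximate 5' end is placed 200 nt upstream of the
#' 5'-most feature. A candidate with neither template nor SM evidence is
#' rejected (NULL).
#'
#' @param candidate list(seq, offset, contig) from [extract_region()]
#' @param repeat_unit "telomere_repeat" or unit string (template query)
#' @param species species label for the output row
#' @param sm_max_mismatch mismatches tolerated in the SM motif
#' @param sm_search_downstream maximum distance (nt) downstream of the
#'   template where the SM motif is accepted
#' @param ku_window Ku search window upstream of the template (nt)
#' @param five_prime_offset nt subtracted from the 5'-most feature start to
#'   approximate the (uncertain) 5' end
#' @return a one-row "ter_table" data.frame with attributes `flags`
#'   (e.g. "incomplete", "approximate_5p") and `evidence`, or NULL
#' @export
annotate_ter <- function(candidate, repeat_unit, species = "candidate",
                         sm_max_mismatch = 1, sm_search_downstream = 2000,
                         ku_window = 600, five_prime_offset = 200) {
  seqF <- candidate$seq
  L <- nchar(seqF)
  if (L < 50) return(NULL)
  th <- find_template(seqF, repeat_unit)
  strand <- NULL
  tpl_ws <- c(NA_integer_, NA_integer_)
  if (nrow(th)) {
    strand <- if (th$strand[1] == "pos") "pos" else "neg"
    if (strand == "pos") {
      tpl_ws <- c(th$start[1], th$end[1])
    } else {
      tpl_ws <- c(L - th$end[1] + 1L, L - th$start[1] + 1L)
    }
  } else {
    smF <- scan_sm(seqF, sm_max_mismatch)
    smR <- scan_sm(rc_dna(seqF), sm_max_mismatch)
    if (!nrow(smF) && !nrow(smR)) return(NULL)
    bf <- if (nrow(smF)) smF$mismatches[1] else Inf
    br <- if (nrow(smR)) smR$mismatches[1] else Inf
    strand <- if (bf <= br) "pos" else "neg"
  }
  ws <- if (strand == "pos") seqF else rc_dna(seqF)
  # SM motif downstream of the template (when the template is known)
  sm <- scan_sm(ws, sm_max_mismatch)
  if (!is.na(tpl_ws[1])) {
    sm <- sm[sm$start > tpl_ws[2] &
               sm$start <= tpl_ws[2] + sm_search_downstream, , drop = FALSE]
  }
  sm_ws <- if (nrow(sm)) {
    sm <- sm[order(sm$mismatches, -sm$start), , drop = FALSE]
    c(sm$start[1], sm$end[1])
  } else c(NA_integer_, NA_integer_)
  if (is.na(tpl_ws[1]) && is.na(sm_ws[1])) return(NULL)
  flags <- character(0)
  if (is.na(sm_ws[1]) || is.na(tpl_ws[1])) flags <- c(flags, "incomplete")
  ku <- if (!is.na(tpl_ws[1]))
    find_ku_hairpin(ws, tpl_ws[1], ku_window) else NULL
  est1 <- NULL
  if (!is.na(tpl_ws[1])) {
    reg_end <- if (!is.na(sm_ws[1])) sm_ws[1] - 1L else
      min(L, tpl_ws[2] + 2000L)
    est1 <- tryCatch(find_est1(ws, c(tpl_ws[2] + 1L, reg_end)),
                     warning = function(w) NULL)
  }
  twj <- NULL
  if (!is.na(tpl_ws[1]) || !is.null(est1)) {
    t0 <- if (!is.null(est1)) est1$end + 1L else tpl_ws[2] + 1L
    t1 <- if (!is.na(sm_ws[1])) sm_ws[1] - 1L else L
    if (t1 > t0) twj <- find_twj(ws, c(t0, t1))
  }
  # transcript-order guards (anchors outrank heuristic hairpins)
  if (!is.null(ku) && !is.na(tpl_ws[1]) && ku$end >= tpl_ws[1]) {
    warning("Ku call violates transcript order; dropped")
    ku <- NULL
  }
  if (!is.null(est1) && !is.null(twj) && twj$start <= est1$end) {
    if (twj$score <= est1$score * 10) {
      warning("TWJ call violates transcript order; dropped")
      twj <- NULL
    } else {
      warning("Est1 call violates transcript order; dropped")
      est1 <- NULL
    }
  }
  feats_ws <- list(ku = if (!is.null(ku)) c(ku$start, ku$end) else
    c(NA_integer_, NA_integer_),
    template = tpl_ws,
    est1 = if (!is.null(est1)) c(est1$start, est1$end) else
      c(NA_integer_, NA_integer_),
    twj = if (!is.null(twj)) c(twj$start, twj$end) else
      c(NA_integer_, NA_integer_),
    sm1 = sm_ws)
  present_start <- vapply(feats_ws, `[`, integer(1), 1)
  five_ws <- max(1L, min(present_start, na.rm = TRUE) -
                   as.integer(five_prime_offset))
  flags <- c(flags, "approximate_5p")
  three_ws <- if (!is.na(sm_ws[1])) min(L, sm_ws[2] + 10L) else
    max(vapply(feats_ws, `[`, integer(1), 2), na.rm = TRUE)
  out <- data.frame(species = species, accession = candidate$contig,
                    strand = strand, stringsAsFactors = FALSE)
  ter_g <- local_to_genomic(five_ws, three_ws, candidate$offset, L, strand)
  out$ter_start <- ter_g[1]; out$ter_end <- ter_g[2]
  for (f in names(feats_ws)) {
    iv <- feats_ws[[f]]
    g <- if (is.na(iv[1])) c(NA_integer_, NA_integer_) else
      local_to_genomic(iv[1], iv[2], candidate$offset, L, strand)
    out[[paste0(f, "_start")]] <- g[1]
    out[[paste0(f, "_end")]] <- g[2]
  }
  # honor the exported 3'-end rule on genomic coordinates
  if (!is.na(out$sm1_start)) {
    p3 <- assign_three_prime(c(out$sm1_start, out$sm1_end), strand)
    if (strand == "pos") out$ter_end <- max(out$ter_end, p3) else
      out$ter_start <- min(out$ter_start, p3)
  }
  out$coord_citation <- FALSE
  class(out) <- c("ter_table", "data.frame")
  attr(out, "flags") <- unique(flags)
  attr(out, "evidence") <- list(ku = ku, est1 = est1, twj = twj)
  out
}
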