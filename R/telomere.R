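# Telomeric repeat inference from contig ends and template localization.
# Repeat units are defined only up to rotation and strand; the stored
# convention is the lexicographically smallest rotation of the G-richer
# strand.

#' Canonical rotation of a repeat unit
#'
#' The lexicographically smallest rotation; idempotent.
#' @param unit non-empty string
#' @return the canonical rotation
#' @export
canonical_rotation <- function(unit) {
  stopifnot(nzchar(unit))
  k <- nchar(unit)
  rots <- vapply(seq_len(k), function(i)
    paste0(substr(unit, i, k), substr(unit, 1, i - 1)), "")
  min(rots)
}

# reduce a unit to its primitive (aperiodic) root
primitive_unit <- function(unit) {
  k <- nchar(unit)
  for (d in seq_len(k)) {
    if (k %% d == 0 && strrep(substr(unit, 1, d), k / d) == unit)
      return(substr(unit, 1, d))
  }
  unit
}

g_count <- function(x) lengths(regmatches(x, gregexpr("G", x, fixed = TRUE)))

# canonical strand+rotation class: G-richer strand, ties broken
# lexicographically; returns NA for units with no G on either strand
canonical_unit <- function(unit) {
  u <- primitive_unit(unit)
  a <- canonical_rotation(u)
  b <- canonical_rotation(rc_dna(u))
  ga <- g_count(a); gb <- g_count(b)
  if (ga == 0 && gb == 0) return(NA_character_)
  if (ga > gb) a else if (gb > ga) b else min(a, b)
}

#' Infer the telomeric repeat unit from contig ends
#'
#' Scans a terminal window at both ends of every contig (both strands) for
#' tandem arrays of units of length 2-30 and returns the unit class whose
#' arrays cover the largest total length, requiring at least `min_copies`
#' consecutive copies in at least one terminus. Most assemblies lack
#' telomere regions, so `NULL` (no telomeric signal) is a normal outcome,
#' not an error.
#'
#' @param genome a [genome()] object
#' @param terminal_window nt examined at each contig end (>= 60)
#' @param min_copies minimum consecutive copies (>= 3)
#' @return a list of class "telomere_repeat" with `unit` (canonical rotation
#'   of the G-richer strand) and `source = "chromosome_ends"`, or NULL
#' @export
infer_repeat_unit <- function(genome, terminal_window = 500, min_copies = 4) {
  stopifnot(terminal_window >= 60, min_copies >= 3)
  coverage <- list()   # canonical class -> total covered nt
  eligible <- character(0)
  for (seq in genome$contigs) {
    L <- nchar(seq)
    w <- min(terminal_window, L)
    termini <- unique(c(substr(seq, 1, w), substr(seq, L - w + 1, L)))
    for (term in termini) {
      for (arr in tandem_arrays(term, min_copies)) {
        cls <- canonical_unit(arr$unit)
        if (is.na(cls)) next
        coverage[[cls]] <- (coverage[[cls]] %||% 0) + arr$covered
        eligible <- union(eligible, cls)
      }
    }
  }
  if (!length(eligible)) return(NULL)
  tot <- unlist(coverage[eligible])
  best <- names(tot)[order(-tot, names(tot))][1]
  structure(list(unit = best, source = "chromosome_ends"),
            class = "telomere_repeat")
}

# all maximal tandem arrays (unit length 2-30, >= min_copies copies) in x
tandem_arrays <- function(x, min_copies) {
  ch <- s2c(x)
  n <- length(ch)
  out <- list()
  for (k in 2:min(30, n %/% 2)) {
    eq <- ch[seq_len(n - k)] == ch[seq_len(n - k) + k] &
      ch[seq_len(n - k)] %in% c("A", "C", "G", "T")
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (j in which(r$values)) {
      run <- r$lengths[j]
      copies <- run %/% k + 1L
      if (copies < min_copies) next
      start <- pos[j]
      unit <- substr(x, start, start + k - 1L)
      if (nchar(primitive_unit(unit)) != k) next # counted at its own k
      out[[length(out) + 1L]] <- list(unit = unit, start = start,
                                      covered = run + k, copies = copies)
    }
  }
  out
}

#' Doubled telomere-repeat query
#'
#' Two concatenated copies of the unit; contains every rotation of the unit
#' as a substring, so a single query covers the rotation ambiguity.
#' @param repeat_unit a "telomere_repeat" object or a unit string
#' @return the doubled query string
#' @export
doubled_query <- function(repeat_unit) {
  u <- if (inherits(repeat_unit, "telomere_repeat")) repeat_unit$unit else
    repeat_unit
  stopifnot(nzchar(u))
  strrep(u, 2)
}

#' Locate template-region candidates in a sequence
#'
#' Matches the doubled repeat query, ungapped, against both strands of the
#' candidate. The template is the reverse complement of the G-rich-strand
#' repeat, so a forward match of the *reverse complement* of the doubled
#' query means the TER transcript runs forward ("pos"); a direct forward
#' match means it runs on the minus strand ("neg").
#'
#' @param candidate_seq candidate region sequence (forward strand)
#' @param repeat_unit a "telomere_repeat" or unit string
#' @param min_match minimum matched length; default `ceiling(1.5 * |unit|)`
#' @param max_mismatch interior mismatches tolerated within a match
#'   (default 1); a mismatch is never preferred over an equally scoring
#'   shorter exact match
#' @return data.frame of hits (start, end, strand, matched_length,
#'   mismatches, end_repeat_length) sorted best-first (matches minus twice
#'   the mismatches, then shorter, then leftmost)
#' @export
find_template <- function(candidate_seq, repeat_unit, min_match = NULL,
                          max_mismatch = 1) {
  u <- if (inherits(repeat_unit, "telomere_repeat")) repeat_unit$unit else
    repeat_unit
  if (is.null(min_match)) min_match <- ceiling(1.5 * nchar(u))
  if (min_match < nchar(u)) stop("min_match must be >= unit length")
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), matched_length = integer(),
                      mismatches = integer(), end_repeat_length = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(candidate_seq)) return(empty)
  # phase-complete periodic extension of the doubled query: enough copies
  # that every rotation of a min_match-long window occurs as a substring
  k <- nchar(u)
  q <- strrep(u, max(2, ceiling((min_match + k - 1) / k) + 1))
  hits <- rbind(
    ungapped_matches(candidate_seq, rc_dna(q), min_match, "pos",
                     max_mismatch),
    ungapped_matches(candidate_seq, q, min_match, "neg", max_mismatch))
  if (!nrow(hits)) return(empty)
  hits <- unique(hits)
  score <- (hits$matched_length - hits$mismatches) - 2 * hits$mismatches
  o <- order(-score, hits$matched_length, hits$start)
  hits <- hits[o, , drop = FALSE]
  # drop hits contained in an earlier (better) hit
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    inside <- hits$start >= hits$start[i] & hits$end <= hits$end[i]
    inside[seq_len(i)] <- FALSE
    keep[inside & keep] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]
  hits$end_repeat_length <- vapply(seq_len(nrow(hits)), function(i) {
    seg <- substr(candidate_seq, hits$start[i], hits$end[i])
    if (hits$strand[i] == "neg") seg <- rc_dna(seg)
    verify_template_ends(seg)$end_repeat_length
  }, integer(1))
  rownames(hits) <- NULL
  hits
}

# maximal ungapped matches (>= min_len, <= max_mm bridged single-position
# mismatches) between candidate and any substring of the (short) query
# pattern; periodicity duplicates are collapsed by the caller
ungapped_matches <- function(cand, pattern, min_len, strand, max_mm = 0) {
  a <- s2c(cand); b <- s2c(pattern)
  n <- length(a); m <- length(b)
  acc <- list()
  if (n == 0 || m == 0)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), matched_length = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  for (d in (-(m - 1)):(n - 1)) { # diagonal: a index = b index + d
    i0 <- max(1L, 1L + d); i1 <- min(n, m + d)
    if (i1 - i0 + 1 < min_len) next
    idx <- i0:i1
    eq <- a[idx] == b[idx - d] & a[idx] %in% c("A", "C", "G", "T")
    mr <- merge_true_runs(eq, max_mm, 1L)
    sel <- which(mr$span >= min_len)
    if (!length(sel)) next
    st <- i0 + mr$start[sel] - 1L
    acc[[length(acc) + 1L]] <- data.frame(
      start = st, end = st + mr$span[sel] - 1L, strand = strand,
      matched_length = mr$span[sel],
      mismatches = mr$span[sel] - mr$paired[sel],
      stringsAsFactors = FALSE)
  }
  if (!length(acc))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), matched_length = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  do.call(rbind, acc)
}

#' Check the end-repetition property of a template region
#'
#' A genuine template usually carries a few nucleotides repeated at both its
#' beginning and end (the alignment register of the repeat copy process).
#' Returns whether a prefix of length >= `min_overlap` equals a suffix, and
#' the longest such proper overlap.
#'
#' @param template_seq template-region sequence
#' @param min_overlap minimum overlap counted as verification (default 3)
#' @return list(verified = logical, end_repeat_length = integer)
#' @export
verify_template_ends <- function(template_seq, min_overlap = 3) {
  stopifnot(min_overlap >= 1)
  n <- nchar(template_seq)
  if (n < 2 * min_overlap)
    return(list(verified = FALSE, end_repeat_length = 0L))
  for (l in (n - 1):min_overlap) {
    if (substr(template_seq, 1, l) == substr(template_seq, n - l + 1, n))
      return(list(verified = TRUE, end_repeat_length = as.integer(l)))
  }
  list(verified = FALSE, end_repeat_length = 0L)
}
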