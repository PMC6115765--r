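# Small shared helpers: DNA strings, intervals, coordinate maps.
# Internal convention everywhere: 1-based inclusive, forward strand.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' Uppercase A/C/G/T/N alphabet; N maps to N.
#' @param x a single character string
#' @return the reverse complement string
#' @export
rc_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
c2s <- function(x) paste(x, collapse = "")

#' Do two closed intervals share at least one position?
#' @param s1,e1,s2,e2 interval bounds (1-based inclusive); vectorized
#' @return logical
#' @export
intervals_overlap <- function(s1, e1, s2, e2) {
  s1 <= e2 & s2 <= e1
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
  pmin(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

#' Map a local interval on an extracted region to genomic coordinates
#'
#' A region of length `L` was extracted starting at genomic position
#' `offset` (forward strand). Local coordinates refer either to the forward
#' sequence (`strand = "pos"`) or to its reverse complement
#' (`strand = "neg"`).
#'
#' @param start,end local 1-based interval
#' @param offset genomic position of the region's first forward-strand base
#' @param L region length
#' @param strand "pos" or "neg"
#' @return integer vector c(start, end) in forward-strand genomic coordinates
#' @export
local_to_genomic <- function(start, end, offset, L, strand = "pos") {
  if (strand == "pos") {
    c(offset + start - 1L, offset + end - 1L)
  } else {
    c(offset + L - end, offset + L - start)
  }
}

#' Inverse of [local_to_genomic()]
#' @inheritParams local_to_genomic
#' @param gstart,gend forward-strand genomic interval
#' @return integer vector c(start, end) in local coordinates
#' @export
genomic_to_local <- function(gstart, gend, offset, L, strand = "pos") {
  if (strand == "pos") {
    c(gstart - offset + 1L, gend - offset + 1L)
  } else {
    c(offset + L - gend, offset + L - gstart)
  }
}

# run code with a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  c2s(sample(c("A", "C", "G", "T"), n, replace = TRUE))
}

# For each TRUE-run of v, the maximal extension over up to `max_merges`
# FALSE-runs of length <= merge_gap. Returns parallel vectors:
# start (index in v), span (total length incl. gaps), paired (TRUE count).
merge_true_runs <- function(v, max_merges, merge_gap, min_merge_run = 1) {
  if (!length(v))
    return(list(start = integer(0), span = integer(0), paired = integer(0)))
  cpp_merge_true_runs(v, as.integer(max_merges), as.integer(merge_gap),
                      as.integer(min_merge_run))
}
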