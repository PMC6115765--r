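# IO for the standard formats the pipeline touches: FASTA + GFF3 + ortholog
# TSV in, TER annotation tables (TSV/GFF3/BED) out. Internal coordinates are
# 1-based inclusive on the forward strand; BED conversion is the only place
# 0-based half-open appears.

TER_FEATURES <- c("ku", "template", "est1", "twj", "sm1")

ter_interval_cols <- function() {
  as.vector(t(outer(c("ter", TER_FEATURES), c("start", "end"), paste,
                    sep = "_")))
}

#' Construct a genome object
#'
#' A light container for one species: named contig sequences plus a gene
#' table carrying ortholog-group labels used as synteny anchors.
#'
#' @param species_id species identifier
#' @param contigs named character vector of uppercase A/C/G/T/N sequences
#' @param genes data.frame with columns gene_id, contig_id, start, end,
#'   strand ("+"/"-"), ortholog_group (NA allowed)
#' @return an object of class "genome"
#' @export
genome <- function(species_id, contigs, genes = empty_gene_table()) {
  stopifnot(is.character(contigs), length(contigs) >= 1)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contig ids must be present and unique")
  if (any(nchar(contigs) == 0)) stop("contig sequences must be non-empty")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig_id", "start", "end", "strand", "ortholog_group")
  if (!all(need %in% names(genes)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  for (k in seq_len(nrow(genes))) {
    cid <- genes$contig_id[k]
    if (!cid %in% names(contigs))
      stop(sprintf("gene '%s' references missing contig '%s'",
                   genes$gene_id[k], cid))
    if (genes$start[k] < 1 || genes$end[k] < genes$start[k] ||
        genes$end[k] > nchar(contigs[[cid]]))
      stop(sprintf("gene '%s' interval %d-%d outside contig '%s' (length %d)",
                   genes$gene_id[k], genes$start[k], genes$end[k], cid,
                   nchar(contigs[[cid]])))
  }
  structure(list(species_id = species_id, contigs = contigs, genes = genes),
            class = "genome")
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), contig_id = character(),
             start = integer(), end = integer(), strand = character(),
             ortholog_group = character(), stringsAsFactors = FALSE)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome '%s': %d contig(s), %s nt total, %d gene(s)\n",
              x$species_id, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Load a genome from FASTA + GFF3 + ortholog table
#'
#' Gene records are taken from GFF3 rows of type "gene"; their ID attribute
#' becomes gene_id. The ortholog table (TSV with columns gene_id,
#' ortholog_group) assigns anchor labels; gene_ids in the table that do not
#' occur in the GFF3 are ignored with a warning.
#'
#' @param fasta_path path to the genome FASTA
#' @param gff3_path path to the gene annotation GFF3
#' @param ortholog_tsv_path optional path to the ortholog TSV
#' @param species_id species label; defaults to the FASTA file stem
#' @return a [genome()] object
#' @export
load_genome <- function(fasta_path, gff3_path, ortholog_tsv_path = NULL,
                        species_id = NULL) {
  stopifnot(file.exists(fasta_path), file.exists(gff3_path))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- setNames(toupper(as.character(seqs)),
                      sub("\\s.*$", "", names(seqs)))
  gff <- rtracklayer::readGFF(gff3_path)
  gff <- as.data.frame(gff, stringsAsFactors = FALSE)
  gff <- gff[gff$type == "gene", , drop = FALSE]
  genes <- data.frame(
    gene_id = as.character(gff$ID),
    contig_id = as.character(gff$seqid),
    start = as.integer(gff$start),
    end = as.integer(gff$end),
    strand = as.character(gff$strand),
    ortholog_group = NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(ortholog_tsv_path)) {
    stopifnot(file.exists(ortholog_tsv_path))
    om <- read.delim(ortholog_tsv_path, stringsAsFactors = FALSE,
                     comment.char = "#")
    stopifnot(all(c("gene_id", "ortholog_group") %in% names(om)))
    unknown <- setdiff(om$gene_id, genes$gene_id)
    if (length(unknown))
      warning(sprintf("%d ortholog-table gene id(s) not in GFF3, ignored: %s",
                      length(unknown),
                      paste(head(unknown, 3), collapse = ", ")))
    idx <- match(genes$gene_id, om$gene_id)
    genes$ortholog_group <- om$ortholog_group[idx]
  }
  genome(species_id %||% sub("\\.(fa|fasta|fna)$", "", basename(fasta_path)),
         contigs, genes)
}

parse_interval <- function(x, row = NA) {
  if (is.na(x) || !nzchar(x)) return(c(NA_integer_, NA_integer_))
  m <- regmatches(x, regexec("^\\s*([0-9]+)\\s*-\\s*([0-9]+)\\s*$", x))[[1]]
  if (length(m) != 3)
    stop(sprintf("malformed interval '%s' (row %s)", x, row))
  out <- as.integer(m[2:3])
  if (out[1] > out[2])
    stop(sprintf("interval start exceeds end: '%s' (row %s)", x, row))
  out
}

format_interval <- function(s, e) {
  ifelse(is.na(s), "", paste0(s, "-", e))
}

#' Load a TER annotation table
#'
#' Reads a TSV in the survey-table schema (species, accession, strand, ter,
#' ku, template, est1, twj, sm1, coord_citation), with intervals written as
#' "start-end" and empty cells marking features that were not located. All
#' coordinates are forward-strand 1-based inclusive regardless of strand.
#'
#' @param tsv_path path to the TSV; defaults to the packaged
#'   Saccharomycetaceae survey fixture
#' @return a data.frame of class "ter_table", one row per annotated locus,
#'   with `*_start`/`*_end` integer columns (NA for absent features) and a
#'   logical `coord_citation`
#' @export
load_ter_table <- function(tsv_path = ter_fixture_path()) {
  stopifnot(file.exists(tsv_path))
  raw <- read.delim(tsv_path, stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = "character")
  need <- c("species", "accession", "strand", "ter", TER_FEATURES,
            "coord_citation")
  if (!all(need %in% names(raw)))
    stop("TER table must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(species = raw$species, accession = raw$accession,
                    strand = raw$strand, stringsAsFactors = FALSE)
  for (f in c("ter", TER_FEATURES)) {
    iv <- t(vapply(seq_len(nrow(raw)),
                   function(i) parse_interval(raw[[f]][i], i),
                   integer(2)))
    out[[paste0(f, "_start")]] <- iv[, 1]
    out[[paste0(f, "_end")]] <- iv[, 2]
  }
  out$coord_citation <- toupper(raw$coord_citation) %in% c("TRUE", "T", "1")
  validate_ter_table(out)
  class(out) <- c("ter_table", "data.frame")
  out
}

#' Path of the packaged Saccharomycetaceae survey fixture
#' @return file path
#' @export
ter_fixture_path <- function() {
  system.file("extdata", "ter_table_saccharomycetaceae.tsv",
              package = "tersearch", mustWork = TRUE)
}

validate_ter_table <- function(tab) {
  stopifnot(all(tab$strand %in% c("pos", "neg")))
  for (f in TER_FEATURES) {
    s <- tab[[paste0(f, "_start")]]; e <- tab[[paste0(f, "_end")]]
    ok <- is.na(s) | (s >= tab$ter_start & e <= tab$ter_end)
    if (!all(ok))
      stop(sprintf("feature '%s' not nested within ter in row(s) %s", f,
                   paste(which(!ok), collapse = ", ")))
  }
  invisible(tab)
}

empty_ter_table <- function() {
  out <- data.frame(species = character(), accession = character(),
                    strand = character(), stringsAsFactors = FALSE)
  for (cl in ter_interval_cols()) out[[cl]] <- integer()
  out$coord_citation <- logical()
  class(out) <- c("ter_table", "data.frame")
  out
}

#' Summarize a TER annotation table
#'
#' @param records a "ter_table" data.frame (see [load_ter_table()])
#' @return a list of class "survey_summary" with `n_species_with_ter`
#'   (number of annotated loci), `n_novel` (loci whose coordinates carry no
#'   prior literature citation), and `per_feature_counts` (non-null feature
#'   cells per feature kind)
#' @export
summarize_table <- function(records) {
  records <- as.data.frame(records)
  counts <- vapply(TER_FEATURES, function(f)
    sum(!is.na(records[[paste0(f, "_start")]])), integer(1))
  out <- list(n_species_with_ter = nrow(records),
              n_novel = sum(!records$coord_citation),
              per_feature_counts = counts)
  stopifnot(out$n_novel <= out$n_species_with_ter)
  class(out) <- "survey_summary"
  out
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("TER survey: %d annotated loci, %d without prior literature coordinates\n",
              x$n_species_with_ter, x$n_novel))
  cat("features located: ",
      paste(sprintf("%s=%d", names(x$per_feature_counts),
                    x$per_feature_counts), collapse = ", "), "\n")
  invisible(x)
}

#' Write TER annotations to TSV, GFF3 or BED
#'
#' TSV keeps the survey-table schema and round-trips losslessly through
#' [load_ter_table()]. GFF3 emits one `ter_gene` record per locus with child
#' features, 1-based inclusive. BED converts to 0-based half-open, one line
#' per locus plus one per located feature; absent features emit no line.
#'
#' @param records a "ter_table" data.frame
#' @param path output file path
#' @param format one of "TSV", "GFF3", "BED"
#' @return `path`, invisibly
#' @export
write_annotations <- function(records, path, format = c("TSV", "GFF3", "BED")) {
  if (!format[1] %in% c("TSV", "GFF3", "BED"))
    stop("unknown format: ", format[1])
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (format == "TSV") {
    out <- data.frame(species = records$species, accession = records$accession,
                      strand = records$strand, stringsAsFactors = FALSE)
    for (f in c("ter", TER_FEATURES))
      out[[f]] <- format_interval(records[[paste0(f, "_start")]],
                                  records[[paste0(f, "_end")]])
    out$coord_citation <- records$coord_citation
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "GFF3") {
    lines <- "##gff-version 3"
    for (i in seq_len(nrow(records))) {
      r <- records[i, ]
      st <- if (r$strand == "pos") "+" else "-"
      gid <- sprintf("TER_%s", gsub("[^A-Za-z0-9]+", "_", r$species))
      lines <- c(lines, sprintf(
        "%s\ttersearch\tter_gene\t%d\t%d\t.\t%s\t.\tID=%s;species=%s;coord_citation=%s",
        r$accession, r$ter_start, r$ter_end, st, gid, r$species,
        tolower(as.character(r$coord_citation))))
      for (f in TER_FEATURES) {
        s <- r[[paste0(f, "_start")]]
        if (!is.na(s))
          lines <- c(lines, sprintf(
            "%s\ttersearch\t%s\t%d\t%d\t.\t%s\t.\tID=%s_%s;Parent=%s",
            r$accession, f, s, r[[paste0(f, "_end")]], st, gid, f, gid))
      }
    }
    writeLines(lines, path)
  } else { # BED: 0-based half-open starts
    lines <- character()
    for (i in seq_len(nrow(records))) {
      r <- records[i, ]
      st <- if (r$strand == "pos") "+" else "-"
      nm <- gsub("\\s+", "_", r$species)
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s|ter\t0\t%s", r$accession,
                                r$ter_start - 1L, r$ter_end, nm, st))
      for (f in TER_FEATURES) {
        s <- r[[paste0(f, "_start")]]
        if (!is.na(s))
          lines <- c(lines, sprintf("%s\t%d\t%d\t%s|%s\t0\t%s", r$accession,
                                    s - 1L, r[[paste0(f, "_end")]], nm, f,
                                    st))
      }
    }
    writeLines(lines, path)
  }
  invisible(path)
}
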