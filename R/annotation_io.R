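#' Read a CDS FASTA into a validated transcript table
#'
#' Each FASTA record is one coding sequence (no UTRs), expected to start with
#' ATG, end with a stop codon, contain no internal stop and have a length
#' that is a multiple of 3. Records violating any of these rules are skipped
#' with a warning (the default) or cause an error in strict mode.
#'
#' @param path path to a FASTA file of CDS nucleotide sequences.
#' @param strict logical; if `TRUE`, any invalid record raises an error
#'   instead of being skipped.
#' @return A tibble with columns `transcript_id`, `cds_seq`, `n_codons`,
#'   carrying attributes `n_records` (records read) and `n_rejected`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "ATGTGGTAA"), fa)
#' read_cds_fasta(fa)
#' @export
read_cds_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    stop("CDS FASTA not found: ", path, call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicated transcript ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  tx <- tibble::tibble(
    transcript_id = ids,
    cds_seq = unname(as.character(seqs))
  )
  if (nrow(tx) == 0L) {
    warning("empty FASTA: no transcripts loaded from ", path, call. = FALSE)
    out <- tibble::tibble(transcript_id = character(0),
                          cds_seq = character(0),
                          n_codons = integer(0))
    attr(out, "n_records") <- 0L
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  reasons <- vapply(tx$cds_seq, cds_validation_reason, character(1),
                    USE.NAMES = FALSE)
  bad <- reasons != ""
  if (any(bad)) {
    msg <- paste0(tx$transcript_id[bad], ": ", reasons[bad], collapse = "; ")
    if (strict) stop("invalid CDS record(s): ", msg, call. = FALSE)
    warning(sum(bad), " CDS record(s) rejected - ", msg, call. = FALSE)
  }
  out <- tx[!bad, ]
  out$n_codons <- nchar(out$cds_seq) %/% 3L
  attr(out, "n_records") <- nrow(tx)
  attr(out, "n_rejected") <- sum(bad)
  out
}

cds_validation_reason <- function(seq) {
  if (grepl("[^ACGT]", seq)) return("non-ACGT characters")
  if (nchar(seq) %% 3L != 0L) return("length not a multiple of 3")
  if (nchar(seq) < 6L) return("shorter than start + stop")
  codons <- split_codons(seq)
  n <- length(codons)
  if (codons[1L] != "ATG") return("does not start with ATG")
  if (!codons[n] %in% stop_codons()) return("does not end with a stop codon")
  if (any(codons[-n] %in% stop_codons())) return("internal stop codon")
  ""
}

#' Write a transcript table as CDS FASTA
#'
#' @param transcripts tibble as returned by [read_cds_fasta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(transcripts$cds_seq)
  names(seqs) <- transcripts$transcript_id
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read ribosome footprints from a transcript-coordinate BED6 file
#'
#' The BED chrom column holds the transcript id; start/end are 0-based
#' half-open nucleotide positions relative to the first nucleotide of the
#' start codon. Footprints are mRNA-sense by construction, so the strand
#' field must be "+" (a "-" row is dropped with a warning, or raises in
#' strict mode). Rows on unknown transcripts, out of CDS bounds, or with a
#' length outside `length_bounds` are dropped and counted.
#'
#' @param path path to a BED6 file.
#' @param transcripts transcript table from [read_cds_fasta()].
#' @param strict logical; escalate dropped rows to errors.
#' @param length_bounds inclusive footprint length bounds in nt.
#' @return A tibble with columns `transcript_id`, `start`, `length`, with
#'   attributes `n_rows` and `n_dropped` such that
#'   `n_rows == nrow(result) + n_dropped`.
#' @export
read_footprints_bed <- function(path, transcripts, strict = FALSE,
                                length_bounds = c(17L, 35L)) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      name = readr::col_character(),
      score = readr::col_character(),
      strand = readr::col_character()
    ),
    progress = FALSE
  )
  probs <- readr::problems(bed)
  if (nrow(probs) > 0L) {
    stop("malformed BED row(s) at line(s) ",
         paste(utils::head(probs$row, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(bed$end <= bed$start)) {
    stop("BED row(s) with end <= start at line(s) ",
         paste(utils::head(which(bed$end <= bed$start), 5L), collapse = ", "),
         call. = FALSE)
  }
  fp <- tibble::tibble(
    transcript_id = bed$chrom,
    start = bed$start,
    length = bed$end - bed$start
  )
  nt_len <- 3L * transcripts$n_codons[match(fp$transcript_id,
                                            transcripts$transcript_id)]
  reason <- dplyr::case_when(
    is.na(nt_len) ~ "unknown transcript",
    bed$strand != "+" ~ "non-plus strand",
    fp$start < 0L ~ "start before CDS",
    fp$start + fp$length > nt_len ~ "end beyond CDS",
    fp$length < length_bounds[1L] | fp$length > length_bounds[2L] ~
      "length out of bounds",
    .default = ""
  )
  drop <- reason != ""
  if (any(drop)) {
    tab <- table(reason[drop])
    msg <- paste(names(tab), tab, sep = ": ", collapse = "; ")
    if (strict) stop("invalid footprint row(s) - ", msg, call. = FALSE)
    warning(sum(drop), " footprint row(s) dropped - ", msg, call. = FALSE)
  }
  out <- fp[!drop, ]
  attr(out, "n_rows") <- nrow(fp)
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Write footprints as transcript-coordinate BED6
#'
#' @param footprints tibble with `transcript_id`, `start`, `length`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_footprints_bed <- function(footprints, path) {
  bed <- tibble::tibble(
    chrom = footprints$transcript_id,
    start = footprints$start,
    end = footprints$start + footprints$length,
    name = sprintf("r%d", seq_len(nrow(footprints))),
    score = 0L,
    strand = "+"
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read per-gene RPF and RNA-seq counts
#'
#' Expects a tab-separated file with header `gene_id`, `rpf_count`,
#' `rna_count`. Counts must be non-negative integers and gene ids unique.
#'
#' @param path path to the counts TSV.
#' @return tibble with columns `gene_id`, `rpf_count`, `rna_count`.
#' @export
read_gene_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("counts TSV not found: ", path, call. = FALSE)
  counts <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      rpf_count = readr::col_double(),
      rna_count = readr::col_double()
    ),
    na = ".",
    progress = FALSE
  )
  if (!identical(names(counts), c("gene_id", "rpf_count", "rna_count"))) {
    stop("counts file must have header gene_id, rpf_count, rna_count",
         call. = FALSE)
  }
  if (anyDuplicated(counts$gene_id)) {
    stop("duplicated gene id(s): ",
         paste(unique(counts$gene_id[duplicated(counts$gene_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (col in c("rpf_count", "rna_count")) {
    x <- counts[[col]]
    if (anyNA(x) || any(x < 0) || any(x != floor(x))) {
      stop(col, " must be non-negative integers", call. = FALSE)
    }
    counts[[col]] <- as.integer(x)
  }
  counts
}

#' Write a result table as deterministic TSV
#'
#' Rows are sorted by the first column (the primary key), columns keep their
#' order, missing values are written as ".". Writing then reading back with
#' [read_table_tsv()] reproduces the records exactly.
#'
#' @param records a data frame.
#' @param path output path.
#' @param allow_empty set `TRUE` to permit writing a header-only table.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, allow_empty = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L && !allow_empty) {
    stop("refusing to write an empty table; set allow_empty = TRUE",
         call. = FALSE)
  }
  if (nrow(records) > 0L) {
    records <- records[order(records[[1L]]), , drop = FALSE]
  }
  readr::write_tsv(records, path, na = ".", progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path, call. = FALSE)
  readr::read_tsv(path, na = ".", progress = FALSE,
                  show_col_types = FALSE)
}
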