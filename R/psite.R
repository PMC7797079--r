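#' Build an A-site offset table
#'
#' Maps footprint read length (nt) to the distance from the 5' end of the
#' read to the first nucleotide of the codon in the ribosomal A-site. Lengths
#' absent from the table fall back to `default_offset` when that offset is
#' valid for the read (`0 < offset < read_length`), otherwise the read is
#' left unassigned.
#'
#' @param read_length integer vector of read lengths (nt).
#' @param a_site_offset integer vector of offsets (nt from the 5' end).
#' @param default_offset fallback offset for unlisted lengths, or `NULL`
#'   for none.
#' @return tibble with columns `read_length`, `a_site_offset` and attribute
#'   `default_offset`.
#' @export
offset_table <- function(read_length, a_site_offset, default_offset = NULL) {
  read_length <- as.integer(read_length)
  a_site_offset <- as.integer(a_site_offset)
  stopifnot(length(read_length) == length(a_site_offset))
  if (anyDuplicated(read_length)) {
    stop("duplicated read lengths in offset table", call. = FALSE)
  }
  bad <- a_site_offset <= 0L | a_site_offset >= read_length
  if (any(bad)) {
    stop("offset must satisfy 0 < offset < read_length; violated for length ",
         paste(read_length[bad], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(read_length = read_length,
                        a_site_offset = a_site_offset)
  attr(out, "default_offset") <- if (is.null(default_offset)) NULL
                                 else as.integer(default_offset)
  class(out) <- c("offset_table", class(out))
  out
}

#' Default A-site offsets
#'
#' The canonical geometry for ~30-nt ribosome footprints: the P-site codon
#' starts 12 nt from the 5' end, so the A-site codon starts at 15 nt. The
#' table lists lengths 27-31 explicitly and applies the same 15-nt offset as
#' default to other lengths where it is valid (i.e. reads of 16 nt or more).
#'
#' @return an [offset_table()].
#' @examples
#' lookup_offset(default_offsets(), 30)  # 15
#' @export
default_offsets <- function() {
  offset_table(27:31, rep(15L, 5L), default_offset = 15L)
}

#' Look up the A-site offset for read lengths
#'
#' @param offsets an [offset_table()].
#' @param read_length integer vector of read lengths.
#' @return integer vector of offsets, `NA` where a length is unlisted and the
#'   default offset is absent or invalid for that length.
#' @export
lookup_offset <- function(offsets, read_length) {
  idx <- match(read_length, offsets$read_length)
  out <- offsets$a_site_offset[idx]
  default <- attr(offsets, "default_offset")
  if (!is.null(default)) {
    usable <- is.na(out) & default > 0L & default < read_length
    out[usable] <- default
  }
  out
}

#' Calibrate A-site offsets from initiating-ribosome footprints
#'
#' For each read-length class, the modal distance from the 5' end to the
#' start codon (over reads whose 5' end lies at or upstream of the ATG,
#' `start <= 0`) locates the P-site on codon 0; the A-site offset is that
#' mode plus 3 nt. Ties pick the smaller offset. Classes with fewer than
#' `min_reads` usable reads fall back to `fallback`.
#'
#' Unlike [read_footprints_bed()], this accepts raw footprint tibbles with
#' negative `start` values: initiating-ribosome reads necessarily begin
#' upstream of the start codon.
#'
#' @param footprints tibble with `transcript_id`, `start`, `length`.
#' @param transcripts transcript table (currently used for validation only).
#' @param min_reads minimum usable reads per length class.
#' @param fallback offset table used for uncalibratable classes.
#' @return an [offset_table()] covering the calibrated lengths, with the
#'   fallback's default offset.
#' @export
calibrate_offsets <- function(footprints, transcripts, min_reads = 500L,
                              fallback = default_offsets()) {
  stopifnot(is.data.frame(footprints))
  near_start <- footprints[footprints$start <= 0L, , drop = FALSE]
  lengths <- sort(unique(footprints$length))
  rows <- lapply(lengths, function(len) {
    d <- -near_start$start[near_start$length == len]
    d <- d[d + 3L > 0L & d + 3L < len]
    if (length(d) < min_reads) return(NULL)
    tab <- table(d)
    mode_d <- min(as.integer(names(tab)[tab == max(tab)]))
    if (sum(tab == max(tab)) > 1L) {
      warning("tied modal 5' distance for length ", len,
              "; choosing the smaller offset", call. = FALSE)
    }
    tibble::tibble(read_length = len, a_site_offset = mode_d + 3L)
  })
  calibrated <- dplyr::bind_rows(rows)
  if (nrow(calibrated) == 0L) {
    stop("no read-length class had >= ", min_reads,
         " usable reads; use default_offsets()", call. = FALSE)
  }
  uncal <- setdiff(lengths, calibrated$read_length)
  if (length(uncal) > 0L) {
    message("length class(es) ", paste(uncal, collapse = ", "),
            " below ", min_reads, " reads; falling back to default offsets")
  }
  fb <- fallback[!fallback$read_length %in% calibrated$read_length, ]
  all_rows <- dplyr::arrange(dplyr::bind_rows(calibrated, fb),
                             .data$read_length)
  offset_table(all_rows$read_length, all_rows$a_site_offset,
               default_offset = attr(fallback, "default_offset"))
}

#' Assign footprints to the A-site codon
#'
#' The A-site codon index of a footprint is
#' `floor((start + offset(length)) / 3)` (0-based). A footprint is unassigned
#' (`NA`) when its length has no valid offset, or the index falls on the stop
#' codon or outside the CDS.
#'
#' @param footprints tibble with `transcript_id`, `start`, `length`.
#' @param offsets an [offset_table()].
#' @param transcripts transcript table with `transcript_id`, `n_codons`.
#' @return integer vector of 0-based A-site codon indices, `NA` for
#'   unassigned footprints.
#' @examples
#' tx <- tibble::tibble(transcript_id = "g1",
#'                      cds_seq = strrep("ATG", 1), n_codons = 100L)
#' fp <- tibble::tibble(transcript_id = "g1", start = 0L, length = 30L)
#' assign_asite(fp, default_offsets(), tx)  # 5
#' @export
assign_asite <- function(footprints, offsets, transcripts) {
  offset <- lookup_offset(offsets, footprints$length)
  idx <- (footprints$start + offset) %/% 3L
  n_codons <- transcripts$n_codons[match(footprints$transcript_id,
                                         transcripts$transcript_id)]
  idx[is.na(offset) | is.na(n_codons) | idx < 0L | idx >= n_codons - 1L] <- NA_integer_
  as.integer(idx)
}

#' Per-codon A-site count tracks
#'
#' Tallies assigned footprints per codon position for every transcript. Each
#' track covers all codon positions of its transcript (zeros included);
#' unassigned footprints are counted in the `n_unassigned` attribute, so
#' `sum(counts) + n_unassigned` equals the number of input footprints.
#'
#' @inheritParams assign_asite
#' @return tibble with columns `transcript_id`, `codon_index` (0-based) and
#'   `count`, one row per codon position of every transcript, with attribute
#'   `n_unassigned`.
#' @export
build_count_tracks <- function(footprints, offsets, transcripts) {
  idx <- assign_asite(footprints, offsets, transcripts)
  assigned <- tibble::tibble(
    transcript_id = footprints$transcript_id[!is.na(idx)],
    codon_index = idx[!is.na(idx)]
  )
  grid <- tibble::tibble(
    transcript_id = rep(transcripts$transcript_id, transcripts$n_codons),
    codon_index = unlist(lapply(transcripts$n_codons,
                                function(n) seq_len(n) - 1L),
                         use.names = FALSE)
  )
  tallied <- dplyr::count(assigned, .data$transcript_id, .data$codon_index,
                          name = "count")
  out <- dplyr::left_join(grid, tallied,
                          by = c("transcript_id", "codon_index"))
  out$count[is.na(out$count)] <- 0L
  out$count <- as.integer(out$count)
  attr(out, "n_unassigned") <- sum(is.na(idx))
  out
}
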