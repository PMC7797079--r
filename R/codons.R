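#' Codon vocabulary helpers
#'
#' The 61 sense codons (amino-acid-encoding codons, start codon included) and
#' the three stop codons of the standard genetic code, plus the codon to
#' amino-acid map used to annotate result tables.
#'
#' @return `sense_codons()` and `stop_codons()` return character vectors in
#'   alphabetical order; `codon_table()` returns a tibble with columns
#'   `codon` and `amino_acid` (one-letter code) for the 61 sense codons.
#' @examples
#' length(sense_codons())  # 61
#' stop_codons()           # TAA TAG TGA
#' @export
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc != "*"])
}

#' @rdname sense_codons
#' @export
stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc == "*"])
}

#' @rdname sense_codons
#' @export
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- sense_codons()
  tibble::tibble(codon = codons, amino_acid = unname(gc[codons]))
}

#' Split a CDS nucleotide sequence into codons
#'
#' @param seq a single nucleotide string whose length is a multiple of 3.
#' @return character vector of trinucleotides, 5' to 3'.
#' @examples
#' split_codons("ATGTGGTAA")
#' @export
split_codons <- function(seq) {
  stopifnot(length(seq) == 1L, nchar(seq) %% 3L == 0L)
  if (nchar(seq) == 0L) return(character(0))
  starts <- seq.int(1L, nchar(seq), by = 3L)
  substring(seq, starts, starts + 2L)
}

# long codon layout: one row per codon position of every transcript.
# codon_index is 0-based; the stop codon is the last position.
transcript_codon_positions <- function(transcripts) {
  stopifnot(is.data.frame(transcripts))
  codons <- lapply(transcripts$cds_seq, split_codons)
  tibble::tibble(
    transcript_id = rep(transcripts$transcript_id, lengths(codons)),
    codon_index = unlist(lapply(lengths(codons), function(n) seq_len(n) - 1L),
                         use.names = FALSE),
    codon = unlist(codons, use.names = FALSE)
  )
}
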