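#' Occupancy analysis configuration
#'
#' @param codon_cutoff 1-based codon index; only codons strictly after this
#'   position enter the analysis (default 90, excluding the initiation ramp).
#' @param min_gene_rpf minimum A-site reads in the eligible region for a gene
#'   to contribute (default 64; caps per-gene multinomial noise).
#' @return a list with class `occupancy_config`.
#' @export
occupancy_config <- function(codon_cutoff = 90L, min_gene_rpf = 64L) {
  stopifnot(codon_cutoff >= 0L, min_gene_rpf >= 1L)
  structure(list(codon_cutoff = as.integer(codon_cutoff),
                 min_gene_rpf = as.integer(min_gene_rpf)),
            class = "occupancy_config")
}

# zero-row occupancy tibble marking an excluded gene
excluded_gene <- function(reason) {
  out <- tibble::tibble(gene_id = character(0), codon = character(0),
                        f = numeric(0), a = numeric(0), o = numeric(0))
  attr(out, "exclusion_reason") <- reason
  out
}

# eligible 0-based codon indices for one transcript: strictly after the
# 1-based cutoff, stop codon excluded
eligible_indices <- function(n_codons, codon_cutoff) {
  idx <- seq_len(n_codons) - 1L
  idx[idx >= codon_cutoff & idx < n_codons - 1L]
}

#' Per-gene normalized codon occupancy
#'
#' For one gene, over the eligible codon positions (1-based index greater
#' than the cutoff, stop codon excluded): `f(c)` is the fraction of the
#' gene's eligible A-site reads that sit on codons of identity `c`; `a(c)`
#' is the fraction of eligible positions with identity `c`; the normalized
#' occupancy is `o(c) = f(c)/a(c)`, defined only where `a(c) > 0`. By
#' construction `sum_c a(c) * o(c) = 1`.
#'
#' @param track count-track rows for one transcript (columns `codon_index`,
#'   `count` covering every codon position).
#' @param transcript one-row transcript tibble.
#' @param cfg an [occupancy_config()].
#' @return tibble with columns `gene_id`, `codon`, `f`, `a`, `o`, one row
#'   per codon identity present in the eligible region — or a zero-row
#'   tibble with an `exclusion_reason` attribute when the gene has fewer
#'   eligible reads than `min_gene_rpf` or no eligible positions.
#' @export
gene_occupancy <- function(track, transcript, cfg = occupancy_config()) {
  stopifnot(nrow(transcript) == 1L)
  n <- transcript$n_codons
  if (nrow(track) != n) {
    stop("track length (", nrow(track), ") disagrees with transcript (",
         n, " codons) for ", transcript$transcript_id, call. = FALSE)
  }
  idx <- eligible_indices(n, cfg$codon_cutoff)
  if (length(idx) == 0L) {
    return(excluded_gene("no eligible positions"))
  }
  codons <- split_codons(transcript$cds_seq)[idx + 1L]
  counts <- track$count[match(idx, track$codon_index)]
  total <- sum(counts)
  if (total < cfg$min_gene_rpf) {
    return(excluded_gene("insufficient eligible reads"))
  }
  by_codon <- tibble::tibble(codon = codons, count = counts) |>
    dplyr::summarise(n_reads = sum(.data$count), n_pos = dplyr::n(),
                     .by = "codon") |>
    dplyr::arrange(.data$codon)
  tibble::tibble(
    gene_id = transcript$transcript_id,
    codon = by_codon$codon,
    f = by_codon$n_reads / total,
    a = by_codon$n_pos / length(idx),
    o = (by_codon$n_reads / total) / (by_codon$n_pos / length(idx))
  )
}

#' Per-gene occupancies for a whole count-track set
#'
#' Applies [gene_occupancy()] to every transcript and keeps track of the
#' excluded genes.
#'
#' @param tracks long count-track tibble from [build_count_tracks()].
#' @param transcripts transcript tibble.
#' @param cfg an [occupancy_config()].
#' @return long tibble of per-gene occupancies with attribute `excluded`
#'   (tibble `gene_id`/`reason`).
#' @export
occupancy_by_gene <- function(tracks, transcripts, cfg = occupancy_config()) {
  track_list <- split(tracks[, c("codon_index", "count")],
                      tracks$transcript_id)
  res <- vector("list", nrow(transcripts))
  excl <- list()
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    g <- gene_occupancy(track_list[[tx$transcript_id]], tx, cfg)
    if (nrow(g) == 0L) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        gene_id = tx$transcript_id,
        reason = attr(g, "exclusion_reason") %||% "excluded")
    } else {
      res[[i]] <- g
    }
  }
  out <- dplyr::bind_rows(res)
  attr(out, "excluded") <- if (length(excl) > 0L) dplyr::bind_rows(excl)
    else tibble::tibble(gene_id = character(0), reason = character(0))
  out
}

#' Average codon occupancy across genes
#'
#' Unweighted mean of the per-gene normalized occupancies, per codon, over
#' the genes where the codon occurs in the eligible region. With
#' `weighted = TRUE` genes are instead pooled by their eligible read counts
#' (read-weighted mean), offered for sensitivity analysis.
#'
#' @param genes long per-gene occupancy tibble from [occupancy_by_gene()].
#' @param weighted logical; read-weighted instead of unweighted averaging.
#' @return an `occupancy_profile` tibble with exactly 61 rows: `codon`,
#'   `amino_acid`, `mean_occupancy`, `n_genes`, `stderr`. Codons present in
#'   no gene carry `NA` occupancy (missing, not zero).
#' @export
average_occupancy <- function(genes, weighted = FALSE) {
  if (is.null(genes) || nrow(genes) == 0L) {
    stop("no contributing genes", call. = FALSE)
  }
  if (weighted) {
    stats_tbl <- genes |>
      dplyr::summarise(
        mean_occupancy = sum(.data$f) / sum(.data$a),
        n_genes = dplyr::n(),
        stderr = NA_real_,
        .by = "codon")
  } else {
    stats_tbl <- genes |>
      dplyr::summarise(
        mean_occupancy = mean(.data$o),
        n_genes = dplyr::n(),
        stderr = stats::sd(.data$o) / sqrt(dplyr::n()),
        .by = "codon")
  }
  out <- codon_table() |>
    dplyr::left_join(stats_tbl, by = "codon") |>
    dplyr::mutate(n_genes = dplyr::coalesce(.data$n_genes, 0L))
  class(out) <- c("occupancy_profile", class(out))
  out
}

#' Full occupancy pipeline
#'
#' Count tracks to averaged 61-codon occupancy profile in one call.
#'
#' @inheritParams occupancy_by_gene
#' @inheritParams average_occupancy
#' @return an `occupancy_profile` tibble (see [average_occupancy()]).
#' @export
occupancy_profile <- function(tracks, transcripts, cfg = occupancy_config(),
                              weighted = FALSE) {
  average_occupancy(occupancy_by_gene(tracks, transcripts, cfg),
                    weighted = weighted)
}

#' Log2 occupancy ratio between two conditions
#'
#' @param profile_stress,profile_control `occupancy_profile` tibbles over
#'   the same codon set.
#' @return tibble `codon`, `amino_acid`, `occupancy_stress`,
#'   `occupancy_control`, `log2_ratio`, `rank` (1 = largest ratio). Codons
#'   missing or non-positive in either profile get `NA` ratio.
#' @export
occupancy_ratio <- function(profile_stress, profile_control) {
  stopifnot(identical(profile_stress$codon, profile_control$codon))
  s <- profile_stress$mean_occupancy
  ctl <- profile_control$mean_occupancy
  bad <- !is.na(s) & !is.na(ctl) & (s <= 0 | ctl <= 0)
  if (any(bad)) {
    warning("non-positive mean occupancy for ",
            paste(profile_stress$codon[bad], collapse = ", "),
            "; ratio set to NA", call. = FALSE)
  }
  ratio <- ifelse(is.na(s) | is.na(ctl) | s <= 0 | ctl <= 0,
                  NA_real_, log2(s / ctl))
  out <- tibble::tibble(
    codon = profile_stress$codon,
    amino_acid = profile_stress$amino_acid,
    occupancy_stress = s,
    occupancy_control = ctl,
    log2_ratio = ratio
  )
  out$rank <- rank(-out$log2_ratio, ties.method = "min", na.last = "keep")
  out
}
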