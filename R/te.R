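#' Relative translation efficiency per gene
#'
#' TE is the footprint count over the mRNA count on the log2 scale, with a
#' pseudocount keeping zero-count genes finite:
#' `log2((rpf + pc) / (rna + pc))`. Genes with `rna_count == 0` are flagged;
#' their TE rests entirely on the pseudocount.
#'
#' @param counts tibble with `gene_id`, `rpf_count`, `rna_count` (as from
#'   [read_gene_counts_tsv()] or [simulate_rnaseq_counts()]).
#' @param pseudocount added to both counts; must be positive when any count
#'   is zero.
#' @return tibble `gene_id`, `rpf_count`, `rna_count`, `log2_te`,
#'   `zero_rna` (logical flag).
#' @examples
#' compute_te(tibble::tibble(gene_id = "g1", rpf_count = 8L, rna_count = 2L),
#'            pseudocount = 0)
#' @export
compute_te <- function(counts, pseudocount = 0.5) {
  stopifnot(nrow(counts) > 0L)
  if (pseudocount <= 0 &&
      any(counts$rpf_count == 0L | counts$rna_count == 0L)) {
    stop("pseudocount must be > 0 when any count is zero", call. = FALSE)
  }
  dplyr::mutate(
    counts,
    log2_te = log2((.data$rpf_count + pseudocount) /
                   (.data$rna_count + pseudocount)),
    zero_rna = .data$rna_count == 0L
  )
}

#' Median-centre a numeric column
#'
#' Subtracts the column median (mean-of-middle-two for even lengths, the
#' [stats::median()] convention); missing values pass through untouched.
#'
#' @param values numeric vector with at least one finite value.
#' @return centred numeric vector with median 0 over the non-missing values.
#' @export
median_center <- function(values) {
  if (all(is.na(values))) stop("all values missing", call. = FALSE)
  values - stats::median(values, na.rm = TRUE)
}

#' Per-gene log2 TE change between conditions
#'
#' `log2_te_change = log2_te_stress - log2_te_control`, median-centred over
#' the shared genes. Genes present in only one condition are dropped and
#' counted in the `n_dropped` attribute.
#'
#' @param te_stress,te_control TE tables from [compute_te()].
#' @return tibble `gene_id`, `log2_te_stress`, `log2_te_control`,
#'   `log2_te_change` (centred), with attribute `n_dropped`.
#' @export
te_change <- function(te_stress, te_control) {
  joined <- dplyr::inner_join(
    dplyr::select(te_stress, "gene_id", log2_te_stress = "log2_te"),
    dplyr::select(te_control, "gene_id", log2_te_control = "log2_te"),
    by = "gene_id"
  )
  if (nrow(joined) == 0L) {
    stop("no genes shared between the two conditions", call. = FALSE)
  }
  out <- dplyr::mutate(
    joined,
    log2_te_change = median_center(.data$log2_te_stress -
                                   .data$log2_te_control)
  )
  attr(out, "n_dropped") <-
    nrow(te_stress) + nrow(te_control) - 2L * nrow(joined)
  out
}

#' Bin genes by codon content
#'
#' The content fraction of a gene is the number of occurrences of the target
#' codon over its sense-codon count (start included, stop excluded). Bin 0
#' holds exactly the zero-content genes; the remaining genes, sorted by
#' (content fraction, gene id), are split into `n_bins - 1` contiguous
#' groups whose sizes differ by at most one.
#'
#' @param transcripts transcript tibble.
#' @param target_codon codon whose content drives the binning.
#' @param n_bins total number of bins including the zero-content bin.
#' @return tibble `gene_id`, `content_fraction`, `bin_id` (0-based), one row
#'   per transcript.
#' @export
bin_by_content <- function(transcripts, target_codon, n_bins = 11L) {
  stopifnot(n_bins >= 2L)
  n_occ <- vapply(transcripts$cds_seq, function(s) {
    codons <- split_codons(s)
    sum(codons[-length(codons)] == target_codon)
  }, integer(1), USE.NAMES = FALSE)
  content <- n_occ / (transcripts$n_codons - 1L)
  out <- tibble::tibble(
    gene_id = transcripts$transcript_id,
    content_fraction = content,
    bin_id = NA_integer_
  )
  out$bin_id[content == 0] <- 0L
  nz <- which(content > 0)
  if (length(nz) < n_bins - 1L) {
    stop("only ", length(nz), " genes with nonzero content; need at least ",
         n_bins - 1L, call. = FALSE)
  }
  ord <- nz[order(content[nz], out$gene_id[nz])]
  # contiguous groups as equal as possible (larger groups first)
  sizes <- rep(length(ord) %/% (n_bins - 1L), n_bins - 1L)
  extra <- length(ord) %% (n_bins - 1L)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  out$bin_id[ord] <- rep(seq_len(n_bins - 1L), times = sizes)
  out
}

#' Per-bin TE-change summary and monotone-trend test
#'
#' Summarises the per-gene log2 TE changes within each codon-content bin
#' (five-number summary) and tests for a monotone trend across the nonzero
#' -content bins: the statistic is the Spearman correlation between bin
#' index (1..k) and bin median, and its two-sided p-value comes from
#' permuting the gene-to-bin assignment.
#'
#' @param bins tibble from [bin_by_content()].
#' @param changes tibble with `gene_id` and `log2_te_change` (as from
#'   [te_change()]).
#' @param n_perm number of permutations (>= 999).
#' @param seed integer seed for the permutations.
#' @return object of class `bin_trend`: list with `summary` (per-bin
#'   tibble), `trend` (Spearman rho), `p_value`, `n_perm`, and `genes`
#'   (the joined gene-level table, for plotting).
#' @export
bin_trend <- function(bins, changes, n_perm = 999L, seed = 1L) {
  stopifnot(n_perm >= 999L)
  genes <- dplyr::inner_join(bins, changes[, c("gene_id", "log2_te_change")],
                             by = "gene_id")
  if (nrow(genes) == 0L) stop("bins and changes share no genes",
                              call. = FALSE)
  trend_bins <- sort(unique(bins$bin_id[bins$bin_id > 0L]))
  present <- genes |>
    dplyr::filter(.data$bin_id > 0L)
  missing_bins <- setdiff(trend_bins, unique(present$bin_id))
  if (length(missing_bins) > 0L) {
    stop("bin(s) ", paste(missing_bins, collapse = ", "),
         " empty after intersecting with TE changes", call. = FALSE)
  }
  if (length(trend_bins) < 2L) {
    stop("need at least two nonzero-content bins for a trend", call. = FALSE)
  }
  summary_tbl <- genes |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$log2_te_change),
      q1 = stats::quantile(.data$log2_te_change, 0.25, names = FALSE),
      median = stats::median(.data$log2_te_change),
      q3 = stats::quantile(.data$log2_te_change, 0.75, names = FALSE),
      max = max(.data$log2_te_change),
      .by = "bin_id") |>
    dplyr::arrange(.data$bin_id)

  bin_idx <- present$bin_id
  vals <- present$log2_te_change
  stat <- function(assignment) {
    med <- tapply(vals, assignment, stats::median)
    stats::cor(as.integer(names(med)), as.numeric(med), method = "spearman")
  }
  observed <- stat(bin_idx)
  withr::with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) stat(sample(bin_idx)),
                   numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(observed))) / (1 + n_perm)
  structure(list(summary = summary_tbl, trend = observed, p_value = p,
                 n_perm = n_perm, genes = genes),
            class = "bin_trend")
}

#' @export
print.bin_trend <- function(x, ...) {
  cat("<bin_trend> Spearman trend over", nrow(x$summary) - 1L,
      "content bins:", round(x$trend, 3),
      " permutation p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

#' Gene-list overlap enrichment test
#'
#' One-sided test of whether two gene lists drawn from a common universe
#' overlap more than chance: the upper hypergeometric tail
#' `P(X >= overlap)`, equivalent to the one-sided Fisher exact test on the
#' 2x2 membership table.
#'
#' @param list_a,list_b character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe character vector of all gene ids considered.
#' @return tibble `n_a`, `n_b`, `n_universe`, `n_overlap`, `p_value`.
#' @examples
#' overlap_test(c("g1", "g2"), c("g1", "g2"), paste0("g", 1:4))  # p = 1/6
#' @export
overlap_test <- function(list_a, list_b, universe) {
  universe <- unique(universe)
  list_a <- unique(list_a)
  list_b <- unique(list_b)
  if (!all(list_a %in% universe) || !all(list_b %in% universe)) {
    stop("both gene lists must be subsets of the universe", call. = FALSE)
  }
  n_overlap <- length(intersect(list_a, list_b))
  p <- stats::phyper(n_overlap - 1L, length(list_a),
                     length(universe) - length(list_a), length(list_b),
                     lower.tail = FALSE)
  tibble::tibble(
    n_a = length(list_a), n_b = length(list_b),
    n_universe = length(universe), n_overlap = n_overlap,
    p_value = p
  )
}
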