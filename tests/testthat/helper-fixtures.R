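# In-code fixtures and independent oracles shared across test files.

# one CDS string from explicit internal codons
make_cds <- function(internal, stop = "TAA") {
  paste0("ATG", paste(internal, collapse = ""), stop)
}

make_transcripts <- function(seqs) {
  tibble::tibble(
    transcript_id = names(seqs),
    cds_seq = unname(seqs),
    n_codons = nchar(unname(seqs)) %/% 3L
  )
}

# dense count-track tibble from a named list of count vectors
make_tracks <- function(count_list) {
  tibble::tibble(
    transcript_id = rep(names(count_list), lengths(count_list)),
    codon_index = unlist(lapply(lengths(count_list),
                                function(n) seq_len(n) - 1L),
                         use.names = FALSE),
    count = as.integer(unlist(count_list, use.names = FALSE))
  )
}

# independent oracle: one-read-at-a-time A-site tally
naive_count_tracks <- function(footprints, offsets, transcripts) {
  tracks <- lapply(stats::setNames(transcripts$n_codons,
                                   transcripts$transcript_id),
                   function(n) integer(n))
  unassigned <- 0L
  for (i in seq_len(nrow(footprints))) {
    id <- footprints$transcript_id[i]
    off <- lookup_offset(offsets, footprints$length[i])
    n <- transcripts$n_codons[transcripts$transcript_id == id]
    if (length(n) == 0L || is.na(off)) {
      unassigned <- unassigned + 1L
      next
    }
    j <- (footprints$start[i] + off) %/% 3L
    if (j < 0L || j >= n - 1L) {
      unassigned <- unassigned + 1L
    } else {
      tracks[[id]][j + 1L] <- tracks[[id]][j + 1L] + 1L
    }
  }
  list(tracks = tracks, unassigned = unassigned)
}

# independent oracle: position-by-position occupancy recount
naive_gene_occupancy <- function(counts, codons, cutoff, min_rpf) {
  n <- length(codons)
  reads <- list(); pos <- list()
  n_eligible <- 0L; total_reads <- 0L
  for (j in seq_len(n)) {
    idx0 <- j - 1L
    if (idx0 < cutoff || idx0 >= n - 1L) next
    n_eligible <- n_eligible + 1L
    total_reads <- total_reads + counts[j]
    cd <- codons[j]
    reads[[cd]] <- (reads[[cd]] %||% 0L) + counts[j]
    pos[[cd]] <- (pos[[cd]] %||% 0L) + 1L
  }
  if (n_eligible == 0L || total_reads < min_rpf) return(NULL)
  cods <- sort(names(pos))
  f <- vapply(cods, function(cd) (reads[[cd]] %||% 0L) / total_reads,
              numeric(1))
  a <- vapply(cods, function(cd) pos[[cd]] / n_eligible, numeric(1))
  tibble::tibble(codon = cods, f = unname(f), a = unname(a),
                 o = unname(f / a))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent oracle: exhaustive overlap enrichment for small universes
enumerate_overlap_p <- function(n_a, n_b, n_universe, n_overlap) {
  a_sets <- utils::combn(n_universe, n_a, simplify = FALSE)
  b <- seq_len(n_b)  # fix B wlog; X counts A-draws hitting B
  hits <- vapply(a_sets, function(a) length(intersect(a, b)), integer(1))
  mean(hits >= n_overlap)
}

# independent oracle: exact expected A-site counts (up to total scale) under
# the dwell-weighted placement rule with the 5'-end boundary skips, by
# enumerating every (codon, length) emission
expected_asite_weights <- function(codons, dwell, len_dist) {
  n <- length(codons)
  w <- numeric(n)
  for (j in seq_len(n - 1L) - 1L) {        # all non-stop codons, 0-based
    keep <- 0
    for (k in seq_len(nrow(len_dist))) {
      len <- len_dist$length[k]
      start <- 3L * j - 15L
      if (start >= 0L && start + len <= 3L * n) {
        keep <- keep + len_dist$prob[k]
      }
    }
    w[j + 1L] <- dwell[[codons[j + 1L]]] * keep
  }
  w
}

# small shared simulation for module-level tests (cheap, cached per session)
small_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(name, overrides = list()) {
    key <- paste0(name, "_", paste(names(overrides), unlist(overrides),
                                   collapse = "_"))
    if (is.null(cache[[key]])) {
      ov <- utils::modifyList(list(n_genes = 50L, n_footprints = 2e5,
                                   n_rna_reads = 2e5, seed = 11L),
                              overrides)
      scn <- make_scenario(name, overrides = ov)
      cache[[key]] <- simulate_experiment(scn)
    }
    cache[[key]]
  }
})
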