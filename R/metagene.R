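#' Metagene analysis configuration
#'
#' @param window codons on each side of the target codon (>= 10).
#' @param min_occurrence_reads minimum A-site reads inside the window for an
#'   occurrence to contribute (occurrences below it are dropped and
#'   counted).
#' @param isolation if `TRUE`, occurrences with another copy of the target
#'   codon inside their window are excluded (sensitivity check; the default
#'   keeps them, each occurrence being its own center).
#' @return list with class `metagene_config`.
#' @export
metagene_config <- function(window = 30L, min_occurrence_reads = 1L,
                            isolation = FALSE) {
  stopifnot(window >= 10L, min_occurrence_reads >= 1L)
  structure(list(window = as.integer(window),
                 min_occurrence_reads = as.integer(min_occurrence_reads),
                 isolation = isolation),
            class = "metagene_config")
}

#' Average RPF density around a target codon
#'
#' For every occurrence of `target_codon` whose full window lies inside the
#' CDS (stop codon excluded), the A-site counts over positions
#' `-window..+window` are normalized by their window mean and the normalized
#' windows are averaged position-wise, so every occurrence carries equal
#' weight regardless of gene expression. The resulting profile has window
#' mean 1; a flat profile means density at the target codon is typical of
#' its surroundings.
#'
#' @param tracks long count-track tibble from [build_count_tracks()].
#' @param transcripts transcript tibble.
#' @param target_codon a sense codon, e.g. `"TGG"`.
#' @param cfg a [metagene_config()].
#' @return a `metagene_profile` tibble with columns `position`,
#'   `mean_density`, `n_occurrences`, and attributes `target_codon`,
#'   `window`, `occurrences_total`, `boundary_dropped`, `zero_read_dropped`,
#'   `used`.
#' @export
metagene_profile <- function(tracks, transcripts, target_codon,
                             cfg = metagene_config()) {
  if (!target_codon %in% sense_codons()) {
    stop("target codon must be one of the 61 sense codons, got ",
         target_codon, call. = FALSE)
  }
  w <- cfg$window
  track_list <- split(tracks$count, tracks$transcript_id)
  windows <- list()
  occurrences_total <- 0L
  boundary_dropped <- 0L
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    codons <- split_codons(tx$cds_seq)
    occ <- which(codons == target_codon) - 1L        # 0-based
    occ <- occ[occ < tx$n_codons - 1L]               # never the stop codon
    if (length(occ) == 0L) next
    occurrences_total <- occurrences_total + length(occ)
    ok <- occ - w >= 0L & occ + w <= tx$n_codons - 2L
    boundary_dropped <- boundary_dropped + sum(!ok)
    occ <- occ[ok]
    if (cfg$isolation && length(occ) > 0L) {
      all_occ <- which(codons == target_codon) - 1L
      iso <- vapply(occ, function(j) {
        sum(abs(all_occ - j) <= w) == 1L
      }, logical(1))
      boundary_dropped <- boundary_dropped + sum(!iso)
      occ <- occ[iso]
    }
    if (length(occ) == 0L) next
    counts <- track_list[[tx$transcript_id]]
    mat <- t(vapply(occ, function(j) counts[(j - w):(j + w) + 1L],
                    numeric(2L * w + 1L)))
    windows[[length(windows) + 1L]] <- mat
  }
  if (length(windows) == 0L) {
    stop("no eligible occurrence of codon ", target_codon, call. = FALSE)
  }
  mat <- do.call(rbind, windows)
  sums <- rowSums(mat)
  usable <- sums >= cfg$min_occurrence_reads & sums > 0
  zero_read_dropped <- sum(!usable)
  if (!any(usable)) {
    stop("every occurrence of ", target_codon,
         " fell below min_occurrence_reads", call. = FALSE)
  }
  mat <- mat[usable, , drop = FALSE]
  norm <- mat / rowMeans(mat)
  out <- tibble::tibble(
    position = seq.int(-w, w),
    mean_density = colMeans(norm),
    n_occurrences = nrow(norm)
  )
  attr(out, "target_codon") <- target_codon
  attr(out, "window") <- w
  attr(out, "occurrences_total") <- occurrences_total
  attr(out, "boundary_dropped") <- boundary_dropped
  attr(out, "zero_read_dropped") <- zero_read_dropped
  attr(out, "used") <- nrow(norm)
  class(out) <- c("metagene_profile", class(out))
  out
}

#' Call density peaks in a metagene profile
#'
#' A position is a candidate peak if it is a strict local maximum within
#' +/- 2 codons. Candidates are visited from highest density down; one is
#' called when its density reaches `min_ratio` times the median density
#' over `search_range`, the median being taken after masking +/- 2 codons
#' around peaks already called. Candidates that fail the threshold are
#' returned with `passes_threshold = FALSE`.
#'
#' @param profile a `metagene_profile`.
#' @param min_ratio density-to-median ratio required to call a peak.
#' @param search_range inclusive position interval searched (default the
#'   whole window).
#' @return tibble `position`, `height` (density ratio over the background
#'   median at call time), `passes_threshold`, sorted by height, possibly
#'   empty.
#' @export
detect_peaks <- function(profile, min_ratio = 1.5, search_range = NULL) {
  stopifnot(inherits(profile, "metagene_profile"), min_ratio > 0)
  w <- attr(profile, "window")
  if (is.null(search_range)) search_range <- c(-w, w)
  pos <- profile$position
  dens <- profile$mean_density
  in_range <- pos >= search_range[1L] & pos <= search_range[2L]
  is_local_max <- vapply(seq_along(pos), function(i) {
    if (i <= 2L || i > length(pos) - 2L) return(FALSE)
    neigh <- dens[c(i - 2L, i - 1L, i + 1L, i + 2L)]
    all(dens[i] > neigh)
  }, logical(1))
  cand <- which(is_local_max & in_range)
  if (length(cand) == 0L) {
    return(tibble::tibble(position = integer(0), height = numeric(0),
                          passes_threshold = logical(0)))
  }
  cand <- cand[order(dens[cand], decreasing = TRUE)]
  called <- integer(0)
  rows <- lapply(cand, function(i) {
    masked <- in_range
    for (p in called) masked[abs(pos - pos[p]) <= 2L] <- FALSE
    med <- stats::median(dens[masked])
    height <- dens[i] / med
    passes <- is.finite(height) && height >= min_ratio
    if (passes) called <<- c(called, i)
    tibble::tibble(position = pos[i], height = height,
                   passes_threshold = passes)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$height, decreasing = TRUE), ]
}

#' Infer the number of stacked ribosomes from called peaks
#'
#' Counts, starting from the stall peak at offset 0, consecutive peaks at
#' one-ribosome-width spacings upstream (0, -w, -2w, ..., each within +/- 1
#' codon). Returns 0 when there is no stall-anchored peak.
#'
#' @param peaks peak table from [detect_peaks()]; only rows with
#'   `passes_threshold` are considered.
#' @param ribosome_width ribosome footprint width in codons.
#' @return integer: stalled ribosome plus queued ribosomes behind it.
#' @examples
#' pk <- tibble::tibble(position = c(0L, -10L, -20L), height = c(8, 3, 2),
#'                      passes_threshold = TRUE)
#' queue_summary(pk)  # 3
#' @export
queue_summary <- function(peaks, ribosome_width = 10L) {
  pos <- peaks$position[peaks$passes_threshold]
  if (!any(abs(pos) <= 1L)) return(0L)
  k <- 1L
  repeat {
    expected <- -k * ribosome_width
    if (!any(abs(pos - expected) <= 1L)) break
    k <- k + 1L
  }
  k
}
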