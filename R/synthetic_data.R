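#' @importFrom rlang .data %||%
NULL

# deterministic per-stage child seeds derived from one master seed
child_seed <- function(master, stage) {
  (as.integer(master) + 1000003L * as.integer(stage)) %% 2147483629L
}

#' Default codon sampling weights for the transcriptome generator
#'
#' Tryptophan (TGG) receives `tgg_weight` of the internal-codon mass
#' (matching its low natural frequency); the remaining 60 sense codons share
#' the rest equally.
#'
#' @param tgg_weight fraction of internal codons that are TGG.
#' @return tibble with columns `codon`, `weight` over the 61 sense codons.
#' @export
default_codon_weights <- function(tgg_weight = 0.02) {
  stopifnot(tgg_weight >= 0, tgg_weight < 1)
  codons <- sense_codons()
  w <- rep((1 - tgg_weight) / 60, length(codons))
  w[codons == "TGG"] <- tgg_weight
  tibble::tibble(codon = codons, weight = w)
}

#' Generate a synthetic transcriptome
#'
#' Every transcript starts with ATG, ends with a random stop codon and has
#' its internal codons drawn independently from `codon_weights` (restricted
#' to sense codons), so realized codon composition matches the weights up to
#' multinomial noise. Lengths are uniform over `length_range_codons`.
#'
#' @param n_genes number of transcripts.
#' @param length_range_codons inclusive codon-length range; the minimum must
#'   exceed the occupancy cutoff plus the metagene window so downstream
#'   analyses have eligible positions.
#' @param codon_weights tibble `codon`/`weight` over sense codons.
#' @param seed integer seed; the same seed reproduces the same FASTA byte
#'   for byte.
#' @param occupancy_cutoff,metagene_window values used only to validate that
#'   `length_range_codons` leaves room for the downstream analyses.
#' @return transcript tibble (`transcript_id`, `cds_seq`, `n_codons`) as
#'   from [read_cds_fasta()].
#' @export
generate_transcriptome <- function(n_genes,
                                   length_range_codons = c(250L, 600L),
                                   codon_weights = default_codon_weights(),
                                   seed = 1L,
                                   occupancy_cutoff = 90L,
                                   metagene_window = 30L) {
  stopifnot(n_genes >= 1L, length(length_range_codons) == 2L)
  if (length_range_codons[1L] <= occupancy_cutoff + metagene_window) {
    stop("minimum transcript length (", length_range_codons[1L],
         " codons) must exceed occupancy cutoff + metagene window (",
         occupancy_cutoff + metagene_window, ")", call. = FALSE)
  }
  stopifnot(all(codon_weights$weight >= 0), sum(codon_weights$weight) > 0)
  cw <- codon_weights[codon_weights$codon %in% sense_codons(), ]
  withr::with_seed(child_seed(seed, 0L), {
    n_codons <- length_range_codons[1L] +
      sample.int(length_range_codons[2L] - length_range_codons[1L] + 1L,
                 n_genes, replace = TRUE) - 1L
    seqs <- vapply(n_codons, function(n) {
      internal <- sample(cw$codon, n - 2L, replace = TRUE, prob = cw$weight)
      paste0("ATG", paste(internal, collapse = ""),
             sample(stop_codons(), 1L))
    }, character(1))
  })
  tibble::tibble(
    transcript_id = sprintf("g%04d", seq_len(n_genes)),
    cds_seq = seqs,
    n_codons = as.integer(n_codons)
  )
}

#' Footprint length distribution
#'
#' The default emulates the gel-purified RPF size range: a discrete
#' triangular distribution on 26-30 nt rising to a mode at 30 (90% of the
#' mass) plus a uniform 17-25 nt minor tail (10%).
#'
#' @return tibble with columns `length`, `prob`.
#' @export
footprint_length_dist <- function() {
  tail_len <- 17:25
  main_len <- 26:30
  tibble::tibble(
    length = c(tail_len, main_len),
    prob = c(rep(0.1 / 9, 9), 0.9 * (1:5) / 15)
  )
}

#' Build a simulation scenario
#'
#' Presets mirror the study conditions: `control` (uniform codon dwell, no
#' stalling), `h2o2` (oxidative stress: TGG dwell raised 8-fold, ribosome
#' queuing with probability 0.3 per layer, up to 2 queued ribosomes) and
#' `h2o2_trp` (stress plus supplemental tryptophan: dwell and queuing
#' identical to control, modelling the charging rescue).
#'
#' @param name one of `"control"`, `"h2o2"`, `"h2o2_trp"`.
#' @param overrides named list of scenario fields to override; recognized
#'   fields are `dwell` (tibble `codon`/`dwell` over the 61 sense codons,
#'   pre-stall), `stall_codon`, `stall_factor`, `queue_prob`,
#'   `max_queue_depth`, `ribosome_width_codons`, `expression`, `n_genes`,
#'   `length_range`, `codon_weights`, `n_footprints`, `n_rna_reads`,
#'   `fixed_length`, `seed`.
#' @return a `sim_scenario` list. The stored `dwell` table has the stall
#'   factor already applied to the stall codon.
#' @examples
#' make_scenario("h2o2", overrides = list(seed = 42))
#' @export
make_scenario <- function(name, overrides = list()) {
  presets <- list(
    control  = list(stall_codon = NULL, stall_factor = 1, queue_prob = 0),
    h2o2     = list(stall_codon = "TGG", stall_factor = 8, queue_prob = 0.3),
    h2o2_trp = list(stall_codon = NULL, stall_factor = 1, queue_prob = 0)
  )
  if (!name %in% names(presets)) {
    stop("unknown scenario '", name, "'; presets: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  scn <- list(
    name = name,
    dwell = NULL,
    stall_codon = presets[[name]]$stall_codon,
    stall_factor = presets[[name]]$stall_factor,
    queue_prob = presets[[name]]$queue_prob,
    max_queue_depth = 2L,
    ribosome_width_codons = 10L,
    expression = NULL,
    n_genes = 200L,
    length_range = c(250L, 600L),
    codon_weights = NULL,
    n_footprints = 1e6,
    n_rna_reads = 1e6,
    fixed_length = NULL,
    seed = 1L
  )
  unknown <- setdiff(names(overrides), names(scn))
  if (length(unknown) > 0L) {
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  scn[names(overrides)] <- overrides
  # base dwell (uniform unless supplied), then the stall multiplier
  base <- scn$dwell %||%
    tibble::tibble(codon = sense_codons(), dwell = 1)
  base <- base[order(base$codon), ]
  if (!identical(base$codon, sense_codons()) || any(base$dwell <= 0)) {
    stop("dwell must map each of the 61 sense codons to a positive value",
         call. = FALSE)
  }
  if (!is.null(scn$stall_codon)) {
    if (!scn$stall_codon %in% sense_codons()) {
      stop("stall_codon must be a sense codon", call. = FALSE)
    }
    if (!is.numeric(scn$stall_factor) || scn$stall_factor < 1) {
      stop("stall_factor must be >= 1", call. = FALSE)
    }
    base$dwell[base$codon == scn$stall_codon] <-
      base$dwell[base$codon == scn$stall_codon] * scn$stall_factor
  }
  scn$dwell <- base
  if (scn$queue_prob < 0 || scn$queue_prob >= 1) {
    stop("queue_prob must lie in [0, 1)", call. = FALSE)
  }
  if (scn$max_queue_depth < 0L) stop("max_queue_depth must be >= 0",
                                     call. = FALSE)
  if (!is.null(scn$fixed_length)) {
    if (!("ribosome_width_codons" %in% names(overrides))) {
      scn$ribosome_width_codons <- as.integer(round(scn$fixed_length / 3))
    }
  }
  nominal <- scn$fixed_length %||% 30L
  if (scn$ribosome_width_codons * 3L != nominal &&
      abs(scn$ribosome_width_codons - nominal / 3) > 0.5) {
    stop("ribosome_width_codons is inconsistent with the nominal footprint ",
         "length (", nominal, " nt)", call. = FALSE)
  }
  if (scn$n_footprints < 1) stop("n_footprints must be >= 1", call. = FALSE)
  structure(scn, class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario>", x$name, "\n")
  cat("  stall:", if (is.null(x$stall_codon)) "none" else
      paste0(x$stall_codon, " x", x$stall_factor),
      " queue_prob:", x$queue_prob,
      " depth:", x$max_queue_depth, "\n")
  cat("  n_footprints:", format(x$n_footprints, scientific = FALSE),
      " n_rna_reads:", format(x$n_rna_reads, scientific = FALSE),
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Read a scenario description from YAML
#'
#' Recognized keys: `scenario` (preset name) plus any [make_scenario()]
#' override field.
#'
#' @param path path to a YAML file.
#' @return a `sim_scenario`.
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$scenario)) stop("YAML must name a 'scenario'", call. = FALSE)
  name <- y$scenario
  y$scenario <- NULL
  if (!is.null(y$length_range)) y$length_range <- as.integer(y$length_range)
  make_scenario(name, overrides = y)
}

# realized relative expression per transcript; lognormal (sdlog 1) unless
# the scenario fixes it. Deterministic given the scenario seed.
scenario_expression <- function(scenario, transcripts) {
  expr <- scenario$expression
  if (is.null(expr)) {
    withr::with_seed(child_seed(scenario$seed, 1L), {
      w <- stats::rlnorm(nrow(transcripts), meanlog = 0, sdlog = 1)
    })
  } else {
    if (is.data.frame(expr)) expr <- stats::setNames(expr$weight, expr$gene_id)
    w <- expr[transcripts$transcript_id]
    if (anyNA(w)) stop("scenario expression is missing some transcripts",
                       call. = FALSE)
    w <- unname(w)
  }
  w / sum(w)
}

#' Simulate ribosome footprints
#'
#' Occupancy-weighted positional sampling: a gene's chance of yielding a
#' footprint is proportional to its expression times its total codon dwell
#' (the steady-state ribosome load), and within a gene the A-site codon is
#' drawn proportionally to dwell over the non-stop codons. The 5' end is
#' placed so that the A-site, under [default_offsets()], falls on the drawn
#' codon; draws whose 5' end would leave the CDS are skipped and counted.
#' Under a queuing scenario, each primary footprint stalled on the stall
#' codon seeds a queued footprint one ribosome width upstream with
#' probability `queue_prob`, and that one seeds a second with the same
#' probability (geometric decay, capped by `max_queue_depth`).
#'
#' @param transcripts transcript tibble.
#' @param scenario a `sim_scenario` from [make_scenario()].
#' @return tibble with columns `transcript_id`, `start`, `length`, `origin`
#'   ("primary" or "queued"), with attributes `n_primary`, `n_queued`,
#'   `n_skipped` (boundary skips, primary + queued).
#' @export
simulate_footprints <- function(transcripts, scenario) {
  stopifnot(inherits(scenario, "sim_scenario"), nrow(transcripts) > 0L)
  expr <- scenario_expression(scenario, transcripts)
  dwell <- stats::setNames(scenario$dwell$dwell, scenario$dwell$codon)
  codons_by_tx <- lapply(transcripts$cds_seq, split_codons)
  # per-transcript dwell over placement-eligible codons (stop excluded)
  dw_by_tx <- lapply(codons_by_tx, function(cd) {
    unname(dwell[cd[-length(cd)]])
  })
  gene_w <- expr * vapply(dw_by_tx, sum, numeric(1))
  # flat codon lookup: codon identity of (transcript row, codon index)
  all_codons <- unlist(codons_by_tx, use.names = FALSE)
  tx_off <- c(0L, cumsum(lengths(codons_by_tx)))[seq_len(nrow(transcripts))]

  len_dist <- footprint_length_dist()
  draw_lengths <- function(n) {
    if (!is.null(scenario$fixed_length)) {
      rep(as.integer(scenario$fixed_length), n)
    } else {
      sample(len_dist$length, n, replace = TRUE, prob = len_dist$prob)
    }
  }
  offsets <- default_offsets()
  place <- function(tx_row, codon_idx) {
    len <- draw_lengths(length(codon_idx))
    start <- 3L * codon_idx - lookup_offset(offsets, len)
    ok <- start >= 0L & start + len <= 3L * transcripts$n_codons[tx_row]
    list(start = start, length = len, ok = ok)
  }

  withr::with_seed(child_seed(scenario$seed, 2L), {
    per_gene <- as.vector(stats::rmultinom(1L, scenario$n_footprints, gene_w))
    tx_row <- rep(seq_len(nrow(transcripts)), per_gene)
    codon_idx <- unlist(lapply(which(per_gene > 0L), function(g) {
      dw <- dw_by_tx[[g]]
      sample.int(length(dw), per_gene[g], replace = TRUE, prob = dw) - 1L
    }), use.names = FALSE)
    p <- place(tx_row, codon_idx)
    n_skipped <- sum(!p$ok)
    primary <- tibble::tibble(
      transcript_id = transcripts$transcript_id[tx_row[p$ok]],
      start = p$start[p$ok],
      length = p$length[p$ok],
      origin = "primary"
    )
    keep_idx <- codon_idx[p$ok]
    keep_row <- tx_row[p$ok]

    queued <- NULL
    if (scenario$queue_prob > 0 && scenario$max_queue_depth > 0L &&
        !is.null(scenario$stall_codon)) {
      codon_id <- all_codons[tx_off[keep_row] + keep_idx + 1L]
      at_stall <- which(codon_id == scenario$stall_codon)
      w <- scenario$ribosome_width_codons
      q_rows <- integer(0); q_idx <- integer(0)
      seed_rows <- at_stall
      for (depth in seq_len(scenario$max_queue_depth)) {
        emit <- seed_rows[stats::runif(length(seed_rows)) < scenario$queue_prob]
        if (length(emit) == 0L) break
        q_rows <- c(q_rows, keep_row[emit])
        q_idx <- c(q_idx, keep_idx[emit] - depth * w)
        seed_rows <- emit
      }
      if (length(q_rows) > 0L) {
        valid <- q_idx >= 0L
        n_skipped <- n_skipped + sum(!valid)
        pq <- place(q_rows[valid], q_idx[valid])
        n_skipped <- n_skipped + sum(!pq$ok)
        queued <- tibble::tibble(
          transcript_id = transcripts$transcript_id[q_rows[valid][pq$ok]],
          start = pq$start[pq$ok],
          length = pq$length[pq$ok],
          origin = "queued"
        )
      }
    }
  })
  out <- dplyr::bind_rows(primary, queued)
  attr(out, "n_primary") <- nrow(primary)
  attr(out, "n_queued") <- if (is.null(queued)) 0L else nrow(queued)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Simulate matched RNA-seq gene counts
#'
#' RNA reads are multinomial over genes with probability proportional to
#' expression times CDS length; RPF counts are the per-gene footprint totals
#' of a matching [simulate_footprints()] run (performed here when not
#' supplied).
#'
#' @param transcripts transcript tibble.
#' @param scenario a `sim_scenario`.
#' @param footprints optional footprint tibble from [simulate_footprints()]
#'   run under the same scenario.
#' @return tibble with columns `gene_id`, `rpf_count`, `rna_count`.
#' @export
simulate_rnaseq_counts <- function(transcripts, scenario, footprints = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$n_rna_reads < 1) stop("n_rna_reads must be >= 1", call. = FALSE)
  if (is.null(footprints)) {
    footprints <- simulate_footprints(transcripts, scenario)
  }
  expr <- scenario_expression(scenario, transcripts)
  withr::with_seed(child_seed(scenario$seed, 3L), {
    rna <- as.vector(stats::rmultinom(1L, scenario$n_rna_reads,
                                      expr * transcripts$n_codons))
  })
  rpf <- table(factor(footprints$transcript_id,
                      levels = transcripts$transcript_id))
  tibble::tibble(
    gene_id = transcripts$transcript_id,
    rpf_count = as.integer(rpf),
    rna_count = as.integer(rna)
  )
}

#' Run a full simulated experiment
#'
#' Convenience wrapper: generate (or reuse) a transcriptome, simulate
#' footprints and matched RNA-seq counts under one scenario.
#'
#' @param scenario a `sim_scenario`.
#' @param transcripts optional pre-built transcript tibble; generated from
#'   the scenario's `n_genes`/`length_range`/`codon_weights`/`seed` when
#'   absent.
#' @return list with elements `transcripts`, `footprints`, `counts`.
#' @export
simulate_experiment <- function(scenario, transcripts = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (is.null(transcripts)) {
    transcripts <- generate_transcriptome(
      n_genes = scenario$n_genes,
      length_range_codons = scenario$length_range,
      codon_weights = scenario$codon_weights %||% default_codon_weights(),
      seed = scenario$seed
    )
  }
  footprints <- simulate_footprints(transcripts, scenario)
  counts <- simulate_rnaseq_counts(transcripts, scenario, footprints)
  list(transcripts = transcripts, footprints = footprints, counts = counts)
}
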