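test_that("generated transcripts satisfy the CDS invariants and are reproducible", {
  tx <- generate_transcriptome(5, c(250, 250), seed = 2)
  expect_equal(tx$n_codons, rep(250L, 5))
  for (s in tx$cds_seq) {
    codons <- split_codons(s)
    expect_equal(codons[1], "ATG")
    expect_true(codons[length(codons)] %in% stop_codons())
    expect_false(any(codons[-length(codons)] %in% stop_codons()))
  }
  # same seed, byte-identical FASTA
  fa1 <- withr::local_tempfile(fileext = ".fa")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  write_cds_fasta(generate_transcriptome(5, c(250, 250), seed = 2), fa1)
  write_cds_fasta(tx, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  # too-short transcripts for the downstream cutoffs are refused
  expect_error(generate_transcriptome(5, c(100, 100)), "cutoff")
})

test_that("realized internal codon composition matches the sampling weights", {
  tx <- generate_transcriptome(60, c(150, 200),
                               codon_weights = default_codon_weights(0.02),
                               seed = 5)
  internal <- unlist(lapply(tx$cds_seq, function(s) {
    cd <- split_codons(s)
    cd[-c(1L, length(cd))]
  }))
  n <- length(internal)
  expect_gt(n, 8000)
  frac <- mean(internal == "TGG")
  tol <- 4 * sqrt(0.02 * 0.98 / n)  # binomial CI at the generator parameter
  expect_lt(abs(frac - 0.02), tol)
})

test_that("scenario presets encode the study conditions and validate overrides", {
  ctl <- make_scenario("control")
  expect_equal(ctl$queue_prob, 0)
  expect_true(all(ctl$dwell$dwell == 1))

  h <- make_scenario("h2o2")
  expect_equal(h$stall_codon, "TGG")
  expect_equal(h$dwell$dwell[h$dwell$codon == "TGG"], 8)
  expect_equal(h$queue_prob, 0.3)
  expect_equal(h$max_queue_depth, 2L)

  # tryptophan rescue: dwell identical to control
  trp <- make_scenario("h2o2_trp")
  expect_equal(trp$dwell, ctl$dwell)
  expect_equal(trp$queue_prob, 0)

  expect_error(make_scenario("mystery"), "control")
  expect_error(make_scenario("h2o2", overrides = list(stall_factor = -1)),
               "stall_factor")
  expect_error(make_scenario("h2o2", overrides = list(queue_prob = 1.2)),
               "queue_prob")
  expect_error(make_scenario("control", overrides = list(typo = 1)),
               "unknown scenario field")
})

test_that("scenario YAML files reproduce make_scenario presets with overrides", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("scenario: h2o2", "n_genes: 20", "stall_factor: 4",
               "queue_prob: 0.2", "n_footprints: 1000", "seed: 9"), yml)
  scn <- read_scenario_yaml(yml)
  expect_equal(scn$name, "h2o2")
  expect_equal(scn$dwell$dwell[scn$dwell$codon == "TGG"], 4)
  expect_equal(scn$queue_prob, 0.2)
  expect_equal(scn$seed, 9)
  writeLines("n_genes: 20", yml)
  expect_error(read_scenario_yaml(yml), "scenario")
})

test_that("footprints respect bounds, length range and count conservation", {
  ex <- small_sim("h2o2")
  fp <- ex$footprints
  nt_len <- 3L * ex$transcripts$n_codons[match(fp$transcript_id,
                                               ex$transcripts$transcript_id)]
  expect_true(all(fp$start >= 0L))
  expect_true(all(fp$start + fp$length <= nt_len))
  expect_true(all(fp$length >= 17L & fp$length <= 30L))
  # primary emissions + boundary skips account for every requested draw
  n_queued_skips <- attr(fp, "n_skipped") -
    (2e5 - attr(fp, "n_primary"))
  expect_gte(n_queued_skips, 0L)
  expect_equal(nrow(fp), attr(fp, "n_primary") + attr(fp, "n_queued"))
  # same seed reproduces the run exactly
  scn <- make_scenario("h2o2", overrides = list(n_genes = 50L,
                                                n_footprints = 2e5,
                                                n_rna_reads = 2e5,
                                                seed = 11L))
  fp2 <- simulate_footprints(ex$transcripts, scn)
  expect_identical(as.data.frame(fp), as.data.frame(fp2))
})

test_that("uniform dwell with no queuing yields near-uniform A-site counts", {
  tx <- make_transcripts(c(g1 = make_cds(rep(c("AAA", "CAC", "GGC", "TTC"),
                                             75))))  # 302 codons
  scn <- make_scenario("control",
                       overrides = list(n_footprints = 3e5, seed = 4L,
                                        expression = c(g1 = 1)))
  fp <- simulate_footprints(tx, scn)
  tracks <- build_count_tracks(fp, default_offsets(), tx)
  # codons 5..300 are reachable for every length; Poisson check there
  inner <- tracks$count[tracks$codon_index >= 10 &
                        tracks$codon_index <= 295]
  lambda <- mean(inner)
  expect_gt(lambda, 900)
  # dispersion near 1 and no position far outside Poisson range
  expect_lt(abs(stats::var(inner) / lambda - 1), 0.2)
  expect_true(all(abs(inner - lambda) < 6 * sqrt(lambda)))
})

test_that("stalling enrichment matches the closed-form sampling mixture", {
  internal <- rep(c(rep("AAA", 24), "TGG"), 12)  # 300 internal codons
  tx <- make_transcripts(c(g1 = make_cds(internal)))
  codons <- split_codons(tx$cds_seq)
  scn <- make_scenario("h2o2",
                       overrides = list(queue_prob = 0, n_footprints = 2e5,
                                        seed = 6L, expression = c(g1 = 1)))
  tracks <- build_count_tracks(simulate_footprints(tx, scn),
                               default_offsets(), tx)
  cfg <- occupancy_config(codon_cutoff = 90)
  g <- gene_occupancy(tracks[tracks$transcript_id == "g1", ], tx, cfg)
  # oracle 1: brute-force enumeration of the emission rule (exact
  # expectation, including boundary skips near the stop codon)
  dwell <- stats::setNames(scn$dwell$dwell, scn$dwell$codon)
  ew <- expected_asite_weights(codons, dwell, footprint_length_dist())
  want <- naive_gene_occupancy(ew, codons, cfg$codon_cutoff, 0)
  o_exp <- want$o[want$codon == "TGG"]
  expect_lt(abs(g$o[g$codon == "TGG"] / o_exp - 1), 0.03)
  # oracle 2: the boundary-free closed form s/(1 + (s-1)a) anchors the
  # magnitude; end-of-CDS skips (last ~10 codons lose most footprint
  # lengths) depress the exact expectation several percent below it
  a <- g$a[g$codon == "TGG"]
  expect_lt(abs(o_exp / (8 / (1 + 7 * a)) - 1), 0.10)
})

test_that("queued footprints appear one ribosome width upstream at rate q", {
  # one gene with a single TGG far from boundaries
  internal <- c(rep("AAA", 199), "TGG", rep("AAA", 100))
  tx <- make_transcripts(c(g1 = make_cds(internal)))
  scn <- make_scenario("h2o2",
                       overrides = list(n_footprints = 1e5, seed = 8L,
                                        expression = c(g1 = 1)))
  fp <- simulate_footprints(tx, scn)
  tracks <- build_count_tracks(fp, default_offsets(), tx)
  cnt <- tracks$count
  stall_idx <- 200L  # 0-based index of the TGG
  n0 <- sum(fp$origin == "primary" &
            assign_asite(fp, default_offsets(), tx) == stall_idx,
            na.rm = TRUE)
  bg <- mean(cnt[(stall_idx - 40):(stall_idx - 25) + 1L])
  excess10 <- cnt[stall_idx - 10L + 1L] - bg
  excess20 <- cnt[stall_idx - 20L + 1L] - bg
  tol10 <- 4 * sqrt(n0 * 0.3 * 0.7 + bg)
  tol20 <- 4 * sqrt(n0 * 0.09 * 0.91 + bg)
  expect_lt(abs(excess10 - 0.3 * n0), tol10)
  expect_lt(abs(excess20 - 0.09 * n0), tol20)
  # depth cap: no excess at -30
  excess30 <- cnt[stall_idx - 30L + 1L] - bg
  expect_lt(abs(excess30), 4 * sqrt(bg))
})

test_that("RNA-seq counts follow the expression-by-length multinomial", {
  tx <- make_transcripts(c(g1 = make_cds(rep("AAA", 248)),
                           g2 = make_cds(rep("GGC", 248))))
  scn <- make_scenario("control",
                       overrides = list(n_footprints = 1000, seed = 12L,
                                        n_rna_reads = 1e6,
                                        expression = c(g1 = 3, g2 = 1)))
  counts <- simulate_rnaseq_counts(tx, scn)
  ratio <- counts$rna_count[1] / counts$rna_count[2]
  p <- 0.75
  se_ratio <- sqrt(p * (1 - p) / 1e6) / (1 - p)^2  # delta method
  expect_lt(abs(ratio - 3), 4 * se_ratio)
  # rpf_count equals the per-gene footprint totals; same seed, same counts
  fp <- simulate_footprints(tx, scn)
  expect_equal(counts$rpf_count,
               as.integer(table(factor(fp$transcript_id,
                                       levels = tx$transcript_id))))
  expect_identical(counts, simulate_rnaseq_counts(tx, scn))
  scn0 <- scn; scn0$n_rna_reads <- 0
  expect_error(simulate_rnaseq_counts(tx, scn0, fp), "n_rna_reads")
})

test_that("control simulation recovers flat occupancy (self-consistency)", {
  ex <- small_sim("control")
  tracks <- build_count_tracks(ex$footprints, default_offsets(),
                               ex$transcripts)
  prof <- occupancy_profile(tracks, ex$transcripts)
  expect_equal(nrow(prof), 61L)
  dev <- abs(prof$mean_occupancy - 1)
  expect_true(all(dev < 3 * prof$stderr + 1e-12))
})

test_that("injected dwell heterogeneity is recovered by estimated occupancy", {
  dw <- withr::with_seed(21, {
    tibble::tibble(codon = sense_codons(),
                   dwell = exp(stats::rnorm(61, sd = 0.5)))
  })
  scn <- make_scenario("control",
                       overrides = list(dwell = dw, n_genes = 50L,
                                        n_footprints = 3e5, seed = 13L))
  ex <- simulate_experiment(scn)
  tracks <- build_count_tracks(ex$footprints, default_offsets(),
                               ex$transcripts)
  prof <- occupancy_profile(tracks, ex$transcripts)
  joined <- dplyr::inner_join(tidy(prof), dw, by = "codon")
  rho <- stats::cor(log(joined$mean_occupancy), log(joined$dwell),
                    method = "spearman")
  expect_gte(rho, 0.9)
})
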