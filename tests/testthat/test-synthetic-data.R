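test_that("transcriptome generation is deterministic for a fixed seed", {
  m1 <- generate_transcriptome(10, seed = 7)
  m2 <- generate_transcriptome(10, seed = 7)
  expect_identical(m1, m2)
  m3 <- generate_transcriptome(10, seed = 8)
  expect_false(identical(m1, m3))
})

test_that("generated transcript models satisfy their structural invariants", {
  models <- generate_transcriptome(40, seed = 3)
  for (tx in models) {
    expect_equal(tx$exons$length, nchar(tx$exons$seq))
    expect_equal(tx$exons$end - tx$exons$start + 1L, tx$exons$length)
    expect_true(all(diff(tx$exons$start) > 0))
    expect_lt(tx$cds_start, tx$cds_stop)
    expect_equal((tx$cds_stop - tx$cds_start) %% 3, 0)
    seq <- paste(tx$exons$seq, collapse = "")
    expect_equal(substr(seq, tx$cds_start, tx$cds_start + 2), "ATG")
    expect_true(substr(seq, tx$cds_stop, tx$cds_stop + 2) %in%
                  c("TAA", "TAG", "TGA"))
    # annotated ORF is clean: no internal in-frame stop
    expect_equal(orf_internal_stops(tx), 0L)
    # CDS spans at least two exons
    start_exon <- which(tx$exons$start <= tx$cds_start &
                          tx$exons$end >= tx$cds_start)
    stop_exon <- which(tx$exons$start <= tx$cds_stop &
                         tx$exons$end >= tx$cds_stop)
    expect_gt(stop_exon, start_exon)
  }
})

test_that("motif_rate = 0 yields motif-free sequences", {
  models <- generate_transcriptome(25, motif_rate = 0, seed = 5)
  seqs <- exon_sequences(models)
  expect_equal(sum(count_motif(seqs$exon_seq)), 0L)
})

test_that("motif planting hits the calibrated per-256-bp rate", {
  # 125 transcripts x 8 exons of exactly 256 bp = 1000 exons; with
  # motif_rate = 1 the mean count per exon is Poisson(1) in expectation.
  models <- generate_transcriptome(125, exons_per_tx = c(8, 8),
                                   exon_len = c(256, 256), motif_rate = 1,
                                   seed = 13)
  seqs <- exon_sequences(models)
  expect_equal(nrow(seqs), 1000L)
  counts <- count_motif(seqs$exon_seq)
  se <- sqrt(1 / length(counts))
  expect_lt(abs(mean(counts) - 1), 3 * se)
})

test_that("generator rejects invalid parameters", {
  expect_error(generate_transcriptome(0), "positive")
  expect_error(generate_transcriptome(5, exons_per_tx = c(1, 3)), "2 exons")
  expect_error(generate_transcriptome(5, motif_rate = -1), ">= 0")
  expect_error(generate_transcriptome(5, exon_len = c(10, 5)), "range")
})

test_that("plant_effects sizes, window exclusion and disjointness hold", {
  models <- generate_transcriptome(100, seed = 2)
  d0 <- simulation_design(frac_de = 0, frac_as = 0, seed = 2)
  t0 <- plant_effects(models, d0)
  expect_equal(nrow(t0$de_transcripts), 0L)
  expect_equal(nrow(t0$as_exons), 0L)

  d <- simulation_design(frac_de = 0.1, frac_as = 0.05, seed = 2)
  tr <- plant_effects(models, d)
  expect_equal(nrow(tr$de_transcripts), 10L)
  expect_true(all(tr$de_transcripts$fold > 0))
  # no planted ratio inside the open (2/3, 1.5) window
  expect_true(all(tr$as_exons$ratio <= 2 / 3 | tr$as_exons$ratio >= 1.5))
  # planted exons never sit on planted DE transcripts
  expect_length(intersect(tr$as_exons$transcript_id,
                          tr$de_transcripts$transcript_id), 0)
  # truth keys exist in the models
  expect_true(all(tr$de_transcripts$transcript_id %in% names(models)))
  expect_true(all(tr$as_exons$transcript_id %in% names(models)))
})

test_that("discrete planted-ratio sets are honoured", {
  models <- generate_transcriptome(80, seed = 4)
  d <- simulation_design(frac_as = 0.1, as_ratio_values = c(0.5, 2), seed = 4)
  tr <- plant_effects(models, d)
  expect_true(all(tr$as_exons$ratio %in% c(0.5, 2)))
  expect_error(simulation_design(as_ratio_values = c(0.8, 2)), "outside")
})

test_that("simulated probe matrices are deterministic and well-formed", {
  models <- generate_transcriptome(30, seed = 9)
  d <- simulation_design(frac_de = 0.1, frac_as = 0.05, seed = 9)
  tr <- plant_effects(models, d)
  pm1 <- simulate_probe_matrix(models, tr, d)
  pm2 <- simulate_probe_matrix(models, tr, d)
  expect_identical(pm1$values, pm2$values)
  expect_true(all(pm1$values >= 0))
  expect_equal(ncol(pm1$values), 8)
  n_exons <- sum(vapply(models, function(tx) nrow(tx$exons), 1L))
  expect_equal(nrow(pm1$probeset_info), length(models) + n_exons)

  bad_truth <- tr
  bad_truth$de_transcripts <- tibble::tibble(transcript_id = "NOPE", fold = 2)
  expect_error(simulate_probe_matrix(models, bad_truth, d), "absent")
})

test_that("full mosaicism collapses KO onto the CTRL expression state", {
  models <- generate_transcriptome(20, seed = 10)
  d <- simulation_design(frac_de = 0.2, frac_as = 0.1, mosaic_fraction = 1,
                         noise_sd = 0, background_mean = 0, seed = 10)
  tr <- plant_effects(models, d)
  pm <- simulate_probe_matrix(models, tr, d)
  ctrl <- pm$values[, 1:4]
  ko <- pm$values[, 5:8]
  expect_equal(unname(ko), unname(ctrl), tolerance = 1e-12)
})

test_that("noise-free planted ratios pass through the splicing index exactly", {
  models <- generate_transcriptome(20, seed = 21)
  d <- simulation_design(frac_de = 0, frac_as = 0.05,
                         as_ratio_values = c(0.5, 2),
                         noise_sd = 0, background_mean = 0, seed = 21)
  tr <- plant_effects(models, d)
  expect_gt(nrow(tr$as_exons), 0)
  pm <- simulate_probe_matrix(models, tr, d)
  # summarize only: no background, no quantile step, so the planted signal
  # is untouched
  prep <- preprocess_probe_matrix(pm, background = FALSE, quantile = FALSE,
                                  gene_linear_floor = 0,
                                  exon_log2_floor = -Inf)
  cands <- compute_psi_ratio(prep$exon, prep$gene, attr(pm, "design"))
  key <- paste(cands$transcript_id, cands$exon_index)
  tkey <- paste(tr$as_exons$transcript_id, tr$as_exons$exon_index)
  got <- cands$psi_ratio[match(tkey, key)]
  expect_equal(got, tr$as_exons$ratio, tolerance = 1e-12)
  # unplanted exons have ratio exactly 1
  expect_equal(cands$psi_ratio[!key %in% tkey],
               rep(1, sum(!key %in% tkey)), tolerance = 1e-12)
})

test_that("mosaicism contracts observed PSI ratios as (1 - m) * r + m", {
  models <- generate_transcriptome(20, seed = 22)
  for (m_frac in c(0.3, 0.7)) {
    d <- simulation_design(frac_de = 0, frac_as = 0.05,
                           as_ratio_values = c(0.5, 2),
                           mosaic_fraction = m_frac,
                           noise_sd = 0, background_mean = 0, seed = 22)
    tr <- plant_effects(models, d)
    pm <- simulate_probe_matrix(models, tr, d)
    prep <- preprocess_probe_matrix(pm, background = FALSE, quantile = FALSE,
                                    gene_linear_floor = 0,
                                    exon_log2_floor = -Inf)
    cands <- compute_psi_ratio(prep$exon, prep$gene, attr(pm, "design"))
    key <- paste(cands$transcript_id, cands$exon_index)
    tkey <- paste(tr$as_exons$transcript_id, tr$as_exons$exon_index)
    got <- cands$psi_ratio[match(tkey, key)]
    expect_equal(got, (1 - m_frac) * tr$as_exons$ratio + m_frac,
                 tolerance = 1e-12)
  }
})

test_that("motif enrichment lifts planted exons to the target frequency", {
  models <- generate_transcriptome(40, motif_rate = 0.3, seed = 30)
  d <- simulation_design(frac_as = 0.08, seed = 30)
  tr <- plant_effects(models, d)
  enriched <- enrich_planted_motifs(models, tr, target_freq = 2.5, seed = 30)
  seqs <- exon_sequences(enriched)
  key <- paste(seqs$transcript_id, seqs$exon_index)
  tkey <- paste(tr$as_exons$transcript_id, tr$as_exons$exon_index)
  planted <- seqs[key %in% tkey, ]
  fr <- motif_frequency(count_motif(planted$exon_seq), planted$exon_length)
  expect_true(all(fr >= 2.5 - 256 / min(planted$exon_length)))
  # ORFs stay clean after enrichment
  for (tx in enriched) expect_equal(orf_internal_stops(tx), 0L)
})
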