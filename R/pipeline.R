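#' Screen configuration
#'
#' Bundles every threshold of the candidate-filter cascade with the
#' synthetic-study parameters. Defaults are the screen's published
#' operating point: gene-level fold 1.5 and p <= 0.05, PSI exclusion
#' window (2/3, 1.5) with exon p <= 0.05, at least one AGAA site with
#' frequency F >= 1.5, gene floor 25 (linear) and exon floor 3 (log2).
#'
#' @param design A [simulation_design()].
#' @param n_transcripts,exons_per_tx,exon_len,motif_rate Transcriptome
#'   generator parameters, see [generate_transcriptome()].
#' @param motif_rich_planted Plant extra AGAA copies into exons carrying a
#'   splicing effect (Tra2b targets are motif-rich), see
#'   [enrich_planted_motifs()].
#' @param gene_fold_cut,gene_p_cut Transcript-level DE thresholds.
#' @param psi_low_cut,psi_high_cut,exon_p_cut Exon-level screen thresholds.
#' @param motif,min_motif_count,min_motif_freq Motif filter settings.
#' @param gene_linear_floor,exon_log2_floor Low-expression floors.
#' @param gc_adjust,n_gc_bins GC-bin centering switch and bin count.
#' @param exon_test `"student"` or `"moderated"`, see [compute_psi_ratio()].
#' @param out_dir Optional directory for result tables and the run log.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(design = simulation_design(),
                          n_transcripts = 300, exons_per_tx = c(4, 8),
                          exon_len = c(80, 300), motif_rate = 1,
                          motif_rich_planted = TRUE,
                          gene_fold_cut = 1.5, gene_p_cut = 0.05,
                          psi_low_cut = 2 / 3, psi_high_cut = 1.5,
                          exon_p_cut = 0.05,
                          motif = "AGAA", min_motif_count = 1,
                          min_motif_freq = 1.5,
                          gene_linear_floor = 25, exon_log2_floor = 3,
                          gc_adjust = FALSE, n_gc_bins = 25,
                          exon_test = "student", out_dir = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (psi_low_cut >= 1 || psi_high_cut <= 1) {
    abort("PSI window must satisfy psi_low_cut < 1 < psi_high_cut.")
  }
  for (nm in c("gene_fold_cut", "gene_p_cut", "exon_p_cut", "min_motif_freq",
               "gene_linear_floor", "exon_log2_floor")) {
    assert_scalar_number(get(nm), nm, positive = TRUE)
  }
  structure(
    list(design = design, n_transcripts = n_transcripts,
         exons_per_tx = exons_per_tx, exon_len = exon_len,
         motif_rate = motif_rate, motif_rich_planted = motif_rich_planted,
         gene_fold_cut = gene_fold_cut, gene_p_cut = gene_p_cut,
         psi_low_cut = psi_low_cut, psi_high_cut = psi_high_cut,
         exon_p_cut = exon_p_cut, motif = motif,
         min_motif_count = min_motif_count, min_motif_freq = min_motif_freq,
         gene_linear_floor = gene_linear_floor,
         exon_log2_floor = exon_log2_floor,
         gc_adjust = gc_adjust, n_gc_bins = n_gc_bins,
         exon_test = exon_test, out_dir = out_dir),
    class = "screen_config"
  )
}

#' Run the full differential-splicing screen on synthetic data
#'
#' Executes the end-to-end cascade: simulate a two-group probe matrix with
#' planted effects, preprocess (background correction, optional GC
#' centering, quantile normalization, mean/log2 summarization, expression
#' floors), call differentially expressed transcripts by moderated t,
#' screen exons by PSI ratio and p-value, exclude exons on DE transcripts,
#' apply the AGAA motif filter, and predict PTC/NMD consequences of
#' skipping each surviving exon. When `out_dir` is set, the candidate
#' tables, DE table, NMD report, exon FASTA and a run log (seed + config
#' hash) are written there.
#'
#' @param config A [screen_config()].
#' @return Object of class `screen_result`: tibbles `candidates` (final),
#'   `all_candidates`, `de_table`, `de_called`, `nmd`, a `stage_counts`
#'   tibble, the planted `truth`, the `models`, the `config` and its hash.
#' @export
run_screen <- function(config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  design <- config$design

  models <- generate_transcriptome(config$n_transcripts,
                                   config$exons_per_tx, config$exon_len,
                                   config$motif_rate, seed = design$seed,
                                   motif = config$motif)
  truth <- plant_effects(models, design)
  if (config$motif_rich_planted) {
    models <- enrich_planted_motifs(models, truth, motif = config$motif,
                                    seed = design$seed)
  }
  pm <- simulate_probe_matrix(models, truth, design)
  grp <- attr(pm, "design")

  prep <- preprocess_probe_matrix(
    pm, background = design$background_mean > 0, gc = config$gc_adjust,
    n_gc_bins = config$n_gc_bins, quantile = TRUE,
    gene_linear_floor = config$gene_linear_floor,
    exon_log2_floor = config$exon_log2_floor,
    bg_mean = design$background_mean, bg_sd = design$background_sd
  )

  de_table <- moderated_t_table(prep$gene, grp)
  de_called <- call_differential(de_table, config$gene_fold_cut,
                                 config$gene_p_cut)

  cands <- compute_psi_ratio(prep$exon, prep$gene, grp,
                             test = config$exon_test)
  filtered <- filter_splicing_candidates(cands, de_called$feature_id,
                                         config$psi_low_cut,
                                         config$psi_high_cut,
                                         config$exon_p_cut)
  seqs <- exon_sequences(models)
  final <- filtered |>
    dplyr::left_join(seqs, by = c("transcript_id", "exon_index")) |>
    apply_motif_filter(config$min_motif_count, config$min_motif_freq,
                       config$motif)
  nmd <- if (nrow(final) > 0) nmd_report(final, models) else tibble::tibble()

  stage_counts <- dplyr::bind_rows(attr(filtered, "stage_counts"),
                                   attr(final, "stage_counts"))
  result <- structure(
    list(candidates = final, all_candidates = cands, de_table = de_table,
         de_called = de_called, nmd = nmd, stage_counts = stage_counts,
         truth = truth, models = models, config = config,
         config_hash = rlang::hash(config)),
    class = "screen_result"
  )
  if (!is.null(config$out_dir)) write_screen_result(result, config$out_dir)
  result
}

# Serialize a screen result: candidate tables, DE table, NMD report, exon
# FASTA and a run log carrying the seed and config hash.
write_screen_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_candidate_table(result$candidates,
                        file.path(dir, "candidates_final.tsv"))
  write_candidate_table(result$all_candidates |>
                          dplyr::left_join(exon_sequences(result$models),
                                           by = c("transcript_id", "exon_index")),
                        file.path(dir, "candidates_all.tsv"))
  write_de_table(result$de_table, file.path(dir, "de_table.tsv"))
  if (nrow(result$nmd) > 0) {
    readr::write_tsv(result$nmd, file.path(dir, "nmd_report.tsv"))
  }
  write_exon_fasta(result$models, file.path(dir, "exons.fasta"))
  log_lines <- c(
    sprintf("psiscreen run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d", result$config$design$seed),
    sprintf("config_hash: %s", result$config_hash),
    sprintf("stage %s: %d", result$stage_counts$stage, result$stage_counts$n)
  )
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  for (i in seq_len(nrow(x$stage_counts))) {
    cat(sprintf("  %-13s %6d exons\n", x$stage_counts$stage[i],
                x$stage_counts$n[i]))
  }
  cat(sprintf("  DE transcripts called: %d\n", nrow(x$de_called)))
  cat(sprintf("  NMD predicted: %d of %d final candidates\n",
              sum(x$nmd$nmd_predicted %in% TRUE), nrow(x$candidates)))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @export
tidy.screen_result <- function(x, ...) x$candidates

#' @exportS3Method generics::glance
#' @export
glance.screen_result <- function(x, ...) {
  counts <- setNames(as.list(x$stage_counts$n),
                     paste0("n_", x$stage_counts$stage))
  tibble::as_tibble(c(
    counts,
    list(n_de_called = nrow(x$de_called),
         n_nmd_predicted = sum(x$nmd$nmd_predicted %in% TRUE),
         sensitivity = screen_sensitivity(x),
         seed = x$config$design$seed,
         config_hash = x$config_hash)
  ))
}

#' Recovery of planted splicing effects
#'
#' Fraction of the planted alternatively spliced exons that survive the
#' full filter cascade (NA when nothing was planted).
#'
#' @param result A `screen_result` from [run_screen()].
#' @return Sensitivity in \[0, 1\], or `NA`.
#' @export
screen_sensitivity <- function(result) {
  planted <- result$truth$as_exons
  if (nrow(planted) == 0) return(NA_real_)
  found <- paste(result$candidates$transcript_id,
                 result$candidates$exon_index)
  mean(paste(planted$transcript_id, planted$exon_index) %in% found)
}
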