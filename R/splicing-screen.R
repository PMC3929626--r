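#' Exon-level inclusion (PSI) ratio screen
#'
#' For every exon probeset, the per-sample splicing index is
#' `SI = 2^(exon_log2 - gene_log2)`, the exon's signal normalized by its
#' parent transcript's gene-level signal. The group PSI is the mean SI over
#' a group's samples, the screened statistic is `psi_ratio = PSI_KO /
#' PSI_CTRL`, and the p-value comes from a two-sided two-sample Student's t
#' on the per-sample log2 splicing indices (a moderated variant is
#' available). Exons whose parent gene was removed by the expression filter
#' are dropped, with the count reported via the `"n_dropped"` attribute.
#'
#' @param exon_s Exon-level [summary_matrix()]; its features must carry
#'   `transcript_id` (and `exon_index`).
#' @param gene_s Gene-level [summary_matrix()] whose feature ids are
#'   transcript ids.
#' @param design A [group_design()].
#' @param test `"student"` (default) for the plain pooled two-sample t, or
#'   `"moderated"` for the empirical-Bayes moderated t.
#' @return Tibble of exon candidates: `probeset_id`, `transcript_id`,
#'   `exon_index`, `psi_ctrl`, `psi_ko`, `psi_ratio`, `p_value`.
#' @export
compute_psi_ratio <- function(exon_s, gene_s, design,
                              test = c("student", "moderated")) {
  stopifnot(inherits(exon_s, "summary_matrix"),
            inherits(gene_s, "summary_matrix"))
  test <- match.arg(test)
  design <- tibble::as_tibble(design)
  samples <- design$sample_id
  if (!all(samples %in% colnames(exon_s$values)) ||
      !all(samples %in% colnames(gene_s$values))) {
    abort("design samples missing from the summary matrices.")
  }
  if (!"transcript_id" %in% names(exon_s$features)) {
    abort("exon features must carry `transcript_id`.")
  }
  tx <- exon_s$features$transcript_id
  has_gene <- tx %in% gene_s$features$feature_id
  n_dropped <- sum(!has_gene)
  if (n_dropped > 0) {
    inform(sprintf("%d exon probesets dropped: parent gene not retained.",
                   n_dropped))
  }
  ex <- exon_s$values[has_gene, samples, drop = FALSE]
  gx <- gene_s$values[match(tx[has_gene], gene_s$features$feature_id),
                      samples, drop = FALSE]
  si_log2 <- ex - gx

  ctrl <- samples[design$group == "CTRL"]
  ko <- samples[design$group == "KO"]
  si_lin <- 2^si_log2
  psi_ctrl <- rowMeans(si_lin[, ctrl, drop = FALSE])
  psi_ko <- rowMeans(si_lin[, ko, drop = FALSE])

  feats <- exon_s$features[has_gene, ]
  out <- tibble::tibble(
    probeset_id = if ("probeset_id" %in% names(feats)) feats$probeset_id else feats$feature_id,
    transcript_id = feats$transcript_id,
    exon_index = if ("exon_index" %in% names(feats)) feats$exon_index else NA_integer_,
    psi_ctrl = unname(psi_ctrl),
    psi_ko = unname(psi_ko),
    psi_ratio = unname(psi_ko / psi_ctrl)
  )
  if (test == "student") {
    out$p_value <- unname(row_student_p(si_log2[, ctrl, drop = FALSE],
                                        si_log2[, ko, drop = FALSE]))
  } else {
    sm <- summary_matrix(si_log2,
                         tibble::tibble(feature_id = out$probeset_id,
                                        kind = "exon"))
    out$p_value <- moderated_t_table(sm, group_design(design$sample_id,
                                                      design$group))$p_value
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

# Vectorized two-sided pooled two-sample Student's t p-values over rows.
row_student_p <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  ss <- rowSums((a - m1)^2) + rowSums((b - m2)^2)
  df <- n1 + n2 - 2
  se <- sqrt(ss / df * (1 / n1 + 1 / n2))
  t <- (m2 - m1) / se
  p <- 2 * pt(-abs(t), df = df)
  p[se == 0 & m1 == m2] <- 1
  p[se == 0 & m1 != m2] <- 0
  p
}

#' Initial candidate filter: PSI window, p-value, DE-artifact exclusion
#'
#' Applies the screen's first two filter stages: (1) keep exons whose PSI
#' ratio falls outside the closed grey window, i.e. `psi_ratio <= low_cut`
#' or `>= high_cut`, with `p_value <= p_cut`; (2) flag and exclude exons
#' whose parent transcript was called differentially expressed, since an
#' apparent inclusion change on such a transcript is indistinguishable from
#' the transcript-level change itself. Stage counts are attached as the
#' `"stage_counts"` attribute.
#'
#' @param cands Candidate tibble from [compute_psi_ratio()].
#' @param de_list Feature ids of differentially expressed transcripts, or
#'   the tibble returned by [call_differential()].
#' @param low_cut,high_cut Grey-window bounds (defaults 2/3 and 1.5, so the
#'   window is symmetric on the log scale).
#' @param p_cut Exon-level p threshold (default 0.05).
#' @return Surviving candidates with logical flag columns `passed_initial`
#'   and `de_overlap`.
#' @export
filter_splicing_candidates <- function(cands, de_list, low_cut = 2 / 3,
                                       high_cut = 1.5, p_cut = 0.05) {
  if (low_cut >= 1 || high_cut <= 1) {
    abort("the exclusion window must satisfy low_cut < 1 < high_cut.")
  }
  if (is.data.frame(de_list)) de_list <- de_list$feature_id
  flagged <- cands |>
    dplyr::mutate(
      passed_initial = (.data$psi_ratio <= low_cut |
                          .data$psi_ratio >= high_cut) &
        .data$p_value <= p_cut,
      de_overlap = .data$transcript_id %in% de_list
    )
  out <- flagged |>
    dplyr::filter(.data$passed_initial, !.data$de_overlap)
  attr(out, "stage_counts") <- tibble::tibble(
    stage = c("input", "psi_p_filter", "de_exclusion"),
    n = c(nrow(cands), sum(flagged$passed_initial),
          sum(flagged$passed_initial & !flagged$de_overlap))
  )
  out
}
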