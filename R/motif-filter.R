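#' Count motif occurrences in a nucleotide sequence
#'
#' Counts all occurrences of `motif` on the given sense strand, including
#' overlapping ones (so `"AGAAGAA"` contains `"AGAA"` twice): clustered
#' GAA-rich stretches are the biological signal, and overlap-counting
#' credits them fully. Matching is case-insensitive; `N` never matches.
#'
#' @param seq Character vector of sequences over A/C/G/T/N.
#' @param motif Motif over A/C/G/T (default `"AGAA"`).
#' @return Integer vector of counts.
#' @export
count_motif <- function(seq, motif = "AGAA") {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif)) {
    abort("`motif` must be a non-empty string.")
  }
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) abort("`motif` must be over {A, C, G, T}.")
  seq <- toupper(seq)
  if (any(grepl("[^ACGTN]", seq))) {
    abort("sequences must be over {A, C, G, T, N}.")
  }
  vapply(seq, function(s) length(find_motif_positions(s, motif)),
         integer(1), USE.NAMES = FALSE)
}

#' Binding-site frequency F
#'
#' The motif occurs by chance about once per 256 bp, so the frequency is
#' calibrated to that stretch: `F = 256 * count / exon_length`, making one
#' site in a 256-bp exon equal exactly 1. A `"literal"` convention
#' (`count * exon_length / 256`) is also provided; the two agree only at
#' 256 bp, and the calibrated form is the default because it matches the
#' once-per-256-nt definition of F = 1 at every exon length.
#'
#' @param count Non-negative motif counts.
#' @param exon_length Exon lengths in bp (each >= the motif length).
#' @param motif Motif the counts refer to (used only for the length check).
#' @param convention `"calibrated"` (default) or `"literal"`.
#' @return Numeric vector of frequencies.
#' @export
motif_frequency <- function(count, exon_length, motif = "AGAA",
                            convention = c("calibrated", "literal")) {
  convention <- match.arg(convention)
  if (any(count < 0)) abort("`count` must be non-negative.")
  if (any(exon_length < nchar(motif))) {
    abort("`exon_length` must be at least the motif length.")
  }
  if (convention == "calibrated") 256 * count / exon_length
  else count * exon_length / 256
}

#' Motif-based candidate filter
#'
#' Populates each candidate's motif columns from its exon sequence and
#' keeps exons with at least `min_count` motif occurrences and a
#' binding-site frequency `F >= min_freq` (defaults: one AGAA site and
#' F >= 1.5). Candidates without a sequence are dropped with a warning.
#'
#' @param cands Candidate tibble (needs `exon_seq`, or join one on via
#'   [exon_sequences()]).
#' @param min_count Minimum motif count (default 1).
#' @param min_freq Minimum frequency F (default 1.5).
#' @param motif Motif (default `"AGAA"`).
#' @param convention F convention, see [motif_frequency()].
#' @return Surviving candidates with `agaa_count`, `agaa_freq`,
#'   `exon_length` and flag `passed_motif` populated; stage counts in the
#'   `"stage_counts"` attribute.
#' @export
apply_motif_filter <- function(cands, min_count = 1, min_freq = 1.5,
                               motif = "AGAA",
                               convention = c("calibrated", "literal")) {
  convention <- match.arg(convention)
  if (nrow(cands) == 0) {
    out <- dplyr::mutate(cands, exon_length = integer(0),
                         agaa_count = integer(0), agaa_freq = numeric(0),
                         passed_motif = logical(0))
    attr(out, "stage_counts") <- tibble::tibble(stage = "motif_filter", n = 0L)
    return(out)
  }
  if (!"exon_seq" %in% names(cands)) {
    abort("`cands` needs an `exon_seq` column (join `exon_sequences()` output).")
  }
  no_seq <- is.na(cands$exon_seq) | !nzchar(cands$exon_seq)
  if (any(no_seq)) {
    warn(sprintf("%d candidates dropped: missing exon sequence.", sum(no_seq)))
    cands <- cands[!no_seq, ]
  }
  scored <- cands |>
    dplyr::mutate(
      exon_length = nchar(.data$exon_seq),
      agaa_count = count_motif(.data$exon_seq, motif),
      agaa_freq = motif_frequency(.data$agaa_count, .data$exon_length,
                                  motif, convention),
      passed_motif = .data$agaa_count >= min_count &
        .data$agaa_freq >= min_freq
    )
  out <- dplyr::filter(scored, .data$passed_motif)
  attr(out, "stage_counts") <- tibble::tibble(stage = "motif_filter",
                                              n = nrow(out))
  out
}

#' Predict premature termination codons upon exon skipping
#'
#' Removes one exon from a transcript model, translates the resulting mRNA
#' from the original start codon, and counts the in-frame stop codons that
#' appear strictly upstream of the original stop codon's position (mapped
#' into the skipped-exon transcript). NMD is predicted by the classical
#' 50-nt rule: the transcript is flagged when its first premature stop lies
#' more than `junction_rule_nt` nucleotides upstream of the last exon-exon
#' junction.
#'
#' @param tx A [transcript_model()].
#' @param skip_exon_index 1-based index of the exon to skip; must not be
#'   the exon containing the start codon.
#' @param junction_rule_nt Distance threshold of the last-junction rule
#'   (default 50 nt).
#' @return One-row tibble: `transcript_id`, `skipped_exon_index`,
#'   `n_ptcs`, `first_ptc_pos` (1-based position in the skipped-exon
#'   transcript, `NA` if none), `distance_to_last_junction` (nt between the
#'   end of the first premature stop and the last junction, `NA` if no
#'   PTC), `nmd_predicted`.
#' @export
predict_ptcs <- function(tx, skip_exon_index, junction_rule_nt = 50) {
  stopifnot(inherits(tx, "transcript_model"))
  n_ex <- nrow(tx$exons)
  if (skip_exon_index < 1 || skip_exon_index > n_ex) {
    abort("`skip_exon_index` out of range.")
  }
  ex <- tx$exons[skip_exon_index, ]
  if (tx$cds_start >= ex$start && tx$cds_start <= ex$end) {
    abort("cannot skip the exon containing the start codon.")
  }
  skip_len <- ex$length

  new_seqs <- tx$exons$seq[-skip_exon_index]
  new_seq <- paste(new_seqs, collapse = "")
  new_start <- if (ex$end < tx$cds_start) tx$cds_start - skip_len else tx$cds_start
  # Position of the original stop codon in the new transcript; if the stop
  # codon itself was skipped, scan to the transcript end.
  boundary <- if (tx$cds_stop > ex$end) {
    tx$cds_stop - skip_len
  } else if (tx$cds_stop >= ex$start) {
    nchar(new_seq) + 1L
  } else {
    tx$cds_stop
  }

  codon_starts <- if (new_start <= nchar(new_seq) - 2L) {
    seq(new_start, nchar(new_seq) - 2L, by = 3)
  } else integer(0)
  codon_starts <- codon_starts[codon_starts < boundary]
  codons <- substring(new_seq, codon_starts, codon_starts + 2L)
  ptc_pos <- codon_starts[codons %in% STOP_CODONS]
  n_ptcs <- length(ptc_pos)
  first_ptc <- if (n_ptcs > 0) ptc_pos[1] else NA_integer_

  # Last exon-exon junction: position of the final nucleotide of the
  # second-to-last remaining exon.
  new_lens <- nchar(new_seqs)
  has_junction <- length(new_lens) >= 2
  last_junction <- if (has_junction) sum(new_lens[-length(new_lens)]) else NA_integer_

  dist <- if (n_ptcs > 0 && has_junction) last_junction - (first_ptc + 2L) else NA_integer_
  nmd <- isTRUE(n_ptcs > 0 && has_junction && dist > junction_rule_nt)

  tibble::tibble(transcript_id = tx$transcript_id,
                 skipped_exon_index = as.integer(skip_exon_index),
                 n_ptcs = as.integer(n_ptcs),
                 first_ptc_pos = as.integer(first_ptc),
                 distance_to_last_junction = as.integer(dist),
                 nmd_predicted = nmd)
}

#' NMD consequence report for screened candidates
#'
#' Runs [predict_ptcs()] for every candidate exon whose transcript model is
#' available, treating the candidate as a skipping event. Candidates whose
#' exon cannot be skipped (start-codon exon) get `NA` results.
#'
#' @param cands Candidate tibble with `transcript_id` and `exon_index`.
#' @param models List of [transcript_model()] objects.
#' @param junction_rule_nt See [predict_ptcs()].
#' @return Tibble with one row per candidate.
#' @export
nmd_report <- function(cands, models, junction_rule_nt = 50) {
  purrr::map_dfr(seq_len(nrow(cands)), function(i) {
    tx <- models[[cands$transcript_id[i]]]
    ei <- cands$exon_index[i]
    if (is.null(tx) || is.na(ei)) {
      return(tibble::tibble(transcript_id = cands$transcript_id[i],
                            skipped_exon_index = as.integer(ei),
                            n_ptcs = NA_integer_, first_ptc_pos = NA_integer_,
                            distance_to_last_junction = NA_integer_,
                            nmd_predicted = NA))
    }
    tryCatch(predict_ptcs(tx, ei, junction_rule_nt),
             error = function(e) {
               tibble::tibble(transcript_id = tx$transcript_id,
                              skipped_exon_index = as.integer(ei),
                              n_ptcs = NA_integer_,
                              first_ptc_pos = NA_integer_,
                              distance_to_last_junction = NA_integer_,
                              nmd_predicted = NA)
             })
  })
}
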