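#' Probe-level intensity container
#'
#' Bundles a linear-scale probe intensity matrix (probes in rows, samples in
#' columns) with its probe-to-probeset and probeset-to-feature annotation.
#' This mirrors what an exon-array preprocessing pipeline carries between
#' background correction, normalization and summarization.
#'
#' @param values Numeric matrix, probes x samples, linear scale,
#'   non-negative, with probe ids as rownames and sample ids as colnames.
#' @param probe_to_probeset Named character vector mapping each probe id to
#'   exactly one probeset id.
#' @param probeset_info Data frame with one row per probeset: columns
#'   `probeset_id`, `feature_id`, `kind` (`"gene"` or `"exon"`), and for exon
#'   probesets `transcript_id` and `exon_index`.
#' @param probe_gc Optional named numeric vector of per-probe GC fractions in
#'   \[0, 1\]; required only for GC adjustment.
#'
#' @return An object of class `probe_matrix`.
#' @export
probe_matrix <- function(values, probe_to_probeset, probeset_info,
                         probe_gc = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (probes x samples).")
  }
  if (any(values < 0)) {
    abort("Probe intensities must be non-negative (linear scale).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` needs probe rownames and sample colnames.")
  }
  missing_map <- setdiff(rownames(values), names(probe_to_probeset))
  if (length(missing_map) > 0) {
    abort(sprintf("%d probes lack a probeset mapping (e.g. %s).",
                  length(missing_map), missing_map[1]))
  }
  probeset_info <- tibble::as_tibble(probeset_info)
  needed <- c("probeset_id", "feature_id", "kind")
  if (!all(needed %in% names(probeset_info))) {
    abort("`probeset_info` needs columns probeset_id, feature_id, kind.")
  }
  if (!all(probeset_info$kind %in% c("gene", "exon"))) {
    abort("probeset `kind` must be \"gene\" or \"exon\".")
  }
  if (!is.null(probe_gc)) {
    if (is.null(names(probe_gc)) || any(probe_gc < 0 | probe_gc > 1)) {
      abort("`probe_gc` must be a named vector of fractions in [0, 1].")
    }
  }
  structure(
    list(values = values,
         probe_to_probeset = probe_to_probeset[rownames(values)],
         probeset_info = probeset_info,
         probe_gc = probe_gc),
    class = "probe_matrix"
  )
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("<probe_matrix> %d probes x %d samples, %d probesets (%d gene / %d exon)%s\n",
              nrow(x$values), ncol(x$values), nrow(x$probeset_info),
              sum(x$probeset_info$kind == "gene"),
              sum(x$probeset_info$kind == "exon"),
              if (is.null(x$probe_gc)) "" else ", with probe GC"))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @export
tidy.probe_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "probe_id") |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                        values_to = "intensity") |>
    dplyr::mutate(probeset_id = unname(x$probe_to_probeset[.data$probe_id]),
                  .after = "probe_id")
}

#' Summarized log2 expression container
#'
#' Holds log2-scale summarized values (features in rows, samples in columns)
#' with a per-feature annotation table. Gene-level and exon-level probesets
#' live in the same container, distinguished by `kind`.
#'
#' @param values Numeric matrix, features x samples, log2 scale, finite.
#' @param features Data frame with columns `feature_id` and `kind`
#'   (plus `transcript_id`/`exon_index` for exon features); one row per row
#'   of `values`, in the same order.
#'
#' @return An object of class `summary_matrix`.
#' @export
summary_matrix <- function(values, features) {
  if (!is.matrix(values) || !is.numeric(values) || any(!is.finite(values))) {
    abort("`values` must be a finite numeric matrix (features x samples).")
  }
  features <- tibble::as_tibble(features)
  if (!all(c("feature_id", "kind") %in% names(features))) {
    abort("`features` needs columns feature_id and kind.")
  }
  if (nrow(features) != nrow(values)) {
    abort("`features` must have one row per feature row of `values`.")
  }
  if (anyDuplicated(features$feature_id)) {
    abort("feature ids must be unique.")
  }
  rownames(values) <- features$feature_id
  structure(list(values = values, features = features),
            class = "summary_matrix")
}

#' @export
print.summary_matrix <- function(x, ...) {
  cat(sprintf("<summary_matrix> %d features (%d gene / %d exon) x %d samples, log2 scale\n",
              nrow(x$values), sum(x$features$kind == "gene"),
              sum(x$features$kind == "exon"), ncol(x$values)))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @export
tidy.summary_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id",
                        values_to = "log2_value") |>
    dplyr::left_join(x$features, by = "feature_id")
}

# Subset a summary matrix to one feature kind.
split_summary <- function(s, kind) {
  keep <- s$features$kind == kind
  summary_matrix(s$values[keep, , drop = FALSE], s$features[keep, ])
}

#' Transcript model
#'
#' A sense-strand transcript as an ordered set of exons in transcript-local
#' coordinates (1-based, inclusive), each carrying its nucleotide sequence,
#' plus the positions of the annotated start codon and stop codon. This is
#' the substrate for AGAA motif scanning and for predicting the coding
#' consequences of exon skipping.
#'
#' @param transcript_id Character id.
#' @param exon_seqs Character vector of exon sequences over A/C/G/T,
#'   5' to 3'.
#' @param cds_start 1-based transcript position of the first nucleotide of
#'   the start codon.
#' @param cds_stop 1-based transcript position of the first nucleotide of
#'   the stop codon. `cds_stop - cds_start` must be divisible by 3.
#'
#' @return An object of class `transcript_model` with an `exons` tibble
#'   (`exon_index`, `start`, `end`, `length`, `seq`).
#' @export
transcript_model <- function(transcript_id, exon_seqs, cds_start, cds_stop) {
  if (length(exon_seqs) < 1 || any(!nzchar(exon_seqs))) {
    abort("`exon_seqs` must be non-empty sequences.")
  }
  exon_seqs <- toupper(exon_seqs)
  if (any(grepl("[^ACGT]", exon_seqs))) {
    abort("exon sequences must be over {A, C, G, T}.")
  }
  lens <- nchar(exon_seqs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  total <- ends[length(ends)]
  assert_scalar_number(cds_start, "cds_start")
  assert_scalar_number(cds_stop, "cds_stop")
  if (cds_start >= cds_stop) abort("`cds_start` must lie before `cds_stop`.")
  if (cds_stop + 2 > total) abort("stop codon exceeds transcript length.")
  if ((cds_stop - cds_start) %% 3 != 0) {
    abort("CDS length (start codon to stop codon) must be divisible by 3.")
  }
  structure(
    list(transcript_id = transcript_id,
         exons = tibble::tibble(exon_index = seq_along(exon_seqs),
                                start = starts, end = ends,
                                length = lens, seq = exon_seqs),
         cds_start = as.integer(cds_start),
         cds_stop = as.integer(cds_stop)),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s: %d exons, %d nt, CDS %d..%d\n",
              x$transcript_id, nrow(x$exons), max(x$exons$end),
              x$cds_start, x$cds_stop + 2L))
  invisible(x)
}

# Full transcript sequence from its exons.
transcript_sequence <- function(tx) paste(tx$exons$seq, collapse = "")

#' Exon sequence table for a set of transcript models
#'
#' @param models List of [transcript_model()] objects.
#' @return Tibble with `transcript_id`, `exon_index`, `exon_seq`,
#'   `exon_length`.
#' @export
exon_sequences <- function(models) {
  purrr::map_dfr(models, function(tx) {
    tibble::tibble(transcript_id = tx$transcript_id,
                   exon_index = tx$exons$exon_index,
                   exon_seq = tx$exons$seq,
                   exon_length = tx$exons$length)
  })
}

#' Two-group array study design
#'
#' @param sample_id Character vector of sample ids.
#' @param group Character vector of group labels, `"CTRL"` or `"KO"`,
#'   with at least two samples per group.
#' @return A tibble of class `group_design`.
#' @export
group_design <- function(sample_id, group) {
  if (length(sample_id) != length(group)) {
    abort("`sample_id` and `group` must have equal length.")
  }
  if (!all(group %in% c("CTRL", "KO"))) {
    abort("groups must be \"CTRL\" or \"KO\".")
  }
  if (any(table(factor(group, levels = c("CTRL", "KO"))) < 2)) {
    abort("each group needs at least 2 samples.")
  }
  out <- tibble::tibble(sample_id = sample_id, group = group)
  class(out) <- c("group_design", class(out))
  out
}
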