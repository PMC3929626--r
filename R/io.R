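# Column dialect of the published candidate tables. Internal names map to
# the table headers; flag and provenance columns follow the core columns.
CANDIDATE_DIALECT <- c(
  PROBESET_ID = "probeset_id",
  `PSI[KOvsCTRL]` = "psi_ratio",
  `p-value` = "p_value",
  EXON_LENGTH = "exon_length",
  AGAA_COUNT = "agaa_count",
  AGAA_FREQ = "agaa_freq",
  PROBESET_SEQ = "probeset_seq",
  EXON_SEQ = "exon_seq",
  TRANSCRIPT_ID = "transcript_id",
  EXON_INDEX = "exon_index",
  PSI_CTRL = "psi_ctrl",
  PSI_KO = "psi_ko",
  PASSED_INITIAL = "passed_initial",
  DE_OVERLAP = "de_overlap",
  PASSED_MOTIF = "passed_motif"
)

#' Read a FASTA file
#'
#' Standard FASTA parsing via Biostrings: multi-line records are
#' concatenated and ids are truncated at the first whitespace. The
#' generator writes exon records with headers `transcriptID|exonIndex`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (empty for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  set <- Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Write exon sequences of transcript models as FASTA
#'
#' Headers follow the `transcriptID|exonIndex` convention (1-based exon
#' indices).
#'
#' @param models List of [transcript_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exon_fasta <- function(models, path) {
  tab <- exon_sequences(models)
  write_fasta(setNames(tab$exon_seq,
                       sprintf("%s|%d", tab$transcript_id, tab$exon_index)),
              path)
}

#' Write / read an exon candidate table
#'
#' Serializes candidates in the published column dialect: tab-separated
#' with header `PROBESET_ID`, `PSI[KOvsCTRL]`, `p-value`, `EXON_LENGTH`,
#' `AGAA_COUNT`, `AGAA_FREQ`, `PROBESET_SEQ`, `EXON_SEQ`, followed by
#' provenance and flag columns. The round trip is lossless; unknown
#' columns on read are preserved as extras with a warning.
#'
#' @param cands Candidate tibble (missing dialect columns are written as
#'   `NA`).
#' @param path TSV path.
#' @return `write_candidate_table()`: `path`, invisibly.
#'   `read_candidate_table()`: candidate tibble with internal column names.
#' @export
write_candidate_table <- function(cands, path) {
  out <- tibble::as_tibble(cands)
  if (!"probeset_seq" %in% names(out) && "exon_seq" %in% names(out)) {
    # Probe-level target sequences are not modeled; the probeset sequence
    # column carries the exon sequence it interrogates.
    out$probeset_seq <- out$exon_seq
  }
  for (col in unname(CANDIDATE_DIALECT)) {
    if (!col %in% names(out)) out[[col]] <- NA
  }
  extra <- setdiff(names(out), unname(CANDIDATE_DIALECT))
  out <- out[, c(unname(CANDIDATE_DIALECT), extra)]
  names(out)[seq_along(CANDIDATE_DIALECT)] <- names(CANDIDATE_DIALECT)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_candidate_table
#' @export
read_candidate_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  known <- names(raw) %in% names(CANDIDATE_DIALECT)
  if (any(!known)) {
    warn(sprintf("unknown columns preserved as extras: %s",
                 paste(names(raw)[!known], collapse = ", ")))
  }
  names(raw)[known] <- unname(CANDIDATE_DIALECT[names(raw)[known]])
  raw
}

#' Write a differential-expression table
#'
#' Tab-separated with header `TRANSCRIPT_ID`, `p-value`, `F_C[KOvsCTRL]`
#' (signed linear fold change, KO over CTRL).
#'
#' @param stats Tibble from [moderated_t_table()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(stats, path) {
  out <- tibble::tibble(TRANSCRIPT_ID = stats$feature_id,
                        `p-value` = stats$p_value,
                        `F_C[KOvsCTRL]` = stats$fold_change)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write / read a probe matrix as TSV files
#'
#' Writes three tab-separated files into `dir`: `probe_intensities.tsv`
#' (probes as rows, samples as columns, linear scale),
#' `probe_to_probeset.tsv` (columns `probe_id`, `probeset_id`) and
#' `probeset_info.tsv` (the probeset-to-feature map).
#'
#' @param m A [probe_matrix()].
#' @param dir Output directory (created if needed).
#' @return `write_probe_matrix()`: `dir`, invisibly.
#'   `read_probe_matrix()`: a [probe_matrix()].
#' @export
write_probe_matrix <- function(m, dir) {
  stopifnot(inherits(m, "probe_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tibble::as_tibble(m$values, rownames = "probe_id"),
                   file.path(dir, "probe_intensities.tsv"))
  readr::write_tsv(tibble::tibble(probe_id = names(m$probe_to_probeset),
                                  probeset_id = unname(m$probe_to_probeset)),
                   file.path(dir, "probe_to_probeset.tsv"))
  readr::write_tsv(m$probeset_info, file.path(dir, "probeset_info.tsv"))
  invisible(dir)
}

#' @rdname write_probe_matrix
#' @export
read_probe_matrix <- function(dir) {
  vals_df <- readr::read_tsv(file.path(dir, "probe_intensities.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  vals <- as.matrix(vals_df[, -1])
  rownames(vals) <- vals_df$probe_id
  map_df <- readr::read_tsv(file.path(dir, "probe_to_probeset.tsv"),
                            show_col_types = FALSE, progress = FALSE)
  info <- readr::read_tsv(file.path(dir, "probeset_info.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  probe_matrix(vals, setNames(map_df$probeset_id, map_df$probe_id), info)
}
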