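# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately written as plain loops, independent of the
# package's vectorized implementations.

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Quadratic sliding-window motif count.
count_motif_oracle <- function(seq, motif = "AGAA") {
  seq <- toupper(seq)
  n <- nchar(seq)
  m <- nchar(motif)
  hits <- 0L
  if (n >= m) {
    for (i in seq_len(n - m + 1L)) {
      if (substr(seq, i, i + m - 1L) == motif) hits <- hits + 1L
    }
  }
  hits
}

# Rank-mean quantile normalization, column by column, with tied ranks
# averaged over the target quantiles they span.
quantile_normalize_oracle <- function(x) {
  target <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    for (i in seq_len(nrow(x))) {
      lo <- floor(r[i]); hi <- ceiling(r[i])
      out[i, j] <- (target[lo] + target[hi]) / 2
    }
  }
  out
}

# Pooled two-sample t statistic and two-sided p, scalar arithmetic.
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

# Codon-by-codon PTC scan on the skipped-exon transcript.
ptc_oracle <- function(exon_seqs, cds_start, cds_stop, skip) {
  lens <- nchar(exon_seqs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  new_seq <- paste(exon_seqs[-skip], collapse = "")
  new_start <- if (ends[skip] < cds_start) cds_start - lens[skip] else cds_start
  boundary <- if (cds_stop > ends[skip]) {
    cds_stop - lens[skip]
  } else if (cds_stop >= starts[skip]) {
    nchar(new_seq) + 1L
  } else cds_stop
  n <- 0L
  first <- NA_integer_
  p <- new_start
  while (p + 2L <= nchar(new_seq) && p < boundary) {
    if (substr(new_seq, p, p + 2L) %in% c("TAA", "TAG", "TGA")) {
      n <- n + 1L
      if (is.na(first)) first <- p
    }
    p <- p + 3L
  }
  list(n_ptcs = n, first_ptc_pos = first)
}

# In-frame stop count of the annotated (unskipped) ORF, excluding the
# stop codon itself.
orf_internal_stops <- function(tx) {
  seq <- paste(tx$exons$seq, collapse = "")
  n <- 0L
  p <- tx$cds_start
  while (p < tx$cds_stop) {
    if (substr(seq, p, p + 2L) %in% c("TAA", "TAG", "TGA")) n <- n + 1L
    p <- p + 3L
  }
  n
}

# Small random summary matrix with the 4v4 CTRL/KO layout.
make_summary_4v4 <- function(n_features, seed = 1, sd = 1, kind = "gene") {
  set.seed(seed)
  samples <- c(paste0("CTRL_", 1:4), paste0("KO_", 1:4))
  x <- matrix(rnorm(n_features * 8, mean = 8, sd = sd), n_features, 8,
              dimnames = list(sprintf("f%03d", seq_len(n_features)), samples))
  summary_matrix(x, tibble::tibble(feature_id = rownames(x), kind = kind))
}

design_4v4 <- function() {
  group_design(c(paste0("CTRL_", 1:4), paste0("KO_", 1:4)),
               rep(c("CTRL", "KO"), each = 4))
}

# Minimal probe_matrix around a plain value matrix, one probeset per probe.
wrap_probe_matrix <- function(values, kind = "gene", probe_gc = NULL) {
  ps <- setNames(paste0("ps_", rownames(values)), rownames(values))
  info <- tibble::tibble(probeset_id = unname(ps),
                         feature_id = unname(ps), kind = kind)
  probe_matrix(values, ps, info, probe_gc = probe_gc)
}
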