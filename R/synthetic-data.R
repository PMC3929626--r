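#' Simulation design for a two-group exon-array study
#'
#' Captures the study conditions emulated by the synthetic-data generator:
#' a 4 CTRL vs 4 KO whole-brain design, a fraction of transcripts with
#' planted expression fold changes, a fraction of exons with planted
#' inclusion (PSI) changes, probe-level Gaussian log2 noise on top of fixed
#' probe affinities, an additive exponential background, and a mosaicism
#' fraction that dilutes every KO effect toward the CTRL expression state
#' (two cell populations contributing RNA, as under incomplete Cre
#' recombination).
#'
#' @param n_ctrl,n_ko Samples per group (default 4 vs 4).
#' @param frac_de Fraction of transcripts with a planted expression fold
#'   change.
#' @param de_fold_range Range of planted linear fold changes (magnitudes;
#'   direction is randomized).
#' @param frac_as Fraction of exons with a planted inclusion change.
#' @param as_ratio_range Range of planted PSI ratios (KO/CTRL). Draws are
#'   log-uniform and never fall inside the open interval (2/3, 1.5), so
#'   planted effects are outside the screen's exclusion window by design.
#' @param as_ratio_values Optional discrete set of planted PSI ratios; when
#'   supplied, ratios are sampled uniformly from this set instead of
#'   `as_ratio_range` (e.g. `c(0.5, 2)` for symmetric halving/doubling of
#'   inclusion). Values must lie outside the (2/3, 1.5) window.
#' @param mosaic_fraction Fraction m of each KO sample's expected signal
#'   contributed by unedited (CTRL-state) cells, applied on the linear
#'   scale: (1 - m) * KO_state + m * CTRL_state.
#' @param noise_sd Standard deviation of Gaussian noise on log2 probe
#'   intensities.
#' @param probes_per_probeset Probes per probeset (>= 2).
#' @param background_mean Mean of the additive exponential background on
#'   the linear scale; 0 disables background.
#' @param background_sd Nominal background spread, carried as the default
#'   normal-background sd for the background corrector.
#' @param seed Integer master seed; every downstream draw derives from it.
#'
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_ctrl = 4, n_ko = 4,
                              frac_de = 0.05, de_fold_range = c(1.5, 3),
                              frac_as = 0.05, as_ratio_range = c(0.5, 2),
                              as_ratio_values = NULL,
                              mosaic_fraction = 0, noise_sd = 0.25,
                              probes_per_probeset = 4,
                              background_mean = 20, background_sd = 5,
                              seed = 1L) {
  assert_scalar_number(n_ctrl, "n_ctrl", positive = TRUE)
  assert_scalar_number(n_ko, "n_ko", positive = TRUE)
  if (n_ctrl < 2 || n_ko < 2) abort("need at least 2 samples per group.")
  assert_fraction(frac_de, "frac_de")
  assert_fraction(frac_as, "frac_as")
  assert_fraction(mosaic_fraction, "mosaic_fraction")
  assert_range(de_fold_range, "de_fold_range")
  assert_range(as_ratio_range, "as_ratio_range")
  if (!is.null(as_ratio_values)) {
    if (any(as_ratio_values <= 0) ||
        any(as_ratio_values > 2 / 3 & as_ratio_values < 1.5)) {
      abort("`as_ratio_values` must be positive and outside (2/3, 1.5).")
    }
  }
  assert_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  assert_scalar_number(probes_per_probeset, "probes_per_probeset")
  if (probes_per_probeset < 2) abort("`probes_per_probeset` must be >= 2.")
  assert_scalar_number(background_mean, "background_mean")
  if (background_mean < 0) abort("`background_mean` must be non-negative.")
  assert_scalar_number(background_sd, "background_sd")
  assert_scalar_number(seed, "seed")
  structure(
    list(n_ctrl = as.integer(n_ctrl), n_ko = as.integer(n_ko),
         frac_de = frac_de, de_fold_range = de_fold_range,
         frac_as = frac_as, as_ratio_range = as_ratio_range,
         as_ratio_values = as_ratio_values,
         mosaic_fraction = mosaic_fraction, noise_sd = noise_sd,
         probes_per_probeset = as.integer(probes_per_probeset),
         background_mean = background_mean, background_sd = background_sd,
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(paste0("<simulation_design> %d CTRL vs %d KO; DE %.0f%% folds [%g, %g]; ",
                     "AS %.0f%% ratios [%g, %g]; mosaic m=%g; noise sd %g; seed %d\n"),
              x$n_ctrl, x$n_ko, 100 * x$frac_de, x$de_fold_range[1],
              x$de_fold_range[2], 100 * x$frac_as, x$as_ratio_range[1],
              x$as_ratio_range[2], x$mosaic_fraction, x$noise_sd, x$seed))
  invisible(x)
}

# --- sequence construction helpers -----------------------------------------

random_dna <- function(n) {
  paste(sample(DNA_LETTERS, n, replace = TRUE), collapse = "")
}

# Remove every occurrence of `motif` by rewriting its G to C. For AGAA-type
# motifs this can neither create a stop codon (stops contain no C) nor a new
# motif occurrence, so a single pass suffices.
scrub_motif <- function(seq, motif = "AGAA") {
  g_off <- regexpr("G", motif, fixed = TRUE)[1]
  if (g_off < 0) abort("scrub_motif needs a motif containing G.")
  chars <- strsplit(seq, "")[[1]]
  hits <- find_motif_positions(seq, motif)
  if (length(hits) > 0) chars[hits + g_off - 1L] <- "C"
  paste(chars, collapse = "")
}

# All (possibly overlapping) 1-based start positions of `motif` in `seq`.
find_motif_positions <- function(seq, motif) {
  m <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Codon starting positions of the CDS frame that overlap positions
# pos..pos+len-1 (1-based transcript coordinates).
overlapping_codon_starts <- function(pos, len, cds_start, cds_stop) {
  first <- cds_start + 3 * floor((pos - cds_start) / 3)
  starts <- seq(from = max(first, cds_start), to = pos + len - 1, by = 3)
  starts[starts >= cds_start & starts < cds_stop]
}

# Plant `k` copies of `motif` into transcript `chars` restricted to
# positions lo..hi, refusing placements that would create an in-frame stop
# codon in the CDS or touch the start/stop codons. Returns the modified
# character vector.
plant_motifs <- function(chars, k, lo, hi, motif, cds_start, cds_stop) {
  ml <- nchar(motif)
  motif_chars <- strsplit(motif, "")[[1]]
  forbidden <- c(seq(cds_start, cds_start + 2), seq(cds_stop, cds_stop + 2))
  planted <- 0L
  attempts <- 0L
  while (planted < k && attempts < 25L * k + 25L) {
    attempts <- attempts + 1L
    if (hi - ml + 1 < lo) break
    p <- resample(seq(lo, hi - ml + 1L))
    span <- seq(p, p + ml - 1L)
    if (any(span %in% forbidden)) next
    old <- chars[span]
    chars[span] <- motif_chars
    if (p + ml - 1 >= cds_start && p <= cds_stop + 2) {
      cods <- overlapping_codon_starts(p, ml, cds_start, cds_stop)
      codons <- vapply(cods, function(s) paste(chars[s:(s + 2)], collapse = ""), "")
      if (any(codons %in% STOP_CODONS)) {
        chars[span] <- old
        next
      }
    }
    planted <- planted + 1L
  }
  chars
}

# --- generators ------------------------------------------------------------

#' Generate a synthetic transcriptome
#'
#' Builds sense-strand transcript models with random exon structure and a
#' clean open reading frame (ATG start, no internal in-frame stop, TAA stop
#' in the last exon, CDS spanning at least two exons). AGAA occurrences are
#' first scrubbed from the raw sequence and then re-planted at a Poisson
#' rate calibrated per 256 bp, so `motif_rate = 1` reproduces the
#' once-per-256-nt background occurrence of the motif and `motif_rate = 0`
#' yields motif-free sequences.
#'
#' @param n_transcripts Number of transcripts (positive).
#' @param exons_per_tx Integer range `c(min, max)` of exons per transcript
#'   (min >= 2).
#' @param exon_len Integer range of exon lengths in bp (min >= 30).
#' @param motif_rate Expected AGAA occurrences per 256 bp of exon sequence.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param motif Motif to plant (default `"AGAA"`).
#'
#' @return List of [transcript_model()] objects named by transcript id.
#' @export
generate_transcriptome <- function(n_transcripts, exons_per_tx = c(4, 8),
                                   exon_len = c(80, 300), motif_rate = 1,
                                   seed = 1L, motif = "AGAA") {
  assert_scalar_number(n_transcripts, "n_transcripts", positive = TRUE)
  assert_range(exons_per_tx, "exons_per_tx")
  assert_range(exon_len, "exon_len")
  if (exons_per_tx[1] < 2) abort("transcripts need at least 2 exons (CDS spans >= 2).")
  if (exon_len[1] < 30) abort("`exon_len` minimum must be >= 30 bp.")
  assert_scalar_number(motif_rate, "motif_rate")
  if (motif_rate < 0) abort("`motif_rate` must be >= 0.")

  with_seed(child_seed(seed, 101), {
    models <- lapply(seq_len(n_transcripts), function(i) {
      tx_id <- sprintf("TX%04d", i)
      n_ex <- resample(seq(exons_per_tx[1], exons_per_tx[2]))
      lens <- resample(seq(exon_len[1], exon_len[2]), n_ex, replace = TRUE)
      total <- sum(lens)
      seq_raw <- scrub_motif(random_dna(total), motif)
      chars <- strsplit(seq_raw, "")[[1]]

      # CDS: start codon early in exon 1, stop codon inside the last exon,
      # frames aligned; the ORF is then cleaned of internal stops.
      cds_start <- resample(3:min(10L, lens[1] - 6L))
      last_start <- total - lens[n_ex] + 1L
      stop_cand <- total - resample(3:8) - 2L
      stop_cand <- stop_cand - ((stop_cand - cds_start) %% 3)
      if (stop_cand < last_start) {
        stop_cand <- last_start + ((cds_start - last_start) %% 3)
        if (stop_cand + 2 > total) abort("last exon too short for stop codon.")
      }
      cds_stop <- stop_cand
      chars[cds_start:(cds_start + 2)] <- c("A", "T", "G")
      chars[cds_stop:(cds_stop + 2)] <- c("T", "A", "A")
      internal <- seq(cds_start + 3, cds_stop - 3, by = 3)
      for (s in internal) {
        if (paste(chars[s:(s + 2)], collapse = "") %in% STOP_CODONS) {
          chars[s] <- "C"  # breaks TAA/TAG/TGA without creating stop or AGAA
        }
      }
      # Writing ATG/TAA cannot create an AGAA, but the random codon body was
      # already scrubbed above; nothing to re-scrub.

      if (motif_rate > 0) {
        ends <- cumsum(lens)
        starts <- ends - lens + 1L
        for (e in seq_len(n_ex)) {
          k <- rpois(1L, motif_rate * lens[e] / 256)
          if (k > 0) {
            chars <- plant_motifs(chars, k, starts[e], ends[e], motif,
                                  cds_start, cds_stop)
          }
        }
      }

      seq_full <- paste(chars, collapse = "")
      ends <- cumsum(lens)
      starts <- ends - lens + 1L
      exon_seqs <- substring(seq_full, starts, ends)
      transcript_model(tx_id, exon_seqs, cds_start, cds_stop)
    })
    names(models) <- vapply(models, function(m) m$transcript_id, "")
    models
  })
}

#' Plant differential-expression and splicing effects
#'
#' Chooses which transcripts carry an expression fold change and which exons
#' carry an inclusion change, returning the ground truth used both by the
#' simulator and by recovery benchmarks. Planted splicing ratios never fall
#' inside the open (2/3, 1.5) window, and no splicing effect is planted on a
#' differentially expressed transcript, so the truth is disjoint from the
#' screen's DE-artifact exclusion rule by construction.
#'
#' @param models List of [transcript_model()] objects.
#' @param design A [simulation_design()].
#'
#' @return Object of class `sim_truth`: list with tibbles `de_transcripts`
#'   (`transcript_id`, `fold`; linear KO/CTRL fold) and `as_exons`
#'   (`transcript_id`, `exon_index`, `ratio`; planted PSI ratio).
#' @export
plant_effects <- function(models, design) {
  stopifnot(inherits(design, "simulation_design"))
  n_tx <- length(models)
  tx_ids <- names(models)

  with_seed(child_seed(design$seed, 202), {
    n_de <- round(design$frac_de * n_tx)
    de_ids <- if (n_de > 0) sample(tx_ids, n_de) else character(0)
    fold_mag <- runif(n_de, design$de_fold_range[1], design$de_fold_range[2])
    up <- sample(c(TRUE, FALSE), n_de, replace = TRUE)
    de <- tibble::tibble(transcript_id = de_ids,
                         fold = ifelse(up, fold_mag, 1 / fold_mag))

    # Candidate cassette exons: internal exons of non-DE transcripts whose
    # removal keeps both the start and the stop codon.
    cand <- purrr::map_dfr(models, function(tx) {
      n_ex <- nrow(tx$exons)
      if (n_ex < 3) return(tibble::tibble())
      keep <- tx$exons$exon_index[-c(1, n_ex)]
      keep <- keep[tx$exons$end[keep] < tx$cds_stop &
                     tx$exons$start[keep] > tx$cds_start + 2]
      tibble::tibble(transcript_id = tx$transcript_id, exon_index = keep)
    })
    cand <- cand[!cand$transcript_id %in% de_ids, ]
    n_exons_total <- sum(vapply(models, function(tx) nrow(tx$exons), 1L))
    n_as <- min(round(design$frac_as * n_exons_total), nrow(cand))
    if (n_as > 0) {
      pick <- cand[sample(nrow(cand), n_as), ]
      pick$ratio <- if (!is.null(design$as_ratio_values)) {
        resample(design$as_ratio_values, n_as, replace = TRUE)
      } else {
        draw_psi_ratios(n_as, design$as_ratio_range)
      }
    } else {
      pick <- tibble::tibble(transcript_id = character(0),
                             exon_index = integer(0), ratio = numeric(0))
    }
    structure(list(de_transcripts = de, as_exons = pick), class = "sim_truth")
  })
}

# Log-uniform draws from `range` excluding the open interval (2/3, 1.5):
# the screen's grey window. Draws are allocated to the low/high side with
# probability proportional to each side's log-width.
draw_psi_ratios <- function(n, range, low = 2 / 3, high = 1.5) {
  lo_side <- c(range[1], min(range[2], low))
  hi_side <- c(max(range[1], high), range[2])
  lo_w <- max(0, log(lo_side[2]) - log(lo_side[1]))
  hi_w <- max(0, log(hi_side[2]) - log(hi_side[1]))
  lo_ok <- lo_side[1] <= lo_side[2]
  hi_ok <- hi_side[1] <= hi_side[2]
  if (!lo_ok && !hi_ok) {
    abort("`as_ratio_range` lies entirely inside the (2/3, 1.5) exclusion window.")
  }
  p_lo <- if (!lo_ok) 0 else if (!hi_ok) 1 else {
    if (lo_w + hi_w == 0) 0.5 else lo_w / (lo_w + hi_w)
  }
  side_lo <- runif(n) < p_lo
  out <- numeric(n)
  if (any(side_lo)) {
    out[side_lo] <- exp(runif(sum(side_lo), log(lo_side[1]), log(lo_side[2])))
  }
  if (any(!side_lo)) {
    out[!side_lo] <- exp(runif(sum(!side_lo), log(hi_side[1]), log(hi_side[2])))
  }
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d DE transcripts, %d AS exons\n",
              nrow(x$de_transcripts), nrow(x$as_exons)))
  invisible(x)
}

#' Enrich planted splicing exons for the AGAA motif
#'
#' Tra2b-responsive exons carry clustered (A)GAA elements; this mirrors that
#' by planting additional AGAA copies into every exon with a planted
#' inclusion change until its binding-site frequency F reaches
#' `target_freq`, leaving all other sequence content untouched.
#'
#' @param models List of [transcript_model()] objects.
#' @param truth A `sim_truth` from [plant_effects()].
#' @param target_freq Target F (256 * count / length) for planted exons.
#' @param motif Motif (default `"AGAA"`).
#' @param seed Integer seed.
#' @return The model list with enriched exon sequences.
#' @export
enrich_planted_motifs <- function(models, truth, target_freq = 2.5,
                                  motif = "AGAA", seed = 1L) {
  if (nrow(truth$as_exons) == 0) return(models)
  with_seed(child_seed(seed, 303), {
    for (i in seq_len(nrow(truth$as_exons))) {
      tx_id <- truth$as_exons$transcript_id[i]
      ei <- truth$as_exons$exon_index[i]
      tx <- models[[tx_id]]
      chars <- strsplit(transcript_sequence(tx), "")[[1]]
      lo <- tx$exons$start[ei]
      hi <- tx$exons$end[ei]
      len <- tx$exons$length[ei]
      need <- ceiling(target_freq * len / 256)
      have <- count_motif(tx$exons$seq[ei], motif)
      if (have < need) {
        chars <- plant_motifs(chars, need - have, lo, hi, motif,
                              tx$cds_start, tx$cds_stop)
      }
      seq_full <- paste(chars, collapse = "")
      exon_seqs <- substring(seq_full, tx$exons$start, tx$exons$end)
      models[[tx_id]] <- transcript_model(tx_id, exon_seqs,
                                          tx$cds_start, tx$cds_stop)
    }
    models
  })
}

#' Simulate a two-group probe-level intensity matrix
#'
#' Each transcript gets one gene-level probeset and one probeset per exon.
#' A probe's log2 intensity is baseline + log2(inclusion) + a fixed
#' probe affinity + Gaussian noise; values are linearized and an additive
#' exponential background is applied. KO samples use the mosaicism-diluted
#' expectation (1 - m) * KO_state + m * CTRL_state on the linear scale, so
#' m = 1 collapses KO onto the CTRL expression state.
#'
#' @param models List of [transcript_model()] objects.
#' @param truth A `sim_truth` from [plant_effects()] on the same models.
#' @param design A [simulation_design()].
#'
#' @return A [probe_matrix()]; samples named `CTRL_1..n` / `KO_1..n`, with
#'   the matching [group_design()] attached as attribute `"design"`.
#' @export
simulate_probe_matrix <- function(models, truth, design) {
  stopifnot(inherits(design, "simulation_design"))
  bad <- setdiff(truth$de_transcripts$transcript_id, names(models))
  bad2 <- setdiff(truth$as_exons$transcript_id, names(models))
  if (length(bad) + length(bad2) > 0) {
    abort("`truth` refers to transcripts absent from `models`.")
  }

  n_s <- design$n_ctrl + design$n_ko
  sample_ids <- c(sprintf("CTRL_%d", seq_len(design$n_ctrl)),
                  sprintf("KO_%d", seq_len(design$n_ko)))
  is_ko <- c(rep(FALSE, design$n_ctrl), rep(TRUE, design$n_ko))
  m <- design$mosaic_fraction
  ppp <- design$probes_per_probeset

  de_fold <- setNames(truth$de_transcripts$fold,
                      truth$de_transcripts$transcript_id)
  as_key <- paste(truth$as_exons$transcript_id, truth$as_exons$exon_index)
  as_ratio <- setNames(truth$as_exons$ratio, as_key)

  with_seed(child_seed(design$seed, 404), {
    # Baseline transcript brightness: expressed transcripts on these
    # arrays sit well above the additive background once the expression
    # floors have been applied; log2 baseline N(8, 1.2) puts the bulk of
    # signals 1-2 orders of magnitude above a background of mean 20.
    baseline <- setNames(rnorm(length(models), mean = 8, sd = 1.2),
                         names(models))

    info <- purrr::map_dfr(models, function(tx) {
      dplyr::bind_rows(
        tibble::tibble(probeset_id = paste0(tx$transcript_id, "_G"),
                       feature_id = tx$transcript_id, kind = "gene",
                       transcript_id = tx$transcript_id,
                       exon_index = NA_integer_),
        tibble::tibble(probeset_id = sprintf("%s_E%02d", tx$transcript_id,
                                             tx$exons$exon_index),
                       feature_id = sprintf("%s_E%02d", tx$transcript_id,
                                            tx$exons$exon_index),
                       kind = "exon", transcript_id = tx$transcript_id,
                       exon_index = tx$exons$exon_index)
      )
    })

    # Expected linear signal per probeset and group. Gene probesets track
    # transcript abundance; exon probesets additionally scale with
    # group-specific inclusion. Planted inclusions are anchored at 0.95 so
    # the KO/CTRL inclusion ratio equals the planted PSI ratio exactly.
    expo <- 2^baseline[info$transcript_id]
    fold <- ifelse(info$transcript_id %in% names(de_fold),
                   de_fold[info$transcript_id], 1)
    key <- paste(info$transcript_id, info$exon_index)
    ratio <- ifelse(key %in% names(as_ratio), as_ratio[key], 1)
    incl_ctrl <- ifelse(info$kind == "exon" & ratio >= 1, 0.95 / ratio,
                        ifelse(info$kind == "exon", 0.95, 1))
    incl_ko <- ifelse(info$kind == "exon" & ratio >= 1, 0.95,
                      ifelse(info$kind == "exon", 0.95 * ratio, 1))
    mu_ctrl <- expo * incl_ctrl
    mu_ko_raw <- expo * fold * incl_ko
    mu_ko <- (1 - m) * mu_ko_raw + m * mu_ctrl

    n_ps <- nrow(info)
    probe_ids <- paste0(rep(info$probeset_id, each = ppp), ".p",
                        rep(seq_len(ppp), times = n_ps))
    affinity <- rnorm(n_ps * ppp, 0, 0.3)
    mu_probe_ctrl <- rep(log2(mu_ctrl), each = ppp) + affinity
    mu_probe_ko <- rep(log2(mu_ko), each = ppp) + affinity

    vals <- matrix(0, nrow = n_ps * ppp, ncol = n_s,
                   dimnames = list(probe_ids, sample_ids))
    for (j in seq_len(n_s)) {
      mu_j <- if (is_ko[j]) mu_probe_ko else mu_probe_ctrl
      x <- mu_j + rnorm(length(mu_j), 0, design$noise_sd)
      lin <- 2^x
      if (design$background_mean > 0) {
        lin <- lin + rexp(length(lin), rate = 1 / design$background_mean)
      }
      vals[, j] <- lin
    }

    pm <- probe_matrix(vals,
                       setNames(rep(info$probeset_id, each = ppp), probe_ids),
                       info)
    attr(pm, "design") <- group_design(sample_ids,
                                       ifelse(is_ko, "KO", "CTRL"))
    pm
  })
}
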