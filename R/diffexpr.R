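#' Fit empirical-Bayes moderated t statistics for a two-group contrast
#'
#' For each feature, the KO vs CTRL difference of log2 group means is
#' tested with a t statistic whose per-feature residual variance is shrunk
#' toward a prior: the posterior variance is
#' `(d0 * s0_sq + d_g * s_g_sq) / (d0 + d_g)` with residual df
#' `d_g = n - 2`, and the statistic is referred to a t distribution on
#' `d0 + d_g` degrees of freedom. The prior `(d0, s0_sq)` is estimated by
#' closed-form moment matching of the log residual variances
#' (digamma/trigamma inversion); `d0 = Inf` degenerates to a common
#' variance, `d0 = 0` to the ordinary pooled two-sample t.
#'
#' @param s A [summary_matrix()] (typically gene-level features).
#' @param design A [group_design()] covering the columns of `s`.
#' @param d0,s0_sq Optional prior df and prior variance overriding the
#'   empirical-Bayes estimates (both must be supplied together).
#' @return Object of class `mod_t_fit`; use [tidy()] for the per-feature
#'   table and [glance()] for the prior estimates.
#' @export
fit_moderated_t <- function(s, design, d0 = NULL, s0_sq = NULL) {
  stopifnot(inherits(s, "summary_matrix"))
  design <- tibble::as_tibble(design)
  if (!all(design$sample_id %in% colnames(s$values))) {
    abort("design samples missing from the summary matrix.")
  }
  ctrl <- design$sample_id[design$group == "CTRL"]
  ko <- design$sample_id[design$group == "KO"]
  if (length(ctrl) < 2 || length(ko) < 2) {
    abort("each group needs at least 2 samples.")
  }
  x_c <- s$values[, ctrl, drop = FALSE]
  x_k <- s$values[, ko, drop = FALSE]
  n1 <- length(ctrl); n2 <- length(ko)
  mean_c <- rowMeans(x_c)
  mean_k <- rowMeans(x_k)
  log2_fc <- mean_k - mean_c
  ss <- rowSums((x_c - mean_c)^2) + rowSums((x_k - mean_k)^2)
  d_g <- n1 + n2 - 2
  s_g_sq <- ss / d_g

  if (is.null(d0) != is.null(s0_sq)) {
    abort("supply both `d0` and `s0_sq`, or neither.")
  }
  if (is.null(d0)) {
    prior <- estimate_variance_prior(s_g_sq, d_g)
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  }
  if (d0 < 0 || (is.finite(s0_sq) && s0_sq < 0)) {
    abort("`d0` and `s0_sq` must be non-negative.")
  }
  s_tilde_sq <- if (is.infinite(d0)) rep(s0_sq, length(s_g_sq)) else {
    (d0 * s0_sq + d_g * s_g_sq) / (d0 + d_g)
  }
  se <- sqrt(s_tilde_sq * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, log2_fc / se, ifelse(log2_fc == 0, 0, Inf * sign(log2_fc)))
  df_total <- d0 + d_g
  p <- 2 * pt(-abs(t_mod), df = df_total)
  p[t_mod == 0] <- 1

  stats <- tibble::tibble(
    feature_id = s$features$feature_id,
    log2_fc = unname(log2_fc),
    fold_change = unname(signed_fold_change_from_log2(log2_fc)),
    t = unname(t_mod),
    p_value = unname(p),
    df_total = df_total,
    fdr = unname(p.adjust(p, method = "BH"))
  )
  structure(list(stats = stats, d0 = d0, s0_sq = s0_sq, d_g = d_g,
                 n_ctrl = n1, n_ko = n2),
            class = "mod_t_fit")
}

# Signed linear fold from log2 difference: +r for r >= 1, else -1/r, so a
# halving is reported as -2.0.
signed_fold_change_from_log2 <- function(log2_fc) {
  r <- 2^log2_fc
  ifelse(r >= 1, r, -1 / r)
}

# Closed-form moment estimation of the scaled inverse-chi-square variance
# prior from log residual variances: matches the mean and the excess
# variance of log(s^2) over its sampling variance trigamma(d_g/2).
estimate_variance_prior <- function(s_g_sq, d_g) {
  ok <- is.finite(s_g_sq) & s_g_sq > 0
  s2 <- s_g_sq[ok]
  if (length(s2) < 2) {
    return(list(d0 = Inf, s0_sq = mean(s_g_sq[is.finite(s_g_sq)])))
  }
  z <- log(s2)
  e <- z - digamma(d_g / 2) + log(d_g / 2)
  e_bar <- mean(e)
  n <- length(e)
  excess <- mean((e - e_bar)^2) * n / (n - 1) - trigamma(d_g / 2)
  if (excess <= 0) {
    # Log-variances no more dispersed than chi-square sampling alone:
    # infinite prior df, common variance.
    return(list(d0 = Inf, s0_sq = exp(e_bar)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of the trigamma function on (0, Inf).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' @exportS3Method generics::tidy
#' @export
tidy.mod_t_fit <- function(x, ...) x$stats

#' @exportS3Method generics::glance
#' @export
glance.mod_t_fit <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s0_sq = x$s0_sq, d_g = x$d_g,
                 n_features = nrow(x$stats),
                 n_ctrl = x$n_ctrl, n_ko = x$n_ko)
}

#' @export
print.mod_t_fit <- function(x, ...) {
  cat(sprintf("<mod_t_fit> %d features, %d vs %d samples; prior d0 = %.3g, s0^2 = %.3g\n",
              nrow(x$stats), x$n_ctrl, x$n_ko, x$d0, x$s0_sq))
  invisible(x)
}

#' Moderated t table for a two-group contrast
#'
#' Convenience wrapper around [fit_moderated_t()] returning the tidy
#' per-feature table directly.
#'
#' @inheritParams fit_moderated_t
#' @return Tibble with `feature_id`, `log2_fc`, signed `fold_change`, `t`,
#'   `p_value`, `df_total` and an informational BH `fdr` column.
#' @export
moderated_t_table <- function(s, design, d0 = NULL, s0_sq = NULL) {
  tidy(fit_moderated_t(s, design, d0 = d0, s0_sq = s0_sq))
}

#' Call differentially expressed features
#'
#' Keeps features whose linear fold-change magnitude is at least
#' `fold_cut` and whose p-value is at most `p_cut` (both inclusive),
#' sorted by ascending p-value. No multiple-testing correction is applied
#' to the call; the BH column in the input is informational only.
#'
#' @param stats Tibble from [moderated_t_table()].
#' @param fold_cut Linear fold-change threshold (default 1.5).
#' @param p_cut P-value threshold (default 0.05).
#' @return The called subset of `stats`, sorted by p-value.
#' @export
call_differential <- function(stats, fold_cut = 1.5, p_cut = 0.05) {
  if (nrow(stats) == 0) abort("`stats` is empty.")
  stats |>
    dplyr::filter(abs(.data$fold_change) >= fold_cut,
                  .data$p_value <= p_cut) |>
    dplyr::arrange(.data$p_value)
}
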