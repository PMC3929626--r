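#' Housekeeping normalization
#'
#' Divides a target signal by its housekeeping reference signal (Gapdh,
#' Hprt, beta-actin) measured in the same sample.
#'
#' @param target Target intensities (arbitrary units, >= 0).
#' @param reference Reference intensities (> 0), same length or scalar.
#' @return `target / reference`.
#' @export
normalize_to_reference <- function(target, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    abort("`reference` intensities must be positive.")
  }
  if (any(target < 0)) abort("`target` intensities must be non-negative.")
  target / reference
}

#' Signed fold change between two group means
#'
#' Reports the ratio `a / b` as a signed fold with magnitude always >= 1:
#' `+r` when `r >= 1`, otherwise `-1/r`, so a drop to a fifth-and-a-half is
#' written -5.5-fold rather than 0.18.
#'
#' @param group_a_mean,group_b_mean Positive group means (a vs b, e.g. KO
#'   vs CTRL).
#' @return Signed fold change.
#' @export
signed_fold_change <- function(group_a_mean, group_b_mean) {
  if (any(!is.finite(group_a_mean)) || any(group_a_mean <= 0) ||
      any(!is.finite(group_b_mean)) || any(group_b_mean <= 0)) {
    abort("group means must be positive.")
  }
  r <- group_a_mean / group_b_mean
  ifelse(r >= 1, r, -1 / r)
}

#' Percent splicing inclusion from two isoform intensities
#'
#' From the intensities of the exon-including and exon-skipping isoform
#' bands of one sample, the inclusion percentage is
#' `100 * included / (included + skipped)`.
#'
#' @param included,skipped Non-negative isoform intensities with positive
#'   sum (element-wise).
#' @return Percentage in \[0, 100\].
#' @export
percent_inclusion <- function(included, skipped) {
  if (any(included < 0) || any(skipped < 0)) {
    abort("isoform intensities must be non-negative.")
  }
  total <- included + skipped
  if (any(total <= 0)) abort("`included + skipped` must be positive.")
  100 * included / total
}

# Significance stars: * p<0.05, ** p<0.01, *** p<0.001.
p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", .default = "")
}

#' Two-group Student's t test with star annotation
#'
#' Two-sided two-sample t test (equal-variance pooled by default, Welch
#' optionally) with the conventional significance stars: `*` p<0.05, `**`
#' p<0.01, `***` p<0.001.
#'
#' @param values_a,values_b Numeric vectors, >= 2 values each.
#' @param var_equal Pooled (TRUE, default) or Welch (FALSE) variance.
#' @return One-row tibble: `t`, `df`, `p_value`, `stars`.
#' @export
two_group_test <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs at least 2 values.")
  }
  n1 <- length(values_a); n2 <- length(values_b)
  m1 <- mean(values_a); m2 <- mean(values_b)
  if (var_equal) {
    sp2 <- (sum((values_a - m1)^2) + sum((values_b - m2)^2)) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- var(values_a) / n1; v2 <- var(values_b) / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- if (se > 0) (m1 - m2) / se else if (m1 == m2) 0 else Inf * sign(m1 - m2)
  p <- if (t == 0) 1 else 2 * pt(-abs(t), df = df)
  tibble::tibble(t = t, df = df, p_value = p, stars = p_stars(p))
}

#' Isoform validation report
#'
#' Applies the quantification conventions of isoform validation
#' experiments to a tidy measurement table: housekeeping normalization per
#' sample, group means with s.e.m., the signed fold change of `group_a`
#' over `group_b`, and a two-group Student's t test with stars, per
#' isoform.
#'
#' @param df Data frame with columns `sample_id`, `group`, `isoform`,
#'   `target_intensity`, `reference_intensity`.
#' @param group_a,group_b The two groups to contrast (fold is a over b;
#'   defaults KO vs CTRL).
#' @param var_equal See [two_group_test()].
#' @return Tibble with one row per isoform: group means, s.e.m., n,
#'   `fold_change`, `t`, `p_value`, `stars`.
#' @export
validate_isoforms <- function(df, group_a = "KO", group_b = "CTRL",
                              var_equal = TRUE) {
  needed <- c("sample_id", "group", "isoform", "target_intensity",
              "reference_intensity")
  if (!all(needed %in% names(df))) {
    abort(sprintf("`df` needs columns: %s.", paste(needed, collapse = ", ")))
  }
  df <- df |>
    dplyr::mutate(normalized = normalize_to_reference(
      .data$target_intensity, .data$reference_intensity))
  df |>
    dplyr::filter(.data$group %in% c(group_a, group_b)) |>
    dplyr::group_by(.data$isoform) |>
    dplyr::group_modify(function(d, key) {
      a <- d$normalized[d$group == group_a]
      b <- d$normalized[d$group == group_b]
      test <- two_group_test(a, b, var_equal = var_equal)
      tibble::tibble(
        mean_a = mean(a), sem_a = sd(a) / sqrt(length(a)), n_a = length(a),
        mean_b = mean(b), sem_b = sd(b) / sqrt(length(b)), n_b = length(b),
        fold_change = signed_fold_change(mean(a), mean(b)),
        t = test$t, p_value = test$p_value, stars = test$stars
      )
    }) |>
    dplyr::ungroup()
}
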