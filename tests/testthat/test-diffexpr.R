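test_that("forcing zero prior df recovers the ordinary pooled t", {
  s <- make_summary_4v4(50, seed = 11)
  tab <- moderated_t_table(s, design_4v4(), d0 = 0, s0_sq = 1)
  for (i in seq_len(50)) {
    o <- pooled_t_oracle(s$values[i, 1:4], s$values[i, 5:8])
    expect_equal(tab$t[i], o$t, tolerance = 1e-12)
    expect_equal(tab$p_value[i], o$p, tolerance = 1e-12)
  }
  expect_equal(unique(tab$df_total), 6)
})

test_that("identical group means give t = 0 and p = 1", {
  x <- matrix(rep(c(1, 2, 3, 4), 2), nrow = 1,
              dimnames = list("f1", c(paste0("CTRL_", 1:4), paste0("KO_", 1:4))))
  x <- rbind(f1 = x[1, ], f2 = rnorm(8, 5))
  s <- summary_matrix(x, tibble::tibble(feature_id = c("f1", "f2"),
                                        kind = "gene"))
  tab <- moderated_t_table(s, design_4v4(), d0 = 2, s0_sq = 0.5)
  expect_equal(tab$t[1], 0)
  expect_equal(tab$p_value[1], 1)
})

test_that("shrinkage leaves a common variance untouched", {
  # all features share the same residual variance: the posterior variance
  # equals it for any prior df
  base <- c(-1.5, -0.5, 0.5, 1.5)
  x <- rbind(f1 = c(base, base + 2), f2 = c(base + 1, base - 1),
             f3 = c(base, base))
  colnames(x) <- c(paste0("CTRL_", 1:4), paste0("KO_", 1:4))
  s <- summary_matrix(x, tibble::tibble(feature_id = rownames(x),
                                        kind = "gene"))
  s2 <- sum((base - mean(base))^2) * 2 / 6
  for (d0 in c(0, 4, 100)) {
    fit <- fit_moderated_t(s, design_4v4(), d0 = d0, s0_sq = s2)
    se_expected <- sqrt(s2 * (1 / 4 + 1 / 4))
    expect_equal(fit$stats$t,
                 unname(rowMeans(x[, 5:8]) - rowMeans(x[, 1:4])) / se_expected,
                 tolerance = 1e-12)
  }
})

test_that("empirical-Bayes prior estimation agrees with the reference implementation", {
  skip_if_not_installed("limma")
  set.seed(42)
  ng <- 400
  v <- 0.05 * rchisq(ng, df = 4) / 4 * exp(rnorm(ng, 0, 1))
  x <- matrix(rnorm(ng * 8, sd = sqrt(rep(v, 8))), ng, 8,
              dimnames = list(sprintf("g%d", 1:ng),
                              c(paste0("CTRL_", 1:4), paste0("KO_", 1:4))))
  s <- summary_matrix(x, tibble::tibble(feature_id = rownames(x),
                                        kind = "gene"))
  mine <- fit_moderated_t(s, design_4v4())
  ref <- limma::eBayes(limma::lmFit(x, cbind(1, rep(0:1, each = 4))))
  expect_equal(mine$d0, ref$df.prior, tolerance = 1e-8)
  expect_equal(mine$s0_sq, ref$s2.prior, tolerance = 1e-8)
  expect_equal(mine$stats$t, unname(ref$t[, 2]), tolerance = 1e-8)
  expect_equal(mine$stats$p_value, unname(ref$p.value[, 2]),
               tolerance = 1e-8)
})

test_that("zero-variance features are rescued by moderation", {
  x <- rbind(flat = rep(c(1, 2), c(4, 4)),
             f2 = rnorm(8), f3 = rnorm(8), f4 = rnorm(8))
  colnames(x) <- c(paste0("CTRL_", 1:4), paste0("KO_", 1:4))
  s <- summary_matrix(x, tibble::tibble(feature_id = rownames(x),
                                        kind = "gene"))
  fit <- fit_moderated_t(s, design_4v4(), d0 = 3, s0_sq = 0.2)
  expect_true(is.finite(fit$stats$t[1]))
  expect_gt(abs(fit$stats$t[1]), 0)
  expect_true(all(fit$stats$p_value > 0 & fit$stats$p_value <= 1))
})

test_that("design validation rejects undersized groups", {
  s <- make_summary_4v4(5, seed = 1)
  expect_error(group_design(c("a", "b", "c"), c("CTRL", "CTRL", "KO")),
               "at least 2")
  bad <- tibble::tibble(sample_id = colnames(s$values)[1:5],
                        group = c("CTRL", "CTRL", "CTRL", "CTRL", "KO"))
  expect_error(fit_moderated_t(s, bad), "at least 2")
})

test_that("differential calls match a brute-force filter and are monotone", {
  stats <- tibble::tibble(
    feature_id = paste0("g", 1:6),
    log2_fc = log2(abs(c(1.4, -1.6, 2.0, 1.5, -3.0, 1.1))),
    fold_change = c(1.4, -1.6, 2.0, 1.5, -3.0, 1.1),
    t = rnorm(6), p_value = c(0.001, 0.04, 0.2, 0.05, 0.01, 0.001),
    df_total = 6, fdr = NA_real_
  )
  called <- call_differential(stats, fold_cut = 1.5, p_cut = 0.05)
  brute <- stats$feature_id[abs(stats$fold_change) >= 1.5 &
                              stats$p_value <= 0.05]
  expect_setequal(called$feature_id, brute)
  expect_setequal(called$feature_id, c("g2", "g4", "g5"))
  expect_equal(called$p_value, sort(called$p_value))
  # fold below the cut is excluded even at tiny p; inclusive boundaries kept
  expect_false("g1" %in% called$feature_id)
  expect_true("g4" %in% called$feature_id)
  # relaxing either threshold never shrinks the called set
  for (fc in c(1.2, 1.5, 2)) {
    for (pc in c(0.01, 0.05, 0.2)) {
      a <- call_differential(stats, fc, pc)$feature_id
      b <- call_differential(stats, fc - 0.1, pc)$feature_id
      c_ <- call_differential(stats, fc, pc + 0.05)$feature_id
      expect_true(all(a %in% b))
      expect_true(all(a %in% c_))
    }
  }
})

test_that("null data yields a nominal moderated-t rejection rate", {
  s <- make_summary_4v4(2000, seed = 77, sd = 0.4)
  tab <- moderated_t_table(s, design_4v4())
  rate <- mean(tab$p_value <= 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("planted two-fold expression changes are recovered", {
  set.seed(88)
  n <- 500
  planted <- sort(sample(n, 50))
  samples <- c(paste0("CTRL_", 1:4), paste0("KO_", 1:4))
  x <- matrix(rnorm(n * 8, mean = 8, sd = 0.25), n, 8,
              dimnames = list(sprintf("f%03d", 1:n), samples))
  x[planted, 5:8] <- x[planted, 5:8] + 1   # 2-fold on the log2 scale
  s <- summary_matrix(x, tibble::tibble(feature_id = rownames(x),
                                        kind = "gene"))
  called <- call_differential(moderated_t_table(s, design_4v4()))
  recovered <- mean(rownames(x)[planted] %in% called$feature_id)
  expect_gte(recovered, 0.9)
})

test_that("signed fold changes follow the +r / -1/r convention", {
  s <- make_summary_4v4(20, seed = 5)
  tab <- moderated_t_table(s, design_4v4())
  expect_true(all(abs(tab$fold_change) >= 1))
  expect_equal(sign(tab$fold_change), ifelse(tab$log2_fc >= 0, 1, -1))
  expect_equal(abs(tab$fold_change),
               pmax(2^tab$log2_fc, 2^(-tab$log2_fc)))
})
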