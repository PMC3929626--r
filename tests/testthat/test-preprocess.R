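test_that("background correction matches its analytic limits", {
  vals <- matrix(c(100, 50, 80, 60), 2, 2,
                 dimnames = list(c("p1", "p2"), c("s1", "s2")))
  pm <- wrap_probe_matrix(vals)
  # sigma -> 0+, negligible signal rate: corrected -> observed - bg_mean
  bc <- background_correct(pm, bg_mean = 40, bg_sd = 1e-6,
                           signal_rate = 1e-9)
  expect_equal(bc$values[1, 1], 60, tolerance = 1e-6)
  # zero background: output equals input
  bc0 <- background_correct(pm, bg_mean = 0, bg_sd = 1e-9,
                            signal_rate = 1e-9)
  expect_equal(bc0$values, vals, tolerance = 1e-6)
})

test_that("background correction is monotone and strictly positive", {
  set.seed(1)
  o <- sort(c(runif(200, 0, 50), runif(200, 50, 2000)))
  vals <- matrix(o, ncol = 1, dimnames = list(sprintf("p%03d", seq_along(o)), "s1"))
  vals <- cbind(vals, s2 = o)  # corrector needs estimable arrays
  pm <- wrap_probe_matrix(vals)
  bc <- background_correct(pm, bg_mean = 30, bg_sd = 10, signal_rate = 1 / 300)
  expect_true(all(bc$values > 0))
  expect_true(all(diff(bc$values[, 1]) >= 0))
  # estimated-parameter path also stays positive and monotone
  bce <- background_correct(pm)
  expect_true(all(bce$values > 0))
  expect_true(all(diff(bce$values[, 1]) >= -1e-9))
})

test_that("background correction validates its parameters", {
  pm <- wrap_probe_matrix(matrix(1:4 * 1.0, 2, 2,
                                 dimnames = list(c("p1", "p2"), c("s1", "s2"))))
  expect_error(background_correct(pm, bg_mean = 10, bg_sd = 0,
                                  signal_rate = 1), "bg_sd")
  expect_error(background_correct(pm, bg_mean = 10, bg_sd = 1,
                                  signal_rate = -2), "signal_rate")
})

test_that("GC adjustment centers bins and degrades gracefully", {
  set.seed(2)
  n <- 200
  base <- 2^rnorm(n, 8, 0.5)
  gc <- c(rep(0.3, n / 2), rep(0.7, n / 2))
  # high-GC probes offset by +1 log2 unit
  vals <- base * ifelse(gc > 0.5, 2, 1)
  m <- matrix(c(vals, vals * 1.1), ncol = 2,
              dimnames = list(sprintf("p%03d", 1:n), c("s1", "s2")))
  pm <- wrap_probe_matrix(m, probe_gc = setNames(gc, rownames(m)))

  adj <- gc_adjust(pm, n_bins = 2)
  for (j in 1:2) {
    lx <- log2(adj$values[, j])
    expect_equal(median(lx[gc <= 0.5]), median(lx[gc > 0.5]),
                 tolerance = 1e-10)
  }
  # a single bin changes nothing
  one <- gc_adjust(pm, n_bins = 1)
  expect_equal(one$values, pm$values, tolerance = 1e-12)
  # absent GC annotation: warning, identity
  pm_nogc <- wrap_probe_matrix(m)
  expect_warning(out <- gc_adjust(pm_nogc), "skipped")
  expect_identical(out$values, pm_nogc$values)
})

test_that("quantile normalization reproduces the hand-executed example", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(quantile_normalize(x), matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))
  # identical columns are unchanged
  y <- matrix(c(5, 1, 9, 5, 1, 9), 3, 2)
  expect_equal(quantile_normalize(y), y)
  expect_error(quantile_normalize(y[, 1, drop = FALSE]), "2 samples")
})

test_that("quantile normalization equalizes distributions and is idempotent", {
  set.seed(3)
  for (i in 1:5) {
    x <- matrix(rnorm(60 * 6, sd = runif(1, 0.5, 3)), 60, 6)
    q <- quantile_normalize(x)
    sorted <- apply(q, 2, sort)
    for (j in 2:6) expect_equal(sorted[, j], sorted[, 1])
    expect_equal(quantile_normalize(q), q)
    # ranks are preserved within each sample
    for (j in 1:6) expect_equal(order(q[, j]), order(x[, j]))
  }
})

test_that("quantile normalization averages tied target values", {
  x <- cbind(c(2, 2, 10), c(1, 5, 9))
  target <- rowMeans(apply(x, 2, sort))
  q <- quantile_normalize(x)
  expect_equal(q[1:2, 1], rep(mean(target[1:2]), 2))
  expect_equal(q[, 2], target)
})

test_that("probeset summarization is the mean of log2 probe values", {
  vals <- matrix(2^c(3, 5, 7, 3, 5, 7), nrow = 3,
                 dimnames = list(c("a1", "a2", "b1"), c("s1", "s2")))
  ps <- c(a1 = "A", a2 = "A", b1 = "B")
  info <- tibble::tibble(probeset_id = c("A", "B"),
                         feature_id = c("A", "B"), kind = "gene")
  pm <- probe_matrix(vals, ps, info)
  s <- summarize_probesets(pm)
  expect_equal(s$values["A", "s1"], 4)       # mean(log2) of {3, 5}
  expect_equal(s$values["B", "s1"], 7)       # single probe: identity
  # random probeset against a brute-force mean
  set.seed(4)
  v5 <- matrix(2^rnorm(10, 6, 1), 5, 2,
               dimnames = list(sprintf("c%d", 1:5), c("s1", "s2")))
  pm5 <- probe_matrix(v5, setNames(rep("C", 5), rownames(v5)),
                      tibble::tibble(probeset_id = "C", feature_id = "C",
                                     kind = "exon"))
  s5 <- summarize_probesets(pm5)
  brute <- sum(sapply(1:5, function(i) log2(v5[i, 1]))) / 5
  expect_equal(s5$values["C", "s1"], brute)
})

test_that("low-expression floors remove the right features", {
  vals <- rbind(gene_lo = log2(c(10, 20, 30, 20)),   # mean linear 20 < 25
                gene_hi = log2(c(100, 90, 110, 100)),
                exon_lo = rep(2.9, 4),               # mean log2 < 3
                exon_hi = rep(6, 4))
  colnames(vals) <- paste0("s", 1:4)
  s <- summary_matrix(vals, tibble::tibble(
    feature_id = rownames(vals),
    kind = c("gene", "gene", "exon", "exon")))
  f <- filter_low_expression(s, gene_linear_floor = 25, exon_log2_floor = 3)
  expect_setequal(f$removed$feature_id, c("gene_lo", "exon_lo"))
  expect_setequal(f$retained$features$feature_id, c("gene_hi", "exon_hi"))
  # all features above both floors: identity
  f2 <- filter_low_expression(f$retained, 25, 3)
  expect_equal(f2$retained$values, f$retained$values)
  expect_equal(nrow(f2$removed), 0L)
})

test_that("preprocessing introduces no non-finite values", {
  models <- generate_transcriptome(20, seed = 6)
  d <- simulation_design(seed = 6)
  tr <- plant_effects(models, d)
  pm <- simulate_probe_matrix(models, tr, d)
  prep <- preprocess_probe_matrix(pm, bg_mean = d$background_mean,
                                  bg_sd = d$background_sd)
  expect_true(all(is.finite(prep$gene$values)))
  expect_true(all(is.finite(prep$exon$values)))
})
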