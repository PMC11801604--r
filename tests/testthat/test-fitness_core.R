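test_that("edge filtering follows the half-open central-80% convention", {
  gene <- toy_gene(start = 100, end = 1099)            # L = 1000, + strand
  imap <- toy_map(rep("chrI", 3), c(150L, 600L, 1050L), c(4L, 7L, 2L))
  p <- assign_and_filter(imap, gene)
  # 150 -> rel 0.05 (excluded), 600 -> 0.5 (kept), 1050 -> 0.95 (excluded)
  expect_equal(p$o_full, 3L)
  expect_equal(p$n_observed, 1L)
  expect_equal(p$edge_excluded, 2L)
  expect_equal(p$reads, 7L)
  expect_equal(p$rel_pos, 0.5)

  minus <- toy_gene(strand = "-")
  pm <- assign_and_filter(imap, minus)
  # on the - strand 1050 -> rel 0.049 (excluded), 600 -> 0.499 (kept),
  # 150 -> rel 0.949 (excluded by the upper bound near that gene's 3' end)
  expect_equal(pm$n_observed, 1L)
  expect_equal(pm$reads, 7L)
  expect_equal(pm$rel_pos, 0.499)
})

test_that("edge boundaries are exact on both strands", {
  gene <- toy_gene(start = 1, end = 10000)             # L = 10000
  pos <- c(1000L, 1001L, 9000L, 9001L)                 # rel .0999/.1/.8999/.9
  imap <- toy_map(rep("chrI", 4), pos, rep(1L, 4))
  p <- assign_and_filter(imap, gene)
  expect_equal(sort(p$rel_pos), c(0.1, 0.8999))
  minus <- toy_gene(start = 1, end = 10000, strand = "-")
  pm <- assign_and_filter(imap, minus)
  # strand flip maps each boundary site onto its mirror image
  expect_equal(sort(pm$rel_pos), c(0.1, 0.8999))
  expect_equal(pm$n_observed, p$n_observed)
})

test_that("zero-site imputation appends the right number of zeros", {
  p <- manual_profile(c(5L, 9L, 9L), o_full = 4L)
  before <- sum(p$reads)
  p10 <- impute_zero_sites(p, 10L)
  expect_equal(p10$reads, c(5L, 9L, 9L, rep(0L, 6)))
  expect_equal(p10$n_zero_imputed, 6L)
  expect_equal(sum(p10$reads), before)                 # reads conserved

  p2 <- manual_profile(rep(1L, 7), o_full = 7L)
  p2 <- impute_zero_sites(p2, 3L)
  expect_equal(p2$n_zero_imputed, 0L)
  expect_equal(p2$reads, rep(1L, 7))
})

test_that("outlier trimming uses the interpolated 5-95 percentile range", {
  # 19 ones and a 100: q5 = 1, q95 = 1 + 0.05 * 99 = 5.95,
  # threshold = 5.95 + 1.5 * 4.95 = 13.375 -> the 100 is removed
  p <- manual_profile(c(rep(1L, 19), 100L))
  p <- trim_outliers(p)
  expect_equal(p$n_trimmed, 1L)
  expect_equal(p$n_after_trim, 19L)
  expect_true(all(p$reads == 1L))

  # with only ten values the interpolated q95 chases the extreme:
  # q95 = 1 + 0.55 * 99 = 55.45, threshold 137.125 -> nothing removed
  p2 <- trim_outliers(manual_profile(c(rep(1L, 9), 100L)))
  expect_equal(p2$n_trimmed, 0L)

  p3 <- trim_outliers(manual_profile(rep(7L, 12)))     # zero range
  expect_equal(p3$n_trimmed, 0L)

  p4 <- trim_outliers(manual_profile(rep(0L, 8)))      # zeros are structural
  expect_equal(p4$reads, rep(0L, 8))
})

test_that("the gene mean is the plain average with zeros included", {
  expect_equal(mean_reads(manual_profile(c(2L, 4L, 6L))), 4)
  expect_equal(mean_reads(manual_profile(c(5L, 9L, 9L, rep(0L, 6)))), 23 / 9)
  expect_equal(mean_reads(manual_profile(c(0L, 0L, 0L, 1L))), 0.25)
  expect_true(is.na(mean_reads(manual_profile(integer(0)))))
})

test_that("median-scaled fitness pins the median gene at 1", {
  res <- fitness_median_scale(c(2, 4, 16))
  expect_equal(res$mu_ref, 2)                          # median(log2) = log2(4)
  expect_equal(res$w, c(0.5, 1, 2))                    # 16 = median^2 -> w 2
  expect_error(fitness_median_scale(c(0.5, 1, 2)), "degenerate")
})

test_that("median-scaled fitness is invariant to the log base", {
  set.seed(3)
  yhat <- exp(rnorm(51, 2, 1))
  w2 <- fitness_median_scale(yhat)$w
  wn <- log(yhat) / stats::median(log(yhat))
  expect_equal(w2, wn, tolerance = 1e-12)
})

test_that("generation-scaled fitness follows the power law", {
  expect_equal(fitness_generation_scale(6, reference = 6), 1)
  expect_equal(fitness_generation_scale(1024 * 3, t_gen = 10, reference = 3),
               2)
  expect_equal(fitness_generation_scale(0, reference = 5), 0)
})

test_that("both fitness scales are strictly increasing in the mean reads", {
  set.seed(4)
  yhat <- sort(exp(rnorm(41, 3, 1)))
  w1 <- fitness_median_scale(yhat)$w
  w2 <- fitness_generation_scale(yhat)
  expect_true(all(diff(w1) > 0))
  expect_true(all(diff(w2) > 0))
})

test_that("negative fitness arises for means below one", {
  yhat <- c(0.25, 2, 4, 8, 64)
  w <- fitness_median_scale(yhat)$w
  expect_lt(w[1], 0)
  expect_true(all(w[-1] > 0))
})

test_that("the full pipeline flags sparse and all-zero genes undetermined", {
  fit <- cached_fit()
  f <- fit$fitness
  expect_true(all(f$status %in% c("ok", "undetermined")))
  und <- f$status == "undetermined"
  # undetermined exactly when too few usable sites or an all-zero read set
  all_zero <- vapply(fit$profiles, function(p)
    p$n_after_trim > 0 && all(p$reads == 0L), TRUE)
  expect_equal(und, f$n_used < 5 | all_zero)
  expect_true(all(is.na(f$fitness_median_scale[und])))
  expect_true(all(!is.na(f$fitness_median_scale[!und])))
})
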