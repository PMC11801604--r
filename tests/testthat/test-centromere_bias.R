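test_that("cumulative counts per arm match a hand count", {
  imap <- toy_map(c("chrI", "chrI"), c(1300L, 1600L), c(1L, 1L))
  cen <- data.frame(chrom = "chrI", start = 1000, end = 1100)
  curve <- cumulative_insertions(imap, cen, grid_step = 100)
  right <- curve$arm_counts["chrI:R", ]
  expect_equal(unname(right[curve$grid == 200]), 1)
  expect_equal(unname(right[curve$grid == 500]), 2)
  expect_equal(unname(right[curve$grid == 100]), 0)
})

test_that("sites inside the centromere interval get distance zero", {
  imap <- toy_map("chrI", 1050L, 3L)
  cen <- data.frame(chrom = "chrI", start = 1000, end = 1100)
  curve <- cumulative_insertions(imap, cen, grid_step = 100)
  expect_equal(unname(curve$arm_counts["chrI:L", 1]), 1)
})

test_that("a chromosome without a centromere entry is an error", {
  imap <- toy_map(c("chrI", "chrMystery"), c(10L, 20L), c(1L, 1L))
  cen <- data.frame(chrom = "chrI", start = 5, end = 6)
  expect_error(cumulative_insertions(imap, cen), "chrMystery")
})

test_that("uniform insertion placement recovers a linear cumulative curve", {
  set.seed(1)
  rho <- 0.005
  L <- 2e6 + 100
  cen <- data.frame(chrom = "chrI", start = 1e6, end = 1e6 + 99)
  pos <- which(runif(L) < rho)
  imap <- toy_map(rep("chrI", length(pos)), pos, rep(1L, length(pos)))
  curve <- cumulative_insertions(imap, cen,
                                 chrom_lengths = c(chrI = L))
  ok <- !is.na(curve$average) & curve$grid > 0
  slope <- stats::coef(lm(curve$average[ok] ~ 0 + curve$grid[ok]))[[1]]
  expect_lt(abs(slope / rho - 1), 0.05)
})

test_that("a linear cumulative curve yields a flat insertion rate", {
  curve <- synthetic_curve(function(r) 0.1 * r)
  model <- fit_bias_model(curve)
  a <- coef(model)
  expect_equal(a[["a1"]], 0.1, tolerance = 1e-8)
  lam <- predict(model, c(0, 5e4, 1e5, 2e5, 3.5e5))
  expect_equal(lam, rep(0.1, 5), tolerance = 1e-8)
})

test_that("the cubic fit matches the normal-equations closed form", {
  set.seed(7)
  r <- seq(0, 4e5, by = 1e3)
  y_true <- 5 + 0.1 * r - 1e-7 * r^2 + 1e-13 * r^3
  y <- y_true + rnorm(length(r), sd = 10)
  curve <- synthetic_curve(function(rr)
    approx(r, y, xout = rr)$y)
  model <- fit_bias_model(curve)
  # independent oracle: column-equilibrated normal equations on raw powers
  X <- cbind(1, r, r^2, r^3)
  sc <- sqrt(colSums(X^2))
  Xs <- sweep(X, 2, sc, "/")
  a_oracle <- solve(t(Xs) %*% Xs, t(Xs) %*% y)[, 1] / sc
  expect_equal(unname(coef(model)), unname(a_oracle),
               tolerance = 1e-8)
})

test_that("the rate is constant and continuous beyond the cutoff", {
  set.seed(7)
  r <- seq(0, 4e5, by = 1e3)
  y <- 5 + 0.1 * r - 1e-7 * r^2 + 1e-13 * r^3 + rnorm(length(r), sd = 5)
  curve <- synthetic_curve(function(rr) approx(r, y, xout = rr)$y)
  model <- fit_bias_model(curve)
  lam <- predict(model, c(2e5, 2.5e5, 3e5, 4e5, 1e7))
  expect_true(all(lam == model$lambda_plateau))
  expect_equal(predict(model, 2e5 - 1e-6)[[1]], model$lambda_plateau,
               tolerance = 1e-9)
})

test_that("a decidedly negative fitted rate is an error", {
  curve <- synthetic_curve(function(r) 1e5 - 0.1 * r)
  expect_error(fit_bias_model(curve), "negative")
})

test_that("the simulator's bias shape is recovered from placement data", {
  set.seed(11)
  genome <- simulate_genome(essential_fraction = 0)
  truth <- synthetic_truth(genome, mean_effect = 0)
  sim <- simulate_library(truth, genome)
  model <- fit_bias_model(cumulative_insertions(sim$insertions,
                                                genome$centromeres))
  expect_lt(abs(predict(model, 0) / truth$lambda_near - 1), 0.15)
  expect_lt(abs(model$lambda_plateau / truth$lambda_far - 1), 0.10)
})

test_that("expected insertion counts follow the floor and plateau rules", {
  flat <- manual_bias(c(0, 0.1, 0, 0))
  gene <- toy_gene(start = 1000, end = 1999)      # L = 1000
  cen <- data.frame(chrom = "chrI", start = 100, end = 200)
  expect_equal(expected_insertions(gene, cen, flat), 100L)

  low <- manual_bias(c(0, 0.0667, 0, 0))
  g100 <- toy_gene(start = 1000, end = 1099)      # L = 100, floor(6.67)
  expect_equal(expected_insertions(g100, cen, low), 6L)

  sloped <- manual_bias(c(0, 0.1, -1e-7, 0))      # lambda = 0.1 - 2e-7 r
  distal <- toy_gene(start = 300000, end = 300999)
  expect_equal(predict(sloped, 2e5)[[1]], sloped$lambda_plateau)
  expect_equal(expected_insertions(distal, cen, sloped),
               as.integer(floor(sloped$lambda_plateau * 1000)))
})

test_that("unobserved site counts never go negative", {
  expect_equal(unobserved_sites(10L, 4L), 6L)
  expect_equal(unobserved_sites(3L, 7L), 0L)
  expect_equal(unobserved_sites(0L, 0L), 0L)
  expect_equal(unobserved_sites(c(10L, 3L, 0L), c(4L, 7L, 0L)),
               c(6L, 0L, 0L))
})
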