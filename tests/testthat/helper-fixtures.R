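# shared fixtures; everything is built in code at test time

toy_map <- function(chrom, position, reads, sample = "toy") {
  insertion_map(chrom, position, reads, sample = sample)
}

toy_gene <- function(gene_id = "G1", chrom = "chrI", start = 100, end = 1099,
                     strand = "+", essential = FALSE) {
  data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
             strand = strand, essential = essential,
             stringsAsFactors = FALSE)
}

# a cumulative curve with a prescribed average (arms long enough everywhere)
synthetic_curve <- function(average_fun, rmax = 4e5, step = 1e3) {
  grid <- seq(0, rmax, by = step)
  avg <- average_fun(grid)
  structure(list(grid = grid,
                 arm_counts = matrix(avg, nrow = 1,
                                     dimnames = list("syn:L", NULL)),
                 average = avg,
                 arms = data.frame(arm = "syn:L", length = rmax),
                 grid_step = step),
            class = "satay_cumcurve")
}

# a bias model with known coefficients, bypassing the fit
manual_bias <- function(a, r_cut = 2e5) {
  lam <- function(r) a[2] + 2 * a[3] * r + 3 * a[4] * r^2
  structure(list(coefficients = stats::setNames(a, paste0("a", 0:3)),
                 r_cut = r_cut, fit_range = 4e5,
                 lambda_plateau = lam(r_cut), rss = 0, n_points = 0,
                 grid_step = 1e3),
            class = "satay_bias")
}

# a gene_profile built directly from read values (post edge-filter)
manual_profile <- function(reads, o_full = length(reads),
                           rel_pos = rep(0.5, length(reads))) {
  structure(list(gene_id = "G1", chrom = "chrI", length = 1000L,
                 strand = "+", rel_pos = rel_pos, reads = as.integer(reads),
                 o_full = o_full, n_observed = length(reads),
                 edge_excluded = 0L, expected = NA_integer_,
                 n_zero_imputed = 0L, n_after_trim = NA_integer_,
                 n_trimmed = 0L),
            class = "gene_profile")
}

# the reference simulation and its fit, computed once per test run
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- simulate_library(seed = 1)
  .sim_cache$sim
}

cached_fit <- function() {
  if (is.null(.sim_cache$fit)) {
    sim <- cached_sim()
    .sim_cache$fit <- satay_fitness(sim$insertions, sim$genome$genes,
                                    sim$genome$centromeres)
  }
  .sim_cache$fit
}
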