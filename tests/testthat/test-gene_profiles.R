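test_that("a single insertion lands in its segment, others undefined", {
  gene <- toy_gene(start = 1, end = 1000)
  imap <- toy_map("chrI", 511L, 7L)                    # rel 0.51 -> bin 11
  prof <- bin_profile(imap, gene)
  expect_equal(nrow(prof), 20L)
  expect_equal(prof$insertions[11], 1L)
  expect_equal(prof$mean_reads[11], 7)
  expect_true(all(is.na(prof$mean_reads[-11])))
  expect_equal(sum(prof$insertions), 1L)
})

test_that("uniform insertions with equal reads give equal segment means", {
  gene <- toy_gene(start = 1, end = 2000)
  pos <- seq(1L, 2000L, by = 20L)
  imap <- toy_map(rep("chrI", length(pos)), pos, rep(5L, length(pos)))
  prof <- bin_profile(imap, gene)
  expect_true(all(prof$insertions == 5L))
  expect_equal(prof$mean_reads, rep(5, 20))
})

test_that("segment insertion counts conserve the CDS insertion count", {
  sim <- cached_sim()
  genes <- sim$genome$genes
  for (cls in c("all", "essential", "nonessential")) {
    prof <- bin_profile(sim$insertions, genes, class_filter = cls)
    sub <- switch(cls, all = genes,
                  essential = genes[genes$essential, ],
                  nonessential = genes[!genes$essential, ])
    s <- sim$insertions$sites
    n_cds <- sum(vapply(seq_len(nrow(sub)), function(i)
      sum(s$chrom == sub$chrom[i] & s$position >= sub$start[i] &
            s$position <= sub$end[i]), 0L))
    expect_equal(sum(prof$insertions), n_cds)
  }
})

test_that("edge-tolerant genes produce a U-shaped read profile", {
  genes <- do.call(rbind, lapply(1:10, function(i)
    toy_gene(sprintf("E%02d", i), start = 1 + (i - 1) * 2000,
             end = 1000 + (i - 1) * 2000)))
  pos <- integer(0); reads <- integer(0)
  for (i in 1:10) {
    off <- (i - 1) * 2000
    edge <- c(10L, 60L, 950L, 990L) + off     # rel < 0.10 or >= 0.90
    cent <- c(300L, 500L, 700L) + off
    pos <- c(pos, edge, cent)
    reads <- c(reads, rep(40L, 4), rep(1L, 3))
  }
  imap <- toy_map(rep("chrI", length(pos)), pos, reads)
  prof <- bin_profile(imap, genes)
  edge_bins <- c(1, 2, 19, 20); central <- 3:18
  edge_means <- prof$mean_reads[edge_bins]
  central_means <- prof$mean_reads[central]
  expect_gt(min(edge_means, na.rm = TRUE),
            max(central_means, na.rm = TRUE))
})

test_that("insertion-free spans match hand-computed gaps", {
  gene <- toy_gene(start = 1, end = 1000)
  expect_equal(insertion_free_span(toy_map(character(0), integer(0),
                                           integer(0)),
                                   gene)$span_fraction, 1)
  mid <- insertion_free_span(toy_map("chrI", 500L, 1L), gene)
  expect_equal(mid$span_fraction, 0.5, tolerance = 1e-2)
  dense_gene <- toy_gene(start = 1, end = 100)
  dense <- insertion_free_span(toy_map(rep("chrI", 100), 1:100,
                                       rep(1L, 100)), dense_gene)
  expect_equal(dense$span_fraction, 1 / 100)
})

test_that("spans are invariant to translation and strand", {
  set.seed(10)
  pos <- sort(sample(2001:3000, 15))
  g1 <- toy_gene(start = 2001, end = 3000)
  g2 <- toy_gene(start = 7001, end = 8000, strand = "-")
  s1 <- insertion_free_span(toy_map(rep("chrI", 15), pos, rep(1L, 15)), g1)
  s2 <- insertion_free_span(toy_map(rep("chrI", 15), pos + 5000L,
                                    rep(1L, 15)), g2)
  expect_equal(s1$span_fraction, s2$span_fraction)
})

test_that("essential genes show longer insertion-free spans in simulation", {
  sim <- cached_sim()
  spans <- insertion_free_span(sim$insertions, sim$genome$genes)
  ess <- sim$genome$genes$essential
  expect_gt(stats::median(spans$span_fraction[ess]),
            stats::median(spans$span_fraction[!ess]))
})
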