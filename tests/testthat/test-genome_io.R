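test_that("wig variableStep files are transcribed faithfully", {
  f <- withr::local_tempfile(lines = c("variableStep chrom=chrI",
                                       "100 3", "250 1"))
  imap <- read_insertion_map(f, dialect = "wig")
  expect_equal(imap$n_sites, 2L)
  expect_equal(imap$total_reads, 4)
  expect_equal(imap$sites$chrom, c("chrI", "chrI"))
  expect_equal(imap$sites$position, c(100L, 250L))
  expect_equal(imap$sites$reads, c(3L, 1L))
})

test_that("an empty file yields an empty insertion map", {
  f <- withr::local_tempfile(lines = character(0))
  imap <- read_insertion_map(f, dialect = "wig")
  expect_equal(imap$n_sites, 0L)
  expect_equal(imap$total_reads, 0)
})

test_that("malformed and invalid records are rejected with line numbers", {
  f <- withr::local_tempfile(lines = c("variableStep chrom=chrI",
                                       "100 3", "junk here too many fields"))
  expect_error(read_insertion_map(f, "wig"), "line 3")
  f2 <- withr::local_tempfile(lines = c("variableStep chrom=chrI", "100 0"))
  expect_error(read_insertion_map(f2, "wig"), "read count.*< 1")
  f3 <- withr::local_tempfile(lines = c("chrom\tposition\treads",
                                        "chrI\t100\t3", "chrI\t100\t2"))
  expect_error(read_insertion_map(f3, "bedlike"), "duplicate")
  f4 <- withr::local_tempfile(lines = c("100 3", "variableStep chrom=chrI"))
  expect_error(read_insertion_map(f4, "wig"), "before any variableStep")
})

test_that("bedlike TSV parses and chromosome renaming applies", {
  f <- withr::local_tempfile(lines = c("chrom\tposition\treads",
                                       "I\t100\t3", "II\t7\t2"))
  imap <- read_insertion_map(f, "bedlike", rename = c(I = "chrI"))
  expect_setequal(unique(imap$sites$chrom), c("chrI", "II"))
  expect_equal(imap$total_reads, 5)
})

test_that("insertion maps round-trip through both dialects", {
  imap <- toy_map(c("chrI", "chrI", "chrII"), c(5L, 900L, 44L), c(2L, 7L, 1L))
  for (dialect in c("wig", "bedlike")) {
    f <- withr::local_tempfile()
    write_insertion_map(imap, f, dialect)
    back <- read_insertion_map(f, dialect)
    expect_equal(back$sites, imap$sites)
    expect_equal(back$total_reads, sum(back$sites$reads))
    expect_equal(back$n_sites, nrow(back$sites))
  }
})

test_that("GFF3 gene records are loaded 1-based inclusive, others skipped", {
  f <- withr::local_tempfile(lines = c(
    "##gff-version 3",
    "chrI\tsgd\tgene\t100\t400\t.\t+\t.\tID=YAL001C",
    "chrI\tsgd\tCDS\t120\t380\t.\t+\t0\tID=YAL001C_CDS"))
  genes <- read_gff3(f)
  expect_equal(nrow(genes), 1L)
  expect_equal(genes$gene_id, "YAL001C")
  expect_equal(genes$end - genes$start + 1, 301)
  expect_false(genes$essential)
})

test_that("GFF3 structural errors are reported", {
  f <- withr::local_tempfile(lines = c(
    "chrI\tsgd\tgene\t100\t400\t.\t+\t.\tNote=missing",
    "chrI\tsgd\tgene\t500\t900\t.\t+\t.\tID=G2"))
  expect_error(read_gff3(f), "line 1.*ID")
  f2 <- withr::local_tempfile(lines = c(
    "chrI\tsgd\tgene\t100\t400\t.\t+\t.\tID=G1",
    "chrI\tsgd\tgene\t500\t900\t.\t+\t.\tID=G1"))
  expect_error(read_gff3(f2), "duplicate gene ID")
})

test_that("gene annotations round-trip through GFF3", {
  genes <- rbind(toy_gene("G1"), toy_gene("G2", start = 2000, end = 2500,
                                          strand = "-"))
  f <- withr::local_tempfile()
  write_gff3(genes, f)
  back <- read_gff3(f, essential = "G2")
  expect_equal(back[c("gene_id", "chrom", "start", "end", "strand")],
               genes[c("gene_id", "chrom", "start", "end", "strand")])
  expect_equal(back$essential, c(FALSE, TRUE))
})

test_that("fitness tables round-trip to 1e-9 and keep undetermined rows", {
  rec <- data.frame(
    gene_id = c("G2", "G1"), chrom = "chrI",
    n_observed = c(12L, 0L), expected_insertions = c(10L, 5L),
    n_zero_imputed = c(0L, 5L), n_used = c(12L, 5L),
    mean_reads = c(3.14159265358979, NA),
    fitness_median_scale = c(0.987654321012345, NA),
    fitness_generation_scale = c(1.00123456789, NA),
    variance = c(17.123456789, NA), standard_error = c(1.19456789, NA),
    status = c("ok", "undetermined"), stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  write_fitness_table(rec, f)
  back <- read_fitness_table(f)
  expect_equal(back$gene_id, c("G1", "G2"))   # deterministic ordering
  ord <- rec[order(rec$gene_id), ]
  for (cl in c("mean_reads", "fitness_median_scale",
               "fitness_generation_scale", "variance", "standard_error"))
    expect_equal(back[[cl]], ord[[cl]], tolerance = 1e-9)
  expect_equal(back$status, c("undetermined", "ok"))
  raw <- readLines(f)
  expect_equal(length(raw), 3L)               # header + two rows
})

test_that("centromere and essential-gene readers validate input", {
  f <- withr::local_tempfile(lines = c("chrom\tstart\tend",
                                       "chrI\t100\t200",
                                       "chrI\t300\t400"))
  expect_error(read_centromeres(f), "more than one centromere")
  f2 <- withr::local_tempfile(lines = c("# comment", "G1", "", "G2"))
  expect_equal(read_essential_genes(f2), c("G1", "G2"))
})
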