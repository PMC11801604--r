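#' Simulate a genome annotation for library simulation
#'
#' Builds a compact genome of \code{n_chrom} chromosomes, each with two arms
#' of \code{arm_length} bp flanking a short centromere, and places
#' non-overlapping genes of random length on the arms (never across a
#' centromere). A fixed fraction of genes is flagged essential.
#'
#' @param n_chrom number of chromosomes (default 3).
#' @param arm_length arm length in bp, recycled across arms (default 5e5 so
#'   the cumulative insertion curve extends past the 400 kb fit window).
#' @param n_genes total number of genes (default 300).
#' @param essential_fraction fraction of genes flagged essential
#'   (default 0.2, the approximate fraction of essential genes in yeast).
#' @param gene_length_range min/max gene length in bp (default 300-4000).
#' @param centromere_length centromere interval length (default 120 bp).
#' @param seed optional integer seed.
#' @return list with \code{genes} (annotation data.frame),
#'   \code{centromeres}, and \code{chrom_lengths} (named vector).
#' @export
simulate_genome <- function(n_chrom = 3, arm_length = 5e5, n_genes = 300,
                            essential_fraction = 0.2,
                            gene_length_range = c(300, 4000),
                            centromere_length = 120, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arm_length <- rep_len(arm_length, 2 * n_chrom)
  chroms <- sprintf("chr%02d", seq_len(n_chrom))
  cen_start <- as.integer(arm_length[2 * seq_len(n_chrom) - 1] + 1)
  cen_end <- as.integer(cen_start + centromere_length - 1)
  chrom_len <- as.integer(cen_end + arm_length[2 * seq_len(n_chrom)])
  centromeres <- data.frame(chrom = chroms, start = cen_start, end = cen_end)
  regions <- data.frame(
    chrom = rep(chroms, each = 2),
    start = as.vector(rbind(1, cen_end + 1)),
    end = as.vector(rbind(cen_start - 1, chrom_len)))
  regions$length <- regions$end - regions$start + 1

  if (n_genes == 0) {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), essential = logical(),
                        stringsAsFactors = FALSE)
  } else {
    lens <- sample(seq(gene_length_range[1], gene_length_range[2]), n_genes,
                   replace = TRUE)
    region_of <- sample(nrow(regions), n_genes, replace = TRUE,
                        prob = regions$length)
    rows <- list()
    for (rg in seq_len(nrow(regions))) {
      idx <- which(region_of == rg)
      if (!length(idx)) next
      l <- lens[idx]
      free <- regions$length[rg] - sum(l)
      if (free < length(l) + 1)
        stop("cannot place ", length(l), " genes totalling ", sum(l),
             " bp in a region of ", regions$length[rg], " bp")
      gaps <- as.vector(stats::rmultinom(1, free, rep(1, length(l) + 1)))
      starts <- regions$start[rg] + cumsum(gaps[-length(gaps)]) +
        c(0, cumsum(l[-length(l)]))
      rows[[rg]] <- data.frame(chrom = regions$chrom[rg],
                               start = as.integer(starts),
                               end = as.integer(starts + l - 1),
                               stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, rows)
    genes <- genes[order(genes$chrom, genes$start), ]
    genes <- data.frame(gene_id = sprintf("G%04d", seq_len(nrow(genes))),
                        genes,
                        strand = sample(c("+", "-"), nrow(genes),
                                        replace = TRUE),
                        stringsAsFactors = FALSE)
    n_ess <- round(essential_fraction * n_genes)
    genes$essential <- FALSE
    genes$essential[sample(nrow(genes), n_ess)] <- TRUE
    rownames(genes) <- NULL
  }
  list(genes = genes, centromeres = centromeres,
       chrom_lengths = stats::setNames(chrom_len, chroms))
}

#' Ground-truth parameters for a simulated transposon library
#'
#' Draws per-gene true growth rates and fixes the noise and bias parameters
#' a simulated library is generated from. Non-essential genes get
#' mu = max(0, 1 - s) doublings per generation-equivalent with a deleterious
#' effect s drawn from an exponential distribution: the bulk of disruptions
#' is near neutral with a skewed tail of deleterious effects, the expected
#' one-peak shape of a distribution of fitness effects. Essential genes get
#' mu = 0 in their central 80% with tolerance rising linearly toward the
#' gene ends (insertions close to a gene end often truncate too little of
#' the protein to abolish function). The insertion-placement rate tapers
#' smoothly from \code{lambda_near} at the centromere to \code{lambda_far}
#' at distance \code{decay_length} and is constant beyond:
#' lambda(r) = far + (near - far) (1 - r/decay)^2 for r < decay. The taper
#' joins the plateau with zero slope, so the true cumulative insertion curve
#' is piecewise cubic -- the same family the bias correction fits, mirroring
#' the local reinsertion preference of the MiniDS transposon.
#'
#' @param genome a genome from \code{\link{simulate_genome}}.
#' @param t_gen generations of library expansion (default 10).
#' @param alpha negative-binomial overdispersion of read counts
#'   (default 0.1).
#' @param neutral_rate growth rate of a neutral disruption and of intergenic
#'   insertions (default 1).
#' @param mean_effect mean of the exponential deleterious-effect
#'   distribution (default 0.1).
#' @param lambda_near,lambda_far insertion rate per bp at the centromere and
#'   far from it (defaults 0.12 and 0.067).
#' @param decay_length distance at which the pericentromeric excess has
#'   tapered to zero, bp (default 2e5).
#' @param bottleneck_per_site population-bottleneck size in cells per
#'   insertion site (default 100).
#' @param reads_per_site mean sequencing depth per insertion site
#'   (default 25).
#' @param seed optional integer seed.
#' @return object of class \code{satay_truth}: per-gene \code{mu} and true
#'   fitness \code{w} (mu scaled by its median), plus all parameters above.
#' @export
synthetic_truth <- function(genome, t_gen = 10, alpha = 0.1,
                            neutral_rate = 1, mean_effect = 0.1,
                            lambda_near = 0.12, lambda_far = 0.067,
                            decay_length = 2e5, bottleneck_per_site = 100,
                            reads_per_site = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- genome$genes
  n <- nrow(genes)
  effect <- stats::rexp(n, rate = 1 / mean_effect)
  mu <- pmax(0, neutral_rate * (1 - effect))
  mu[genes$essential] <- 0
  structure(list(gene_id = genes$gene_id, mu = mu,
                 w = if (n) mu / stats::median(mu) else numeric(0),
                 t_gen = t_gen, alpha = alpha,
                 neutral_rate = neutral_rate, mean_effect = mean_effect,
                 lambda_near = lambda_near, lambda_far = lambda_far,
                 decay_length = decay_length,
                 bottleneck_per_site = bottleneck_per_site,
                 reads_per_site = reads_per_site, seed = seed),
            class = "satay_truth")
}

#' @export
print.satay_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d genes, alpha = %g, t = %g generations\n",
              length(x$mu), x$alpha, x$t_gen))
  cat(sprintf("  insertion rate %g -> %g /bp (decay %g kb)\n",
              x$lambda_near, x$lambda_far, x$decay_length / 1e3))
  invisible(x)
}

# per-site true growth rate: gene assignment + essential edge ramp
site_growth_rates <- function(pos, chrom, genome, truth) {
  mu <- rep(truth$neutral_rate, length(pos))
  gene_id <- rep(NA_character_, length(pos))
  genes <- genome$genes
  for (ch in unique(chrom)) {
    gs <- genes[genes$chrom == ch, ]
    if (!nrow(gs)) next
    gs <- gs[order(gs$start), ]
    sel <- which(chrom == ch)
    gi <- findInterval(pos[sel], gs$start)
    inside <- gi >= 1L & pos[sel] <= gs$end[pmax(gi, 1L)]
    hit <- sel[inside]; gidx <- gi[inside]
    if (!length(hit)) next
    gene_id[hit] <- gs$gene_id[gidx]
    gmu <- truth$mu[match(gs$gene_id[gidx], truth$gene_id)]
    L <- gs$end[gidx] - gs$start[gidx] + 1
    rel <- (pos[hit] - gs$start[gidx]) / L
    edge <- pmin(rel, 1 - rel)
    ess <- gs$essential[gidx]
    ramp <- truth$neutral_rate * pmax(0, 1 - edge / 0.1)
    mu[hit] <- ifelse(ess, ifelse(edge < 0.1, ramp, 0), gmu)
  }
  list(mu = mu, gene_id = gene_id)
}

place_insertions <- function(genome, truth) {
  chrom <- character(0); pos <- integer(0)
  for (ch in names(genome$chrom_lengths)) {
    L <- genome$chrom_lengths[[ch]]
    ci <- genome$centromeres[genome$centromeres$chrom == ch, ]
    p <- seq_len(L)
    d <- pmax(0, pmax(ci$start - p, p - ci$end))
    lam <- truth$lambda_far + (truth$lambda_near - truth$lambda_far) *
      pmax(0, 1 - d / truth$decay_length)^2
    hit <- which(stats::runif(L) < lam)
    chrom <- c(chrom, rep(ch, length(hit)))
    pos <- c(pos, hit)
  }
  list(chrom = chrom, pos = pos)
}

draw_reads <- function(mu_reads, alpha) {
  if (alpha > 0) stats::rnbinom(length(mu_reads), mu = mu_reads,
                                size = 1 / alpha)
  else stats::rpois(length(mu_reads), mu_reads)
}

# one complete library realization: placement -> growth -> bottleneck ->
# negative-binomial read sampling; returns site table with read counts
realize_library <- function(genome, truth, depth) {
  sites <- place_insertions(genome, truth)
  sg <- site_growth_rates(sites$pos, sites$chrom, genome, truth)
  cells <- 2^(sg$mu * truth$t_gen)
  if (is.infinite(truth$bottleneck_per_site)) {
    # infinite bottleneck: abundances pass through undistorted
    mu_reads <- depth * cells / sum(cells)
  } else {
    bn <- round(truth$bottleneck_per_site * length(sites$pos))
    b <- as.vector(stats::rmultinom(1, bn, prob = cells))
    mu_reads <- depth * b / sum(b)
  }
  data.frame(chrom = sites$chrom, pos = sites$pos, mu = sg$mu,
             gene_id = sg$gene_id, mu_reads = mu_reads,
             stringsAsFactors = FALSE)
}

as_imap <- function(tab, reads, sample) {
  keep <- reads > 0
  insertion_map(tab$chrom[keep], tab$pos[keep], reads[keep], sample = sample)
}

#' Simulate a SATAY-style transposon insertion library
#'
#' Forward-simulates a sequencing-ready insertion map with known ground
#' truth: (i) insertion sites are placed per base pair with the
#' pericentromerically elevated rate of the truth object; (ii) each insertion
#' mutant starts from one cell and grows to 2^(mu t) cells under Malthusian
#' growth, with mu = 0 in the central 80% of essential genes; (iii) the grown
#' population passes a multinomial bottleneck; (iv) read counts are drawn
#' negative-binomially with mean proportional to post-bottleneck abundance
#' times depth and overdispersion alpha (which absorbs, rather than
#' mechanistically simulates, PCR noise). Sites with zero reads are absent
#' from the returned map, exactly as in real data.
#'
#' \code{split_point} produces a replicate pair that shares all stages before
#' the split and is re-randomized after it: \code{expansion} shares nothing
#' (independent libraries from the same truth), \code{pcr} shares the
#' insertion sites and bottleneck but redraws the read noise, and
#' \code{sequencing} shares one amplified template and redraws only the
#' multinomial depth sampling. These mimic replicates split before library
#' expansion, before PCR, and before sequencing.
#'
#' @param truth a \code{\link{synthetic_truth}}; generated with defaults if
#'   NULL.
#' @param genome a \code{\link{simulate_genome}} result; generated with
#'   defaults if NULL.
#' @param depth total reads; default \code{reads_per_site} (from the truth)
#'   times the number of placed sites.
#' @param split_point \code{"none"}, \code{"expansion"}, \code{"pcr"} or
#'   \code{"sequencing"}.
#' @param seed optional integer seed for the whole simulation.
#' @return object of class \code{satay_sim}: \code{insertions} (an
#'   \code{\link{insertion_map}}), \code{replicate} (second map, or NULL for
#'   \code{"none"}), \code{truth}, \code{genome}, \code{sites} (per-site
#'   table with true growth rates), \code{depth}, \code{split_point}.
#' @export
simulate_library <- function(truth = NULL, genome = NULL, depth = NULL,
                             split_point = c("none", "expansion", "pcr",
                                             "sequencing"),
                             seed = NULL) {
  split_point <- match.arg(split_point)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genome)) genome <- simulate_genome()
  if (is.null(truth)) truth <- synthetic_truth(genome)
  tab <- realize_library(genome, truth,
                         depth = 1)  # mu_reads rescaled below
  if (is.null(depth)) depth <- round(truth$reads_per_site * nrow(tab))
  tab$mu_reads <- tab$mu_reads * depth
  rep2 <- NULL
  if (split_point == "sequencing") {
    template <- draw_reads(tab$mu_reads, truth$alpha)
    sample_depth <- function() {
      if (sum(template) == 0) return(integer(length(template)))
      as.vector(stats::rmultinom(1, depth, prob = template))
    }
    r1 <- sample_depth(); r2 <- sample_depth()
    map1 <- as_imap(tab, r1, "sim_rep1"); rep2 <- as_imap(tab, r2, "sim_rep2")
  } else {
    r1 <- draw_reads(tab$mu_reads, truth$alpha)
    map1 <- as_imap(tab, r1, "sim_rep1")
    if (split_point == "pcr") {
      rep2 <- as_imap(tab, draw_reads(tab$mu_reads, truth$alpha), "sim_rep2")
    } else if (split_point == "expansion") {
      tab2 <- realize_library(genome, truth, depth = 1)
      tab2$mu_reads <- tab2$mu_reads * depth
      rep2 <- as_imap(tab2, draw_reads(tab2$mu_reads, truth$alpha),
                      "sim_rep2")
    }
  }
  structure(list(insertions = map1, replicate = rep2, truth = truth,
                 genome = genome, sites = tab, depth = depth,
                 split_point = split_point, seed = seed),
            class = "satay_sim")
}

#' @export
print.satay_sim <- function(x, ...) {
  cat(sprintf("Simulated SATAY library: %d sites placed, depth %s reads%s\n",
              nrow(x$sites), format(x$depth, big.mark = ","),
              if (is.null(x$replicate)) "" else
                sprintf(" (replicate pair, split at %s)", x$split_point)))
  print(x$insertions)
  invisible(x)
}

#' Write a simulated library to disk
#'
#' Writes the insertion map(s) as wig, the annotation as GFF3, the
#' centromeres as TSV and the ground truth as TSV, ready for the
#' command-line pipeline.
#'
#' @param sim a \code{satay_sim}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_insertion_map(sim$insertions, file.path(dir, "insertions.wig"))
  if (!is.null(sim$replicate))
    write_insertion_map(sim$replicate, file.path(dir, "insertions_rep2.wig"))
  write_gff3(sim$genome$genes, file.path(dir, "genes.gff3"))
  write_centromeres(sim$genome$centromeres, file.path(dir, "centromeres.tsv"))
  writeLines(sim$genome$genes$gene_id[sim$genome$genes$essential],
             file.path(dir, "essential.txt"))
  truth <- data.frame(gene_id = sim$truth$gene_id, mu = sim$truth$mu,
                      w = sim$truth$w)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
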