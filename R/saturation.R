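#' Subsample reads without replacement
#'
#' Draws n reads from the pooled read set of an insertion map using a
#' multivariate hypergeometric model: the reads form an urn with one colour
#' per insertion site, and exactly n are drawn without replacement. Sampling
#' is exact, implemented as a sequence of conditional univariate
#' hypergeometric draws per site, so memory does not scale with total reads.
#' Sites drawn zero times are dropped from the returned map.
#'
#' @param imap an \code{\link{insertion_map}}.
#' @param n number of reads to draw (0 <= n <= total reads).
#' @param seed optional integer seed; a fixed seed makes the draw
#'   reproducible.
#' @return an \code{\link{insertion_map}} with \code{sum(reads) == n}.
#' @export
subsample_reads <- function(imap, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- imap$total_reads
  if (n > N) stop(sprintf("cannot draw %g reads from a map with %g", n, N))
  if (n == N) return(imap)
  s <- imap$sites
  K <- s$reads
  x <- integer(nrow(s))
  n_rem <- as.integer(n); N_rem <- as.integer(N)
  for (i in seq_along(K)) {
    if (n_rem == 0L) break
    x[i] <- stats::rhyper(1L, K[i], N_rem - K[i], n_rem)
    n_rem <- n_rem - x[i]
    N_rem <- N_rem - K[i]
  }
  keep <- x > 0L
  out <- insertion_map(s$chrom[keep], s$position[keep], x[keep],
                       sample = imap$sample)
  out$subsample_seed <- seed
  out
}

#' Sequencing-saturation analysis
#'
#' Recomputes the fitness pipeline at a series of sequencing depths obtained
#' by hypergeometric subsampling of the input map, and records how the number
#' of unique insertion sites, the reads per site, and the relative standard
#' error of the fitness estimates respond. When most sites carry a single
#' read, the median reads per site barely moves with depth and the relative
#' errors plateau -- deeper sequencing then buys little accuracy.
#'
#' By default the depth series is nested (each depth is subsampled from the
#' previous, larger one), which makes the unique-insertion curve monotone by
#' construction; independent draws agree with nested ones in expectation.
#'
#' @param imap an \code{\link{insertion_map}}.
#' @param genes,centromeres pipeline inputs (see \code{\link{satay_fitness}}).
#' @param depths read depths to evaluate; default 10 log-spaced depths from
#'   1% to 100% of the total.
#' @param seed optional integer seed.
#' @param nested draw depths as a nested sequence (default TRUE).
#' @param config pipeline configuration.
#' @return data.frame of class \code{satay_saturation}, one row per depth:
#'   \code{n_reads}, \code{n_sites}, \code{mean_reads_per_site},
#'   \code{median_reads_per_site}, \code{rel_se_q25}, \code{rel_se_median},
#'   \code{rel_se_q75}, \code{n_ok_genes}.
#' @export
saturation_curve <- function(imap, genes, centromeres, depths = NULL,
                             seed = NULL, nested = TRUE,
                             config = satay_config()) {
  if (!is.null(seed)) set.seed(seed)
  N <- imap$total_reads
  if (is.null(depths))
    depths <- unique(round(exp(seq(log(0.01 * N), log(N), length.out = 10))))
  depths <- sort(depths, decreasing = TRUE)
  cur <- imap
  rows <- vector("list", length(depths))
  for (k in seq_along(depths)) {
    n <- depths[k]
    sub <- if (nested) subsample_reads(cur, n) else subsample_reads(imap, n)
    if (nested) cur <- sub
    fit <- try(satay_fitness(sub, genes, centromeres, config = config),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      rel_se <- numeric(0)
    } else {
      f <- fit$fitness
      ok <- f$status == "ok" & f$mean_reads > 0
      rel_se <- f$standard_error[ok] / f$mean_reads[ok]
    }
    q <- if (length(rel_se)) stats::quantile(rel_se, c(0.25, 0.5, 0.75),
                                             names = FALSE)
      else rep(NA_real_, 3)
    rows[[k]] <- data.frame(
      n_reads = n, n_sites = sub$n_sites,
      mean_reads_per_site = sub$total_reads / max(sub$n_sites, 1L),
      median_reads_per_site = if (sub$n_sites) stats::median(sub$sites$reads)
        else NA_real_,
      rel_se_q25 = q[1], rel_se_median = q[2], rel_se_q75 = q[3],
      n_ok_genes = length(rel_se))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$n_reads), ]
  rownames(out) <- NULL
  class(out) <- c("satay_saturation", "data.frame")
  out
}

#' @export
plot.satay_saturation <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$n_reads, x$n_sites, log = "x", type = "b", pch = 19,
                 xlab = "reads sampled", ylab = "unique insertion sites", ...)
  graphics::plot(x$n_reads, x$rel_se_median, log = "x", type = "b", pch = 19,
                 xlab = "reads sampled", ylab = "median relative SE", ...)
  invisible(x)
}
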