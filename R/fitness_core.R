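#' Assign insertion sites to a gene and apply the edge filter
#'
#' Insertions within the first or last 10% of a coding region frequently fail
#' to knock the gene out (truncations near the C-terminus in particular often
#' leave partial function), so their read counts are not comparable with those
#' of central insertions. Sites whose relative position along the coding
#' strand falls outside [edge_fraction, 1 - edge_fraction) are therefore
#' excluded from the read set used for fitness. They still count toward the
#' observed insertion total O(X_g), which is compared against the expected
#' count computed on the full gene length.
#'
#' The relative position is (position - start) / L on the + strand and
#' (end - position) / L on the - strand, so "first 10%" always means the 10%
#' nearest the start codon.
#'
#' @param imap an \code{\link{insertion_map}}.
#' @param gene one-row annotation data.frame (gene_id, chrom, start, end,
#'   strand).
#' @param edge_fraction fraction excluded at each gene end (default 0.10).
#' @return An object of class \code{gene_profile}: gene_id, chrom,
#'   \code{rel_pos} and \code{reads} for retained sites, \code{o_full}
#'   (all observed insertions in the gene), \code{n_observed} (retained,
#'   central sites), \code{edge_excluded}, and imputation/trim bookkeeping
#'   fields filled in by later stages.
#' @export
assign_and_filter <- function(imap, gene, edge_fraction = 0.10) {
  stopifnot(nrow(gene) == 1L)
  s <- imap$sites
  hit <- s$chrom == gene$chrom & s$position >= gene$start &
    s$position <= gene$end
  pos <- s$position[hit]; reads <- s$reads[hit]
  L <- gene$end - gene$start + 1
  rel <- if (gene$strand == "-") (gene$end - pos) / L else
    (pos - gene$start) / L
  keep <- rel >= edge_fraction & rel < 1 - edge_fraction
  structure(list(gene_id = gene$gene_id, chrom = gene$chrom,
                 length = L, strand = gene$strand,
                 rel_pos = rel[keep], reads = reads[keep],
                 o_full = length(pos),
                 n_observed = sum(keep),
                 edge_excluded = sum(!keep),
                 expected = NA_integer_, n_zero_imputed = 0L,
                 n_after_trim = NA_integer_, n_trimmed = 0L),
            class = "gene_profile")
}

#' Impute unobserved insertion sites as zero-read records
#'
#' Appends \code{max(0, E - O)} zero-read sites to a gene's read set, where E
#' is the bias-corrected expected insertion count and O the number of
#' insertions observed anywhere in the gene (the same full-length denominator
#' E is computed on). Zero sites carry no genomic position. Observed reads
#' are unchanged, so the read total is conserved.
#'
#' @param profile a \code{gene_profile}.
#' @param expected integer E(X_g) for this gene.
#' @return the updated \code{gene_profile}.
#' @export
impute_zero_sites <- function(profile, expected) {
  nz <- unobserved_sites(expected, profile$o_full)
  profile$expected <- as.integer(expected)
  profile$n_zero_imputed <- nz
  if (nz > 0L) {
    profile$rel_pos <- c(profile$rel_pos, rep(NA_real_, nz))
    profile$reads <- c(profile$reads, rep(0L, nz))
  }
  profile
}

#' Remove upper-tail read-count outliers
#'
#' Reads exceeding 1.5 times the 5-95 percentile range above the 95th
#' percentile of the gene's read distribution (zero-imputed sites included)
#' are removed. Percentiles use linear interpolation between order statistics
#' (\code{quantile} type 7, the convention of the common numerical stats
#' routines), so the threshold is reproducible. The rule is upper-tail only:
#' zeros are structural records, never outliers. Applied once, after
#' imputation.
#'
#' @param profile a \code{gene_profile} (post-imputation).
#' @param multiplier range multiplier (default 1.5).
#' @param probs percentile pair (default \code{c(0.05, 0.95)}).
#' @return the updated \code{gene_profile} with \code{n_after_trim} set.
#' @export
trim_outliers <- function(profile, multiplier = 1.5, probs = c(0.05, 0.95)) {
  reads <- profile$reads
  if (length(reads) == 0L) {
    profile$n_after_trim <- 0L
    return(profile)
  }
  q <- stats::quantile(reads, probs = probs, names = FALSE, type = 7)
  thr <- q[2] + multiplier * (q[2] - q[1])
  drop <- reads > thr
  profile$n_trimmed <- sum(drop)
  profile$reads <- reads[!drop]
  profile$rel_pos <- profile$rel_pos[!drop]
  profile$n_after_trim <- length(profile$reads)
  profile
}

#' Mean read count of a gene profile
#'
#' The maximum-likelihood estimate of the per-mutant read level under the
#' Poisson read model is the sample mean of the retained read counts, zeros
#' included.
#'
#' @param profile a \code{gene_profile} after imputation and trimming.
#' @return the arithmetic mean, or NA for an empty profile.
#' @export
mean_reads <- function(profile) {
  if (length(profile$reads) == 0L) return(NA_real_)
  mean(profile$reads)
}

#' Median-scaled fitness
#'
#' Under Malthusian growth the read count of a mutant after t generations is
#' proportional to 2^(mu t), so log2 of the mean read count is proportional
#' to the growth rate mu (each mutant starting from a single cell). Scaling
#' by the median of log2 mean reads across genes -- most gene disruptions are
#' near neutral, so the median stands in for the ancestral strain -- yields a
#' time-free fitness w = log2(yhat) / median(log2(yhat)). A mean read count
#' below one gives a negative w: the mutant grows so poorly that it is
#' typically lost in the sampling bottlenecks.
#'
#' The value is invariant to the logarithm base, being a ratio of same-base
#' logs.
#'
#' @param yhat vector of per-gene mean read counts (usable genes only; all
#'   must be > 0).
#' @param mu_ref optional reference; defaults to \code{median(log2(yhat))}.
#' @return list with \code{w} (fitness vector) and \code{mu_ref}.
#' @export
fitness_median_scale <- function(yhat, mu_ref = NULL) {
  stopifnot(all(yhat > 0, na.rm = TRUE))
  lg <- log2(yhat)
  if (is.null(mu_ref)) mu_ref <- stats::median(lg, na.rm = TRUE)
  if (!is.finite(mu_ref) || mu_ref == 0)
    stop("median scaling is degenerate: median log2 mean read count is 0 ",
         "(median mean read count equals 1)")
  list(w = lg / mu_ref, mu_ref = mu_ref)
}

#' Generation-scaled fitness
#'
#' Converts mean read counts to the scale used by pooled competition assays:
#' w = (yhat / median(yhat))^(1/t_gen), with all mutants assumed equally
#' abundant at the start of the expansion and t_gen the number of generations
#' spent in library expansion (about 10 for a standard SATAY library). Equals
#' 1 at the population median and 0 for a zero mean.
#'
#' @param yhat vector of per-gene mean read counts (>= 0).
#' @param t_gen generations of library expansion (default 10).
#' @param reference optional reference level; defaults to
#'   \code{median(yhat)}.
#' @return fitness vector on the generation scale.
#' @export
fitness_generation_scale <- function(yhat, t_gen = 10, reference = NULL) {
  stopifnot(all(yhat >= 0, na.rm = TRUE), t_gen > 0)
  if (is.null(reference)) reference <- stats::median(yhat, na.rm = TRUE)
  if (!is.finite(reference) || reference <= 0)
    stop("generation scaling needs a positive reference mean read count")
  (yhat / reference)^(1 / t_gen)
}

#' Estimate per-gene disruption fitness from a transposon insertion library
#'
#' The full estimation pipeline: fit (or reuse) the pericentromeric
#' insertion-bias model, assign insertion sites to genes, exclude sites in
#' the outer 10% of each coding region, impute unobserved sites as zero-read
#' records from the bias-corrected expected insertion count, remove
#' upper-tail read outliers, average the remaining read counts per gene,
#' estimate the shared negative-binomial overdispersion from the genome-wide
#' mean-variance relationship, and report fitness on the median-log scale and
#' the per-generation scale with variance and standard error per gene.
#'
#' Genes with fewer than \code{min_sites} usable sites after trimming, or
#' whose remaining reads are all zero, get status \code{undetermined} and NA
#' estimates.
#'
#' @param insertions an \code{\link{insertion_map}}.
#' @param genes annotation data.frame (see \code{\link{read_gff3}}).
#' @param centromeres centromere data.frame (chrom, start, end).
#' @param config a \code{\link{satay_config}} list of pipeline constants.
#' @param bias optional pre-fitted \code{satay_bias} model; fitted from
#'   \code{insertions} when NULL.
#' @return An object of class \code{satay_fit} with elements \code{fitness}
#'   (per-gene data.frame), \code{bias}, \code{dispersion}, \code{profiles},
#'   \code{mu_ref}, \code{median_mean_reads} and \code{config}. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{fitted}, \code{plot}.
#' @examples
#' sim <- simulate_library(seed = 1)
#' fit <- satay_fitness(sim$insertions, sim$genome$genes,
#'                      sim$genome$centromeres)
#' summary(fit)
#' @export
satay_fitness <- function(insertions, genes, centromeres,
                          config = satay_config(), bias = NULL) {
  stopifnot(inherits(insertions, "insertion_map"), nrow(genes) > 0L)
  if (is.null(bias)) {
    curve <- cumulative_insertions(insertions, centromeres,
                                   grid_step = config$grid_step)
    bias <- fit_bias_model(curve, fit_range = config$fit_range,
                           r_cut = config$r_cut)
  }
  E <- expected_insertions(genes, centromeres, bias)
  profiles <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    p <- assign_and_filter(insertions, genes[g, , drop = FALSE],
                           edge_fraction = config$edge_fraction)
    if (config$impute) p <- impute_zero_sites(p, E[g]) else p$expected <- E[g]
    p <- trim_outliers(p, multiplier = config$outlier_multiplier,
                       probs = config$percentiles)
    profiles[[g]] <- p
  }
  yhat <- vapply(profiles, mean_reads, 0)
  s2 <- vapply(profiles, function(p)
    if (p$n_after_trim >= 2L) stats::var(p$reads) else NA_real_, 0)
  n_used <- vapply(profiles, function(p) p$n_after_trim, 0L)
  all_zero <- vapply(profiles, function(p)
    p$n_after_trim > 0L && all(p$reads == 0L), TRUE)
  status <- ifelse(n_used < config$min_sites | all_zero, "undetermined", "ok")
  ok <- status == "ok"
  if (!any(ok)) stop("no gene has enough usable insertion sites")

  dispersion <- if (!is.null(config$alpha))
    structure(list(alpha = config$alpha, alpha_raw = config$alpha,
                   n_genes = 0L, slope_se = NA_real_, fixed = TRUE),
              class = "satay_dispersion")
  else fit_alpha(data.frame(yhat = yhat, s2 = s2, n = n_used)[ok, ])

  V <- SE <- rep(NA_real_, length(yhat))
  V[ok] <- gene_variance(yhat[ok], s2[ok], dispersion)
  SE[ok] <- standard_error(V[ok], n_used[ok])

  med <- fitness_median_scale(yhat[ok])
  w_med <- rep(NA_real_, length(yhat)); w_med[ok] <- med$w
  median_yhat <- stats::median(yhat[ok])
  w_gen <- rep(NA_real_, length(yhat))
  w_gen[ok] <- fitness_generation_scale(yhat[ok], t_gen = config$t_gen,
                                        reference = median_yhat)

  fitness <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom,
    n_observed = vapply(profiles, function(p) p$n_observed, 0L),
    expected_insertions = E,
    n_zero_imputed = vapply(profiles, function(p) p$n_zero_imputed, 0L),
    n_used = n_used,
    mean_reads = ifelse(ok, yhat, NA_real_),
    fitness_median_scale = w_med,
    fitness_generation_scale = w_gen,
    variance = V, standard_error = SE,
    status = status, stringsAsFactors = FALSE)
  if ("essential" %in% names(genes)) fitness$essential <- genes$essential

  structure(list(fitness = fitness, bias = bias, dispersion = dispersion,
                 profiles = profiles, mu_ref = med$mu_ref,
                 median_mean_reads = median_yhat, config = config,
                 call = match.call()),
            class = "satay_fit")
}

#' @export
print.satay_fit <- function(x, ...) {
  f <- x$fitness
  cat("SATAY per-gene fitness fit\n")
  cat(sprintf("  genes: %d (%d ok, %d undetermined)\n", nrow(f),
              sum(f$status == "ok"), sum(f$status == "undetermined")))
  cat(sprintf("  overdispersion alpha = %.4g\n", x$dispersion$alpha))
  cat(sprintf("  bias model: lambda(0) = %.4g /bp, plateau = %.4g /bp\n",
              predict(x$bias, 0), x$bias$lambda_plateau))
  invisible(x)
}

#' @export
summary.satay_fit <- function(object, ...) {
  f <- object$fitness
  ok <- f$status == "ok"
  out <- list(n_genes = nrow(f), n_ok = sum(ok),
              n_undetermined = sum(!ok),
              alpha = object$dispersion$alpha,
              lambda0 = unname(predict(object$bias, 0)),
              lambda_plateau = object$bias$lambda_plateau,
              w_median = stats::quantile(f$fitness_median_scale[ok],
                                         c(0.05, 0.25, 0.5, 0.75, 0.95)),
              w_generation = stats::quantile(f$fitness_generation_scale[ok],
                                             c(0.05, 0.25, 0.5, 0.75, 0.95)),
              mean_se = mean(f$standard_error[ok]))
  class(out) <- "summary.satay_fit"
  out
}

#' @export
print.summary.satay_fit <- function(x, ...) {
  cat("SATAY fitness fit summary\n")
  cat(sprintf("  %d genes, %d with fitness estimates, %d undetermined\n",
              x$n_genes, x$n_ok, x$n_undetermined))
  cat(sprintf("  insertion rate: %.4g /bp near centromere, %.4g /bp distal\n",
              x$lambda0, x$lambda_plateau))
  cat(sprintf("  shared overdispersion alpha: %.4g\n", x$alpha))
  cat("  fitness (median scale), quantiles 5/25/50/75/95%:\n   ")
  cat(sprintf(" %.3f", x$w_median), "\n")
  cat("  fitness (generation scale), quantiles 5/25/50/75/95%:\n   ")
  cat(sprintf(" %.3f", x$w_generation), "\n")
  invisible(x)
}

#' @param object a \code{satay_fit}.
#' @param scale which fitness scale to return.
#' @rdname satay_fitness
#' @export
coef.satay_fit <- function(object,
                           scale = c("median", "generation"), ...) {
  scale <- match.arg(scale)
  f <- object$fitness
  w <- if (scale == "median") f$fitness_median_scale else
    f$fitness_generation_scale
  stats::setNames(w, f$gene_id)
}

#' @export
fitted.satay_fit <- function(object, ...) {
  stats::setNames(object$fitness$mean_reads, object$fitness$gene_id)
}

#' @export
plot.satay_fit <- function(x, scale = c("median", "generation"),
                           breaks = 50, ...) {
  scale <- match.arg(scale)
  w <- coef(x, scale = scale)
  w <- w[is.finite(w)]
  graphics::hist(w, breaks = breaks, main = "Distribution of fitness effects",
                 xlab = sprintf("fitness (%s scale)", scale), ...)
  graphics::abline(v = 1, lty = 2, col = "red3")
  invisible(x)
}

#' @export
as.data.frame.satay_fit <- function(x, ...) x$fitness
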