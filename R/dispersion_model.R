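#' Estimate the shared overdispersion from the mean-variance relationship
#'
#' Read counts across insertion sites within a gene are modelled as negative
#' binomial with Var = mu + alpha * mu^2; a single alpha is shared by all
#' genes of a dataset (all counts are conditional on the same sequencing
#' depth, so alpha and the per-gene means are separable). Rearranging the
#' mean-variance relation gives the regression form
#' (s2_g - yhat_g) / yhat_g = alpha * yhat_g, and alpha is the no-intercept
#' ordinary-least-squares slope of that response on yhat_g across genes.
#' As alpha shrinks to zero the model reduces to Poisson, so a negative OLS
#' estimate is clamped to zero with a warning.
#'
#' @param profiles either a data.frame with columns \code{yhat} (per-gene
#'   mean reads), \code{s2} (per-gene sample variance, n-1 denominator) and
#'   \code{n} (sites per gene), or a list of \code{gene_profile} objects from
#'   which those are computed. Genes need \code{n >= 2} and \code{yhat > 0}
#'   to contribute.
#' @return An object of class \code{satay_dispersion}: \code{alpha} (clamped),
#'   \code{alpha_raw}, \code{n_genes} used, and the slope standard error.
#' @export
fit_alpha <- function(profiles) {
  if (is.data.frame(profiles)) {
    d <- profiles
  } else {
    d <- data.frame(
      yhat = vapply(profiles, mean_reads, 0),
      s2 = vapply(profiles, function(p)
        if (length(p$reads) >= 2L) stats::var(p$reads) else NA_real_, 0),
      n = vapply(profiles, function(p) length(p$reads), 0L))
  }
  use <- !is.na(d$yhat) & !is.na(d$s2) & d$n >= 2L & d$yhat > 0
  d <- d[use, , drop = FALSE]
  if (nrow(d) < 10L)
    stop("need at least 10 usable genes to estimate the overdispersion (got ",
         nrow(d), ")")
  z <- (d$s2 - d$yhat) / d$yhat
  fit <- stats::lm(z ~ 0 + yhat, data = data.frame(z = z, yhat = d$yhat))
  alpha_raw <- unname(stats::coef(fit)[1])
  alpha <- alpha_raw
  if (alpha < 0) {
    warning(sprintf("overdispersion estimate %.4g is negative; clamped to 0 (Poisson limit)",
                    alpha_raw))
    alpha <- 0
  }
  structure(list(alpha = alpha, alpha_raw = alpha_raw,
                 n_genes = nrow(d),
                 slope_se = unname(sqrt(diag(stats::vcov(fit)))[1]),
                 fixed = FALSE),
            class = "satay_dispersion")
}

#' @export
print.satay_dispersion <- function(x, ...) {
  if (isTRUE(x$fixed))
    cat(sprintf("Overdispersion alpha = %.4g (fixed by configuration)\n",
                x$alpha))
  else
    cat(sprintf("Overdispersion alpha = %.4g (OLS over %d genes, se %.3g)\n",
                x$alpha, x$n_genes, x$slope_se))
  invisible(x)
}

#' Per-gene read-count variance
#'
#' The working variance of a gene is the larger of the trended
#' negative-binomial variance yhat + alpha * yhat^2 and the gene's own sample
#' variance, so that genes that are genuinely noisier than the genome-wide
#' trend are never assigned an optimistically small variance.
#'
#' @param yhat per-gene mean read counts.
#' @param s2 per-gene sample variances (NA treated as 0, i.e. no sample
#'   evidence above the trend).
#' @param fit a \code{satay_dispersion} object (or a single alpha value).
#' @return variance vector \code{pmax(yhat + alpha yhat^2, s2)}.
#' @export
gene_variance <- function(yhat, s2, fit) {
  alpha <- if (inherits(fit, "satay_dispersion")) fit$alpha else fit
  s2[is.na(s2)] <- 0
  pmax(yhat + alpha * yhat^2, s2)
}

#' Standard error of a gene's mean read count
#'
#' @param V per-gene variance (see \code{\link{gene_variance}}).
#' @param n number of insertion sites used for the gene's mean.
#' @return \code{sqrt(V / n)}.
#' @export
standard_error <- function(V, n) {
  stopifnot(all(n >= 1))
  sqrt(V / n)
}
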