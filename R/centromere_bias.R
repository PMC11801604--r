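#' Cumulative insertion counts around centromeres
#'
#' The MiniDS transposon excises from a plasmid-borne locus and preferentially
#' reinserts near its excision site, which produces an elevated insertion
#' density within roughly 200 kb of each centromere. This function computes,
#' for every chromosome arm, the number of insertions that map within a
#' distance r of the centromere, on a regular grid of r, together with the
#' arm-averaged curve that the bias model is fitted to.
#'
#' A site on the right arm has distance \code{position - cen_end}; on the left
#' arm \code{cen_start - position}. Sites inside the centromere interval get
#' distance 0 (assigned to the left arm; they are rare and the convention only
#' needs to be fixed). The average at distance r is taken over the arms whose
#' length is at least r, so short arms do not truncate the tail of the curve.
#'
#' @param imap an \code{\link{insertion_map}}.
#' @param cen centromere data.frame (chrom, start, end); every chromosome in
#'   \code{imap} must be present.
#' @param grid_step grid spacing in bp (default 1000).
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   absent the right-arm length defaults to the largest observed position.
#' @return An object of class \code{satay_cumcurve}: list with \code{grid}
#'   (distances in bp), \code{arm_counts} (arms x grid matrix, NA beyond an
#'   arm's length), \code{average}, \code{arms} (data.frame chrom, side,
#'   length) and \code{grid_step}.
#' @export
cumulative_insertions <- function(imap, cen, grid_step = 1000,
                                  chrom_lengths = NULL) {
  s <- imap$sites
  chroms <- unique(s$chrom)
  missing <- setdiff(chroms, cen$chrom)
  if (length(missing))
    stop("no centromere entry for chromosome(s): ",
         paste(missing, collapse = ", "))
  arms <- list(); dists <- list()
  for (ch in chroms) {
    ci <- cen[cen$chrom == ch, ]
    sub <- s[s$chrom == ch, ]
    len_l <- ci$start - 1
    len_r <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] - ci$end else max(c(sub$position, ci$end)) - ci$end
    left <- sub$position <= ci$end     # includes distance-0 sites
    d_l <- pmax(0, ci$start - sub$position[left])
    d_r <- sub$position[!left] - ci$end
    arms[[paste0(ch, ":L")]] <- len_l
    arms[[paste0(ch, ":R")]] <- len_r
    dists[[paste0(ch, ":L")]] <- d_l
    dists[[paste0(ch, ":R")]] <- d_r
  }
  arm_len <- unlist(arms)
  grid <- seq(0, max(arm_len), by = grid_step)
  counts <- matrix(NA_real_, nrow = length(arm_len), ncol = length(grid),
                   dimnames = list(names(arm_len), NULL))
  for (k in seq_along(arm_len)) {
    d <- sort(dists[[names(arm_len)[k]]])
    defined <- grid <= arm_len[k]
    counts[k, defined] <- findInterval(grid[defined], d)
  }
  avg <- colMeans(counts, na.rm = TRUE)
  avg[colSums(!is.na(counts)) == 0L] <- NA_real_
  structure(list(grid = grid, arm_counts = counts, average = avg,
                 arms = data.frame(arm = names(arm_len),
                                   length = unname(arm_len),
                                   stringsAsFactors = FALSE),
                 grid_step = grid_step),
            class = "satay_cumcurve")
}

#' @export
print.satay_cumcurve <- function(x, ...) {
  cat(sprintf("Cumulative insertion curve: %d arms, grid 0-%g bp (step %g)\n",
              nrow(x$arm_counts), max(x$grid), x$grid_step))
  invisible(x)
}

#' Fit the pericentromeric insertion-bias model
#'
#' Fits a cubic polynomial by least squares to the arm-averaged cumulative
#' insertion curve over distances up to \code{fit_range} (400 kb). The local
#' insertion rate lambda(r) is the derivative of that cubic for r below
#' \code{r_cut} (200 kb); beyond \code{r_cut} the rate is held constant at
#' lambda(r_cut), reflecting that the bias is local to the centromere and a
#' cubic extrapolated further starts to oscillate. The fitted rate must be
#' non-negative over [0, r_cut]; if it is not, the curve needs inspection and
#' an error is raised rather than a silent clamp.
#'
#' Internally the fit runs on a scaled abscissa (r divided by the fit range)
#' for numerical stability and the coefficients are rescaled to bp units, so
#' \code{coef()} returns the coefficients a0..a3 of the cumulative-count
#' polynomial in counts and bp.
#'
#' @param curve a \code{satay_cumcurve} from \code{\link{cumulative_insertions}}.
#' @param fit_range fit window in bp (default 4e5).
#' @param r_cut distance beyond which the rate is constant (default 2e5).
#' @return An object of class \code{satay_bias}: coefficients a0..a3,
#'   \code{lambda_plateau}, \code{r_cut}, \code{fit_range}, residual sum of
#'   squares and the number of grid points used.
#' @export
fit_bias_model <- function(curve, fit_range = 4e5, r_cut = 2e5) {
  stopifnot(inherits(curve, "satay_cumcurve"))
  ok <- curve$grid <= fit_range & !is.na(curve$average)
  r <- curve$grid[ok]; y <- curve$average[ok]
  if (length(r) < 8L)
    stop("too few grid points (", length(r), ") to fit a cubic bias model")
  if (max(r) < fit_range)
    warning(sprintf("cumulative curve only extends to %g bp; fitting on the available range",
                    max(r)))
  s <- r / fit_range
  fit <- stats::lm(y ~ s + I(s^2) + I(s^3))
  b <- unname(stats::coef(fit))
  a <- b / fit_range^(0:3)
  names(a) <- paste0("a", 0:3)
  lambda_raw <- function(rr) a[[2]] + 2 * a[[3]] * rr + 3 * a[[4]] * rr^2
  # minimum of the quadratic rate over [0, r_cut]
  cand <- c(0, r_cut)
  if (a[[4]] != 0) {
    vertex <- -a[[3]] / (3 * a[[4]])
    if (vertex > 0 && vertex < r_cut) cand <- c(cand, vertex)
  }
  lam_min <- min(lambda_raw(cand))
  tol <- sqrt(.Machine$double.eps) * max(abs(lambda_raw(cand)), 1e-12)
  if (lam_min < -tol)
    stop(sprintf(paste("fitted insertion rate is negative (min %.3g /bp) within the",
                       "fit window; inspect the cumulative curve"), lam_min))
  structure(list(coefficients = a,
                 r_cut = r_cut, fit_range = fit_range,
                 lambda_plateau = unname(lambda_raw(r_cut)),
                 rss = sum(stats::residuals(fit)^2),
                 n_points = length(r),
                 grid_step = curve$grid_step),
            class = "satay_bias")
}

#' Evaluate the bias-corrected insertion rate
#'
#' @param object a \code{satay_bias} model.
#' @param r distances from the centromere in bp.
#' @param ... unused.
#' @return lambda(r) in insertions per bp: the derivative of the fitted cubic
#'   below \code{r_cut}, constant at \code{lambda_plateau} beyond.
#' @export
predict.satay_bias <- function(object, r, ...) {
  a <- object$coefficients
  lam <- a[[2]] + 2 * a[[3]] * r + 3 * a[[4]] * r^2
  lam[r >= object$r_cut] <- object$lambda_plateau
  pmax(lam, 0)
}

#' @export
coef.satay_bias <- function(object, ...) object$coefficients

#' @export
print.satay_bias <- function(x, ...) {
  cat("Pericentromeric insertion-bias model (cubic cumulative fit)\n")
  cat(sprintf("  lambda(0)       = %.4g /bp\n", predict(x, 0)))
  cat(sprintf("  lambda(plateau) = %.4g /bp beyond %g kb\n",
              x$lambda_plateau, x$r_cut / 1e3))
  cat(sprintf("  fit: %d grid points over 0-%g kb, RSS %.4g\n",
              x$n_points, x$fit_range / 1e3, x$rss))
  invisible(x)
}

#' @export
plot.satay_bias <- function(x, curve = NULL, ...) {
  r <- seq(0, x$fit_range, length.out = 401)
  graphics::plot(r / 1e3, predict(x, r), type = "l", lwd = 2,
                 xlab = "distance from centromere (kb)",
                 ylab = expression(lambda ~ (bp^-1)), ...)
  graphics::abline(v = x$r_cut / 1e3, lty = 3)
  if (!is.null(curve)) {
    ok <- !is.na(curve$average) & curve$grid <= x$fit_range
    emp <- diff(curve$average[ok]) / diff(curve$grid[ok])
    graphics::lines(curve$grid[ok][-1] / 1e3, emp, col = "grey60")
  }
  invisible(x)
}

#' Expected number of insertions per gene
#'
#' The expected insertion count of a gene is the bias-corrected rate at the
#' gene's center multiplied by the full gene length, rounded down to the
#' nearest integer (insertion counts are discrete). The gene center is
#' \code{floor((start + end) / 2)} and its centromere distance is measured to
#' the nearer edge of the centromere interval.
#'
#' @param genes annotation data.frame (gene_id, chrom, start, end).
#' @param cen centromere data.frame.
#' @param model a \code{satay_bias} model.
#' @return integer vector of expected insertion counts, one per gene.
#' @export
expected_insertions <- function(genes, cen, model) {
  idx <- match(genes$chrom, cen$chrom)
  if (anyNA(idx))
    stop("no centromere entry for chromosome(s): ",
         paste(unique(genes$chrom[is.na(idx)]), collapse = ", "))
  center <- floor((genes$start + genes$end) / 2)
  d <- pmax(0, pmax(cen$start[idx] - center, center - cen$end[idx]))
  L <- genes$end - genes$start + 1
  as.integer(floor(pmax(0, predict(model, d)) * L))
}

#' Number of unobserved (zero-read) insertion sites
#'
#' When the expected insertion count of a gene exceeds the observed count,
#' the difference is taken to be the number of insertion mutants that were
#' lost before sequencing; these enter the fitness estimate as sites with
#' zero reads. When observed insertions exceed the expectation, no unobserved
#' sites are assumed to exist.
#'
#' @param expected integer vector E(X_g) (already floored).
#' @param observed integer vector O(X_g) of observed insertion counts.
#' @return \code{pmax(0, expected - observed)}.
#' @export
unobserved_sites <- function(expected, observed) {
  stopifnot(all(expected >= 0), all(observed >= 0))
  pmax(0L, as.integer(expected) - as.integer(observed))
}
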