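#' Pipeline configuration
#'
#' Collects every tunable constant of the fitness pipeline with the defaults
#' of the published procedure; the zero-argument call is the reference
#' configuration.
#'
#' @param edge_fraction fraction of each coding region excluded at both gene
#'   ends (default 0.10: the central 80% is used).
#' @param outlier_multiplier multiplier of the 5-95 percentile range for the
#'   upper-tail outlier threshold (default 1.5).
#' @param percentiles percentile pair for the outlier rule (default
#'   \code{c(0.05, 0.95)}).
#' @param min_sites minimum usable sites after trimming for a determined
#'   fitness value (default 5).
#' @param min_expected minimum expected insertion count for cross-dataset
#'   comparisons (default 5).
#' @param r_cut distance beyond which the insertion rate is constant
#'   (default 2e5 bp).
#' @param fit_range fit window of the cumulative-curve cubic (default 4e5 bp).
#' @param grid_step grid spacing of the cumulative curve (default 1000 bp).
#' @param t_gen generations of library expansion for the generation-scaled
#'   fitness (default 10).
#' @param match_window replicate matching window (default 2 bp).
#' @param impute include unobserved sites as zero-read records
#'   (default TRUE).
#' @param alpha optional fixed overdispersion; estimated from the data when
#'   NULL.
#' @param rename optional chromosome rename map applied by the readers.
#' @param seed optional integer seed recorded for subsampling steps.
#' @return a list of class \code{satay_config}.
#' @export
satay_config <- function(edge_fraction = 0.10, outlier_multiplier = 1.5,
                         percentiles = c(0.05, 0.95), min_sites = 5,
                         min_expected = 5, r_cut = 2e5, fit_range = 4e5,
                         grid_step = 1000, t_gen = 10, match_window = 2,
                         impute = TRUE, alpha = NULL, rename = NULL,
                         seed = NULL) {
  stopifnot(edge_fraction >= 0, edge_fraction < 0.5,
            outlier_multiplier >= 0, length(percentiles) == 2,
            percentiles[1] < percentiles[2], min_sites >= 1,
            r_cut > 0, fit_range >= r_cut, grid_step > 0, t_gen > 0)
  structure(list(edge_fraction = edge_fraction,
                 outlier_multiplier = outlier_multiplier,
                 percentiles = percentiles, min_sites = min_sites,
                 min_expected = min_expected, r_cut = r_cut,
                 fit_range = fit_range, grid_step = grid_step,
                 t_gen = t_gen, match_window = match_window,
                 impute = impute, alpha = alpha, rename = rename,
                 seed = seed),
            class = "satay_config")
}

#' @export
print.satay_config <- function(x, ...) {
  cat("satayfit configuration:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-19s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

config_as_header <- function(config) {
  vals <- vapply(config, function(v)
    if (is.null(v)) "NULL" else paste(format(v), collapse = ","), "")
  sprintf("# config %s=%s", names(vals), vals)
}
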