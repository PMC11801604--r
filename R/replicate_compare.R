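#' Match insertion sites between two datasets
#'
#' Two replicate libraries rarely carry insertions at exactly the same
#' coordinate (independent transposition, plus limited mapping accuracy), so
#' sites within a small window of each other are treated as the same
#' insertion. Matching is one-to-one and greedy: candidate pairs within
#' \code{window} bp are accepted in order of increasing distance (ties broken
#' toward the lower coordinate), so the result is deterministic and symmetric
#' in A and B. An unmatched site counts toward the presence difference
#' delta-P only if its read count is at least 2 -- a single stray read is not
#' taken as evidence that a mutant existed in one library and not the other.
#'
#' Read-count differences at matched sites (delta-R) are reported both raw
#' and after depth normalization (reads per million mapped), since two
#' libraries generally differ in total depth.
#'
#' @param a,b \code{\link{insertion_map}} objects with the same chromosome
#'   naming.
#' @param window maximum coordinate difference for a match, bp (default 2).
#' @return An object of class \code{satay_match}: \code{pairs} (data.frame
#'   chrom, pos_a, reads_a, pos_b, reads_b, delta_r_raw, delta_r_cpm),
#'   \code{unmatched_a}, \code{unmatched_b}, \code{delta_p} (count of
#'   differentially present sites), \code{n_matched}, \code{mean_delta_r_raw},
#'   \code{mean_delta_r_cpm}.
#' @export
match_insertions <- function(a, b, window = 2) {
  sa <- a$sites; sb <- b$sites
  norm_a <- 1e6 / max(a$total_reads, 1)
  norm_b <- 1e6 / max(b$total_reads, 1)
  pairs <- list(); un_a <- list(); un_b <- list()
  for (ch in union(unique(sa$chrom), unique(sb$chrom))) {
    pa <- sa[sa$chrom == ch, ]; pb <- sb[sb$chrom == ch, ]
    na <- nrow(pa); nb <- nrow(pb)
    used_a <- logical(na); used_b <- logical(nb)
    ia <- ib <- integer(0)
    if (na > 0L && nb > 0L) {
      # candidate pairs: for each a-site the b-sites within the window
      lo <- findInterval(pa$position - window - 0.5, pb$position) + 1L
      hi <- findInterval(pa$position + window + 0.5, pb$position)
      reps <- pmax(0L, hi - lo + 1L)
      ia <- rep.int(seq_len(na), reps)
      ib <- unlist(lapply(seq_len(na), function(i)
        if (reps[i] > 0L) seq.int(lo[i], hi[i]) else integer(0)))
      if (length(ia)) {
        dist <- abs(pa$position[ia] - pb$position[ib])
        o <- order(dist, pmin(pa$position[ia], pb$position[ib]),
                   pmax(pa$position[ia], pb$position[ib]))
        ia <- ia[o]; ib <- ib[o]
        keep <- logical(length(ia))
        for (k in seq_along(ia)) {
          if (!used_a[ia[k]] && !used_b[ib[k]]) {
            keep[k] <- TRUE; used_a[ia[k]] <- TRUE; used_b[ib[k]] <- TRUE
          }
        }
        ia <- ia[keep]; ib <- ib[keep]
      }
    }
    pairs[[ch]] <- data.frame(chrom = rep(ch, length(ia)),
                              pos_a = pa$position[ia], reads_a = pa$reads[ia],
                              pos_b = pb$position[ib], reads_b = pb$reads[ib],
                              stringsAsFactors = FALSE)
    if (na > 0L) un_a[[ch]] <- pa[!used_a, , drop = FALSE]
    if (nb > 0L) un_b[[ch]] <- pb[!used_b, , drop = FALSE]
  }
  pairs <- do.call(rbind, c(pairs, list(make.row.names = FALSE)))
  un_a <- if (length(un_a)) do.call(rbind, c(un_a, list(make.row.names = FALSE)))
    else sa[0, ]
  un_b <- if (length(un_b)) do.call(rbind, c(un_b, list(make.row.names = FALSE)))
    else sb[0, ]
  if (is.null(pairs)) pairs <- data.frame(chrom = character(0))
  if (nrow(pairs)) {
    pairs$delta_r_raw <- abs(pairs$reads_a - pairs$reads_b)
    pairs$delta_r_cpm <- abs(pairs$reads_a * norm_a - pairs$reads_b * norm_b)
  } else {
    pairs$delta_r_raw <- numeric(0); pairs$delta_r_cpm <- numeric(0)
  }
  delta_p <- sum(un_a$reads >= 2) + sum(un_b$reads >= 2)
  structure(list(pairs = pairs, unmatched_a = un_a, unmatched_b = un_b,
                 window = window, delta_p = delta_p,
                 n_matched = nrow(pairs),
                 mean_delta_r_raw = if (nrow(pairs)) mean(pairs$delta_r_raw)
                   else NA_real_,
                 mean_delta_r_cpm = if (nrow(pairs)) mean(pairs$delta_r_cpm)
                   else NA_real_),
            class = "satay_match")
}

#' @export
print.satay_match <- function(x, ...) {
  cat(sprintf("Insertion match (window %d bp): %d matched pairs\n",
              x$window, x$n_matched))
  cat(sprintf("  delta-P (differentially present, reads >= 2): %d\n",
              x$delta_p))
  cat(sprintf("  mean |delta-R|: %.3f raw, %.3f per million mapped\n",
              x$mean_delta_r_raw, x$mean_delta_r_cpm))
  invisible(x)
}

#' Compare per-gene fitness between two datasets
#'
#' Pairs the fitness estimates of two fits (or fitness tables) by gene,
#' keeping genes with a determined estimate in both and an expected insertion
#' count of at least \code{min_expected} in both (genes expected to carry
#' fewer than five insertions hold too little information for a reliable
#' estimate). Reports Pearson and Spearman correlations and the per-gene
#' deviation from the identity line, the quantity screened for
#' genetic-interaction-style analyses.
#'
#' @param fa,fb \code{satay_fit} objects or fitness data.frames.
#' @param scale fitness scale to compare.
#' @param min_expected minimum expected insertion count in both datasets
#'   (default 5).
#' @return list with \code{table} (gene_id, w_a, w_b, deviation),
#'   \code{pearson}, \code{spearman}, \code{mean_deviation}, \code{n_genes}.
#' @export
compare_fitness_tables <- function(fa, fb, scale = c("median", "generation"),
                                   min_expected = 5) {
  scale <- match.arg(scale)
  col <- paste0("fitness_", scale, "_scale")
  ta <- if (inherits(fa, "satay_fit")) fa$fitness else fa
  tb <- if (inherits(fb, "satay_fit")) fb$fitness else fb
  m <- merge(ta[c("gene_id", "status", "expected_insertions", col)],
             tb[c("gene_id", "status", "expected_insertions", col)],
             by = "gene_id", suffixes = c("_a", "_b"))
  m <- m[m$status_a == "ok" & m$status_b == "ok" &
           m$expected_insertions_a >= min_expected &
           m$expected_insertions_b >= min_expected, ]
  if (nrow(m) < 3L)
    stop("fewer than 3 genes usable in both datasets")
  w_a <- m[[paste0(col, "_a")]]; w_b <- m[[paste0(col, "_b")]]
  list(table = data.frame(gene_id = m$gene_id, w_a = w_a, w_b = w_b,
                          deviation = w_b - w_a),
       pearson = stats::cor(w_a, w_b, method = "pearson"),
       spearman = stats::cor(w_a, w_b, method = "spearman"),
       mean_deviation = mean(w_b - w_a),
       n_genes = nrow(m))
}
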