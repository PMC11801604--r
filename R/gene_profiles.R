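#' Positional read-count profile along coding regions
#'
#' Splits every coding region into 20 equally sized segments (5% of the gene
#' each) and reports, per segment, the number of insertions, the total reads
#' and the mean read count per insertion, pooled over a gene class. Essential
#' genes show a characteristic U shape -- higher read counts in the outermost
#' segments, where insertions truncate little of the protein -- which is the
#' diagnostic motivating the edge filter of the fitness pipeline. For that
#' reason the profile deliberately includes the edge sites that the fitness
#' pipeline removes.
#'
#' @param imap an \code{\link{insertion_map}}.
#' @param genes annotation data.frame; needs an \code{essential} column when
#'   filtering by class.
#' @param class_filter which genes to pool: all, essential or nonessential.
#' @param bins number of segments (default 20).
#' @param per_gene_mean if TRUE, a segment's value is the unweighted average
#'   of per-gene segment means instead of the insertion-pooled mean.
#' @return data.frame with one row per segment: \code{bin}, \code{rel_start},
#'   \code{rel_end}, \code{insertions}, \code{reads}, \code{mean_reads}
#'   (NA for segments without insertions).
#' @export
bin_profile <- function(imap, genes,
                        class_filter = c("all", "essential", "nonessential"),
                        bins = 20, per_gene_mean = FALSE) {
  class_filter <- match.arg(class_filter)
  if (class_filter != "all") {
    if (!"essential" %in% names(genes))
      stop("annotation has no 'essential' column")
    genes <- genes[if (class_filter == "essential") genes$essential
                   else !genes$essential, , drop = FALSE]
  }
  s <- imap$sites
  ins <- rds <- numeric(bins)
  pg <- matrix(NA_real_, nrow = nrow(genes), ncol = bins)
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    hit <- s$chrom == gene$chrom & s$position >= gene$start &
      s$position <= gene$end
    if (!any(hit)) next
    pos <- s$position[hit]; reads <- s$reads[hit]
    L <- gene$end - gene$start + 1
    rel <- if (gene$strand == "-") (gene$end - pos) / L else
      (pos - gene$start) / L
    b <- pmin(floor(rel * bins), bins - 1L) + 1L
    ins <- ins + tabulate(b, bins)
    rds <- rds + as.numeric(tapply_sum(reads, b, bins))
    if (per_gene_mean) {
      gi <- tabulate(b, bins); gr <- tapply_sum(reads, b, bins)
      pg[g, gi > 0] <- gr[gi > 0] / gi[gi > 0]
    }
  }
  mean_reads <- if (per_gene_mean) colMeans(pg, na.rm = TRUE) else
    ifelse(ins > 0, rds / ins, NA_real_)
  mean_reads[ins == 0] <- NA_real_
  data.frame(bin = seq_len(bins),
             rel_start = (seq_len(bins) - 1) / bins,
             rel_end = seq_len(bins) / bins,
             insertions = as.integer(ins), reads = as.integer(rds),
             mean_reads = mean_reads)
}

tapply_sum <- function(x, group, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(as.numeric(x), group)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Largest insertion-free span per gene
#'
#' For each gene, the longest stretch of the coding region that carries no
#' observed insertion, expressed as a fraction of gene length. Gaps are
#' measured from the gene start to the first insertion, between consecutive
#' insertions, and from the last insertion to the gene end; a gene without
#' any insertion has span 1. Essential genes show a tail toward long spans
#' (their central region tolerates no insertions), which is the basis of
#' span-based essentiality classification elsewhere; here it is reported as
#' a diagnostic only.
#'
#' @param imap an \code{\link{insertion_map}}.
#' @param genes annotation data.frame (one or more genes).
#' @return data.frame with columns \code{gene_id}, \code{n_insertions},
#'   \code{span_fraction}.
#' @export
insertion_free_span <- function(imap, genes) {
  s <- imap$sites
  out <- data.frame(gene_id = genes$gene_id,
                    n_insertions = 0L,
                    span_fraction = 1.0)
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    pos <- s$position[s$chrom == gene$chrom & s$position >= gene$start &
                        s$position <= gene$end]
    out$n_insertions[g] <- length(pos)
    if (length(pos) == 0L) next
    L <- gene$end - gene$start + 1
    pos <- sort(pos)
    gaps <- c(pos[1] - gene$start, diff(pos), gene$end - pos[length(pos)])
    out$span_fraction[g] <- max(gaps) / L
  }
  out
}
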