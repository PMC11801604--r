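#' Construct an insertion map
#'
#' An insertion map is the primary experimental input: one record per unique
#' transposon insertion site, with the number of sequencing reads supporting
#' that site. Coordinates are 1-based base pairs. Positions must be unique
#' within a chromosome and every read count must be a positive integer --
#' zero-read sites never occur in input data; they exist only as imputed
#' records created downstream by the fitness pipeline.
#'
#' @param chrom character vector of chromosome names.
#' @param position integer vector of 1-based insertion coordinates.
#' @param reads integer vector of read counts (all >= 1).
#' @param sample optional sample name stored in the metadata.
#' @return An object of class \code{insertion_map}: a list with elements
#'   \code{sites} (data.frame with columns chrom, position, reads, sorted by
#'   chromosome then position), \code{sample}, \code{total_reads} and
#'   \code{n_sites}.
#' @export
insertion_map <- function(chrom = character(), position = integer(),
                          reads = integer(), sample = NA_character_) {
  if (length(chrom) != length(position) || length(chrom) != length(reads))
    stop("chrom, position and reads must have equal length")
  sites <- data.frame(chrom = as.character(chrom),
                      position = as.integer(position),
                      reads = as.integer(reads),
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  obj <- structure(list(sites = sites,
                        sample = sample,
                        total_reads = sum(as.numeric(sites$reads)),
                        n_sites = nrow(sites)),
                   class = "insertion_map")
  validate_insertion_map(obj)
  obj
}

validate_insertion_map <- function(x) {
  s <- x$sites
  if (nrow(s) == 0L) return(invisible(x))
  if (anyNA(s$position) || anyNA(s$reads))
    stop("insertion map contains missing positions or read counts")
  if (any(s$reads < 1L))
    stop("all read counts must be >= 1 (zero-read sites arise only by imputation)")
  dup <- duplicated(s[c("chrom", "position")])
  if (any(dup)) {
    d <- s[dup, , drop = FALSE][1L, ]
    stop(sprintf("duplicate insertion position %d on chromosome %s",
                 d$position, d$chrom))
  }
  invisible(x)
}

#' @export
print.insertion_map <- function(x, ...) {
  cat(sprintf("Insertion map%s: %d sites on %d chromosome(s), %s reads\n",
              if (is.na(x$sample)) "" else paste0(" [", x$sample, "]"),
              x$n_sites, length(unique(x$sites$chrom)),
              format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Read an insertion map from disk
#'
#' Two plain-text dialects are supported. \code{wig} is the variableStep
#' wiggle format produced by transposon-mapping pipelines:
#' \preformatted{variableStep chrom=chrI
#' 100 3
#' 250 1}
#' \code{bedlike} is a 3-column TSV with a header line
#' (\code{chrom<TAB>position<TAB>reads}). Both are 1-based. Duplicate
#' positions within a chromosome are an error, never silently merged, and a
#' read count below 1 is a validation error. Unknown chromosome names are
#' retained; filtering against an annotation happens later.
#'
#' @param path file to read.
#' @param dialect \code{"wig"} or \code{"bedlike"}.
#' @param sample sample name to record; defaults to the file name.
#' @param rename optional named character vector mapping chromosome names in
#'   the file to the names used by the annotation (e.g. \code{c(I = "chrI")}).
#' @return An \code{\link{insertion_map}}.
#' @export
read_insertion_map <- function(path, dialect = c("wig", "bedlike"),
                               sample = NULL, rename = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample)) sample <- basename(path)
  lines <- readLines(path)
  chrom <- character(0); pos <- integer(0); rds <- integer(0)
  if (dialect == "wig") {
    ln <- trimws(lines)
    skip <- ln == "" | startsWith(ln, "#") | startsWith(ln, "track")
    decl <- startsWith(ln, "variableStep")
    use <- which(!skip)
    if (length(use)) {
      is_decl <- decl[use]
      cur <- rep(NA_character_, length(use))
      m <- regmatches(ln[use][is_decl],
                      regexec("chrom=([^[:space:]]+)", ln[use][is_decl]))
      bad <- vapply(m, length, 1L) < 2L
      if (any(bad))
        stop(sprintf("line %d: variableStep declaration without chrom=",
                     use[is_decl][bad][1L]))
      cur[is_decl] <- vapply(m, `[`, "", 2L)
      # carry the current chromosome forward over data lines
      grp <- cumsum(is_decl)
      data_i <- use[!is_decl]
      if (length(data_i)) {
        if (grp[!is_decl][1L] == 0L)
          stop(sprintf("line %d: data line before any variableStep declaration",
                       data_i[1L]))
        chrom <- cur[is_decl][grp[!is_decl]]
        flds <- strsplit(ln[data_i], "[[:space:]]+")
        nf <- lengths(flds)
        if (any(nf != 2L))
          stop(sprintf("line %d: malformed wig data line '%s'",
                       data_i[nf != 2L][1L], lines[data_i[nf != 2L][1L]]))
        fm <- matrix(unlist(flds), ncol = 2L, byrow = TRUE)
        pos <- suppressWarnings(as.numeric(fm[, 1L]))
        rds <- suppressWarnings(as.numeric(fm[, 2L]))
        bad <- is.na(pos) | is.na(rds) | pos != round(pos) | rds != round(rds)
        if (any(bad))
          stop(sprintf("line %d: malformed wig data line '%s'",
                       data_i[bad][1L], lines[data_i[bad][1L]]))
        if (any(rds < 1))
          stop(sprintf("line %d: read count %g is < 1",
                       data_i[rds < 1][1L], rds[rds < 1][1L]))
      }
    }
  } else {
    if (length(lines) > 0L) {
      body_i <- which(nzchar(trimws(lines)))[-1L]
      body_i <- body_i[!is.na(body_i)]
      if (length(body_i)) {
        flds <- strsplit(lines[body_i], "\t")
        nf <- lengths(flds)
        if (any(nf < 3L))
          stop(sprintf("line %d: expected 3 tab-separated fields",
                       body_i[nf < 3L][1L]))
        chrom <- vapply(flds, `[`, "", 1L)
        pos <- suppressWarnings(as.numeric(vapply(flds, `[`, "", 2L)))
        rds <- suppressWarnings(as.numeric(vapply(flds, `[`, "", 3L)))
        bad <- is.na(pos) | is.na(rds) | pos != round(pos) | rds != round(rds)
        if (any(bad))
          stop(sprintf("line %d: malformed record '%s'",
                       body_i[bad][1L], lines[body_i[bad][1L]]))
        if (any(rds < 1))
          stop(sprintf("line %d: read count %g is < 1",
                       body_i[rds < 1][1L], rds[rds < 1][1L]))
      }
    }
  }
  chrom <- rename_chroms(chrom, rename)
  insertion_map(chrom, pos, rds, sample = sample)
}

rename_chroms <- function(chrom, rename) {
  if (is.null(rename)) return(chrom)
  hit <- chrom %in% names(rename)
  chrom[hit] <- unname(rename[chrom[hit]])
  chrom
}

#' Write an insertion map
#'
#' @param imap an \code{\link{insertion_map}}.
#' @param path output file.
#' @param dialect \code{"wig"} or \code{"bedlike"} (see
#'   \code{\link{read_insertion_map}}).
#' @return \code{path}, invisibly.
#' @export
write_insertion_map <- function(imap, path, dialect = c("wig", "bedlike")) {
  dialect <- match.arg(dialect)
  s <- imap$sites
  con <- file(path, "w"); on.exit(close(con))
  if (dialect == "wig") {
    for (ch in unique(s$chrom)) {
      writeLines(sprintf("variableStep chrom=%s", ch), con)
      sub <- s[s$chrom == ch, , drop = FALSE]
      writeLines(sprintf("%d %d", sub$position, sub$reads), con)
    }
  } else {
    writeLines("chrom\tposition\treads", con)
    if (nrow(s) > 0L)
      writeLines(sprintf("%s\t%d\t%d", s$chrom, s$position, s$reads), con)
  }
  invisible(path)
}

#' Read gene annotations from a GFF3 file
#'
#' Only records of type \code{gene} are loaded. Coordinates are kept 1-based
#' and inclusive, as in GFF3. The gene identifier is taken from the \code{ID}
#' attribute; a missing ID or a duplicated ID is an error.
#'
#' @param path GFF3 file.
#' @param essential optional character vector of gene IDs to flag as
#'   essential (see \code{\link{read_essential_genes}}).
#' @param rename optional chromosome rename map, as in
#'   \code{\link{read_insertion_map}}.
#' @return A data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{essential}.
#' @export
read_gff3 <- function(path, essential = NULL, rename = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  idx <- which(keep)
  out <- list()
  for (i in idx) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 9L) next
    if (f[3] != "gene") next
    attrs <- strsplit(f[9], ";")[[1]]
    id <- sub("^ID=", "", attrs[startsWith(attrs, "ID=")])
    if (length(id) != 1L || !nzchar(id))
      stop(sprintf("line %d: gene record without an ID attribute", i))
    out[[length(out) + 1L]] <- data.frame(
      gene_id = id, chrom = f[1],
      start = as.integer(f[4]), end = as.integer(f[5]),
      strand = f[7], stringsAsFactors = FALSE)
  }
  genes <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ID(s): ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (nrow(genes) && any(genes$end < genes$start))
    stop("gene with end < start in ", path)
  genes$chrom <- rename_chroms(genes$chrom, rename)
  genes$essential <- if (is.null(essential)) logical(nrow(genes)) else
    genes$gene_id %in% essential
  rownames(genes) <- NULL
  genes
}

#' Write gene annotations as GFF3
#' @param genes annotation data.frame as returned by \code{\link{read_gff3}}.
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "satayfit") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0L)
    writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom, source, genes$start, genes$end,
                       genes$strand, genes$gene_id), con)
  invisible(path)
}

#' Read centromere coordinates
#'
#' Expects a TSV with a header and columns \code{chrom}, \code{start},
#' \code{end} (1-based, inclusive).
#' @param path TSV file.
#' @param rename optional chromosome rename map.
#' @return data.frame with columns chrom, start, end.
#' @export
read_centromeres <- function(path, rename = NULL) {
  cen <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(cen)))
    stop("centromere table must have columns chrom, start, end")
  cen <- cen[need]
  cen$chrom <- rename_chroms(as.character(cen$chrom), rename)
  if (anyDuplicated(cen$chrom))
    stop("more than one centromere interval for chromosome(s): ",
         paste(unique(cen$chrom[duplicated(cen$chrom)]), collapse = ", "))
  cen
}

#' Write centromere coordinates
#' @param cen centromere data.frame (chrom, start, end).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_centromeres <- function(cen, path) {
  utils::write.table(cen[c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an essential-gene list (one gene ID per line)
#' @param path text file.
#' @return character vector of gene IDs.
#' @export
read_essential_genes <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

fitness_columns <- c("gene_id", "chrom", "n_observed", "expected_insertions",
                     "n_zero_imputed", "n_used", "mean_reads",
                     "fitness_median_scale", "fitness_generation_scale",
                     "variance", "standard_error", "status")

#' Write a per-gene fitness table
#'
#' Writes the fitness records of a fit (or a compatible data.frame) as a TSV
#' with a fixed column set and deterministic row order (gene_id ascending).
#' Rows with status \code{undetermined} have empty numeric fields. Comment
#' lines (\code{#}) at the top record the shared overdispersion estimate when
#' a fit object is supplied.
#'
#' @param fit a \code{satay_fit} object or a data.frame of fitness records.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fitness_table <- function(fit, path) {
  header <- character(0)
  if (inherits(fit, "satay_fit")) {
    d <- fit$dispersion
    header <- c(sprintf("# satayfit fitness table"),
                sprintf("# alpha=%.10g n_genes_dispersion=%d",
                        d$alpha, d$n_genes),
                sprintf("# mu_ref=%.10g median_mean_reads=%.10g t_gen=%g",
                        fit$mu_ref, fit$median_mean_reads, fit$config$t_gen))
    records <- fit$fitness
  } else records <- fit
  stopifnot(all(fitness_columns %in% names(records)))
  records <- records[order(records$gene_id), fitness_columns, drop = FALSE]
  num <- setdiff(fitness_columns, c("gene_id", "chrom", "status"))
  fmt <- records
  for (cl in num) {
    v <- records[[cl]]
    fmt[[cl]] <- ifelse(is.na(v), "",
                        formatC(v, digits = 15, format = "g"))
  }
  con <- file(path, "w"); on.exit(close(con))
  if (length(header)) writeLines(header, con)
  writeLines(paste(fitness_columns, collapse = "\t"), con)
  if (nrow(fmt) > 0L)
    writeLines(do.call(paste, c(unname(as.list(fmt)), sep = "\t")), con)
  invisible(path)
}

#' Read a fitness table written by \code{\link{write_fitness_table}}
#' @param path TSV file.
#' @return data.frame of fitness records.
#' @export
read_fitness_table <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  stopifnot(all(fitness_columns %in% names(x)))
  num <- setdiff(fitness_columns, c("gene_id", "chrom", "status"))
  for (cl in num) {
    v <- x[[cl]]
    v[!nzchar(v)] <- NA
    x[[cl]] <- as.numeric(v)
  }
  for (cl in c("n_observed", "expected_insertions", "n_zero_imputed", "n_used"))
    x[[cl]] <- as.integer(x[[cl]])
  x
}
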