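new_taxon_table <- function(lineage, counts, excluded_samples = character()) {
  structure(list(lineage = lineage, counts = counts,
                 excluded_samples = excluded_samples),
            class = "taxon_table")
}

parse_lineage <- function(strings) {
  parts <- strsplit(strings, ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- p[seq_len(min(length(p), length(RANKS)))]
    out <- c(p, rep("", length(RANKS) - length(p)))
    out[!nzchar(out) | is.na(out)] <- UNASSIGNED
    out
  }, character(length(RANKS))))
  colnames(mat) <- RANKS
  as.data.frame(mat, stringsAsFactors = FALSE)
}

#' Read a taxon count table
#'
#' Expects a TSV with a lineage column (`lineage` or `taxonomy`;
#' semicolon-delimited ranks kingdom to genus) and one integer count
#' column per sample. Missing ranks become the explicit placeholder
#' `"Unassigned"`. Duplicate lineages are merged (with a warning);
#' samples whose counts are all zero are dropped (with a warning).
#'
#' @param path TSV file path.
#' @return Object of class `taxon_table`: list with `lineage`
#'   (data.frame of ranks), `counts` (taxa x samples integer matrix)
#'   and `excluded_samples`.
#' @export
read_taxon_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lin_col <- intersect(c("lineage", "taxonomy"), names(d))
  if (length(lin_col) == 0) {
    stop("taxon table needs a 'lineage' (or 'taxonomy') column", call. = FALSE)
  }
  lin_col <- lin_col[[1]]
  sample_cols <- setdiff(names(d), lin_col)
  if (length(sample_cols) == 0) stop("no sample columns found", call. = FALSE)
  counts <- as.matrix(d[, sample_cols, drop = FALSE])
  storage.mode(counts) <- "double"
  if (anyNA(counts)) stop("non-numeric or missing counts", call. = FALSE)
  if (any(counts < 0)) stop("negative counts are not allowed", call. = FALSE)
  taxon_table(d[[lin_col]], counts)
}

#' Build a taxon table from lineages and counts
#'
#' @param lineages Character vector of semicolon-delimited lineages.
#' @param counts Numeric matrix (taxa x samples) or vector for a single
#'   sample; column names are sample labels.
#' @return A `taxon_table` (see [read_taxon_table()]).
#' @export
taxon_table <- function(lineages, counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1,
                                             dimnames = list(NULL, "sample1"))
  stopifnot(length(lineages) == nrow(counts))
  if (any(counts < 0)) stop("negative counts are not allowed", call. = FALSE)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  lineage <- parse_lineage(as.character(lineages))
  key <- do.call(paste, c(lineage, sep = ";"))
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate taxon row(s) merged",
            call. = FALSE)
    counts <- rowsum(counts, key) # sorts rows by lineage key
    lineage <- parse_lineage(rownames(counts))
  }
  empty <- colSums(counts) == 0
  excluded <- colnames(counts)[empty]
  if (any(empty)) {
    warning("dropping sample(s) with zero total counts: ",
            paste(excluded, collapse = ", "), call. = FALSE)
    counts <- counts[, !empty, drop = FALSE]
  }
  rownames(counts) <- do.call(paste, c(lineage, sep = ";"))
  new_taxon_table(lineage, counts, excluded)
}

#' @export
print.taxon_table <- function(x, ...) {
  cat("<taxon_table>", nrow(x$counts), "taxa x", ncol(x$counts),
      "sample(s);", sum(x$counts), "total reads\n")
  invisible(x)
}

rank_labels <- function(lineage, rank) {
  ri <- match(rank, RANKS)
  if (is.na(ri)) stop("unknown rank '", rank, "'", call. = FALSE)
  vapply(seq_len(nrow(lineage)), function(i) {
    row <- unlist(lineage[i, seq_len(ri)])
    if (row[ri] != UNASSIGNED) return(row[ri])
    assigned <- which(row != UNASSIGNED)
    if (length(assigned) == 0) return(UNASSIGNED)
    deepest <- max(assigned)
    paste0(row[deepest], " (", RANKS[deepest], ")")
  }, character(1))
}

new_profile <- function(percent, residual, rank, threshold = NULL,
                        excluded_reads = NULL) {
  structure(list(percent = percent, residual = residual, rank = rank,
                 threshold = threshold, excluded_reads = excluded_reads),
            class = "abundance_profile")
}

#' Relative-abundance profile at a taxonomic rank
#'
#' Aggregates counts to the requested rank and converts them to
#' percentages of each sample's classified reads. Taxa unassigned at
#' the requested rank are aggregated under their deepest assigned rank
#' and labelled accordingly (e.g. `"Bacteria (kingdom)"`). Reads with
#' no kingdom assignment are excluded from the denominator; the
#' excluded count per sample is kept in the result. Samples with a
#' zero classified total are excluded with a warning.
#'
#' @param t A `taxon_table`.
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return Object of class `abundance_profile`: `percent` (taxa x
#'   samples matrix summing to 100 per sample), `residual` (per-sample
#'   percentage pooled below a threshold; zero before filtering),
#'   `rank`, `threshold`, `excluded_reads`.
#' @export
relative_abundance <- function(t, rank = "genus") {
  stopifnot(inherits(t, "taxon_table"))
  classified <- t$lineage$kingdom != UNASSIGNED
  excluded_reads <- colSums(t$counts[!classified, , drop = FALSE])
  counts <- t$counts[classified, , drop = FALSE]
  lineage <- t$lineage[classified, , drop = FALSE]
  if (nrow(counts) == 0) stop("no kingdom-classified taxa", call. = FALSE)
  labels <- rank_labels(lineage, rank)
  agg <- rowsum(counts, labels)
  totals <- colSums(agg)
  zero <- totals == 0
  if (any(zero)) {
    warning("excluding zero-total sample(s): ",
            paste(colnames(agg)[zero], collapse = ", "), call. = FALSE)
    agg <- agg[, !zero, drop = FALSE]
    totals <- totals[!zero]
  }
  percent <- sweep(agg, 2, totals, "/") * 100
  new_profile(percent,
              residual = stats::setNames(numeric(ncol(percent)),
                                         colnames(percent)),
              rank = rank, excluded_reads = excluded_reads)
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat("<abundance_profile> rank", x$rank, "-", nrow(x$percent), "taxa x",
      ncol(x$percent), "sample(s)")
  if (!is.null(x$threshold)) cat("; threshold >", x$threshold, "%")
  cat("\n")
  invisible(x)
}

#' Apply a display threshold to an abundance profile
#'
#' Within each sample, taxa at or below the threshold are pooled into
#' the residual ("other") bucket; only strictly greater abundances are
#' retained (a taxon at exactly the threshold is pooled). The
#' per-sample sum of retained percentages plus residual stays 100.
#'
#' @param p An [relative_abundance()] profile.
#' @param threshold Percent threshold (default 1, the conventional
#'   display filter for stacked-bar community plots).
#' @return A filtered `abundance_profile`; rows pooled in every sample
#'   are dropped from the matrix.
#' @export
filter_threshold <- function(p, threshold = 1) {
  stopifnot(inherits(p, "abundance_profile"))
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  keep <- p$percent > threshold # strict: "higher than"
  pooled <- p$percent
  pooled[keep] <- 0
  residual <- p$residual + colSums(pooled)
  percent <- p$percent
  percent[!keep] <- 0
  any_kept <- rowSums(keep) > 0
  percent <- percent[any_kept, , drop = FALSE]
  new_profile(percent, residual, p$rank, threshold, p$excluded_reads)
}

#' Per-sample kingdom split
#'
#' Percentages of Bacteria, Archaea and everything else (eukaryotes
#' and kingdom-unassigned reads) over all reads in each sample.
#'
#' @param t A `taxon_table`.
#' @return Matrix with rows `Bacteria`, `Archaea`, `other` and one
#'   column per sample; columns sum to 100.
#' @export
domain_split <- function(t) {
  stopifnot(inherits(t, "taxon_table"))
  king <- t$lineage$kingdom
  bucket <- ifelse(king %in% c("Bacteria", "Archaea"), king, "other")
  agg <- rowsum(t$counts, bucket)
  out <- matrix(0, 3, ncol(t$counts),
                dimnames = list(c("Bacteria", "Archaea", "other"),
                                colnames(t$counts)))
  out[rownames(agg), ] <- agg
  sweep(out, 2, colSums(out), "/") * 100
}

#' Write an abundance profile as CSV
#'
#' @param p An `abundance_profile`.
#' @param path Output CSV path. Rows are taxa (plus an
#'   `other/below-threshold` row when a threshold was applied),
#'   columns are samples.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path) {
  stopifnot(inherits(p, "abundance_profile"))
  m <- p$percent
  if (!is.null(p$threshold)) {
    m <- rbind(m, `other/below-threshold` = p$residual)
  }
  utils::write.csv(data.frame(taxon = rownames(m), m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
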