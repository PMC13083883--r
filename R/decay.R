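#' Median-of-ratios size factors
#'
#' The standard library-size estimator for count data: for each sample, the
#' median over all-positive features of the ratio between the sample's count
#' and the feature's geometric mean across samples.
#'
#' @param counts Feature x sample matrix of non-negative values (or a
#'   \code{SummarizedExperiment} with a \code{counts} assay).
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as_count_matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature is positive in all samples; cannot estimate size factors")
  sub <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub, 2L, function(col) median(col / geo))
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("degenerate size factors")
  sf
}

as_count_matrix <- function(x) {
  if (is(x, "SummarizedExperiment")) x <- assay(x, "counts")
  as.matrix(x)
}

#' Normalise counts by size factors
#'
#' @inheritParams size_factors
#' @param sf Optional precomputed size factors.
#' @return Matrix of normalised counts.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  counts <- as_count_matrix(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  sweep(counts, 2L, sf, "/")
}

#' Per-feature log2 fold change between two sample groups
#'
#' log2((mean normalised group-b + 0.5) / (mean normalised group-a + 0.5));
#' the pseudocount bounds fold changes of zero-count features.
#'
#' @inheritParams size_factors
#' @param group_a,group_b Column selectors (names or indices) for the
#'   reference and the comparison group.
#' @return Named numeric vector of log2 fold changes per feature.
#' @export
log2_fold_change <- function(counts, group_a, group_b) {
  norm <- normalize_counts(counts)
  a <- norm[, group_a, drop = FALSE]
  b <- norm[, group_b, drop = FALSE]
  if (ncol(a) == 0L || ncol(b) == 0L)
    stop("both contrast groups must contain samples")
  lfc <- log2((rowMeans(b) + 0.5) / (rowMeans(a) + 0.5))
  setNames(lfc, rownames(norm))
}

#' Stratify genes by m6A mark and reader targeting
#'
#' A gene is m6A-modified when at least one m6A peak overlaps its exonic
#' span (intronic peaks do not count, matching the non-intronic treatment of
#' reader targets); it is a target when it belongs to the reader
#' target-gene set. The two labels are independent.
#'
#' @param ann A \code{\link{genome_annotation}}.
#' @param m6a_peaks \code{GRanges} of m6A peaks (e.g. imported from BED).
#' @param lace_targets Character vector of reader target gene ids; unknown
#'   ids raise a warning and are ignored.
#' @return data.frame with \code{gene_id}, logical \code{m6a_modified},
#'   logical \code{target}.
#' @export
stratify_features <- function(ann, m6a_peaks, lace_targets = character(0)) {
  ids <- ann$genes$gene_id
  modified <- rep(FALSE, length(ids))
  if (length(m6a_peaks) > 0L && length(ids) > 0L) {
    ex_all <- unlist(ann$exons)
    ex_gene <- rep(names(ann$exons), lengths(ann$exons))
    hits <- findOverlaps(m6a_peaks, ex_all, ignore.strand = TRUE)
    modified <- ids %in% unique(ex_gene[subjectHits(hits)])
  }
  unknown <- setdiff(lace_targets, ids)
  if (length(unknown) > 0L)
    warning(length(unknown), " target id(s) absent from annotation; ignored")
  data.frame(gene_id = ids, m6a_modified = modified,
             target = ids %in% lace_targets)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided KS test between two groups of values (asymptotic p), the
#' statistic used throughout for cumulative-distribution shifts of log2
#' fold changes.
#'
#' @param a,b Numeric vectors, each with at least 5 values.
#' @return List with \code{D} (sup ECDF difference) and \code{p}.
#' @export
ks_compare <- function(a, b) {
  if (length(a) < 5L || length(b) < 5L)
    stop("ks_compare needs at least 5 values per group")
  res <- suppressWarnings(ks.test(a, b, alternative = "two.sided",
                                  exact = FALSE))
  list(D = unname(res$statistic), p = unname(res$p.value))
}

ecdf_table <- function(values, group) {
  by_group <- split(values, group)
  out <- do.call(rbind, lapply(names(by_group), function(g) {
    v <- sort(by_group[[g]])
    data.frame(group = g, value = v, ecdf = seq_along(v) / length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Transcript stability report
#'
#' The decay read-out of the knockdown + transcription-inhibition design:
#' per-feature normalised log2 fold changes (knockdown vs control, both
#' under the Pol II elongation inhibitor DRB), stratified by m6A mark and by
#' reader targeting, with KS comparisons between strata and
#' cumulative-distribution tables for plotting. The reported \code{shift} is
#' the difference of stratum medians (modified - unmodified, target -
#' non-target), which is invariant to the global normalisation.
#'
#' @inheritParams size_factors
#' @param strata Output of \code{\link{stratify_features}}; only features
#'   present in \code{counts} are used.
#' @param group_a,group_b Column selectors for control and knockdown
#'   samples (both DRB arms).
#' @return List of class \code{stability_report}: \code{log2fc} (per-gene
#'   table with strata), \code{tests} (per-contrast D, p, median shift) and
#'   \code{ecdf} (cumulative tables).
#' @export
stability_report <- function(counts, strata, group_a, group_b) {
  counts <- as_count_matrix(counts)
  lfc <- log2_fold_change(counts, group_a, group_b)
  keep <- intersect(names(lfc), strata$gene_id)
  if (length(keep) == 0L) stop("no overlap between counts and strata")
  st <- strata[match(keep, strata$gene_id), ]
  tab <- data.frame(gene_id = keep, log2fc = unname(lfc[keep]),
                    m6a_modified = st$m6a_modified, target = st$target)
  contrasts <- list(
    m6a = list(hi = tab$log2fc[tab$m6a_modified],
               lo = tab$log2fc[!tab$m6a_modified],
               labels = c("m6a_modified", "m6a_unmodified")),
    target = list(hi = tab$log2fc[tab$target],
                  lo = tab$log2fc[!tab$target],
                  labels = c("target", "non_target")))
  tests <- do.call(rbind, lapply(names(contrasts), function(nm) {
    co <- contrasts[[nm]]
    ks <- ks_compare(co$hi, co$lo)
    data.frame(contrast = nm, group_hi = co$labels[1L],
               group_lo = co$labels[2L],
               n_hi = length(co$hi), n_lo = length(co$lo),
               D = ks$D, p = ks$p,
               shift = median(co$hi) - median(co$lo))
  }))
  ecdfs <- list(
    m6a = ecdf_table(tab$log2fc,
                     ifelse(tab$m6a_modified, "m6a_modified",
                            "m6a_unmodified")),
    target = ecdf_table(tab$log2fc,
                        ifelse(tab$target, "target", "non_target")))
  structure(list(log2fc = tab, tests = tests, ecdf = ecdfs),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability_report over", nrow(x$log2fc), "features\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
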