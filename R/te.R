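#' Fractional TE-subfamily read counting
#'
#' Each read contributes total weight 1: a read with \code{k} genomic hits
#' carries weight \code{1/k}, and a tag overlapping instances of several
#' subfamilies splits that weight evenly between them. This fractional
#' scheme is a deliberately simple, exactly checkable replacement for
#' EM-based multi-mapper redistribution; subfamily-level totals behave the
#' same qualitatively.
#'
#' @param tags A \code{\link{tag_set}} whose \code{k} column is the number
#'   of genomic hits per read.
#' @param ann A \code{\link{genome_annotation}} with TE instances.
#' @return Named numeric vector of fractional counts per subfamily, with an
#'   \code{unassigned} attribute giving the weight of reads outside any TE.
#' @export
count_te_reads <- function(tags, ann) {
  stopifnot(inherits(tags, "tag_set"))
  t <- tags$tags
  if (any(t$k < 1L)) stop("multi-hit count k must be >= 1")
  subfams <- sort(unique(ann$tes$subfamily))
  counts <- setNames(numeric(length(subfams)), subfams)
  unassigned <- 0
  if (nrow(t) == 0L) {
    attr(counts, "unassigned") <- 0
    return(counts)
  }
  tag_gr <- GRanges(t$contig, IRanges(t$pos + 1L, t$pos + 1L))
  hits <- findOverlaps(tag_gr, ann$tes, ignore.strand = TRUE)
  hit_sub <- split(ann$tes$subfamily[subjectHits(hits)], queryHits(hits))
  for (i in seq_len(nrow(t))) {
    w <- 1 / t$k[i]
    subs <- unique(hit_sub[[as.character(i)]])
    if (is.null(subs) || length(subs) == 0L) {
      unassigned <- unassigned + w
    } else {
      counts[subs] <- counts[subs] + w / length(subs)
    }
  }
  attr(counts, "unassigned") <- unassigned
  counts
}

#' Binding-read enrichment per TE subfamily
#'
#' Observed fraction of binding tags falling in each subfamily against an
#' expected fraction from either the genomic footprint of the subfamily or a
#' matched background tag set; score = log2(observed/expected) with a
#' pseudofraction of 1/(2 * total tags) guarding empty categories.
#'
#' @param binding_tags A \code{\link{tag_set}} of reader binding reads.
#' @param ann A \code{\link{genome_annotation}}.
#' @param background Either \code{"genomic"} (instance length fractions of
#'   the genome) or a \code{\link{tag_set}} of matched input reads.
#' @return data.frame with \code{subfamily}, \code{observed_fraction},
#'   \code{expected_fraction}, \code{score}.
#' @export
te_enrichment <- function(binding_tags, ann, background = "genomic") {
  stopifnot(inherits(binding_tags, "tag_set"))
  n_tags <- nrow(binding_tags$tags)
  if (n_tags == 0L) stop("binding tag set is empty")
  subfams <- sort(unique(ann$tes$subfamily))
  if (length(subfams) == 0L) stop("annotation has no TE instances")
  obs <- te_tag_fractions(binding_tags, ann, subfams)
  if (identical(background, "genomic")) {
    genome_size <- sum(as.numeric(ann$contig_lengths))
    exp_frac <- vapply(subfams, function(s) {
      sum(width(reduce(ann$tes[ann$tes$subfamily == s],
                       ignore.strand = TRUE))) / genome_size
    }, 0)
  } else if (inherits(background, "tag_set")) {
    if (nrow(background$tags) == 0L) stop("background tag set is empty")
    exp_frac <- te_tag_fractions(background, ann, subfams)
  } else stop("background must be 'genomic' or a tag_set")
  pseudo <- 1 / (2 * n_tags)
  score <- log2(pmax(obs, pseudo) / pmax(exp_frac, pseudo))
  data.frame(subfamily = subfams, observed_fraction = unname(obs),
             expected_fraction = unname(exp_frac), score = unname(score))
}

te_tag_fractions <- function(tags, ann, subfams) {
  t <- tags$tags
  tag_gr <- GRanges(t$contig, IRanges(t$pos + 1L, t$pos + 1L))
  hits <- findOverlaps(tag_gr, ann$tes, ignore.strand = TRUE)
  # a tag in several instances of one subfamily counts once for it
  pair <- unique(data.frame(q = queryHits(hits),
                            s = ann$tes$subfamily[subjectHits(hits)]))
  cnt <- table(factor(pair$s, levels = subfams))
  as.numeric(cnt) / nrow(t)
}

#' Differential TE-subfamily expression
#'
#' Median-of-ratios normalisation followed by a per-subfamily Welch t test
#' on log2 normalised counts (pseudocount 0.5) and Benjamini-Hochberg
#' adjustment. A documented simplification of negative-binomial GLM testing;
#' adequate for the subfamily-level shifts this pipeline plants and reports.
#'
#' @param counts Matrix subfamily x sample of (possibly fractional) counts.
#' @param condition Character vector of sample conditions, two levels; the
#'   first level is the reference.
#' @param sf Optional externally estimated size factors (e.g. from the full
#'   gene + TE count matrix). With only a handful of subfamilies, factors
#'   estimated from the TE table alone would absorb genuine global TE
#'   shifts, so supplying genome-wide factors is recommended.
#' @return data.frame with \code{subfamily}, \code{log2fc} (second level vs
#'   first), \code{p}, \code{padj}.
#' @export
te_differential <- function(counts, condition, sf = NULL) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    stop("condition must have exactly two levels")
  if (any(table(condition) < 2L))
    stop("need >= 2 samples per condition")
  if (is.null(sf)) sf <- size_factors(counts)
  stopifnot(length(sf) == ncol(counts))
  norm <- sweep(counts, 2L, sf, "/")
  ref <- levels(condition)[1L]; alt <- levels(condition)[2L]
  lfc <- log2((rowMeans(norm[, condition == alt, drop = FALSE]) + 0.5) /
                (rowMeans(norm[, condition == ref, drop = FALSE]) + 0.5))
  lg <- log2(norm + 0.5)
  p <- apply(lg, 1L, function(x) {
    a <- x[condition == alt]; b <- x[condition == ref]
    tryCatch(t.test(a, b)$p.value, error = function(e) {
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    })
  })
  data.frame(subfamily = rownames(counts), log2fc = unname(lfc),
             p = unname(p), padj = p.adjust(p, "BH"))
}
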