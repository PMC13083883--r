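#' Parameters of the binding-site caller
#'
#' Defaults mirror standard LACE-seq post-processing: read 5' ends closer
#' than 100 bp are merged into a cluster, clusters need more than 10 unique
#' reads (strict), the local background is the 500-bp window around the
#' summit, DRACH motif search windows are extended 30 nt upstream, and
#' clusters must exceed the methylation-inhibitor control two-fold.
#'
#' @param merge_distance Maximum gap (exclusive) between successive 5'-end
#'   positions joined into one cluster, bp.
#' @param min_unique_reads Clusters with a unique-read count less than or
#'   equal to this are discarded.
#' @param background_halfwidth Half-width of the background window centred
#'   on the summit, bp.
#' @param upstream_extension Upstream extension of the motif search window,
#'   nt, on the cluster strand.
#' @param control_fold Minimum library-normalised treatment/control ratio.
#' @param motif IUPAC consensus searched in the extended cluster window.
#' @return A list of class \code{caller_params}.
#' @export
caller_params <- function(merge_distance = 100L, min_unique_reads = 10L,
                          background_halfwidth = 250L,
                          upstream_extension = 30L, control_fold = 2,
                          motif = "DRACH") {
  stopifnot(merge_distance > 0, min_unique_reads >= 0,
            background_halfwidth > 0, upstream_extension >= 0,
            control_fold >= 0)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", motif))
    stop("motif must be an IUPAC consensus string")
  structure(list(merge_distance = as.integer(merge_distance),
                 min_unique_reads = as.integer(min_unique_reads),
                 background_halfwidth = as.integer(background_halfwidth),
                 upstream_extension = as.integer(upstream_extension),
                 control_fold = control_fold, motif = motif),
            class = "caller_params")
}

empty_clusters <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), summit = integer(0),
             unique_reads = integer(0))
}

#' Cluster read 5' ends into candidate binding sites
#'
#' Single-linkage merge of sorted 5'-end positions per (contig, strand):
#' successive positions are joined while their gap is strictly less than
#' \code{merge_distance}. The summit is the position with the highest 5'-end
#' multiplicity; ties break towards the 5' side of the cluster strand
#' (left-most on \code{+}, right-most on \code{-}). Clusters with
#' \code{unique_reads <= min_unique_reads} are discarded.
#'
#' @param tags A \code{\link{tag_set}}.
#' @param params A \code{\link{caller_params}}.
#' @return data.frame of clusters: \code{contig}, \code{start}, \code{end}
#'   (0-based half-open span of the merged 5' ends), \code{strand},
#'   \code{summit} (0-based), \code{unique_reads}.
#' @export
cluster_tags <- function(tags, params = caller_params()) {
  stopifnot(inherits(tags, "tag_set"))
  t <- tags$tags
  if (nrow(t) == 0L) return(empty_clusters())
  out <- list()
  groups <- split(t, list(t$contig, t$strand), drop = TRUE)
  for (g in groups) {
    cnt <- table(g$pos)
    pos <- as.integer(names(cnt))
    o <- order(pos)
    pos <- pos[o]
    mult <- as.integer(cnt)[o]
    brk <- which(diff(pos) >= params$merge_distance)
    cl_id <- rep(seq_len(length(brk) + 1L),
                 times = diff(c(0L, brk, length(pos))))
    minus <- g$strand[1L] == "-"
    for (id in unique(cl_id)) {
      sel <- cl_id == id
      p <- pos[sel]; m <- mult[sel]
      n <- sum(m)
      if (n <= params$min_unique_reads) next
      best <- which(m == max(m))
      summit <- if (minus) p[best[length(best)]] else p[best[1L]]
      out[[length(out) + 1L]] <- data.frame(
        contig = g$contig[1L], start = p[1L], end = p[length(p)] + 1L,
        strand = g$strand[1L], summit = summit, unique_reads = n)
    }
  }
  if (length(out) == 0L) return(empty_clusters())
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

background_window <- function(clusters, params, contig_lens) {
  half <- params$background_halfwidth
  bg_start <- pmax(0L, clusters$summit - half)
  bg_end <- clusters$summit + half
  if (!missing(contig_lens) && !is.null(contig_lens))
    bg_end <- pmin(bg_end, as.integer(contig_lens[clusters$contig]))
  cbind(start = bg_start, end = bg_end)
}

#' Score local background enrichment of clusters
#'
#' Tag density within the cluster span divided by tag density in the
#' background window (summit +/- \code{background_halfwidth}, clipped to the
#' contig), excluding the cluster span itself from the background. An empty
#' background yields \code{Inf}.
#'
#' @param clusters Output of \code{\link{cluster_tags}}.
#' @param tags The \code{\link{tag_set}} the clusters were called from.
#' @param params A \code{\link{caller_params}}.
#' @param contig_lens Optional named contig lengths for edge clipping.
#' @return \code{clusters} with added \code{signal_enrichment},
#'   \code{bg_start}, \code{bg_end} columns.
#' @export
score_enrichment <- function(clusters, tags, params = caller_params(),
                             contig_lens = NULL) {
  if (nrow(clusters) == 0L) {
    clusters$signal_enrichment <- numeric(0)
    clusters$bg_start <- integer(0); clusters$bg_end <- integer(0)
    return(clusters)
  }
  bg <- background_window(clusters, params, contig_lens)
  if (any(bg[, "end"] <= bg[, "start"]))
    stop("background window fully clipped away at a contig edge")
  t <- tags$tags
  enr <- numeric(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    on_ctg <- t$contig == cl$contig & t$strand == cl$strand
    p <- t$pos[on_ctg]
    n_in <- sum(p >= cl$start & p < cl$end)
    in_bg <- p >= bg[i, "start"] & p < bg[i, "end"]
    in_cl <- p >= cl$start & p < cl$end
    n_bg <- sum(in_bg & !in_cl)
    len_cl <- cl$end - cl$start
    len_bg <- (bg[i, "end"] - bg[i, "start"]) -
      (min(bg[i, "end"], cl$end) - max(bg[i, "start"], cl$start))
    sig_d <- n_in / len_cl
    enr[i] <- if (n_bg == 0L || len_bg <= 0L) Inf else sig_d / (n_bg / len_bg)
  }
  clusters$signal_enrichment <- enr
  clusters$bg_start <- bg[, "start"]
  clusters$bg_end <- bg[, "end"]
  clusters
}

#' Subtract the methylation-inhibitor negative control
#'
#' For each cluster, the library-normalised ratio of treatment tags to
#' control tags within the cluster span (pseudocount 1 on the control
#' count). Clusters with ratio below \code{control_fold} are removed. This
#' arithmetic is a declared policy: published pipelines state the intent of
#' control subtraction without fixing the formula.
#'
#' @param clusters Cluster table.
#' @param tags Treatment \code{\link{tag_set}}.
#' @param control_tags Inhibitor-condition \code{\link{tag_set}}.
#' @param params A \code{\link{caller_params}}.
#' @return Filtered clusters with added \code{control_ratio}.
#' @export
subtract_control <- function(clusters, tags, control_tags,
                             params = caller_params()) {
  stopifnot(inherits(control_tags, "tag_set"))
  if (control_tags$condition != "inhibitor")
    warning("control tag set condition is not 'inhibitor'")
  n_treat <- nrow(tags$tags); n_ctrl <- nrow(control_tags$tags)
  if (n_treat == 0L || n_ctrl == 0L)
    stop("zero-size library in control subtraction")
  if (nrow(clusters) == 0L) {
    clusters$control_ratio <- numeric(0)
    return(clusters)
  }
  ratio <- numeric(nrow(clusters))
  tt <- tags$tags; ct <- control_tags$tags
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    in_t <- sum(tt$contig == cl$contig & tt$strand == cl$strand &
                  tt$pos >= cl$start & tt$pos < cl$end)
    in_c <- sum(ct$contig == cl$contig & ct$strand == cl$strand &
                  ct$pos >= cl$start & ct$pos < cl$end)
    ratio[i] <- (in_t / n_treat) / ((in_c + 1) / n_ctrl)
  }
  clusters$control_ratio <- ratio
  clusters[ratio >= params$control_fold, , drop = FALSE]
}

#' The 18 DRACH pentamers
#'
#' D = G/A/T, R = A/G, then A, C, H = A/T/C.
#'
#' @return Character vector of the 18 pentamers matching the m6A consensus.
#' @export
drach_pentamers <- function() {
  grid <- expand.grid(d = c("G", "A", "T"), r = c("A", "G"),
                      a = "A", c = "C", h = c("A", "T", "C"),
                      stringsAsFactors = FALSE)
  sort(apply(grid, 1L, paste0, collapse = ""))
}

drach_regex <- "[GAT][AG]AC[ATC]"

#' Filter clusters for the m6A DRACH consensus
#'
#' The search window is the cluster span extended
#' \code{upstream_extension} nt upstream on the cluster strand (clipped at
#' contig edges); a cluster passes when the strand-aware window sequence
#' contains at least one DRACH pentamer. Windows containing N never match.
#'
#' @param clusters Cluster table.
#' @param genome \code{DNAStringSet} named by contig.
#' @param params A \code{\link{caller_params}}.
#' @param keep_failing Keep non-passing clusters (flagged) instead of
#'   dropping them.
#' @return Clusters with added logical \code{drach_pass}; non-passing rows
#'   removed unless \code{keep_failing}.
#' @export
drach_filter <- function(clusters, genome, params = caller_params(),
                         keep_failing = FALSE) {
  if (nrow(clusters) == 0L) {
    clusters$drach_pass <- logical(0)
    return(clusters)
  }
  lens <- contig_lengths(genome)
  ext <- params$upstream_extension
  minus <- clusters$strand == "-"
  w_start <- ifelse(minus, clusters$start, pmax(0L, clusters$start - ext))
  w_end <- ifelse(minus, pmin(lens[clusters$contig], clusters$end + ext),
                  clusters$end)
  gr <- GRanges(clusters$contig,
                IRanges(w_start + 1L, w_end),
                strand = clusters$strand)
  seqs <- fetch_sequence(genome, gr)
  clusters$drach_pass <- grepl(drach_regex, seqs)
  if (keep_failing) clusters else
    clusters[clusters$drach_pass, , drop = FALSE]
}

#' Annotate clusters to genes and TE instances
#'
#' Assignment is by summit position with precedence
#' exon > intron > TE > intergenic; a summit inside a TE instance always
#' also gets the subfamily label, independent of genic status.
#'
#' @param clusters Cluster table.
#' @param ann A \code{\link{genome_annotation}}.
#' @return \code{clusters} with added \code{gene_id}, \code{feature_class}
#'   (\code{exon}/\code{intron}/\code{intergenic}) and \code{te_subfamily}
#'   (\code{NA} when outside any TE).
#' @export
annotate_clusters <- function(clusters, ann) {
  clusters$gene_id <- NA_character_
  clusters$feature_class <- rep("intergenic", nrow(clusters))
  clusters$te_subfamily <- NA_character_
  if (nrow(clusters) == 0L) return(clusters)
  summit_gr <- GRanges(clusters$contig,
                       IRanges(clusters$summit + 1L, clusters$summit + 1L),
                       strand = clusters$strand)
  if (length(ann$genes) > 0L) {
    hit_g <- findOverlaps(summit_gr, ann$genes, ignore.strand = FALSE)
    ex_all <- unlist(ann$exons)
    ex_gene <- rep(names(ann$exons), lengths(ann$exons))
    hit_e <- findOverlaps(summit_gr, ex_all, ignore.strand = FALSE)
    exonic_genes <- split(ex_gene[subjectHits(hit_e)], queryHits(hit_e))
    for (q in unique(queryHits(hit_g))) {
      genes_here <- ann$genes$gene_id[subjectHits(hit_g)[queryHits(hit_g) == q]]
      exg <- intersect(genes_here, exonic_genes[[as.character(q)]])
      if (length(exg) > 0L) {
        clusters$gene_id[q] <- exg[1L]
        clusters$feature_class[q] <- "exon"
      } else {
        clusters$gene_id[q] <- genes_here[1L]
        clusters$feature_class[q] <- "intron"
      }
    }
  }
  if (length(ann$tes) > 0L) {
    hit_t <- findOverlaps(summit_gr, ann$tes, ignore.strand = TRUE)
    clusters$te_subfamily[queryHits(hit_t)] <-
      ann$tes$subfamily[subjectHits(hit_t)]
  }
  clusters
}

#' Target genes of a reader
#'
#' Genes with at least one retained exonic cluster (the non-intronic gene
#' level used for target-set overlap statistics).
#'
#' @param annotated Output of \code{\link{annotate_clusters}} after all
#'   filters.
#' @return Character vector of gene ids.
#' @export
target_gene_set <- function(annotated) {
  sort(unique(annotated$gene_id[annotated$feature_class == "exon" &
                                  !is.na(annotated$gene_id)]))
}

#' Reciprocal overlap of two target-gene sets
#'
#' @param a,b Character vectors of gene ids.
#' @return Named numeric: \code{frac_a} = |A&B|/|A|, \code{frac_b} =
#'   |A&B|/|B| (NaN for an empty set), and \code{n_common}.
#' @export
target_overlap <- function(a, b) {
  common <- length(intersect(a, b))
  c(frac_a = common / length(a), frac_b = common / length(b),
    n_common = common)
}

#' Full binding-site calling pipeline for one reader
#'
#' Runs clustering, enrichment scoring, inhibitor-control subtraction, DRACH
#' filtering and annotation in the order used for reader CLIP-style data.
#'
#' @param tags Treatment \code{\link{tag_set}} (condition control).
#' @param control_tags Inhibitor \code{\link{tag_set}}, or \code{NULL} to
#'   skip control subtraction.
#' @param genome \code{DNAStringSet}.
#' @param ann A \code{\link{genome_annotation}} (optional; skip annotation
#'   with \code{NULL}).
#' @param params A \code{\link{caller_params}}.
#' @return Annotated cluster data.frame of retained binding sites.
#' @export
call_binding_sites <- function(tags, control_tags = NULL, genome,
                               ann = NULL, params = caller_params()) {
  cl <- cluster_tags(tags, params)
  cl <- score_enrichment(cl, tags, params, contig_lengths(genome))
  if (!is.null(control_tags))
    cl <- subtract_control(cl, tags, control_tags, params)
  cl <- drach_filter(cl, genome, params)
  if (!is.null(ann)) cl <- annotate_clusters(cl, ann)
  rownames(cl) <- NULL
  cl
}

#' Write called clusters as BED6+
#'
#' @param clusters Cluster table.
#' @param path Output path.
#' @export
write_clusters <- function(clusters, path) {
  df <- data.frame(chrom = clusters$contig, start = clusters$start,
                   end = clusters$end,
                   name = sprintf("cluster%05d", seq_len(nrow(clusters))),
                   score = clusters$unique_reads, strand = clusters$strand,
                   summit = clusters$summit,
                   enrichment = clusters$signal_enrichment %||% NA,
                   control_ratio = clusters$control_ratio %||% NA,
                   drach_pass = clusters$drach_pass %||% NA)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
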