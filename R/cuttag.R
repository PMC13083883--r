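track_values <- function(track, contig, start, end) {
  v <- track$signal[[contig]]
  if (is.null(v)) stop("track has no contig '", contig, "'")
  if (start < 1L || end > length(v)) stop("window off contig")
  v[start:end]
}

#' Anchored metagene profile
#'
#' Mean strand-oriented CPM profile around gene TSS or TES: each eligible
#' gene contributes a binned window of \code{2*flank} bp centred on the
#' anchor, minus-strand genes are flipped so upstream is always left, and
#' genes whose window runs off the contig are excluded (counted).
#'
#' @param track A \code{\link{coverage_track}}.
#' @param ann A \code{\link{genome_annotation}}.
#' @param anchor \code{"TSS"} or \code{"TES"}.
#' @param flank Half-window, bp.
#' @param bins Number of bins across the window.
#' @return List of class \code{metagene_profile}: \code{position} (bin
#'   centre relative to anchor), \code{mean}, \code{ci_lower},
#'   \code{ci_upper} (normal 95\% CI of the mean), \code{n_genes},
#'   \code{n_excluded}.
#' @export
metagene_profile <- function(track, ann, anchor = c("TSS", "TES"),
                             flank = 2000L, bins = 100L) {
  anchor <- match.arg(anchor)
  genes <- ann$genes
  if (length(genes) == 0L) stop("no genes in annotation")
  cpm <- cpm_factor(track)
  width_bp <- 2L * flank
  if (width_bp %% bins != 0L) stop("2*flank must be divisible by bins")
  bw <- width_bp %/% bins
  anchors <- if (anchor == "TSS") genes$tss else genes$tes
  lens <- ann$contig_lengths[as.character(seqnames(genes))]
  strands <- as.character(strand(genes))
  # windows are placed so the anchor base falls in the first downstream
  # bin after strand flipping
  w_start <- anchors - flank + (strands == "-")
  w_end <- anchors + flank - 1L + (strands == "-")
  usable <- w_start >= 1L & w_end <= lens
  if (!any(usable)) stop("no gene has the full flank on its contig")
  mat <- matrix(NA_real_, sum(usable), bins)
  idx <- which(usable)
  ctgs <- as.character(seqnames(genes))
  for (r in seq_along(idx)) {
    i <- idx[r]
    v <- track_values(track, ctgs[i], w_start[i], w_end[i])
    if (strands[i] == "-") v <- rev(v)
    mat[r, ] <- colMeans(matrix(v, nrow = bw)) * cpm
  }
  mu <- colMeans(mat)
  se <- apply(mat, 2L, sd) / sqrt(nrow(mat))
  structure(list(position = seq(-flank + bw / 2, flank - bw / 2, by = bw),
                 mean = mu, ci_lower = mu - 1.96 * se,
                 ci_upper = mu + 1.96 * se,
                 n_genes = nrow(mat), n_excluded = sum(!usable)),
            class = "metagene_profile")
}

# Strand-oriented promoter/body windows in genomic coordinates (1-based
# closed). promoter_window is relative to the TSS in transcript direction.
promoter_body_ranges <- function(tss, tes, strand,
                                 promoter_window = c(-50L, 300L),
                                 body_offset = 300L) {
  if (strand == "-") {
    promoter <- c(tss - (promoter_window[2L] - 1L), tss - promoter_window[1L])
    body <- c(tes, tss - body_offset)
  } else {
    promoter <- c(tss + promoter_window[1L], tss + promoter_window[2L] - 1L)
    body <- c(tss + body_offset, tes)
  }
  list(promoter = promoter, body = body)
}

#' Promoter-proximal pausing index
#'
#' Per gene, the ratio of mean polymerase signal density in the
#' promoter-proximal window to the density over the remaining gene body;
#' high values flag stalled polymerase. Default windows (-50 to +300 around
#' the TSS; +300 to the TES for the body) follow common pausing-index
#' practice and are configurable.
#'
#' @param track A \code{\link{coverage_track}}.
#' @param ann A \code{\link{genome_annotation}}.
#' @param promoter_window Window around the TSS in transcript-oriented bp,
#'   \code{c(from, to)} with \code{from < to}.
#' @param body_offset Body starts this many bp downstream of the TSS.
#' @param min_length Genes shorter than this are excluded.
#' @return data.frame: \code{gene_id}, \code{promoter_density},
#'   \code{body_density} (mean CPM per bp), \code{pi}. Genes excluded for
#'   length, zero body signal or off-contig windows are absent; the number
#'   excluded is in \code{attr(, "n_excluded")}.
#' @export
pausing_index <- function(track, ann, promoter_window = c(-50L, 300L),
                          body_offset = 300L, min_length = 600L) {
  genes <- ann$genes
  cpm <- cpm_factor(track)
  ids <- genes$gene_id
  ctgs <- as.character(seqnames(genes))
  strands <- as.character(strand(genes))
  tsss <- genes$tss; tess <- genes$tes
  widths <- width(genes)
  prom_d <- body_d <- rep(NA_real_, length(genes))
  excluded <- 0L
  for (i in seq_along(ids)) {
    if (widths[i] <= min_length) { excluded <- excluded + 1L; next }
    win <- promoter_body_ranges(tsss[i], tess[i], strands[i],
                                promoter_window, body_offset)
    clen <- ann$contig_lengths[[ctgs[i]]]
    if (win$promoter[1L] < 1L || win$promoter[2L] > clen ||
        win$body[1L] > win$body[2L]) { excluded <- excluded + 1L; next }
    prom <- mean(track_values(track, ctgs[i], win$promoter[1L],
                              win$promoter[2L]))
    body <- mean(track_values(track, ctgs[i], win$body[1L], win$body[2L]))
    if (body <= 0) { excluded <- excluded + 1L; next }
    prom_d[i] <- prom; body_d[i] <- body
  }
  keep <- !is.na(prom_d)
  out <- data.frame(gene_id = ids[keep],
                    promoter_density = prom_d[keep] * cpm,
                    body_density = body_d[keep] * cpm,
                    pi = prom_d[keep] / body_d[keep])
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}

#' Differential signal over merged peak regions
#'
#' Replicate peak sets are union-merged (bookended intervals joined), the
#' coverage of every sample is summed per region, counts are normalised by
#' median-of-ratios size factors and each region is tested with a Welch t
#' test on log2 normalised counts (pseudocount 0.5), BH-adjusted.
#'
#' @param tracks List of \code{\link{coverage_track}}, one per sample.
#' @param peak_sets List of \code{GRanges} peak sets (any number; typically
#'   one per replicate).
#' @param condition Character vector, one label per track, two levels; the
#'   first level is the reference.
#' @return data.frame: region coordinates, \code{log2fc} (second level vs
#'   first), \code{p}, \code{padj}.
#' @export
differential_regions <- function(tracks, peak_sets, condition) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    stop("condition must have exactly two levels")
  if (any(table(condition) < 2L)) stop("need >= 2 replicates per condition")
  stopifnot(length(tracks) == length(condition))
  regions <- reduce(do.call(c, lapply(peak_sets, granges)),
                    ignore.strand = TRUE)
  if (length(regions) == 0L) stop("empty peak union")
  counts <- vapply(tracks, function(tr) {
    vapply(seq_along(regions), function(i) {
      sum(track_values(tr, as.character(seqnames(regions))[i],
                       start(regions)[i], end(regions)[i]))
    }, 0)
  }, numeric(length(regions)))
  rownames(counts) <- sprintf("%s:%d-%d", as.character(seqnames(regions)),
                              start(regions) - 1L, end(regions))
  stats_tab <- region_stats(counts, condition)
  out <- cbind(data.frame(contig = as.character(seqnames(regions)),
                          start = start(regions) - 1L, end = end(regions)),
               stats_tab)
  attr(out, "counts") <- counts
  out
}

region_stats <- function(counts, condition) {
  sf <- size_factors(counts)
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
  data.frame(log2fc = unname(lfc), p = unname(p),
             padj = p.adjust(p, "BH"))
}

#' Stratify region fold changes by distance to the nearest B2 locus
#'
#' Bins region-level log2 fold changes by genomic distance to the nearest
#' B2-subfamily instance (overlap = 0 kb bin) and reports per-bin medians
#' plus KS tests between adjacent bins — the read-out used to ask whether
#' polymerase changes are confined to the neighbourhood of B2 elements.
#'
#' @param regions \code{GRanges} of scored regions.
#' @param log2fc Numeric vector, one value per region.
#' @param ann A \code{\link{genome_annotation}} containing B2 instances.
#' @param breaks_kb Ascending bin edges in kb (default 5, 10, 20, 50, 100);
#'   bins are 0, (0,b1], ..., (b_last, Inf).
#' @param b2_pattern Regular expression selecting B2 subfamilies.
#' @return List of class \code{b2_distance_table}: \code{table} (per-region
#'   bin assignment), \code{summary} (per-bin n and median log2fc),
#'   \code{adjacent_ks} (D and p between neighbouring bins).
#' @export
b2_distance_stratification <- function(regions, log2fc, ann,
                                       breaks_kb = c(5, 10, 20, 50, 100),
                                       b2_pattern = "^B2") {
  stopifnot(length(regions) == length(log2fc))
  b2 <- ann$tes[grepl(b2_pattern, ann$tes$subfamily)]
  if (length(b2) == 0L) stop("annotation contains no B2 instances")
  d <- nearest_distance(regions, b2)
  edges <- c(0, breaks_kb * 1000, Inf)
  labels <- c("0", paste0("(", c(0, breaks_kb[-length(breaks_kb)]), ",",
                          breaks_kb, "]"),
              paste0(">", breaks_kb[length(breaks_kb)]))
  bin <- character(length(d))
  bin[d == 0] <- labels[1L]
  for (i in seq_along(breaks_kb)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    bin[d > lo & d <= hi] <- labels[i + 1L]
  }
  bin[d > edges[length(edges) - 1L]] <- labels[length(labels)]
  bin <- factor(bin, levels = labels)
  summ <- data.frame(bin = labels,
                     n = as.integer(table(bin)),
                     median_log2fc = vapply(labels, function(l) {
                       v <- log2fc[bin == l]
                       if (length(v) == 0L) NA_real_ else median(v)
                     }, 0))
  ks <- do.call(rbind, lapply(seq_len(length(labels) - 1L), function(i) {
    a <- log2fc[bin == labels[i]]; b <- log2fc[bin == labels[i + 1L]]
    if (length(a) < 5L || length(b) < 5L)
      return(data.frame(bin_a = labels[i], bin_b = labels[i + 1L],
                        D = NA_real_, p = NA_real_))
    kc <- ks_compare(a, b)
    data.frame(bin_a = labels[i], bin_b = labels[i + 1L], D = kc$D, p = kc$p)
  }))
  structure(list(table = data.frame(distance = d, bin = bin,
                                    log2fc = log2fc),
                 summary = summ, adjacent_ks = ks),
            class = "b2_distance_table")
}

#' @export
print.b2_distance_table <- function(x, ...) {
  cat("B2 distance stratification of", nrow(x$table), "regions\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Length-scaled metagene over repeat instances
#'
#' Each instance body is rescaled to a fixed number of bins; flanks are
#' binned in absolute bp. Strand-oriented (upstream left). Used to profile
#' polymerase occupancy over B2 or MERVL loci.
#'
#' @param track A \code{\link{coverage_track}}.
#' @param instances \code{GRanges} of repeat instances (one subfamily).
#' @param flank Flank size, bp.
#' @param body_bins Number of bins across the scaled body.
#' @param flank_bin Flank bin width, bp; \code{flank} must be a multiple.
#' @return List of class \code{repeat_metagene}: \code{region} (upstream /
#'   body / downstream per bin), \code{mean} CPM per bin, \code{n_instances}.
#' @export
repeat_locus_metagene <- function(track, instances, flank = 1000L,
                                  body_bins = 60L, flank_bin = 50L) {
  if (length(instances) == 0L) stop("no instances supplied")
  if (flank %% flank_bin != 0L) stop("flank must be a multiple of flank_bin")
  nf <- flank %/% flank_bin
  lens <- vapply(names(track$signal), function(ct) length(track$signal[[ct]]),
                 0L)
  ctg <- as.character(seqnames(instances))
  usable <- start(instances) - flank >= 1L &
    end(instances) + flank <= lens[ctg]
  if (!any(usable)) stop("no instance has full flanks on its contig")
  inst <- instances[usable]
  cpm <- cpm_factor(track)
  prof <- matrix(NA_real_, length(inst), 2L * nf + body_bins)
  for (i in seq_along(inst)) {
    g <- inst[i]
    ct <- as.character(seqnames(g))
    up <- track_values(track, ct, start(g) - flank, start(g) - 1L)
    body <- track_values(track, ct, start(g), end(g))
    down <- track_values(track, ct, end(g) + 1L, end(g) + flank)
    body_binned <- vapply(seq_len(body_bins), function(b) {
      lo <- floor((b - 1L) * length(body) / body_bins) + 1L
      hi <- floor(b * length(body) / body_bins)
      mean(body[lo:max(lo, hi)])
    }, 0)
    up_binned <- colMeans(matrix(up, nrow = flank_bin))
    down_binned <- colMeans(matrix(down, nrow = flank_bin))
    v <- c(up_binned, body_binned, down_binned)
    if (as.character(strand(g)) == "-") v <- rev(v)
    prof[i, ] <- v * cpm
  }
  structure(list(region = rep(c("upstream", "body", "downstream"),
                              c(nf, body_bins, nf)),
                 mean = colMeans(prof), n_instances = length(inst)),
            class = "repeat_metagene")
}
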