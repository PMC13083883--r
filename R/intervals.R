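#' Load a genome FASTA
#'
#' @param path FASTA path.
#' @return A \code{DNAStringSet} named by contig.
#' @export
read_genome <- function(path) {
  seqs <- readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Contig lengths of a genome
#'
#' @param genome A \code{DNAStringSet}.
#' @return Named integer vector.
#' @export
contig_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

#' Strand-aware sequence fetch
#'
#' Returns the genomic sequence of each interval; minus-strand intervals are
#' reverse-complemented. Unstranded (\code{*} / \code{.}) intervals are
#' treated as plus strand.
#'
#' @param genome A \code{DNAStringSet} named by contig.
#' @param gr A \code{GRanges} of intervals to fetch.
#' @return Character vector of sequences, one per interval.
#' @export
fetch_sequence <- function(genome, gr) {
  if (length(gr) == 0L) return(character(0))
  ctg <- as.character(seqnames(gr))
  unknown <- setdiff(unique(ctg), names(genome))
  if (length(unknown) > 0L)
    stop("interval on contig absent from genome: ",
         paste(unknown, collapse = ", "))
  lens <- contig_lengths(genome)
  if (any(start(gr) < 1L) || any(end(gr) > lens[ctg]))
    stop("interval out of contig bounds")
  out <- character(length(gr))
  for (i in seq_along(gr)) {
    s <- subseq(genome[[ctg[i]]], start(gr)[i], end(gr)[i])
    if (as.character(strand(gr))[i] == "-") s <- reverseComplement(s)
    out[i] <- as.character(s)
  }
  out
}

#' Distance to the nearest target interval
#'
#' For each query interval, the gap in bp to the closest target interval on
#' the same contig (0 if they overlap or are bookended), ignoring strand.
#' Queries on contigs with no target get \code{Inf}.
#'
#' @param query,targets \code{GRanges}.
#' @return Numeric vector, one distance per query.
#' @export
nearest_distance <- function(query, targets) {
  if (length(targets) == 0L)
    stop("targets must be non-empty")
  if (length(query) == 0L) return(numeric(0))
  # contigs absent from targets are a supported case (Inf sentinel), so
  # the no-common-seqlevels warning is noise here
  hits <- suppressWarnings(
    distanceToNearest(query, targets, ignore.strand = TRUE))
  out <- rep(Inf, length(query))
  out[queryHits(hits)] <- as.numeric(mcols(hits)$distance)
  out
}

#' Tag set: deduplicated read 5'-end positions
#'
#' The evidence unit of LACE-seq-style data: one record per unique read,
#' keeping only the strand-aware 5'-end crosslink position.
#'
#' @param tags data.frame with columns \code{contig}, \code{pos} (0-based
#'   5'-end position), \code{strand} (\code{+}/\code{-}) and optionally
#'   \code{k} (number of genomic hits of the read, for multi-mapper
#'   weighting; default 1).
#' @param sample_id Sample label.
#' @param condition \code{"control"} or \code{"inhibitor"}.
#' @return An object of class \code{tag_set}.
#' @export
tag_set <- function(tags, sample_id = "sample", condition = "control") {
  stopifnot(is.data.frame(tags))
  if (nrow(tags) == 0L)
    tags <- data.frame(contig = character(0), pos = integer(0),
                       strand = character(0), k = integer(0))
  if (is.null(tags$k)) tags$k <- 1L
  stopifnot(all(c("contig", "pos", "strand", "k") %in% names(tags)))
  if (!all(tags$strand %in% c("+", "-")))
    stop("tag strand must be '+' or '-'")
  if (any(tags$pos < 0L)) stop("tag positions must be >= 0 (0-based)")
  if (any(tags$k < 1L)) stop("multi-hit count k must be >= 1")
  structure(list(sample_id = sample_id, condition = condition,
                 tags = tags[, c("contig", "pos", "strand", "k")]),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat("tag_set '", x$sample_id, "' (", x$condition, "): ",
      nrow(x$tags), " tags on ",
      length(unique(x$tags$contig)), " contig(s)\n", sep = "")
  invisible(x)
}

#' Read 5'-end tags from BED6
#'
#' One BED record per deduplicated read; the record start is the 0-based
#' 5'-end position and the score field carries the read's number of genomic
#' hits \code{k} (0 or missing is read as 1).
#'
#' @param path BED6 path.
#' @inheritParams tag_set
#' @return A \code{\link{tag_set}}.
#' @export
read_tags <- function(path, sample_id = basename(path),
                      condition = "control") {
  gr <- import(path, format = "bed")
  k <- if (!is.null(gr$score)) as.integer(gr$score) else rep(1L, length(gr))
  k[is.na(k) | k < 1L] <- 1L
  tag_set(data.frame(contig = as.character(seqnames(gr)),
                     pos = start(gr) - 1L,
                     strand = as.character(strand(gr)),
                     k = k),
          sample_id = sample_id, condition = condition)
}

#' Write a tag set to BED6
#'
#' @param x A \code{\link{tag_set}}.
#' @param path Output path.
#' @export
write_tags <- function(x, path) {
  t <- x$tags
  df <- data.frame(chrom = t$contig, start = t$pos, end = t$pos + 1L,
                   name = sprintf("%s_tag%06d", x$sample_id, seq_len(nrow(t))),
                   score = t$k, strand = t$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-base polymerase coverage track
#'
#' @param signal Named list of non-negative numeric vectors, one per contig,
#'   at 1-bp resolution.
#' @param polymerase \code{"PolII"} or \code{"PolIII"}.
#' @param condition Condition label.
#' @return An object of class \code{coverage_track} with the raw signal and
#'   its library size (total signal, used for counts-per-million scaling).
#' @export
coverage_track <- function(signal, polymerase = "PolII",
                           condition = "control") {
  stopifnot(is.list(signal), !is.null(names(signal)))
  for (v in signal) {
    if (any(!is.finite(v)) || any(v < 0))
      stop("coverage must be finite and non-negative")
  }
  structure(list(signal = signal,
                 library_size = sum(vapply(signal, sum, 0)),
                 polymerase = polymerase, condition = condition),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track (", x$polymerase, ", ", x$condition, "): ",
      length(x$signal), " contig(s), library size ",
      format(round(x$library_size, 1), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Counts-per-million scale factor of a track
#' @param track A \code{\link{coverage_track}}.
#' @return Multiplier taking raw signal to CPM.
#' @export
cpm_factor <- function(track) {
  if (track$library_size <= 0) stop("empty coverage track")
  1e6 / track$library_size
}

#' Read a bedGraph into a coverage track
#'
#' @param path bedGraph path.
#' @param contig_lengths Named integer vector giving the full contig sizes.
#' @inheritParams coverage_track
#' @return A \code{\link{coverage_track}}.
#' @export
read_bedgraph <- function(path, contig_lengths, polymerase = "PolII",
                          condition = "control") {
  gr <- import(path, format = "bedGraph")
  contig_lengths <- validate_contig_lengths(contig_lengths)
  signal <- lapply(contig_lengths, numeric)
  ctg <- as.character(seqnames(gr))
  for (i in seq_along(gr)) {
    signal[[ctg[i]]][start(gr)[i]:end(gr)[i]] <- gr$score[i]
  }
  coverage_track(signal, polymerase = polymerase, condition = condition)
}

#' Write a coverage track as bedGraph
#'
#' Zero-signal runs are omitted, matching common bedGraph practice.
#'
#' @param track A \code{\link{coverage_track}}.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(track$signal)) {
    v <- track$signal[[ctg]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (any(keep)) {
      df <- data.frame(ctg, starts[keep] - 1L, ends[keep],
                       sprintf("%.17g", r$values[keep]))
      write.table(df, con, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}
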