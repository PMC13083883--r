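#' Genome annotation container
#'
#' Bundles the gene models and transposable-element (TE) instances used by all
#' downstream analyses on a shared coordinate system. Genes carry their
#' transcription start/end sites (TSS/TES, strand-aware) and exon structure;
#' TE instances carry a subfamily label (e.g. \code{B2_Mm1a}) and a repeat
#' family (\code{SINE}, \code{LINE}, \code{LTR} or \code{other}).
#'
#' @param genes A \code{GRanges} with metadata columns \code{gene_id}
#'   (unique character), \code{tss} and \code{tes} (1-based genomic
#'   positions inside the gene span; on the minus strand the TSS is the
#'   right-most base).
#' @param exons A named \code{GRangesList}, one element per \code{gene_id},
#'   exons sorted and non-overlapping within each gene span.
#' @param tes A \code{GRanges} with metadata columns \code{subfamily} and
#'   \code{family}.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return An object of class \code{genome_annotation}.
#' @export
genome_annotation <- function(genes, exons, tes, contig_lengths) {
  stopifnot(is(genes, "GRanges"), is(tes, "GRanges"))
  contig_lengths <- validate_contig_lengths(contig_lengths)
  if (is.null(genes$gene_id) && length(genes) > 0L)
    stop("genes must carry a 'gene_id' metadata column")
  if (anyDuplicated(genes$gene_id))
    stop("gene_ids must be unique; duplicated: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (length(tes) > 0L) {
    if (is.null(tes$subfamily) || is.null(tes$family))
      stop("tes must carry 'subfamily' and 'family' metadata columns")
    if (any(!nzchar(tes$subfamily)))
      stop("TE subfamily labels must be non-empty")
    bad <- setdiff(unique(tes$family), c("SINE", "LINE", "LTR", "other"))
    if (length(bad) > 0L)
      stop("unknown TE family: ", paste(bad, collapse = ", "),
           " (expected SINE, LINE, LTR or other)")
  }
  check_within_contigs(genes, contig_lengths, "gene")
  check_within_contigs(tes, contig_lengths, "TE instance")
  if (length(genes) > 0L) {
    if (!setequal(names(exons), genes$gene_id))
      stop("exons must be a GRangesList named by gene_id")
    exons <- sort(exons[genes$gene_id])
    n_ex <- lengths(exons)
    if (any(n_ex == 0L))
      stop("gene ", genes$gene_id[which(n_ex == 0L)[1L]], " has no exons")
    ex_flat <- unlist(exons, use.names = FALSE)
    gidx <- rep(seq_along(genes), n_ex)
    outside <- start(ex_flat) < start(genes)[gidx] |
      end(ex_flat) > end(genes)[gidx] |
      as.character(seqnames(ex_flat)) != as.character(seqnames(genes))[gidx]
    if (any(outside))
      stop("exon outside gene span for gene ",
           genes$gene_id[gidx[which(outside)[1L]]])
    if (length(ex_flat) > 1L) {
      same_gene <- gidx[-1L] == gidx[-length(gidx)]
      overl <- same_gene &
        start(ex_flat)[-1L] <= end(ex_flat)[-length(ex_flat)]
      if (any(overl))
        stop("overlapping exons for gene ",
             genes$gene_id[gidx[which(overl)[1L]]])
    }
    minus <- as.character(strand(genes)) == "-"
    tss_expect <- ifelse(minus, end(genes), start(genes))
    tes_expect <- ifelse(minus, start(genes), end(genes))
    bad_site <- genes$tss != tss_expect | genes$tes != tes_expect
    if (any(bad_site))
      stop("gene ", genes$gene_id[which(bad_site)[1L]],
           ": tss/tes inconsistent with span and strand")
  } else {
    exons <- GRangesList()
  }
  structure(list(genes = genes, exons = exons, tes = tes,
                 contig_lengths = contig_lengths),
            class = "genome_annotation")
}

validate_contig_lengths <- function(contig_lengths) {
  if (is.null(names(contig_lengths)) || any(!nzchar(names(contig_lengths))))
    stop("contig_lengths must be a named vector")
  if (any(contig_lengths <= 0))
    stop("contig lengths must be positive")
  lens <- as.integer(contig_lengths)
  names(lens) <- names(contig_lengths)
  lens
}

check_within_contigs <- function(gr, contig_lengths, what) {
  if (length(gr) == 0L) return(invisible(NULL))
  ctg <- as.character(seqnames(gr))
  unknown <- setdiff(unique(ctg), names(contig_lengths))
  if (length(unknown) > 0L)
    stop(what, " on unknown contig: ", paste(unknown, collapse = ", "))
  over <- end(gr) > contig_lengths[ctg] | start(gr) < 1L
  if (any(over))
    stop(what, " interval exceeds contig bounds (first offender index ",
         which(over)[1L], ")")
  invisible(NULL)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$contig_lengths), "contigs (",
      format(sum(as.numeric(x$contig_lengths)), big.mark = ","), "bp ),",
      length(x$genes), "genes,", length(x$tes), "TE instances\n")
  if (length(x$tes) > 0L) {
    tab <- sort(table(x$tes$subfamily), decreasing = TRUE)
    cat("  TE subfamilies:",
        paste(names(tab), "(", as.integer(tab), ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read gene and repeat annotation
#'
#' Imports a GTF (gene and exon features) plus a repeat BED6 whose name field
#' encodes \code{"subfamily:family"} into a validated
#' \code{\link{genome_annotation}}. GTF 1-based closed coordinates are kept in
#' the native \code{GRanges} representation; BED input is converted by
#' \pkg{rtracklayer}.
#'
#' @param gtf_path Path to a GTF file with \code{gene} and \code{exon} rows
#'   carrying a \code{gene_id} attribute.
#' @param repeat_bed_path Path to a BED6 of TE instances,
#'   name = \code{"subfamily:family"}.
#' @param contig_lengths Named integer vector of contig lengths (e.g. from the
#'   genome FASTA via \code{\link{read_genome}}).
#' @return A \code{\link{genome_annotation}}.
#' @export
read_annotation <- function(gtf_path, repeat_bed_path, contig_lengths) {
  gtf <- tryCatch(import(gtf_path, format = "gtf"),
                  error = function(e) stop("failed to parse GTF '", gtf_path,
                                           "': ", conditionMessage(e)))
  genes <- gtf[gtf$type == "gene"]
  exons <- gtf[gtf$type == "exon"]
  if (length(genes) > 0L && is.null(genes$gene_id))
    stop("GTF gene rows lack a gene_id attribute")
  genes <- granges_keep(genes, "gene_id")
  genes$tss <- ifelse(as.character(strand(genes)) == "-",
                      end(genes), start(genes))
  genes$tes <- ifelse(as.character(strand(genes)) == "-",
                      start(genes), end(genes))
  exl <- if (length(genes) > 0L) {
    ex <- granges_keep(exons, "gene_id")
    missing_ex <- setdiff(genes$gene_id, unique(ex$gene_id))
    if (length(missing_ex) > 0L)
      stop("genes without exon rows: ", paste(missing_ex, collapse = ", "))
    ex_split <- split(granges(ex), ex$gene_id)
    ex_split[genes$gene_id]
  } else GRangesList()
  tes <- read_repeat_bed(repeat_bed_path)
  genome_annotation(genes = genes, exons = exl, tes = tes,
                    contig_lengths = contig_lengths)
}

granges_keep <- function(gr, cols) {
  out <- granges(gr)
  mcols(out) <- mcols(gr)[, cols, drop = FALSE]
  out
}

#' Read a repeat BED6 with "subfamily:family" names
#'
#' @param path BED6 path.
#' @return \code{GRanges} with \code{subfamily} and \code{family} columns.
#' @export
read_repeat_bed <- function(path) {
  gr <- import(path, format = "bed")
  if (length(gr) == 0L) {
    out <- GRanges()
    mcols(out)$subfamily <- character(0)
    mcols(out)$family <- character(0)
    return(out)
  }
  nm <- gr$name
  parts <- strsplit(nm, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 2L | !nzchar(nm))
  if (length(bad) > 0L)
    stop("repeat BED record ", bad[1L],
         ": name field must be 'subfamily:family', got '", nm[bad[1L]], "'")
  out <- granges(gr)
  mcols(out)$subfamily <- vapply(parts, `[`, "", 1L)
  mcols(out)$family <- vapply(parts, `[`, "", 2L)
  out
}

#' Write TE instances as a repeat BED6
#'
#' @param tes \code{GRanges} with \code{subfamily}/\code{family} columns.
#' @param path Output path.
#' @export
write_repeat_bed <- function(tes, path) {
  df <- data.frame(
    chrom = as.character(seqnames(tes)),
    start = start(tes) - 1L,
    end = end(tes),
    name = paste0(tes$subfamily, ":", tes$family),
    score = 0L,
    strand = as.character(strand(tes)))
  df$strand[df$strand == "*"] <- "."
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
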