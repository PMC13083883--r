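# Independent oracles and tiny fixture builders used across the suite.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(SummarizedExperiment)
})

# O(n^2) all-pairs minimum-gap oracle (0 on overlap), 1-based closed coords
brute_nearest <- function(q_start, q_end, t_start, t_end) {
  vapply(seq_along(q_start), function(i) {
    gaps <- vapply(seq_along(t_start), function(j) {
      if (q_start[i] <= t_end[j] && t_start[j] <= q_end[i]) return(0)
      if (q_end[i] < t_start[j]) t_start[j] - q_end[i] - 1
      else q_start[i] - t_end[j] - 1
    }, 0)
    min(gaps)
  }, 0)
}

# Transitive-closure merge oracle: build the all-pairs adjacency graph
# (gap < merge_distance) and take its connected components — an
# implementation-independent route to the same partition.
brute_cluster <- function(pos, merge_distance = 100L,
                          min_unique_reads = 10L) {
  if (length(pos) == 0L) return(list())
  adj <- abs(outer(pos, pos, "-")) < merge_distance
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
  out <- lapply(unique(comp), function(cc) sort(pos[comp == cc]))
  out <- out[vapply(out, length, 0L) > min_unique_reads]
  out[order(vapply(out, min, 0))]
}

# summit under the caller's tie rule, from a sorted member vector
brute_summit <- function(members, strand) {
  cnt <- table(members)
  best <- as.integer(names(cnt)[cnt == max(cnt)])
  if (strand == "-") max(best) else min(best)
}

# independent median-of-ratios
brute_size_factors <- function(counts) {
  pos <- apply(counts, 1L, function(r) all(r > 0))
  geo <- apply(counts[pos, , drop = FALSE], 1L, function(r)
    exp(mean(log(r))))
  apply(counts[pos, , drop = FALSE], 2L, function(col)
    median(col / geo))
}

# sup over pooled points of |ECDF_a - ECDF_b|
brute_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), 0)))
}

# a small two-gene annotation plus genome used by caller/annotation tests:
# ctg1 is 10 kb; geneA (+) 1001..4000 with exons 1001..2000 and 2501..4000;
# geneB (-) 6001..9000 single exon; one B2 at 1801..1980 (inside geneA's
# first exon), one MERVL at 5000..5600 (intergenic).
make_test_ann <- function() {
  genes <- GRanges("ctg1", IRanges(c(1001, 6001), c(4000, 9000)),
                   strand = c("+", "-"))
  genes$gene_id <- c("geneA", "geneB")
  genes$tss <- c(1001, 9000)
  genes$tes <- c(4000, 6001)
  exons <- GRangesList(
    geneA = GRanges("ctg1", IRanges(c(1001, 2501), c(2000, 4000)),
                    strand = "+"),
    geneB = GRanges("ctg1", IRanges(6001, 9000), strand = "-"))
  tes <- GRanges("ctg1", IRanges(c(1801, 5000), c(1980, 5600)),
                 strand = "+")
  tes$subfamily <- c("B2_Mm1a", "MERVL-int")
  tes$family <- c("SINE", "LTR")
  genome_annotation(genes, exons, tes, c(ctg1 = 10000L))
}

make_test_genome <- function(seed = 42L, len = 10000L) {
  set.seed(seed)
  DNAStringSet(c(ctg1 = paste(sample(c("A", "C", "G", "T"), len,
                                     replace = TRUE), collapse = "")))
}

# uniform-signal coverage track over the test annotation's contig
flat_track <- function(value = 2, len = 10000L, ...) {
  coverage_track(list(ctg1 = rep(value, len)), ...)
}

make_tags <- function(pos, strand = "+", contig = "ctg1", k = 1L, ...) {
  tag_set(data.frame(contig = contig, pos = as.integer(pos),
                     strand = strand, k = k), ...)
}
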