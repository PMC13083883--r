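test_that("single-linkage merging and the unique-read threshold are strict", {
  # 6 tags at 100, 4 at 150, 2 at 260: gap 50 merges, gap 110 does not
  tags <- make_tags(c(rep(100, 6), rep(150, 4), rep(260, 2)))
  pre <- cluster_tags(tags, caller_params(min_unique_reads = 1L))
  expect_equal(nrow(pre), 2L)
  expect_equal(pre$start, c(100L, 260L))
  expect_equal(pre$end, c(151L, 261L))
  expect_equal(pre$unique_reads, c(10L, 2L))
  expect_equal(pre$summit, c(100L, 260L))
  # at the default "more than 10" rule both clusters go (10 is not > 10)
  expect_equal(nrow(cluster_tags(tags)), 0L)

  twelve <- make_tags(rep(500, 12))
  cl <- cluster_tags(twelve)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 500L)
  expect_equal(cl$end, 501L)
  expect_equal(cl$summit, 500L)
  expect_equal(cl$unique_reads, 12L)

  # a gap of exactly merge_distance does not merge
  tags2 <- make_tags(c(rep(0, 12), rep(100, 12)))
  expect_equal(nrow(cluster_tags(tags2)), 2L)
  expect_equal(nrow(cluster_tags(tags2,
                                 caller_params(merge_distance = 101L))), 1L)
})

test_that("clustering matches the transitive-closure oracle on random sets", {
  set.seed(11)
  params <- caller_params(min_unique_reads = 1L)
  for (rep in 1:60) {
    n <- sample(1:50, 1)
    pos <- sample(0:9999, n, replace = TRUE)
    tags <- make_tags(pos)
    got <- cluster_tags(tags, params)
    want <- brute_cluster(pos, 100L, 1L)
    expect_equal(nrow(got), length(want))
    for (i in seq_along(want)) {
      expect_equal(got$start[i], min(want[[i]]))
      expect_equal(got$end[i], max(want[[i]]) + 1L)
      expect_equal(got$unique_reads[i], length(want[[i]]))
      expect_equal(got$summit[i], brute_summit(want[[i]], "+"))
    }
  }
})

test_that("caller output is invariant to tag order and strands never merge", {
  set.seed(12)
  pos <- sample(0:5000, 40, replace = TRUE)
  strand <- sample(c("+", "-"), 40, replace = TRUE)
  tags <- make_tags(pos, strand = strand)
  sh <- sample(40)
  tags_sh <- make_tags(pos[sh], strand = strand[sh])
  p <- caller_params(min_unique_reads = 1L)
  expect_equal(cluster_tags(tags, p), cluster_tags(tags_sh, p))
  by_strand <- cluster_tags(tags, p)
  expect_true(all(by_strand$strand %in% c("+", "-")))
  # plus and minus tags at identical positions form separate clusters
  mixed <- make_tags(rep(100, 24), strand = rep(c("+", "-"), 12))
  expect_equal(nrow(cluster_tags(mixed)), 2L)
})

test_that("summit ties break toward the transcript 5' end", {
  p <- caller_params(min_unique_reads = 1L)
  plus <- make_tags(c(10, 10, 40, 40))
  expect_equal(cluster_tags(plus, p)$summit, 10L)
  minus <- make_tags(c(10, 10, 40, 40), strand = "-")
  expect_equal(cluster_tags(minus, p)$summit, 40L)
})

test_that("raising thresholds never adds clusters; shrinking merge distance never merges more", {
  set.seed(13)
  pos <- sample(0:3000, 80, replace = TRUE)
  tags <- make_tags(pos)
  for (thr in c(1L, 3L, 6L, 12L)) {
    lo <- cluster_tags(tags, caller_params(min_unique_reads = thr))
    hi <- cluster_tags(tags, caller_params(min_unique_reads = thr + 2L))
    expect_lte(nrow(hi), nrow(lo))
  }
  # with no read threshold, shrinking the merge distance can only split
  for (md in c(20L, 50L, 100L)) {
    wide <- cluster_tags(tags, caller_params(merge_distance = md,
                                             min_unique_reads = 0L))
    narrow <- cluster_tags(tags, caller_params(merge_distance = md %/% 2L,
                                               min_unique_reads = 0L))
    expect_gte(nrow(narrow), nrow(wide))
    expect_equal(sum(narrow$unique_reads), sum(wide$unique_reads))
  }
})

test_that("background enrichment reproduces the density-ratio arithmetic", {
  # 12 tags in a 10-bp cluster, 5 tags elsewhere in the 500-bp window
  pos <- c(rep(1000, 6), rep(1009, 6), 800, 850, 900, 1100, 1200)
  tags <- make_tags(pos)
  cl <- data.frame(contig = "ctg1", start = 1000L, end = 1010L,
                   strand = "+", summit = 1000L, unique_reads = 12L)
  sc <- score_enrichment(cl, tags, caller_params(),
                         contig_lens = c(ctg1 = 10000L))
  expect_equal(sc$signal_enrichment, (12 / 10) / (5 / 490))

  # perfectly uniform tags score any cluster span at exactly 1
  unif <- make_tags(rep(0:9999, each = 2))
  clu <- data.frame(contig = "ctg1", start = 1000L, end = 1010L,
                    strand = "+", summit = 1005L, unique_reads = 20L)
  scu <- score_enrichment(clu, unif, contig_lens = c(ctg1 = 10000L))
  expect_equal(scu$signal_enrichment, 1)

  # no background tags: infinity sentinel
  lone <- make_tags(rep(5000, 12))
  cl2 <- cluster_tags(lone)
  sc2 <- score_enrichment(cl2, lone, contig_lens = c(ctg1 = 10000L))
  expect_identical(sc2$signal_enrichment, Inf)
})

test_that("inhibitor-control subtraction follows the pseudocount ratio policy", {
  treat <- make_tags(rep(100, 20), sample_id = "t", condition = "control")
  ctrl_empty <- make_tags(sample(5000:9000, 20), sample_id = "c",
                          condition = "inhibitor")
  cl <- cluster_tags(treat)
  out <- subtract_control(cl, treat, ctrl_empty)
  # 20 treatment tags, 0 control tags, equal libraries: ratio 20/1
  expect_equal(out$control_ratio, 20)
  expect_equal(nrow(out), 1L)

  # identical treatment and control: ratios ~ 1, removed at fold 2
  same <- make_tags(rep(100, 20), condition = "inhibitor")
  gone <- subtract_control(cl, treat, same)
  expect_equal(nrow(gone), 0L)
  kept <- subtract_control(cl, treat, same,
                           caller_params(control_fold = 0))
  expect_equal(nrow(kept), 1L)
  expect_lt(abs(kept$control_ratio - 1), 0.1)

  empty <- tag_set(data.frame(), condition = "inhibitor")
  expect_error(subtract_control(cl, treat, empty), "zero-size library")
})

test_that("DRACH filtering matches the 18-pentamer consensus on the cluster strand", {
  expect_length(drach_pentamers(), 18L)
  # a window holding GGACT passes, an A-free window cannot
  genome <- DNAStringSet(c(ctg1 = paste0("TTGGACTTT",
                                         strrep("C", 91))))
  cl <- data.frame(contig = "ctg1", start = 0L, end = 9L, strand = "+",
                   summit = 4L, unique_reads = 12L)
  out <- drach_filter(cl, genome, keep_failing = TRUE)
  expect_true(out$drach_pass)
  cl_c <- data.frame(contig = "ctg1", start = 40L, end = 48L, strand = "+",
                     summit = 44L, unique_reads = 12L)
  out_c <- drach_filter(cl_c, genome, caller_params(upstream_extension = 0L),
                        keep_failing = TRUE)
  expect_false(out_c$drach_pass)
  expect_equal(nrow(drach_filter(cl_c, genome,
                                 caller_params(upstream_extension = 0L))),
               0L)

  # minus-strand search uses the reverse complement: genome AGTCC == GGACT
  genome_m <- DNAStringSet(c(ctg1 = paste0("TTAGTCCTT", strrep("G", 91))))
  cl_m <- data.frame(contig = "ctg1", start = 0L, end = 9L, strand = "-",
                     summit = 4L, unique_reads = 12L)
  expect_true(drach_filter(cl_m, genome_m, keep_failing = TRUE)$drach_pass)
  expect_false(drach_filter(transform(cl_m, strand = "+"), genome_m,
                            keep_failing = TRUE)$drach_pass)

  # N anywhere in the only candidate pentamer scores no match
  genome_n <- DNAStringSet(c(ctg1 = paste0("TTGGNCTTT", strrep("C", 91))))
  expect_false(drach_filter(cl, genome_n, keep_failing = TRUE)$drach_pass)
})

test_that("upstream extension is strand-oriented and clipped at contig edges", {
  # DRACH sits 20 nt upstream of the cluster on the plus strand
  genome <- DNAStringSet(c(ctg1 = paste0(strrep("C", 30), "GGACT",
                                         strrep("C", 65))))
  cl <- data.frame(contig = "ctg1", start = 50L, end = 60L, strand = "+",
                   summit = 55L, unique_reads = 12L)
  expect_true(drach_filter(cl, genome, caller_params(), TRUE)$drach_pass)
  expect_false(drach_filter(cl, genome,
                            caller_params(upstream_extension = 10L),
                            TRUE)$drach_pass)
  # a cluster at the very contig start survives clipping
  cl_edge <- data.frame(contig = "ctg1", start = 2L, end = 10L,
                        strand = "+", summit = 5L, unique_reads = 12L)
  expect_false(drach_filter(cl_edge, genome, caller_params(),
                            TRUE)$drach_pass)
})

test_that("cluster annotation applies exon > intron > TE > intergenic precedence", {
  ann <- make_test_ann()
  mk <- function(summit, strand = "+") {
    data.frame(contig = "ctg1", start = summit - 5L, end = summit + 5L,
               strand = strand, summit = summit, unique_reads = 12L)
  }
  # summit inside geneA exon1 AND inside the B2 copy
  both <- annotate_clusters(mk(1850L), ann)
  expect_equal(both$gene_id, "geneA")
  expect_equal(both$feature_class, "exon")
  expect_equal(both$te_subfamily, "B2_Mm1a")
  # intronic summit (between geneA exons)
  intron <- annotate_clusters(mk(2200L), ann)
  expect_equal(intron$feature_class, "intron")
  expect_equal(intron$gene_id, "geneA")
  # TE outside genes keeps its subfamily, class intergenic
  te_only <- annotate_clusters(mk(5200L), ann)
  expect_equal(te_only$feature_class, "intergenic")
  expect_equal(te_only$te_subfamily, "MERVL-int")
  # bare intergenic
  none <- annotate_clusters(mk(9700L), ann)
  expect_equal(none$feature_class, "intergenic")
  expect_true(is.na(none$te_subfamily))
  # tags on the wrong strand do not annotate to the gene
  wrong <- annotate_clusters(mk(1850L, strand = "-"), ann)
  expect_true(is.na(wrong$gene_id))
})

test_that("target sets use exonic clusters only and overlap statistics are exact", {
  ann <- make_test_ann()
  cl <- data.frame(contig = "ctg1",
                   start = c(1845L, 2195L), end = c(1855L, 2205L),
                   strand = "+", summit = c(1850L, 2200L),
                   unique_reads = 12L)
  annd <- annotate_clusters(cl, ann)
  expect_equal(target_gene_set(annd), "geneA")  # intronic hit ignored
  expect_equal(unname(target_overlap(c("a", "b"), c("a", "b"))),
               c(1, 1, 2))
  expect_equal(unname(target_overlap(c("a"), c("b"))), c(0, 0, 0))
})

test_that("empty tag sets yield empty cluster tables, not errors", {
  empty <- tag_set(data.frame())
  expect_equal(nrow(cluster_tags(empty)), 0L)
  genome <- make_test_genome()
  cl0 <- cluster_tags(empty)
  cl0 <- score_enrichment(cl0, empty)
  cl0 <- drach_filter(cl0, genome)
  expect_equal(nrow(cl0), 0L)
})
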