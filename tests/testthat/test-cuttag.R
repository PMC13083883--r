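test_that("metagene profiles respond correctly to flat and impulse signal", {
  ann <- make_test_ann()
  tr <- flat_track(2)
  prof <- metagene_profile(tr, ann, "TSS", flank = 500L, bins = 50L)
  cpm <- 2 * 1e6 / tr$library_size
  expect_equal(prof$mean, rep(cpm, 50L), tolerance = 1e-12)
  expect_equal(prof$n_genes, 2L)
  # a delta at each TSS lands in the single anchor bin, flipped for minus
  sig <- rep(0, 10000)
  sig[1001] <- 100  # geneA TSS (+)
  sig[9000] <- 100  # geneB TSS (-)
  tr2 <- coverage_track(list(ctg1 = sig))
  prof2 <- metagene_profile(tr2, ann, "TSS", flank = 500L, bins = 50L)
  hit <- which(prof2$mean > 0)
  expect_length(hit, 1L)
  expect_equal(prof2$position[hit], 10)  # first downstream bin centre
  # genes whose flank would leave the contig are excluded and counted
  prof3 <- metagene_profile(tr, ann, "TES", flank = 2000L, bins = 100L)
  expect_equal(prof3$n_genes + prof3$n_excluded, 2L)
})

test_that("pausing index is exact on constructed signal and scale-invariant", {
  ann <- make_test_ann()
  # geneA (+): promoter 951..1300 at 10, body 1301..4000 at 2
  sig <- rep(0, 10000)
  sig[951:1300] <- 10
  sig[1301:4000] <- 2
  # geneB (-): promoter 8701..9050 at 6, body 6001..8700 at 3
  sig[8701:9050] <- 6
  sig[6001:8700] <- 3
  tr <- coverage_track(list(ctg1 = sig))
  pi_tab <- pausing_index(tr, ann)
  expect_equal(pi_tab$pi[pi_tab$gene_id == "geneA"], 5)
  expect_equal(pi_tab$pi[pi_tab$gene_id == "geneB"], 2)
  # uniform coverage: pi == 1
  expect_equal(pausing_index(flat_track(3), ann)$pi, c(1, 1))
  # doubling the track leaves the index unchanged
  tr2 <- coverage_track(list(ctg1 = 2 * sig))
  expect_equal(pausing_index(tr2, ann)$pi, pi_tab$pi)
  # zero body signal excludes the gene rather than dividing by zero
  sig0 <- rep(0, 10000); sig0[951:1300] <- 10
  pi0 <- pausing_index(coverage_track(list(ctg1 = sig0)), ann)
  expect_false("geneA" %in% pi0$gene_id)
  # short genes are excluded
  short_ann <- make_test_ann()
  expect_equal(nrow(pausing_index(flat_track(1), short_ann,
                                  min_length = 5000L)), 0L)
})

test_that("differential regions union-merge peaks and count signal per region", {
  # union semantics
  ann <- make_test_ann()
  p1 <- GRanges("ctg1", IRanges(c(1, 51), c(100, 150)))
  p2 <- GRanges("ctg1", IRanges(c(1, 300), c(100, 400)))
  tr_a <- list(flat_track(2), flat_track(2.2))
  tr_b <- list(flat_track(4), flat_track(4.4))
  dr <- differential_regions(c(tr_a, tr_b), list(p1, p2),
                             rep(c("ctrl", "kd"), each = 2))
  expect_equal(dr$start, c(0L, 299L))
  expect_equal(dr$end, c(150L, 400L))
  # identical peak sets: the union is the set itself
  dr2 <- differential_regions(c(tr_a, tr_b), list(p2, p2),
                              rep(c("ctrl", "kd"), each = 2))
  expect_equal(nrow(dr2), 2L)
  # flat tracks differing only in depth: normalisation kills the contrast
  expect_equal(dr$log2fc, c(0, 0), tolerance = 1e-9)
  expect_error(differential_regions(tr_a, list(p1), c("a", "a")),
               "two levels")

  # count step equals a brute-force per-base sum
  set.seed(51)
  sig <- runif(10000)
  trr <- coverage_track(list(ctg1 = sig))
  reg <- GRanges("ctg1", IRanges(c(10, 500, 900), c(60, 700, 950)))
  dr3 <- differential_regions(list(trr, trr, flat_track(1), flat_track(1)),
                              list(reg),
                              rep(c("a", "b"), each = 2))
  counts <- attr(dr3, "counts")
  for (i in 1:3) {
    expect_equal(unname(counts[i, 1]),
                 sum(sig[start(reg)[i]:end(reg)[i]]))
    expect_equal(unname(counts[i, 3]),
                 end(reg)[i] - start(reg)[i] + 1)
  }
})

test_that("B2 distance bins partition regions and follow the overlap rule", {
  ann <- make_test_ann()  # B2 at 1801..1980
  reg <- GRanges("ctg1", IRanges(c(1900, 4981, 7500), c(1950, 5080, 7600)))
  lfc <- c(-0.5, -0.2, 0.1)
  bs <- b2_distance_stratification(reg, lfc, ann)
  expect_equal(as.character(bs$table$bin),
               c("0", "(0,5]", "(5,10]"))
  expect_equal(bs$table$distance, c(0, 3000, 5519))
  expect_equal(sum(bs$summary$n), 3L)
  expect_true(all(levels(bs$table$bin) ==
                    c("0", "(0,5]", "(5,10]", "(10,20]", "(20,50]",
                      "(50,100]", ">100")))
  expect_error(b2_distance_stratification(reg, lfc, ann,
                                          b2_pattern = "^ZZZ"),
               "no B2 instances")
  expect_error(b2_distance_stratification(reg, lfc[1:2], ann))
})

test_that("repeat-locus metagenes rescale bodies and keep flanks absolute", {
  ann <- make_test_ann()
  inst <- ann$tes[ann$tes$subfamily == "B2_Mm1a"]  # 1801..1980
  flat <- flat_track(2)
  prof <- repeat_locus_metagene(flat, inst, flank = 500L, body_bins = 20L,
                                flank_bin = 50L)
  cpm <- 2 * 1e6 / flat$library_size
  expect_equal(prof$mean, rep(cpm, 40L), tolerance = 1e-12)
  expect_equal(prof$region,
               rep(c("upstream", "body", "downstream"), c(10, 20, 10)))
  # signal confined to the instance body: zero flanks, positive body
  sig <- rep(0, 10000); sig[1801:1980] <- 5
  tr <- coverage_track(list(ctg1 = sig))
  prof2 <- repeat_locus_metagene(tr, inst, flank = 500L, body_bins = 20L,
                                 flank_bin = 50L)
  expect_true(all(prof2$mean[prof2$region == "body"] > 0))
  expect_true(all(prof2$mean[prof2$region != "body"] == 0))
  expect_error(repeat_locus_metagene(tr, inst[0]), "no instances")
})

test_that("simulated Pol III concentrates on B2 bodies at the configured ratio", {
  cfg <- sim_config(seed = 9, n_contigs = 1L, contig_length = 200000L,
                    n_genes = 20L,
                    n_te = c(B2_Mm1a = 12L, B2_Mm1t = 6L, "MERVL-int" = 6L,
                             L1Md_A = 6L),
                    coverage_noise_sd = 0)
  sim <- simulate_genome(cfg)
  tr <- simulate_coverage(cfg, sim$truth, "control", "PolIII")
  b2 <- sim$ann$tes[grepl("^B2", sim$ann$tes$subfamily)]
  prof <- repeat_locus_metagene(tr, b2, flank = 500L, body_bins = 20L,
                                flank_bin = 50L)
  body <- mean(prof$mean[prof$region == "body"])
  cpm <- cpm_factor(tr)
  # body density equals the configured Pol III level; flanks sit between
  # the background floor and the body (B2 copies cluster in islands, so
  # flanks cross neighbouring copies)
  expect_lt(abs(body - cfg$pol3_b2_density * cpm) /
              (cfg$pol3_b2_density * cpm), 0.10)
  flank <- mean(prof$mean[prof$region != "body"])
  expect_lt(flank, body)
  expect_gt(flank, cfg$pol3_background * cpm)
})
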