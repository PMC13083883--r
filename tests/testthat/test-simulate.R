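# A small, fast configuration shared by generator tests.
small_cfg <- function(seed = 1L, n_genes = 40L, ...) {
  sim_config(seed = seed, n_contigs = 1L, contig_length = 200000L,
             n_genes = n_genes,
             n_te = c(B2_Mm1a = 12L, B2_Mm1t = 6L, "MERVL-int" = 6L,
                      L1Md_A = 6L), ...)
}

test_that("the generator is byte-deterministic under a fixed seed", {
  s1 <- simulate_genome(small_cfg(seed = 5L))
  s2 <- simulate_genome(small_cfg(seed = 5L))
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth$genes, s2$truth$genes)
  expect_identical(s1$truth$sites, s2$truth$sites)
  expect_identical(as.data.frame(s1$ann$tes), as.data.frame(s2$ann$tes))
  s3 <- simulate_genome(small_cfg(seed = 6L))
  expect_false(identical(as.character(s1$genome),
                         as.character(s3$genome)))

  t1 <- simulate_tags(small_cfg(seed = 5L), s1$truth, "control")
  t2 <- simulate_tags(small_cfg(seed = 5L), s2$truth, "control")
  expect_identical(t1$tags, t2$tags)
})

test_that("a gene-free configuration still yields a valid annotation", {
  sim <- simulate_genome(small_cfg(n_genes = 0L))
  expect_length(sim$ann$genes, 0L)
  expect_gt(length(sim$ann$tes), 0L)
  # no gene-anchored sites; B2-anchored ones are still planted
  expect_equal(sum(sim$truth$sites$origin == "gene"), 0L)
})

test_that("infeasible packing is rejected", {
  expect_error(simulate_genome(sim_config(n_contigs = 1L,
                                          contig_length = 20000L,
                                          n_genes = 20L)),
               "infeasible packing")
})

test_that("every planted summit sits on a DRACH occurrence on its strand", {
  sim <- simulate_genome(small_cfg())
  sites <- sim$truth$sites
  expect_gt(nrow(sites), 0L)
  win <- GRanges(sites$contig,
                 IRanges(sites$summit - 1L, sites$summit + 3L),
                 strand = sites$strand)
  seqs <- fetch_sequence(sim$genome, win)
  expect_true(all(grepl("[GAT][AG]AC[ATC]", seqs)))
  # and reader targets are always m6A-marked
  g <- sim$truth$genes
  expect_true(all(g$m6a[g$df_target]))
})

test_that("tag counts around summits match the Poisson rate", {
  cfg <- sim_config(seed = 1L, n_genes = 250L, fraction_m6a = 1,
                    fraction_df_target_given_m6a = 0.8,
                    te_site_fraction = 0)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$truth$sites), 200L)
  tags <- simulate_tags(cfg, sim$truth, "control")
  s <- sim$truth$sites
  n_near <- vapply(seq_len(nrow(s)), function(i) {
    sum(tags$tags$contig == s$contig[i] & tags$tags$strand == s$strand[i] &
          abs(tags$tags$pos - s$summit[i]) <= 25L)
  }, 0L)
  # expected: lambda truncated to +/-25 bp of jitter, plus a sliver of
  # stranded background over the 51-bp window
  expected <- cfg$lambda_signal *
    (pnorm(25.5, 0, cfg$tag_jitter_sd) - pnorm(-25.5, 0, cfg$tag_jitter_sd)) +
    cfg$lambda_background / 2 * 51
  se3 <- 3 * sqrt(cfg$lambda_signal / nrow(s))
  expect_lt(abs(mean(n_near) - expected), se3)
})

test_that("lambda_signal = 0 leaves control and inhibitor statistically identical", {
  cfg <- small_cfg(lambda_signal = 0)
  sim <- simulate_genome(cfg)
  ctrl <- simulate_tags(cfg, sim$truth, "control", seed = 101L)
  inh <- simulate_tags(cfg, sim$truth, "inhibitor", seed = 102L)
  expected <- cfg$lambda_background * cfg$contig_length
  expect_lt(abs(nrow(ctrl$tags) - expected), 4 * sqrt(expected))
  expect_lt(abs(nrow(inh$tags) - expected), 4 * sqrt(expected))
})

test_that("noise-free counts with equal libraries equal the rounded means", {
  cfg <- small_cfg(nb_dispersion = 0, te_dispersion = 0,
                   lib_range = c(1, 1))
  tab <- simulate_gene_table(cfg)
  se <- simulate_counts(cfg, list(genes = tab, te = NULL))
  counts <- assay(se, "counts")
  cond <- colData(se)$condition
  ctrl_cols <- which(cond == "control")
  expect_equal(unname(counts[, ctrl_cols[1]]), round(tab$base_mean))
  # replicates are identical in the noise-free limit
  expect_equal(counts[, ctrl_cols[1]], counts[, ctrl_cols[2]])
  # the planted shift appears only in the kd_DRB arm
  kd_drb <- which(cond == "kd_DRB")[1]
  drb <- which(cond == "DRB")[1]
  tgt <- tab$df_target
  expect_equal(unname(counts[tgt, kd_drb]),
               round(tab$base_mean[tgt] * 2^cfg$decay_shift_log2))
  expect_equal(counts[!tgt, kd_drb], counts[!tgt, drb])
})

test_that("stage counts follow each gene's class template", {
  cfg <- small_cfg(nb_dispersion = 0, lib_range = c(1, 1))
  tab <- simulate_gene_table(cfg)
  se <- simulate_stage_counts(cfg, list(genes = tab))
  counts <- assay(se, "counts")
  stage <- colData(se)$stage
  means <- vapply(cfg$stages, function(s)
    rowMeans(counts[, stage == s, drop = FALSE]), numeric(nrow(counts)))
  tmpl <- stage_templates()
  cors <- vapply(seq_len(nrow(tab)), function(i) {
    cor(means[i, ], tmpl[tab$stage_class[i], ])
  }, 0)
  expect_gt(min(cors), 0.99)
})

test_that("simulated profile sets carry their true class labels", {
  sp <- simulate_stage_profiles(n_per_class = 5L, noise_sd = 0.2, seed = 3L)
  expect_equal(nrow(sp$profiles), 13L * 5L)
  expect_equal(as.integer(table(sp$truth)), rep(5L, 13L))
  sp2 <- simulate_stage_profiles(n_per_class = 5L, noise_sd = 0.2,
                                 seed = 3L)
  expect_identical(sp$profiles, sp2$profiles)
})

test_that("noise-free coverage realises the planted pausing and cis effects", {
  cfg <- small_cfg(coverage_noise_sd = 0)
  sim <- simulate_genome(cfg)
  ctrl <- simulate_coverage(cfg, sim$truth, "control", "PolII")
  kd <- simulate_coverage(cfg, sim$truth, "kd", "PolII")
  pi_c <- pausing_index(ctrl, sim$ann)
  expect_true(all(abs(pi_c$pi - cfg$pausing_factor) < 1e-9))
  # kd depresses genes near B2 by exactly 2^b2_cis_effect, leaves the rest
  g <- sim$truth$genes
  ggr <- GRanges(g$contig, IRanges(g$start, g$end))
  b2 <- sim$truth$te[grepl("^B2", sim$truth$te$subfamily), ]
  d <- nearest_distance(ggr, GRanges(b2$contig,
                                     IRanges(b2$start, b2$end)))
  mid_val <- function(track, i) {
    track$signal[[g$contig[i]]][(g$start[i] + g$end[i]) %/% 2]
  }
  for (i in seq_len(nrow(g))) {
    ratio <- mid_val(kd, i) / mid_val(ctrl, i)
    if (d[i] <= cfg$b2_cis_radius) {
      expect_equal(ratio, 2^cfg$b2_cis_effect)
    } else {
      expect_equal(ratio, 1)
    }
  }
})

test_that("Pol III coverage concentrates on B2 bodies", {
  cfg <- small_cfg(coverage_noise_sd = 0)
  sim <- simulate_genome(cfg)
  tr <- simulate_coverage(cfg, sim$truth, "control", "PolIII")
  b2 <- sim$truth$te[grepl("^B2", sim$truth$te$subfamily), ][1, ]
  body <- tr$signal[[b2$contig]][b2$start:b2$end]
  expect_true(all(body == cfg$pol3_b2_density))
  away <- tr$signal[[b2$contig]][b2$end + 5000L]
  expect_equal(away, cfg$pol3_background)
})
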