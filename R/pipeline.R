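#' Write a simulated genome annotation as GTF
#'
#' @param ann A \code{\link{genome_annotation}}.
#' @param path Output path.
#' @export
write_gtf <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ann$genes)) {
    g <- ann$genes[i]
    attrs <- sprintf('gene_id "%s";', g$gene_id)
    writeLines(paste(as.character(seqnames(g)), "ythdfpipe", "gene",
                     start(g), end(g), ".", as.character(strand(g)), ".",
                     attrs, sep = "\t"), con)
    ex <- ann$exons[[g$gene_id]]
    for (j in seq_along(ex)) {
      writeLines(paste(as.character(seqnames(ex))[j], "ythdfpipe", "exon",
                       start(ex)[j], end(ex)[j], ".",
                       as.character(strand(ex))[j], ".", attrs, sep = "\t"),
                 con)
    }
  }
  invisible(path)
}

#' m6A peaks of the ground truth as a GRanges
#'
#' @param truth Ground truth from \code{\link{simulate_genome}}.
#' @return \code{GRanges} of peaks.
#' @export
m6a_peak_ranges <- function(truth) {
  p <- truth$m6a_peaks
  if (nrow(p) == 0L) return(GRanges())
  GRanges(p$contig, IRanges(p$start + 1L, p$end))
}

write_m6a_bed <- function(truth, path) {
  p <- truth$m6a_peaks
  df <- data.frame(p$contig, p$start, p$end,
                   paste0("m6a_", p$gene_id), 0L, ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_counts_tsv <- function(se, path) {
  mat <- assay(se, "counts")
  df <- cbind(data.frame(feature = rownames(mat)), as.data.frame(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- as.data.frame(colData(se))
  meta <- cbind(data.frame(sample = rownames(meta)), meta)
  write.table(meta, sub("\\.tsv$", "_samples.tsv", path), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-data pipeline
#'
#' Generates a seeded synthetic dataset and runs every analysis stage over
#' it: binding-site calling with inhibitor-control subtraction and DRACH
#' filtering, TE binding enrichment and differential subfamily expression,
#' the stratified decay/stability report, stage-pattern classification, and
#' the Pol II pausing / B2-distance analyses. All outputs plus a manifest
#' (parameters and MD5 hashes of every written file) go to \code{out_dir}.
#'
#' @param config A \code{\link{sim_config}}, or a path to a YAML file whose
#'   keys are \code{sim_config} arguments.
#' @param out_dir Output directory (created).
#' @param write_files Write data and result files (TSV/BED/GTF/FASTA);
#'   switch off to get just the in-memory result list.
#' @return (Invisibly) a list with every stage's result tables.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         write_files = !is.null(out_dir)) {
  if (is.character(config)) {
    vals <- yaml::read_yaml(config)
    unknown <- setdiff(names(vals), names(formals(sim_config)))
    if (length(unknown) > 0L)
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    config <- do.call(sim_config, vals)
  }
  stopifnot(inherits(config, "sim_config"))
  if (write_files) {
    stopifnot(!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  cfg <- config
  sim <- simulate_genome(cfg)
  ann <- sim$ann; truth <- sim$truth

  tags_ctrl <- simulate_tags(cfg, truth, "control")
  tags_inh <- simulate_tags(cfg, truth, "inhibitor")
  clusters <- call_binding_sites(tags_ctrl, tags_inh, sim$genome, ann)
  targets <- target_gene_set(clusters)

  te_enr <- te_enrichment(tags_ctrl, ann, background = "genomic")
  counts <- simulate_counts(cfg, truth)
  cond <- colData(counts)$condition
  te_rows <- rowData(counts)$feature_type == "te"
  drb_arm <- cond %in% c("DRB", "kd_DRB")
  sf_all <- size_factors(assay(counts)[, drb_arm, drop = FALSE])
  te_diff <- te_differential(assay(counts)[te_rows, drb_arm, drop = FALSE],
                             factor(cond[drb_arm],
                                    levels = c("DRB", "kd_DRB")),
                             sf = sf_all)

  strata <- stratify_features(ann, m6a_peak_ranges(truth), targets)
  gene_counts <- counts[rowData(counts)$feature_type == "gene", ]
  decay <- stability_report(gene_counts, strata,
                            group_a = which(cond == "DRB"),
                            group_b = which(cond == "kd_DRB"))

  stage_se <- simulate_stage_counts(cfg, truth)
  profiles <- build_profiles(stage_se, colData(stage_se)$stage,
                             stages = cfg$stages)
  modules <- cluster_profiles(profiles)
  classes <- assign_classes(modules)

  pol2_ctrl <- lapply(seq_len(cfg$n_replicates), function(r)
    simulate_coverage(cfg, truth, "control", "PolII", replicate = r))
  pol2_kd <- lapply(seq_len(cfg$n_replicates), function(r)
    simulate_coverage(cfg, truth, "kd", "PolII", replicate = r))
  pi_tab <- pausing_index(pol2_ctrl[[1L]], ann)
  gene_regions <- granges(ann$genes)
  diff_reg <- differential_regions(c(pol2_ctrl, pol2_kd),
                                   list(gene_regions),
                                   factor(rep(c("control", "kd"),
                                              each = cfg$n_replicates),
                                          levels = c("control", "kd")))
  reg_gr <- GRanges(diff_reg$contig,
                    IRanges(diff_reg$start + 1L, diff_reg$end))
  b2_strat <- b2_distance_stratification(reg_gr, diff_reg$log2fc, ann)

  res <- list(config = cfg, truth = truth, clusters = clusters,
              targets = targets, te_enrichment = te_enr,
              te_differential = te_diff, stability = decay,
              stage_classes = classes, pausing = pi_tab,
              differential_regions = diff_reg,
              b2_distance = b2_strat)

  if (write_files) {
    writeXStringSet(sim$genome, file.path(out_dir, "genome.fa"))
    write_gtf(ann, file.path(out_dir, "genes.gtf"))
    write_repeat_bed(ann$tes, file.path(out_dir, "repeats.bed"))
    write_tags(tags_ctrl, file.path(out_dir, "tags_control.bed"))
    write_tags(tags_inh, file.path(out_dir, "tags_inhibitor.bed"))
    write_m6a_bed(truth, file.path(out_dir, "m6a_peaks.bed"))
    write_counts_tsv(counts, file.path(out_dir, "counts_decay.tsv"))
    write_counts_tsv(stage_se, file.path(out_dir, "counts_stages.tsv"))
    write_bedgraph(pol2_ctrl[[1L]],
                   file.path(out_dir, "pol2_control_rep1.bedGraph"))
    write_bedgraph(pol2_kd[[1L]],
                   file.path(out_dir, "pol2_kd_rep1.bedGraph"))
    write_clusters(clusters, file.path(out_dir, "binding_clusters.tsv"))
    write.table(te_enr, file.path(out_dir, "te_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(te_diff, file.path(out_dir, "te_differential.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(decay$log2fc, file.path(out_dir, "stability_log2fc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(decay$tests, file.path(out_dir, "stability_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene_id = names(classes), class = classes),
                file.path(out_dir, "stage_classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(pi_tab, file.path(out_dir, "pausing_index.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(diff_reg, file.path(out_dir, "differential_regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(b2_strat$summary, file.path(out_dir, "b2_distance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    truth_genes <- truth$genes
    write.table(truth_genes, file.path(out_dir, "truth_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(truth$sites, file.path(out_dir, "truth_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(cfg, out_dir)
  }
  invisible(res)
}

write_manifest <- function(cfg, out_dir) {
  files <- setdiff(list.files(out_dir), "manifest.yaml")
  hashes <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(parameters = cfg[setdiff(names(cfg), "stages")],
                   stages = cfg$stages,
                   files = as.list(setNames(unname(hashes), files)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
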