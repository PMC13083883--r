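#' Simulation configuration
#'
#' All knobs of the synthetic-data generator. The defaults define the study
#' conditions every downstream module is exercised under: a two-contig toy
#' genome, 300 genes, TE instances of the named B2/MERVL/LINE subfamilies,
#' 40\% of genes m6A-marked with 70\% of those bound by the reader, Poisson
#' reader tags of mean 30 per site over a 0.005 tags/bp background, a +0.5
#' log2 stabilisation of targets under knockdown + transcription inhibition,
#' five-fold promoter pausing, and a -0.5 log2 Pol II depression within
#' 50 kb of B2 loci under knockdown.
#'
#' @param seed Integer seed fixing all randomness of generator calls.
#' @param n_contigs,contig_length Genome shape.
#' @param n_genes Number of genes (spread evenly over the genome).
#' @param n_te Named integer vector: TE instances per subfamily. B2
#'   subfamilies are placed in two compact islands per contig so that gene
#'   distances to the nearest B2 locus populate every distance bin.
#' @param fraction_m6a Fraction of genes carrying an m6A mark (deterministic
#'   count, random identity).
#' @param fraction_df_target_given_m6a Fraction of m6A genes bound by the
#'   reader (targets always carry the mark).
#' @param sites_per_gene Planted binding sites per target gene.
#' @param te_site_fraction Fraction of m6A B2 copies receiving a planted
#'   binding site.
#' @param decay_shift_log2 Planted log2 stabilisation of target features
#'   under knockdown + DRB.
#' @param lambda_signal Mean tag count per planted site (Poisson).
#' @param lambda_background Background tag density, tags/bp genome-wide.
#' @param tag_jitter_sd SD (bp) of the discretised Gaussian jitter of tag
#'   5' ends around summits.
#' @param nb_dispersion Negative-binomial dispersion of gene counts (0
#'   gives the noise-free rounded-mean limit).
#' @param te_dispersion Dispersion of TE-subfamily counts; subfamily totals
#'   aggregate hundreds of loci, so their relative overdispersion is much
#'   smaller than per-gene dispersion.
#' @param lib_range Range of the uniform library-size factors of simulated
#'   count samples; \code{c(1, 1)} gives equal libraries.
#' @param n_replicates Replicates per condition / stage.
#' @param pausing_factor Promoter/body polymerase density ratio.
#' @param b2_cis_effect Log2 Pol II change within \code{b2_cis_radius} of a
#'   B2 locus under knockdown.
#' @param b2_cis_radius Radius (bp) of the B2 cis effect.
#' @param coverage_noise_sd Per-gene log2 SD of coverage density (0 gives
#'   noise-free tracks).
#' @param noise_sd Stage-profile noise SD (z-score units).
#' @param pol3_b2_density,pol3_background Pol III signal densities on B2
#'   bodies and elsewhere.
#' @param stages Developmental stages for stage-wise expression.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_contigs = 2L, contig_length = 1e6,
                       n_genes = 300L,
                       n_te = c(B2_Mm1a = 60L, B2_Mm1t = 30L, B2_Mm2 = 30L,
                                "MERVL-int" = 40L, L1Md_A = 40L),
                       fraction_m6a = 0.4,
                       fraction_df_target_given_m6a = 0.7,
                       sites_per_gene = 1L, te_site_fraction = 0.2,
                       decay_shift_log2 = 0.5,
                       lambda_signal = 30, lambda_background = 0.005,
                       tag_jitter_sd = 10,
                       nb_dispersion = 0.1, te_dispersion = 0.02,
                       lib_range = c(0.5, 2), n_replicates = 3L,
                       pausing_factor = 5, b2_cis_effect = -0.5,
                       b2_cis_radius = 5e4, coverage_noise_sd = 0.05,
                       noise_sd = 0.3,
                       pol3_b2_density = 10, pol3_background = 0.5,
                       stages = developmental_stages()) {
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              n_genes = as.integer(n_genes), n_te = n_te,
              fraction_m6a = fraction_m6a,
              fraction_df_target_given_m6a = fraction_df_target_given_m6a,
              sites_per_gene = as.integer(sites_per_gene),
              te_site_fraction = te_site_fraction,
              decay_shift_log2 = decay_shift_log2,
              lambda_signal = lambda_signal,
              lambda_background = lambda_background,
              tag_jitter_sd = tag_jitter_sd,
              nb_dispersion = nb_dispersion,
              te_dispersion = te_dispersion, lib_range = lib_range,
              n_replicates = as.integer(n_replicates),
              pausing_factor = pausing_factor,
              b2_cis_effect = b2_cis_effect,
              b2_cis_radius = b2_cis_radius,
              coverage_noise_sd = coverage_noise_sd, noise_sd = noise_sd,
              pol3_b2_density = pol3_b2_density,
              pol3_background = pol3_background, stages = stages)
  stopifnot(cfg$fraction_m6a >= 0, cfg$fraction_m6a <= 1,
            cfg$fraction_df_target_given_m6a >= 0,
            cfg$fraction_df_target_given_m6a <= 1,
            cfg$te_site_fraction >= 0, cfg$te_site_fraction <= 1,
            cfg$lambda_signal >= 0, cfg$lambda_background >= 0,
            cfg$nb_dispersion >= 0, cfg$te_dispersion >= 0,
            length(cfg$lib_range) == 2L, all(cfg$lib_range > 0),
            cfg$n_contigs >= 1,
            cfg$contig_length >= 1e4, cfg$pausing_factor > 0)
  class(cfg) <- "sim_config"
  cfg
}

sim_contig_names <- function(cfg) paste0("ctg", seq_len(cfg$n_contigs))

te_family_of <- function(subfamily) {
  ifelse(grepl("^B2", subfamily), "SINE",
         ifelse(grepl("MERVL|^ERV|^IAP|int$", subfamily), "LTR",
                ifelse(grepl("^L1", subfamily), "LINE", "other")))
}

#' Gene label table of the generator
#'
#' The per-gene ground-truth labels (m6A mark, reader targeting, stage
#' class, baseline expression, planted decay shift) without building a
#' genome — enough to drive the count simulators on their own. Label counts
#' are deterministic (\code{round(n * fraction)}); identities are random
#' under the seed.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param seed Seed (default \code{cfg$seed}); \code{NULL} continues the
#'   current RNG stream.
#' @return data.frame with one row per gene.
#' @export
simulate_gene_table <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_genes
  ids <- sprintf("gene%04d", seq_len(n))
  m6a <- rep(FALSE, n)
  m6a[sample.int(n, round(n * cfg$fraction_m6a))] <- TRUE
  target <- rep(FALSE, n)
  idx_m6a <- which(m6a)
  n_target <- round(length(idx_m6a) * cfg$fraction_df_target_given_m6a)
  if (n_target > 0L)
    target[sample(idx_m6a, n_target)] <- TRUE
  classes <- rownames(stage_templates())
  data.frame(gene_id = ids, m6a = m6a, df_target = target,
             stage_class = sample(classes, n, replace = TRUE),
             base_mean = exp(rnorm(n, log(200), 0.5)),
             decay_shift = ifelse(target, cfg$decay_shift_log2, 0))
}

# Even-spread placement: one candidate per equal slot, random offset.
place_in_slots <- function(n, lens, contig_len, margin = 100L) {
  if (n == 0L) return(integer(0))
  slot <- contig_len %/% n
  if (any(lens + 2L * margin > slot))
    stop("infeasible packing: requested features exceed genome capacity")
  offs <- vapply(seq_len(n), function(i) {
    sample.int(slot - lens[i] - 2L * margin, 1L) + margin
  }, 0L)
  (seq_len(n) - 1L) * slot + offs
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# B2 island anchor fractions per contig; two compact islands so that gene
# distances to the nearest B2 locus cover 0 to ~0.45 * contig_length.
b2_island_fractions <- c(0.10, 0.55)

#' Simulate the toy genome, annotation and ground truth
#'
#' Builds random contig sequences; places genes evenly on both strands with
#' 1-3 exons each; places B2 instances in two compact islands per contig
#' and the remaining TE subfamilies evenly; plants a DRACH pentamer (and a
#' binding summit) inside an exon of every reader-target gene and inside a
#' fraction of m6A-marked B2 copies; and emits m6A peaks over all planted
#' marks. Every planted summit therefore sits on a DRACH occurrence, and
#' reader targets are always m6A-marked.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List of class \code{sim_genome} with elements \code{genome}
#'   (\code{DNAStringSet}), \code{ann} (\code{\link{genome_annotation}})
#'   and \code{truth} (ground-truth tables: \code{genes}, \code{sites},
#'   \code{te}, \code{m6a_peaks}, \code{contig_lengths}, \code{config}).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  contigs <- sim_contig_names(cfg)
  L <- cfg$contig_length
  seqs <- lapply(contigs, function(x) random_dna(L))
  names(seqs) <- contigs

  # label draw inside the same RNG stream for end-to-end determinism
  gene_tab <- if (cfg$n_genes == 0L) NULL else
    simulate_gene_table(cfg, seed = NULL)

  # --- genes: evenly spread slots, round-robin over contigs ---
  genes_df <- NULL
  exon_list <- list()
  if (cfg$n_genes > 0L) {
    per_ctg <- table(factor(rep_len(contigs, cfg$n_genes), levels = contigs))
    rows <- list()
    gi <- 0L
    for (ci in seq_along(contigs)) {
      nct <- as.integer(per_ctg[ci])
      lens <- sample(1500:4000, nct, replace = TRUE)
      starts <- place_in_slots(nct, lens, L)
      strands <- sample(c("+", "-"), nct, replace = TRUE)
      for (k in seq_len(nct)) {
        gi <- gi + 1L
        s <- starts[k]; e <- s + lens[k] - 1L
        rows[[gi]] <- data.frame(gene_id = gene_tab$gene_id[gi],
                                 contig = contigs[ci], start = s, end = e,
                                 strand = strands[k])
        exon_list[[gene_tab$gene_id[gi]]] <- make_exons(s, e)
      }
    }
    genes_df <- do.call(rbind, rows)
  }

  # --- TEs ---
  te_rows <- list()
  b2_sub <- names(cfg$n_te)[grepl("^B2", names(cfg$n_te))]
  other_sub <- setdiff(names(cfg$n_te), b2_sub)
  # B2 copies into islands
  b2_lens_all <- list()
  if (length(b2_sub) > 0L && sum(cfg$n_te[b2_sub]) > 0L) {
    b2_ids <- rep(b2_sub, times = cfg$n_te[b2_sub])
    b2_ids <- sample(b2_ids)
    n_islands <- length(b2_island_fractions) * cfg$n_contigs
    isl <- rep_len(seq_len(n_islands), length(b2_ids))
    for (ii in seq_len(n_islands)) {
      ctg_i <- ((ii - 1L) %/% length(b2_island_fractions)) + 1L
      frac_i <- ((ii - 1L) %% length(b2_island_fractions)) + 1L
      members <- which(isl == ii)
      if (length(members) == 0L) next
      cursor <- as.integer(b2_island_fractions[frac_i] * L)
      for (m in members) {
        len <- sample(150:200, 1L)
        te_rows[[length(te_rows) + 1L]] <- data.frame(
          contig = contigs[ctg_i], start = cursor, end = cursor + len - 1L,
          strand = sample(c("+", "-"), 1L), subfamily = b2_ids[m])
        cursor <- cursor + len + sample(20:60, 1L)
      }
    }
  }
  # other subfamilies spread evenly
  for (sub in other_sub) {
    n_sub <- cfg$n_te[[sub]]
    if (n_sub == 0L) next
    per_ctg <- table(factor(rep_len(contigs, n_sub), levels = contigs))
    for (ci in seq_along(contigs)) {
      nct <- as.integer(per_ctg[ci])
      if (nct == 0L) next
      lens <- sample(400:900, nct, replace = TRUE)
      # offset slots by half a slot so they rarely coincide with genes
      starts <- place_in_slots(nct, lens, L) + sample(50:500, nct, TRUE)
      for (k in seq_len(nct)) {
        te_rows[[length(te_rows) + 1L]] <- data.frame(
          contig = contigs[ci], start = starts[k],
          end = min(starts[k] + lens[k] - 1L, L),
          strand = sample(c("+", "-"), 1L), subfamily = sub)
      }
    }
  }
  te_df <- if (length(te_rows) > 0L) do.call(rbind, te_rows) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), subfamily = character(0))
  te_df$family <- te_family_of(te_df$subfamily)
  te_df$m6a <- te_df$family %in% c("SINE", "LTR")
  te_df$has_site <- FALSE
  if (nrow(te_df) > 0L) te_df$te_id <- sprintf("te%04d", seq_len(nrow(te_df)))

  # --- plant DRACH + binding sites ---
  sites <- list()
  peaks <- list()
  if (!is.null(genes_df)) {
    for (i in seq_len(nrow(genes_df))) {
      if (!gene_tab$m6a[i]) next
      g <- genes_df[i, ]
      n_sites <- if (gene_tab$df_target[i]) cfg$sites_per_gene else 1L
      for (s in seq_len(n_sites)) {
        pos <- pick_exonic_position(exon_list[[g$gene_id]], g)
        if (is.na(pos)) next
        seqs[[g$contig]] <- plant_drach(seqs[[g$contig]], pos, g$strand)
        peaks[[length(peaks) + 1L]] <- data.frame(
          contig = g$contig, start = max(0L, pos - 76L), end = pos + 75L,
          gene_id = g$gene_id)
        if (gene_tab$df_target[i])
          sites[[length(sites) + 1L]] <- data.frame(
            contig = g$contig, summit = pos - 1L, strand = g$strand,
            feature_id = g$gene_id, origin = "gene")
      }
    }
  }
  if (nrow(te_df) > 0L && cfg$te_site_fraction > 0) {
    cand <- which(te_df$m6a & te_df$family == "SINE")
    n_te_sites <- round(length(cand) * cfg$te_site_fraction)
    if (n_te_sites > 0L) {
      chosen <- sample(cand, n_te_sites)
      for (i in chosen) {
        mid <- as.integer((te_df$start[i] + te_df$end[i]) / 2)
        seqs[[te_df$contig[i]]] <- plant_drach(seqs[[te_df$contig[i]]],
                                               mid, te_df$strand[i])
        te_df$has_site[i] <- TRUE
        sites[[length(sites) + 1L]] <- data.frame(
          contig = te_df$contig[i], summit = mid - 1L,
          strand = te_df$strand[i], feature_id = te_df$te_id[i],
          origin = "te")
        peaks[[length(peaks) + 1L]] <- data.frame(
          contig = te_df$contig[i], start = max(0L, mid - 76L),
          end = mid + 75L, gene_id = te_df$te_id[i])
      }
    }
  }
  sites_df <- if (length(sites) > 0L) do.call(rbind, sites) else
    data.frame(contig = character(0), summit = integer(0),
               strand = character(0), feature_id = character(0),
               origin = character(0))
  if (nrow(sites_df) > 0L)
    sites_df$site_id <- sprintf("site%04d", seq_len(nrow(sites_df)))
  peaks_df <- if (length(peaks) > 0L) do.call(rbind, peaks) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               gene_id = character(0))

  genome <- DNAStringSet(unlist(seqs))
  clens <- setNames(rep(L, cfg$n_contigs), contigs)

  genes_gr <- if (is.null(genes_df)) {
    gr <- GRanges(); mcols(gr)$gene_id <- character(0)
    mcols(gr)$tss <- integer(0); mcols(gr)$tes <- integer(0)
    gr
  } else {
    gr <- GRanges(genes_df$contig,
                  IRanges(genes_df$start, genes_df$end),
                  strand = genes_df$strand)
    gr$gene_id <- genes_df$gene_id
    gr$tss <- ifelse(genes_df$strand == "-", genes_df$end, genes_df$start)
    gr$tes <- ifelse(genes_df$strand == "-", genes_df$start, genes_df$end)
    gr
  }
  exons_grl <- if (is.null(genes_df)) GRangesList() else {
    n_ex <- vapply(genes_df$gene_id, function(id) nrow(exon_list[[id]]), 0L)
    ex_all <- do.call(rbind, exon_list[genes_df$gene_id])
    flat <- GRanges(rep(genes_df$contig, n_ex),
                    IRanges(ex_all$start, ex_all$end),
                    strand = rep(genes_df$strand, n_ex))
    split(flat, factor(rep(genes_df$gene_id, n_ex),
                       levels = genes_df$gene_id))
  }
  tes_gr <- GRanges(te_df$contig,
                    IRanges(as.integer(te_df$start), as.integer(te_df$end)),
                    strand = te_df$strand)
  mcols(tes_gr)$subfamily <- te_df$subfamily
  mcols(tes_gr)$family <- te_df$family
  ann <- genome_annotation(genes_gr, exons_grl, tes_gr, clens)

  truth <- list(genes = if (is.null(gene_tab)) NULL else
                  cbind(gene_tab, genes_df[, c("contig", "start", "end",
                                               "strand")]),
                sites = sites_df, te = te_df, m6a_peaks = peaks_df,
                contig_lengths = clens, config = cfg)
  structure(list(genome = genome, ann = ann, truth = truth),
            class = "sim_genome")
}

make_exons <- function(s, e) {
  len <- e - s + 1L
  n_ex <- sample(1:3, 1L)
  if (n_ex == 1L || len < 1200L)
    return(data.frame(start = s, end = e))
  cuts <- sort(sample(seq(400L, len - 400L, by = 50L), n_ex - 1L))
  intron_half <- 50L
  starts <- c(s, s + cuts + intron_half)
  ends <- c(s + cuts - intron_half - 1L, e)
  keep <- ends - starts + 1L >= 300L
  if (!all(keep)) return(data.frame(start = s, end = e))
  data.frame(start = starts, end = ends)
}

# 1-based position of the planted A; pentamer occupies pos-2 .. pos+2
pick_exonic_position <- function(exons, gene) {
  margin <- 110L
  ok <- exons[exons$end - exons$start + 1L >= 2L * margin + 10L, ,
              drop = FALSE]
  if (nrow(ok) == 0L) {
    if (gene$end - gene$start < 2L * margin + 10L) return(NA_integer_)
    return(sample(seq(gene$start + margin, gene$end - margin), 1L))
  }
  row <- ok[sample.int(nrow(ok), 1L), ]
  sample(seq(row$start + margin, row$end - margin), 1L)
}

plant_drach <- function(seq_str, pos, strand) {
  pent <- sample(drach_pentamers(), 1L)
  if (strand == "-")
    pent <- as.character(reverseComplement(DNAStringSet(pent))[[1L]])
  substr(seq_str, pos - 2L, pos + 2L) <- pent
  seq_str
}

#' Simulate reader LACE-seq tags
#'
#' Control condition: per planted site, Poisson(\code{lambda_signal}) 5'
#' ends jittered around the summit (discretised Gaussian, SD
#' \code{tag_jitter_sd}) on the transcript strand, plus uniform
#' Poisson(\code{lambda_background}) genome-wide noise on random strands.
#' Inhibitor condition (methyltransferase-inhibited, so m6A-dependent
#' binding is lost): background only.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param truth Ground truth from \code{\link{simulate_genome}}.
#' @param condition \code{"control"} or \code{"inhibitor"}.
#' @param sample_id Sample label.
#' @param seed Seed (default derived from \code{cfg$seed} and condition).
#' @return A \code{\link{tag_set}}.
#' @export
simulate_tags <- function(cfg, truth, condition = c("control", "inhibitor"),
                          sample_id = NULL,
                          seed = cfg$seed + 11L +
                            (condition[1L] == "inhibitor")) {
  condition <- match.arg(condition)
  if (is.null(sample_id)) sample_id <- paste0("DF_", condition)
  set.seed(seed)
  clens <- truth$contig_lengths
  parts <- list()
  if (condition == "control" && nrow(truth$sites) > 0L &&
      cfg$lambda_signal > 0) {
    n_per <- rpois(nrow(truth$sites), cfg$lambda_signal)
    for (i in seq_len(nrow(truth$sites))) {
      if (n_per[i] == 0L) next
      s <- truth$sites[i, ]
      pos <- s$summit + as.integer(round(rnorm(n_per[i], 0,
                                               cfg$tag_jitter_sd)))
      pos <- pmin(pmax(pos, 0L), clens[[s$contig]] - 1L)
      parts[[length(parts) + 1L]] <- data.frame(
        contig = s$contig, pos = pos, strand = s$strand, k = 1L)
    }
  }
  n_bg <- rpois(1L, cfg$lambda_background * sum(as.numeric(clens)))
  if (n_bg > 0L) {
    ctg <- sample(names(clens), n_bg, replace = TRUE,
                  prob = as.numeric(clens) / sum(as.numeric(clens)))
    pos <- vapply(ctg, function(ct) sample.int(clens[[ct]], 1L) - 1L, 0L)
    parts[[length(parts) + 1L]] <- data.frame(
      contig = ctg, pos = pos,
      strand = sample(c("+", "-"), n_bg, replace = TRUE), k = 1L)
  }
  tags <- if (length(parts) > 0L) do.call(rbind, parts) else
    data.frame(contig = character(0), pos = integer(0),
               strand = character(0), k = integer(0))
  rownames(tags) <- NULL
  tag_set(tags, sample_id = sample_id, condition = condition)
}

te_base_means <- function(subfams) {
  base <- setNames(rep(800, length(subfams)), subfams)
  base[grepl("^B2_Mm1a", subfams)] <- 3000
  base[grepl("^B2_Mm1t", subfams)] <- 1500
  base[grepl("MERVL", subfams)] <- 1200
  base[grepl("^L1", subfams)] <- 1000
  base
}

nb_draw <- function(n, mu, dispersion) {
  if (dispersion == 0) return(round(mu))
  rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate the knockdown / transcription-inhibition count experiment
#'
#' Gene and TE-subfamily counts for the four arms
#' \code{control}, \code{kd} (reader knockdown), \code{DRB} (Pol II
#' elongation inhibitor) and \code{kd_DRB}, with \code{n_replicates} each.
#' Under \code{kd_DRB}, reader-target genes and m6A-marked B2 subfamilies
#' have their means multiplied by \code{2^decay_shift_log2} relative to
#' \code{DRB} — decay lost upon knockdown shows up as stabilisation once
#' new transcription is frozen. Library sizes vary uniformly in [0.5, 2].
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param truth Ground truth (only \code{$genes} and \code{$te} are used, so
#'   a \code{\link{simulate_gene_table}} result wrapped as
#'   \code{list(genes = tab, te = NULL)} is also accepted).
#' @param seed Seed (default \code{cfg$seed + 21}).
#' @return \code{SummarizedExperiment}: assay \code{counts}, colData
#'   \code{condition}/\code{replicate}, rowData \code{feature_type} and the
#'   planted \code{decay_shift}.
#' @export
simulate_counts <- function(cfg, truth, seed = cfg$seed + 21L) {
  set.seed(seed)
  genes <- truth$genes
  stopifnot(!is.null(genes))
  subfams <- if (!is.null(truth$te) && nrow(truth$te) > 0L)
    sort(unique(truth$te$subfamily)) else character(0)
  te_m6a <- if (length(subfams) > 0L)
    vapply(subfams, function(s) any(truth$te$m6a[truth$te$subfamily == s]),
           TRUE) else logical(0)
  mu_base <- c(setNames(genes$base_mean, genes$gene_id),
               te_base_means(subfams))
  shift <- c(setNames(genes$decay_shift, genes$gene_id),
             setNames(ifelse(te_m6a & grepl("^B2", subfams),
                             cfg$decay_shift_log2, 0), subfams))
  conditions <- c("control", "kd", "DRB", "kd_DRB")
  cond <- rep(conditions, each = cfg$n_replicates)
  repl <- rep(seq_len(cfg$n_replicates), times = length(conditions))
  lib <- runif(length(cond), cfg$lib_range[1L], cfg$lib_range[2L])
  counts <- matrix(0, length(mu_base), length(cond),
                   dimnames = list(names(mu_base),
                                   paste0(cond, "_", repl)))
  is_te <- c(rep(FALSE, nrow(genes)), rep(TRUE, length(subfams)))
  for (j in seq_along(cond)) {
    mu <- mu_base
    if (cond[j] == "kd_DRB") mu <- mu * 2^shift
    counts[!is_te, j] <- nb_draw(sum(!is_te), mu[!is_te] * lib[j],
                                 cfg$nb_dispersion)
    if (any(is_te))
      counts[is_te, j] <- nb_draw(sum(is_te), mu[is_te] * lib[j],
                                  cfg$te_dispersion)
  }
  SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(condition = cond, replicate = repl,
                        row.names = colnames(counts)),
    rowData = DataFrame(feature_type = c(rep("gene", nrow(genes)),
                                         rep("te", length(subfams))),
                        decay_shift = unname(shift)))
}

#' Simulate stage-wise expression counts
#'
#' Counts across the nine developmental stages with
#' \code{n_replicates} samples per stage; each gene's stage means follow its
#' assigned class template (shifted to be positive), scaled by its baseline
#' mean, with negative-binomial noise and variable library sizes.
#'
#' @inheritParams simulate_counts
#' @param seed Seed (default \code{cfg$seed + 31}).
#' @return \code{SummarizedExperiment} with colData \code{stage} and
#'   \code{replicate}.
#' @export
simulate_stage_counts <- function(cfg, truth, seed = cfg$seed + 31L) {
  set.seed(seed)
  genes <- truth$genes
  stopifnot(!is.null(genes))
  tmpl <- stage_templates()
  stages <- cfg$stages
  stopifnot(all(stages %in% colnames(tmpl)))
  stage_v <- rep(stages, each = cfg$n_replicates)
  repl <- rep(seq_len(cfg$n_replicates), times = length(stages))
  lib <- runif(length(stage_v), cfg$lib_range[1L], cfg$lib_range[2L])
  # template z-profiles shifted to positive relative expression
  rel <- tmpl - min(tmpl) + 0.1
  counts <- matrix(0, nrow(genes), length(stage_v),
                   dimnames = list(genes$gene_id,
                                   paste0(stage_v, "_", repl)))
  for (j in seq_along(stage_v)) {
    mu <- genes$base_mean * rel[genes$stage_class, stage_v[j]]
    counts[, j] <- nb_draw(length(mu), mu * lib[j], cfg$nb_dispersion)
  }
  SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(stage = stage_v, replicate = repl,
                        row.names = colnames(counts)),
    rowData = DataFrame(stage_class = genes$stage_class))
}

#' Simulate noisy stage z-profiles drawn from the class templates
#'
#' Directly emits z-scored profiles (template + Gaussian stage noise,
#' re-standardised), the input expected by \code{\link{cluster_profiles}} —
#' the quickest route to exercising classification without counts.
#'
#' @param n_per_class Genes per class.
#' @param noise_sd Per-stage Gaussian noise SD, z-units.
#' @param seed Seed.
#' @return List: \code{profiles} (matrix) and \code{truth} (named character
#'   vector of true classes).
#' @export
simulate_stage_profiles <- function(n_per_class = 100L, noise_sd = 0.3,
                                    seed = 1L) {
  set.seed(seed)
  tmpl <- stage_templates()
  cls <- rep(rownames(tmpl), each = n_per_class)
  prof <- t(vapply(seq_along(cls), function(i) {
    zscore(tmpl[cls[i], ] + rnorm(ncol(tmpl), 0, noise_sd))
  }, numeric(ncol(tmpl))))
  rownames(prof) <- sprintf("g%05d", seq_along(cls))
  colnames(prof) <- colnames(tmpl)
  list(profiles = prof, truth = setNames(cls, rownames(prof)))
}

b2_distances_of_genes <- function(truth) {
  b2 <- truth$te[grepl("^B2", truth$te$subfamily), , drop = FALSE]
  if (nrow(b2) == 0L)
    return(rep(Inf, nrow(truth$genes)))
  g_gr <- GRanges(truth$genes$contig,
                  IRanges(truth$genes$start, truth$genes$end))
  b_gr <- GRanges(b2$contig, IRanges(as.integer(b2$start),
                                     as.integer(b2$end)))
  nearest_distance(g_gr, b_gr)
}

#' Simulate polymerase CUT&Tag coverage
#'
#' Pol II: every gene body gets a per-gene density (log-normal noise of
#' log2-SD \code{coverage_noise_sd}; exactly 1 when that is 0) and the
#' promoter window the same density times \code{pausing_factor}; under
#' knockdown, genes within \code{b2_cis_radius} of a B2 locus are depressed
#' by \code{2^b2_cis_effect}. Pol III: B2 instance bodies at
#' \code{pol3_b2_density} over a \code{pol3_background} floor. Promoter and
#' body windows are shared with \code{\link{pausing_index}}, so the
#' noise-free pausing index equals \code{pausing_factor} exactly.
#'
#' @inheritParams simulate_counts
#' @param condition \code{"control"} or \code{"kd"}.
#' @param polymerase \code{"PolII"} or \code{"PolIII"}.
#' @param replicate Replicate number (only labels the sample; use distinct
#'   seeds for distinct replicates).
#' @param seed Seed (default derived from \code{cfg$seed}, condition,
#'   polymerase and replicate).
#' @return A \code{\link{coverage_track}}.
#' @export
simulate_coverage <- function(cfg, truth, condition = c("control", "kd"),
                              polymerase = c("PolII", "PolIII"),
                              replicate = 1L,
                              seed = cfg$seed + 41L +
                                7L * (condition[1L] == "kd") +
                                13L * (polymerase[1L] == "PolIII") +
                                replicate) {
  condition <- match.arg(condition)
  polymerase <- match.arg(polymerase)
  set.seed(seed)
  clens <- truth$contig_lengths
  signal <- lapply(clens, numeric)
  sdlog <- cfg$coverage_noise_sd * log(2)
  if (polymerase == "PolII") {
    genes <- truth$genes
    d_b2 <- b2_distances_of_genes(truth)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      d <- if (sdlog == 0) 1 else exp(rnorm(1L, 0, sdlog))
      if (condition == "kd" && is.finite(d_b2[i]) &&
          d_b2[i] <= cfg$b2_cis_radius)
        d <- d * 2^cfg$b2_cis_effect
      tss <- if (g$strand == "-") g$end else g$start
      tes <- if (g$strand == "-") g$start else g$end
      win <- promoter_body_ranges(tss, tes, g$strand)
      clen <- clens[[g$contig]]
      span <- c(max(1L, min(win$promoter[1L], g$start)),
                min(clen, max(win$promoter[2L], g$end)))
      v <- signal[[g$contig]]
      v[span[1L]:span[2L]] <- pmax(v[span[1L]:span[2L]], d)
      p1 <- max(1L, win$promoter[1L]); p2 <- min(clen, win$promoter[2L])
      v[p1:p2] <- d * cfg$pausing_factor
      signal[[g$contig]] <- v
    }
  } else {
    for (ct in names(signal))
      signal[[ct]][] <- cfg$pol3_background
    te <- truth$te
    b2 <- te[grepl("^B2", te$subfamily), , drop = FALSE]
    kd_fac <- if (condition == "kd") 2^(-0.5) else 1
    for (i in seq_len(nrow(b2))) {
      d <- if (sdlog == 0) 1 else exp(rnorm(1L, 0, sdlog))
      rng <- as.integer(b2$start[i]):as.integer(b2$end[i])
      signal[[b2$contig[i]]][rng] <- cfg$pol3_b2_density * d * kd_fac
    }
  }
  coverage_track(signal, polymerase = polymerase,
                 condition = if (condition == "kd") "kd" else "control")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", length(x$genome), "contigs;",
      nrow(x$truth$genes %||% data.frame()), "genes;",
      nrow(x$truth$te), "TE instances;",
      nrow(x$truth$sites), "planted binding sites\n")
  invisible(x)
}
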