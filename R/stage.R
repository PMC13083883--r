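#' Developmental stages, oocyte to blastocyst
#'
#' @return Character vector of the nine profiled stages in order: MII
#'   oocyte, zygote, early/middle/late 2-cell, 4-cell, 8-cell, morula,
#'   blastocyst.
#' @export
developmental_stages <- function() {
  c("MII", "Zygote", "E2C", "M2C", "L2C", "4C", "8C", "MO", "BL")
}

#' The 13 stage-related expression class templates
#'
#' Template z-profiles over the nine stages for the stage-related gene
#' classes used to interpret embryo transcriptomes: maternal programs
#' (stable or early-decaying), minor and major zygotic genome activation
#' (ZGA), the 2-cell transient program, mid-preimplantation activation
#' (MGA, peaking at 4-8 cells), late-preimplantation activation (LGA,
#' peaking at morula or blastocyst), plus biphasic, constitutive,
#' mid-decay, late-decay and an irregular "others" pattern. The shapes are
#' an explicit, versioned convention of this package (the field names the
#' classes but not a canonical parameterisation); each row is z-normalised.
#'
#' @return Matrix, 13 classes x 9 stages, rows z-scored.
#' @export
stage_templates <- function() {
  raw <- rbind(
    maternal            = c(1.00, 1.00, 0.60, 0.10, 0.00, 0.00, 0.00, 0.00, 0.00),
    maternal_early_decay = c(1.00, 0.15, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00),
    minor_zga           = c(0.00, 0.60, 1.00, 0.30, 0.00, 0.00, 0.00, 0.00, 0.00),
    major_zga           = c(0.00, 0.00, 0.00, 0.80, 1.00, 0.90, 0.80, 0.80, 0.80),
    two_cell_transient  = c(0.00, 0.00, 0.15, 1.00, 0.80, 0.00, 0.00, 0.00, 0.00),
    mga                 = c(0.00, 0.00, 0.00, 0.00, 0.30, 1.00, 0.90, 0.20, 0.00),
    lga_morula          = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.20, 0.50, 1.00, 0.40),
    lga_blastocyst      = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.10, 0.40, 1.00),
    biphasic            = c(1.00, 0.70, 0.20, 0.00, 0.00, 0.20, 0.50, 0.90, 1.00),
    constitutive        = c(0.60, 0.80, 1.00, 0.90, 1.00, 0.90, 1.00, 0.80, 0.90),
    mid_decay           = c(0.80, 0.95, 1.00, 1.00, 0.95, 0.35, 0.00, 0.00, 0.00),
    late_decay          = c(0.40, 0.55, 0.70, 0.80, 0.90, 1.00, 1.00, 0.95, 0.00),
    others              = c(1.00, 0.20, 0.90, 0.30, 1.00, 0.20, 0.90, 0.30, 1.00))
  colnames(raw) <- developmental_stages()
  t(apply(raw, 1L, zscore))
}

zscore <- function(x) {
  s <- sd(x)
  if (s == 0) stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

#' Per-gene stage expression profiles
#'
#' Normalises counts (median-of-ratios), averages samples within each
#' developmental stage and z-scores the resulting per-gene stage vector.
#' Constant genes cannot be z-scored and are dropped with a message.
#'
#' @param counts Gene x sample matrix (or \code{SummarizedExperiment} with a
#'   \code{counts} assay) with one or more samples per stage.
#' @param stage Character vector assigning each sample to a stage; every
#'   stage in \code{stages} must be present.
#' @param stages Stage order (default \code{\link{developmental_stages}}).
#' @return Matrix gene x stage of z-scored profiles.
#' @export
build_profiles <- function(counts, stage, stages = developmental_stages()) {
  counts <- as_count_matrix(counts)
  stage <- as.character(stage)
  stopifnot(length(stage) == ncol(counts))
  missing_st <- setdiff(stages, unique(stage))
  if (length(missing_st) > 0L)
    stop("no samples for stage(s): ", paste(missing_st, collapse = ", "))
  norm <- normalize_counts(counts)
  means <- vapply(stages, function(s) {
    rowMeans(norm[, stage == s, drop = FALSE])
  }, numeric(nrow(norm)))
  constant <- apply(means, 1L, sd) == 0
  if (any(constant)) {
    message("dropping ", sum(constant), " constant gene(s) from profiles")
    means <- means[!constant, , drop = FALSE]
  }
  t(apply(means, 1L, zscore))
}

#' Cluster stage profiles into gene modules
#'
#' Average-linkage hierarchical clustering on 1 - Pearson correlation
#' distance, cut at a fixed height, followed by iterative merging of
#' modules whose mean-profile correlation exceeds \code{merge_corr}
#' (closest pair first) until stable. The static cut plus close-module
#' merging is a deterministic, dependency-free stand-in for dynamic tree
#' cutting; the interface of interest is template recovery, not tree
#' topology.
#'
#' @param profiles Gene x stage matrix of z-profiles
#'   (\code{\link{build_profiles}}).
#' @param cut_height Dendrogram cut height on the correlation-distance
#'   scale.
#' @param merge_corr Modules with eigenpattern correlation above this are
#'   merged.
#' @return List of class \code{stage_modules}: \code{module} (named integer
#'   per gene) and \code{eigenpatterns} (module x stage matrix of mean
#'   z-profiles).
#' @export
cluster_profiles <- function(profiles, cut_height = 0.25, merge_corr = 0.8) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2L)
  d <- as.dist(1 - cor(t(profiles)))
  hc <- hclust(d, method = "average")
  module <- cutree(hc, h = cut_height)
  repeat {
    eig <- module_eigenpatterns(profiles, module)
    if (nrow(eig) < 2L) break
    cc <- cor(t(eig))
    diag(cc) <- -Inf
    if (max(cc) <= merge_corr) break
    idx <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    pair <- sort(as.integer(rownames(eig)[idx]))
    module[module == pair[2L]] <- pair[1L]
  }
  # renumber by first appearance for order-independence up to labels
  module <- as.integer(factor(module, levels = unique(module[order(names(module))])))
  names(module) <- rownames(profiles)
  structure(list(module = module,
                 eigenpatterns = module_eigenpatterns(profiles, module)),
            class = "stage_modules")
}

module_eigenpatterns <- function(profiles, module) {
  ids <- sort(unique(module))
  eig <- t(vapply(ids, function(m) {
    colMeans(profiles[module == m, , drop = FALSE])
  }, numeric(ncol(profiles))))
  rownames(eig) <- ids
  colnames(eig) <- colnames(profiles)
  eig
}

#' Assign gene modules to stage classes
#'
#' Each module goes to the template with the highest Pearson correlation to
#' its eigenpattern; modules whose best correlation is below
#' \code{min_corr} fall back to \code{"others"}. Genes inherit their
#' module's class.
#'
#' @param modules A \code{stage_modules} object.
#' @param templates Class x stage template matrix; must contain 13 classes
#'   unless \code{allow_custom}.
#' @param min_corr Fallback threshold.
#' @param allow_custom Permit a template set of a different size.
#' @return Named character vector: class per gene.
#' @export
assign_classes <- function(modules, templates = stage_templates(),
                           min_corr = 0.5, allow_custom = FALSE) {
  if (nrow(templates) != 13L && !allow_custom)
    stop("expected 13 class templates (use allow_custom to override)")
  eig <- modules$eigenpatterns
  stopifnot(ncol(eig) == ncol(templates))
  cls <- apply(eig, 1L, function(e) {
    r <- apply(templates, 1L, function(tm) cor(e, tm))
    if (max(r) < min_corr) "others" else rownames(templates)[which.max(r)]
  })
  out <- cls[as.character(modules$module)]
  names(out) <- names(modules$module)
  out
}

#' Class-overlap enrichment of a gene set
#'
#' One-sided Fisher exact test of the overlap between a gene set and each
#' stage class within the profiled universe, BH-adjusted across classes.
#'
#' @param gene_set Character vector of gene ids.
#' @param classes Named character vector gene -> class (the universe).
#' @return data.frame: \code{class}, \code{n_class}, \code{n_overlap},
#'   \code{odds_ratio}, \code{p}, \code{padj}.
#' @export
overlap_enrichment <- function(gene_set, classes) {
  universe <- names(classes)
  if (length(universe) == 0L) stop("empty gene universe")
  gene_set <- intersect(gene_set, universe)
  in_set <- universe %in% gene_set
  out <- do.call(rbind, lapply(sort(unique(classes)), function(cl) {
    in_cl <- classes == cl
    tab <- matrix(c(sum(in_set & in_cl), sum(in_set & !in_cl),
                    sum(!in_set & in_cl), sum(!in_set & !in_cl)), 2L)
    ft <- fisher.test(tab, alternative = "greater")
    data.frame(class = cl, n_class = sum(in_cl),
               n_overlap = sum(in_set & in_cl),
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  }))
  out$padj <- p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
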