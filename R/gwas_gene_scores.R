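#' Map SNPs to genes by window overlap
#'
#' A SNP maps to a gene when it lies on the same chromosome within
#' `window_bp` of the gene's most extreme transcript boundaries
#' (`start - window <= pos <= end + window`, 1-based inclusive; 500 kb in
#' the original analysis). A SNP may map to several genes. SNP positions and
#' the annotation must share a genome build — that is the caller's
#' responsibility.
#'
#' @param sumstats Data.frame from [read_sumstats()].
#' @param annotation Data.frame from [read_gene_annotation()].
#' @param window_bp Non-negative flank size in bp (default 500000).
#' @return Data.frame with one row per (gene, SNP) assignment: `gene`,
#'   `snp`, `pos`, `p`, `beta`, `se`, `gene_length`. Genes with no mapped
#'   SNP are reported in attribute `unscored_genes`; `window_bp` is attached
#'   as an attribute.
#' @export
map_snps_to_genes <- function(sumstats, annotation, window_bp = 500000L) {
  if (window_bp < 0) stop("window must be non-negative", call. = FALSE)
  out <- list()
  for (chr in unique(annotation$chrom)) {
    ann <- annotation[annotation$chrom == chr, , drop = FALSE]
    ss <- sumstats[sumstats$chrom == chr, , drop = FALSE]
    if (nrow(ss) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = ss$pos, width = 1L),
      IRanges::IRanges(start = pmax(1L, ann$start - window_bp),
                       end = ann$end + window_bp))
    if (length(hits) == 0L) next
    i <- S4Vectors::queryHits(hits)
    j <- S4Vectors::subjectHits(hits)
    out[[chr]] <- data.frame(gene = ann$gene[j], snp = ss$snp[i],
                             pos = ss$pos[i], p = ss$p[i], beta = ss$beta[i],
                             se = ss$se[i],
                             gene_length = ann$end[j] - ann$start[j] + 1L,
                             stringsAsFactors = FALSE)
  }
  mapping <- if (length(out))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  else
    data.frame(gene = character(), snp = character(), pos = integer(),
               p = numeric(), beta = numeric(), se = numeric(),
               gene_length = integer(), stringsAsFactors = FALSE)
  mapping <- mapping[order(mapping$gene, mapping$pos), , drop = FALSE]
  rownames(mapping) <- NULL
  attr(mapping, "unscored_genes") <- setdiff(annotation$gene, mapping$gene)
  attr(mapping, "window_bp") <- window_bp
  mapping
}

#' Best-SNP gene scores with confounder correction
#'
#' Assigns each mapped gene the `-log10` p-value of its most significant SNP
#' (ties broken by lowest genomic position), then residualizes that raw
#' score on `log10(gene length + 2 * window)` and `log10(n_snps)` by least
#' squares — larger genes and denser SNP coverage mechanically produce
#' smaller best p-values, and the residual removes that confounding. LD
#' structure is not consumed; SNP count stands in for the number of
#' independent SNPs, and additional per-gene covariates can be supplied.
#' Percentiles use average ranks on the corrected score.
#'
#' @param mapping Data.frame from [map_snps_to_genes()].
#' @param extra_covariates Optional numeric matrix/data.frame of additional
#'   regression covariates, one row per scored gene (in the order of the
#'   returned table).
#' @return Object of class `gene_scores`: data.frame with `gene`,
#'   `best_snp`, `best_p`, `raw_score`, `corrected_score`, `percentile`,
#'   `gene_length`, `n_snps`.
#' @export
score_genes <- function(mapping, extra_covariates = NULL) {
  if (nrow(mapping) == 0L) stop("empty mapping", call. = FALSE)
  window_bp <- attr(mapping, "window_bp") %||% 0L
  split_idx <- split(seq_len(nrow(mapping)), mapping$gene)
  rows <- lapply(split_idx, function(idx) {
    m <- mapping[idx, , drop = FALSE]
    best <- m[order(m$p, m$pos), , drop = FALSE][1, ]
    data.frame(gene = best$gene, best_snp = best$snp, best_p = best$p,
               raw_score = -log10(best$p), gene_length = best$gene_length,
               n_snps = nrow(m), stringsAsFactors = FALSE)
  })
  sc <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  sc <- sc[order(sc$gene), , drop = FALSE]
  rownames(sc) <- NULL
  x1 <- log10(sc$gene_length + 2 * window_bp)
  x2 <- log10(sc$n_snps)
  X <- cbind(len = x1, nsnp = x2)
  if (!is.null(extra_covariates)) X <- cbind(X, as.matrix(extra_covariates))
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (nrow(sc) < 2L || !any(keep)) {
    if (nrow(sc) < 2L)
      message("no correction possible: fewer than two scored genes")
    sc$corrected_score <- sc$raw_score
  } else {
    fit <- stats::lm.fit(cbind(1, X[, keep, drop = FALSE]), sc$raw_score)
    sc$corrected_score <- unname(fit$residuals)
  }
  sc$percentile <- rank(sc$corrected_score, ties.method = "average") /
    nrow(sc)
  class(sc) <- c("gene_scores", "data.frame")
  sc
}

#' Gene-set enrichment above a gene-score percentile cutoff
#'
#' Counts how many members of a gene set score strictly above the empirical
#' `percentile_cutoff` quantile of all corrected gene scores (the 95th
#' percentile in the original analysis) and compares the count with
#' size-matched random gene sets drawn from the scored universe. Genes
#' without a score are excluded from both the set and the sampling universe.
#'
#' @param scores A `gene_scores` object.
#' @param gene_set Character vector of candidate genes.
#' @param percentile_cutoff Quantile in (0, 1), default 0.95.
#' @param n_sim Number of random sets (default 10000).
#' @param seed Integer seed.
#' @return Object of class `cutoff_enrichment`: list with
#'   `set_size_scored`, `observed_above`, `expected_above`, `cutoff_value`,
#'   `p_empirical` (an `empirical_p`).
#' @export
cutoff_enrichment <- function(scores, gene_set, percentile_cutoff = 0.95,
                              n_sim = 10000L, seed) {
  set_scored <- intersect(unique(gene_set), scores$gene)
  if (length(set_scored) == 0L)
    stop("gene set has no scored genes", call. = FALSE)
  cutoff <- stats::quantile(scores$corrected_score, percentile_cutoff,
                            names = FALSE)
  above <- scores$gene[scores$corrected_score > cutoff]
  observed <- sum(set_scored %in% above)
  nulls <- sample_gene_sets(scores$gene, length(set_scored), n_sim, seed)
  null_counts <- vapply(nulls, function(s) sum(s %in% above), integer(1))
  structure(list(set_size_scored = length(set_scored),
                 observed_above = observed,
                 expected_above = mean(null_counts),
                 cutoff_value = cutoff,
                 p_empirical = empirical_p(observed, null_counts,
                                           "greater")),
            class = "cutoff_enrichment")
}

#' @export
print.cutoff_enrichment <- function(x, ...) {
  cat("Cutoff enrichment: ", x$observed_above, " of ", x$set_size_scored,
      " set genes above cutoff (", format(x$expected_above, digits = 3),
      " expected by chance); empirical p = ",
      format(x$p_empirical$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Joint significance of a gene set's best SNPs
#'
#' Evaluates a caller-supplied statistic (typically a multi-SNP risk score
#' on the set's best SNPs, see [score_test_for_gene_set()]) against the
#' distribution of the same statistic on size-matched random gene sets,
#' using a compound extremeness condition (by default: a null draw counts as
#' extreme when its p-value is at most the observed one AND its effect is
#' positive, matching the published procedure).
#'
#' @param scores A `gene_scores` object.
#' @param gene_set Character vector of candidate genes.
#' @param statistic Function taking the `gene_scores` rows for one gene set
#'   and returning a list with at least elements `p` and `beta`.
#' @param n_sim Number of random sets.
#' @param seed Integer seed.
#' @param extreme Predicate `function(null_stat, obs_stat)` returning TRUE
#'   when the null draw is at least as extreme; default
#'   `null$p <= obs$p && null$beta > 0`.
#' @return An `empirical_p` with the observed statistic in attribute
#'   `observed_stat`.
#' @export
best_snp_joint_significance <- function(scores, gene_set, statistic,
                                        n_sim = 10000L, seed,
                                        extreme = NULL) {
  set_scored <- intersect(unique(gene_set), scores$gene)
  if (length(set_scored) == 0L)
    stop("gene set has no scored genes", call. = FALSE)
  if (is.null(extreme))
    extreme <- function(null_stat, obs_stat)
      null_stat$p <= obs_stat$p && null_stat$beta > 0
  obs <- statistic(scores[scores$gene %in% set_scored, , drop = FALSE])
  nulls <- sample_gene_sets(scores$gene, length(set_scored), n_sim, seed)
  null_stats <- lapply(nulls, function(s)
    statistic(scores[scores$gene %in% s, , drop = FALSE]))
  res <- empirical_p(obs$p, null_stats,
                     direction = function(ns) extreme(ns, obs))
  attr(res, "observed_stat") <- obs
  res
}

#' Overlap between a gene set and trait-associated loci
#'
#' Counts the genes of a set with at least one catalog SNP (e.g. published
#' trait associations) within `window_bp` of the gene boundaries (250 kb in
#' the original analysis), and compares the count against size-matched
#' random gene sets drawn from `universe`.
#'
#' @param gene_set Character vector of candidate genes.
#' @param catalog_snps Data.frame with columns `chrom`, `pos` (and
#'   optionally `trait`).
#' @param annotation Data.frame from [read_gene_annotation()].
#' @param window_bp Flank size in bp (default 250000).
#' @param n_sim Number of random sets (default 10000).
#' @param seed Integer seed.
#' @param universe Sampling universe for the null sets (default: all
#'   annotated genes).
#' @return An `empirical_p` with the observed overlap count as `observed`.
#' @export
trait_locus_overlap <- function(gene_set, catalog_snps, annotation,
                                window_bp = 250000L, n_sim = 10000L, seed,
                                universe = annotation$gene) {
  near <- .genes_near_snps(annotation, catalog_snps, window_bp)
  count_near <- function(genes) sum(genes %in% near)
  set_ann <- intersect(unique(gene_set), annotation$gene)
  observed <- count_near(set_ann)
  universe <- intersect(unique(universe), annotation$gene)
  nulls <- sample_gene_sets(universe, length(set_ann), n_sim, seed)
  empirical_p(observed, vapply(nulls, count_near, integer(1)), "greater")
}

## Genes with >= 1 catalog SNP within the window.
.genes_near_snps <- function(annotation, catalog_snps, window_bp) {
  hit <- character()
  for (chr in unique(annotation$chrom)) {
    ann <- annotation[annotation$chrom == chr, , drop = FALSE]
    sn <- catalog_snps[catalog_snps$chrom == chr, , drop = FALSE]
    if (nrow(sn) == 0L) next
    ov <- IRanges::countOverlaps(
      IRanges::IRanges(start = pmax(1L, ann$start - window_bp),
                       end = ann$end + window_bp),
      IRanges::IRanges(start = sn$pos, width = 1L))
    hit <- c(hit, ann$gene[ov > 0])
  }
  hit
}
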