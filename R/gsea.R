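## Per-gene two-group statistics on an expression matrix. Group 1 is the
## second factor level (treatment), group 0 the first (reference).
.group_stats <- function(values, condition) {
  lev <- levels(condition)
  m0 <- values[, condition == lev[[1]], drop = FALSE]
  m1 <- values[, condition == lev[[2]], drop = FALSE]
  row_sd <- function(m, mu) {
    n <- ncol(m)
    sqrt(pmax(rowSums(m * m) - n * mu^2, 0) / (n - 1))
  }
  mu0 <- rowMeans(m0)
  mu1 <- rowMeans(m1)
  list(mu0 = mu0, mu1 = mu1,
       sd0 = row_sd(m0, mu0), sd1 = row_sd(m1, mu1),
       n0 = ncol(m0), n1 = ncol(m1))
}

#' Rank genes by differential expression
#'
#' Computes a per-gene ranking statistic between the two condition groups
#' and returns genes in descending order. The default metric is
#' signal-to-noise, `(mu1 - mu0) / (sd1 + sd0)`, with each group's standard
#' deviation floored at `0.2 * |mean|` and at 0.2 absolute — the floor keeps
#' near-constant genes from dominating the ranking. A Welch t statistic is
#' available as an alternative. Ties are broken alphabetically by symbol so
#' the ordering is strict and deterministic.
#'
#' @param expr An `expression_set` (two condition levels, >= 2 samples
#'   each).
#' @param metric `"s2n"` (default) or `"welch_t"`.
#' @return Data.frame with columns `gene`, `stat`, in ranking order.
#' @export
rank_genes <- function(expr, metric = c("s2n", "welch_t")) {
  metric <- match.arg(metric)
  stopifnot(inherits(expr, "expression_set"))
  if (min(table(expr$condition)) < 2L)
    stop("need >= 2 samples per condition group", call. = FALSE)
  g <- .group_stats(expr$values, expr$condition)
  if (metric == "s2n") {
    s0 <- pmax(g$sd0, 0.2 * abs(g$mu0), 0.2)
    s1 <- pmax(g$sd1, 0.2 * abs(g$mu1), 0.2)
    stat <- (g$mu1 - g$mu0) / (s1 + s0)
  } else {
    v0 <- pmax(g$sd0, 0.2)^2 / g$n0
    v1 <- pmax(g$sd1, 0.2)^2 / g$n1
    stat <- (g$mu1 - g$mu0) / sqrt(v0 + v1)
  }
  genes <- rownames(expr$values)
  ord <- order(-stat, genes)
  data.frame(gene = genes[ord], stat = unname(stat[ord]),
             stringsAsFactors = FALSE)
}

#' GSEA enrichment score (weighted running sum)
#'
#' Walks down the ranked list; genes in the set ("hits") increment the
#' running sum by `|stat|^weight_exponent` normalized by the total over
#' hits, genes outside it decrement by `1 / (N - n_hits)`. The enrichment
#' score is the signed maximum deviation of the running sum from zero.
#'
#' @param ranked Data.frame from [rank_genes()] (columns `gene`, `stat`).
#' @param gene_set Character vector; must overlap the ranked genes and must
#'   not cover them all.
#' @param weight_exponent Exponent on `|stat|` for hit increments (1 =
#'   classic weighted GSEA; 0 = unweighted Kolmogorov-Smirnov walk).
#' @return List with `es` (scalar in [-1, 1]) and `running_sum` (numeric
#'   vector along the ranking).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  hit <- ranked$gene %in% gene_set
  N <- nrow(ranked)
  nh <- sum(hit)
  if (nh == 0L) stop("gene set does not overlap the ranked list",
                     call. = FALSE)
  if (nh == N) stop("no miss steps: gene set covers all ranked genes",
                    call. = FALSE)
  w <- abs(ranked$stat)^weight_exponent
  denom <- sum(w[hit])
  step <- ifelse(hit, if (denom > 0) w / denom else 1 / nh, 0)
  step[!hit] <- -1 / (N - nh)
  running <- cumsum(step)
  es <- running[which.max(abs(running))]
  list(es = es, running_sum = running)
}

## ES for many sets on one ranking; sets given as list of membership vectors.
.es_many <- function(ranked, gene_sets, weight_exponent) {
  vapply(gene_sets, function(s)
    enrichment_score(ranked, s, weight_exponent)$es, numeric(1))
}

#' GSEA with permutation significance (NES, sign-restricted p, FDR)
#'
#' Computes enrichment scores for a collection of gene sets and calibrates
#' them against a permutation null. In `"sample"` mode the condition labels
#' are permuted and genes re-ranked for every permutation (preserving
#' gene-gene correlation); in `"gene"` mode random gene sets of matched size
#' are drawn from the ranked list. `"auto"` picks sample mode when both
#' groups have >= 7 samples, gene mode otherwise.
#'
#' Following the standard sign-restricted procedure, the p-value for a set
#' compares `|ES_obs|` only against null ES of the same sign, with add-one
#' smoothing; NES divides ES by the mean `|null ES|` of the same sign; the
#' FDR q-value compares the same-sign tail fractions of the null and
#' observed NES distributions.
#'
#' @param expr An `expression_set`.
#' @param gene_sets Named list of gene sets.
#' @param n_perm Number of permutations (>= 100).
#' @param perm_mode `"auto"`, `"sample"`, or `"gene"`.
#' @param weight_exponent Passed to [enrichment_score()].
#' @param metric Passed to [rank_genes()].
#' @param seed Integer seed.
#' @return Object of class `gsea_result`: data.frame with `set_name`,
#'   `size` (genes in the ranked list), `es`, `nes`, `p_sign_restricted`,
#'   `fdr_q`, `no_same_sign_null` (flag). Attribute `perm_mode` records the
#'   mode used.
#' @export
gsea <- function(expr, gene_sets, n_perm = 1000L,
                 perm_mode = c("auto", "sample", "gene"),
                 weight_exponent = 1, metric = "s2n", seed) {
  perm_mode <- match.arg(perm_mode)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  ranked <- rank_genes(expr, metric)
  if (perm_mode == "auto")
    perm_mode <- if (min(table(expr$condition)) >= 7L) "sample" else "gene"
  sets <- lapply(gene_sets, function(s) intersect(s, ranked$gene))
  es_obs <- .es_many(ranked, sets, weight_exponent)
  n_sets <- length(sets)
  null_es <- withr::with_seed(seed, {
    if (perm_mode == "sample") {
      t(vapply(seq_len(n_perm), function(i) {
        pexpr <- expr
        pexpr$condition <- sample(expr$condition)
        .es_many(rank_genes(pexpr, metric), sets, weight_exponent)
      }, numeric(n_sets)))
    } else {
      sizes <- lengths(sets)
      out <- matrix(NA_real_, n_perm, n_sets)
      for (j in seq_len(n_sets)) {
        out[, j] <- vapply(seq_len(n_perm), function(i)
          enrichment_score(ranked, sample(ranked$gene, sizes[[j]]),
                           weight_exponent)$es, numeric(1))
      }
      out
    }
  })
  if (n_sets == 1L) null_es <- matrix(null_es, ncol = 1L)
  nes <- p <- rep(NA_real_, n_sets)
  flag <- logical(n_sets)
  null_nes <- matrix(NA_real_, n_perm, n_sets)
  for (j in seq_len(n_sets)) {
    nj <- null_es[, j]
    same <- nj[sign(nj) == sign(es_obs[[j]]) & nj != 0]
    if (length(same) == 0L) {
      flag[[j]] <- TRUE
      p[[j]] <- 1
      next
    }
    nes[[j]] <- es_obs[[j]] / mean(abs(same))
    p[[j]] <- (sum(abs(same) >= abs(es_obs[[j]])) + 1) / (length(same) + 1)
    pos_mean <- mean(nj[nj > 0])
    neg_mean <- mean(abs(nj[nj < 0]))
    null_nes[, j] <- ifelse(nj > 0, nj / pos_mean, nj / neg_mean)
  }
  all_null_nes <- null_nes[is.finite(null_nes)]
  fdr <- vapply(seq_len(n_sets), function(j) {
    if (is.na(nes[[j]])) return(NA_real_)
    v <- nes[[j]]
    if (v >= 0) {
      num <- mean(all_null_nes[all_null_nes >= 0] >= v)
      den <- mean(nes[!is.na(nes) & nes >= 0] >= v)
    } else {
      num <- mean(all_null_nes[all_null_nes < 0] <= v)
      den <- mean(nes[!is.na(nes) & nes < 0] <= v)
    }
    if (!is.finite(den) || den == 0) return(1)
    min(1, num / den)
  }, numeric(1))
  out <- data.frame(set_name = names(gene_sets), size = lengths(sets),
                    es = es_obs, nes = nes, p_sign_restricted = p,
                    fdr_q = fdr, no_same_sign_null = flag,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "perm_mode") <- perm_mode
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("GSEA (", attr(x, "perm_mode"), "-permutation null, ",
      nrow(x), " set(s))\n", sep = "")
  print.data.frame(x, digits = 3)
  invisible(x)
}
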