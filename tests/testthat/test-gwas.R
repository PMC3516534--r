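mini_sumstats <- function(snp, pos, p = 0.5, beta = 0.1, se = 0.05,
                          chrom = "1") {
  data.frame(snp = snp, chrom = chrom, pos = as.integer(pos),
             effect_allele = "A", other_allele = "G", beta = beta, se = se,
             p = p, stringsAsFactors = FALSE)
}

mini_annot <- function(gene, start, end, chrom = "1") {
  data.frame(gene = gene, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = "+", stringsAsFactors = FALSE)
}

test_that("SNP-to-gene mapping honours the window boundary exactly", {
  ann <- mini_annot("GENE1", 1000000, 1050000)
  ss <- mini_sumstats(c("in_body", "at_edge", "past_edge", "before"),
                      c(1025000, 1050000 + 499999, 1050000 + 500001,
                        1000000 - 500000))
  m <- map_snps_to_genes(ss, ann, 500000)
  expect_setequal(m$snp, c("in_body", "at_edge", "before"))
  expect_error(map_snps_to_genes(ss, ann, -1), "non-negative")

  ## shrinking the window never adds SNPs
  m250 <- map_snps_to_genes(ss, ann, 250000)
  expect_true(all(m250$snp %in% m$snp))
})

test_that("mapping equals a brute-force interval check on random layouts", {
  withr::with_seed(41, {
    ann <- mini_annot(sprintf("G%02d", 1:15),
                      start = sample.int(5e6, 15),
                      end = NA, chrom = sample(c("1", "2"), 15, TRUE))
    ann$end <- ann$start + sample.int(100000, 15)
    ss <- mini_sumstats(sprintf("rs%03d", 1:200),
                        pos = sample.int(6e6, 200),
                        chrom = sample(c("1", "2"), 200, TRUE))
  })
  w <- 200000
  m <- map_snps_to_genes(ss, ann, w)
  bf <- character()
  for (i in seq_len(nrow(ann))) for (j in seq_len(nrow(ss)))
    if (ann$chrom[i] == ss$chrom[j] && ss$pos[j] >= ann$start[i] - w &&
        ss$pos[j] <= ann$end[i] + w)
      bf <- c(bf, paste(ann$gene[i], ss$snp[j]))
  expect_setequal(paste(m$gene, m$snp), bf)
  expect_setequal(attr(m, "unscored_genes"),
                  setdiff(ann$gene, m$gene))
})

test_that("gene scores pick the best SNP and correct for confounders", {
  ## constant confounders: corrected ranking equals raw ranking
  ann <- mini_annot(sprintf("G%02d", 1:10), seq(1e6, 1e7, 1e6),
                    seq(1e6, 1e7, 1e6) + 1000)
  ss <- mini_sumstats(sprintf("rs%02d", 1:10), seq(1e6, 1e7, 1e6) + 500,
                      p = withr::with_seed(42, runif(10)))
  sc <- score_genes(map_snps_to_genes(ss, ann, 100))
  expect_identical(order(sc$corrected_score), order(sc$raw_score))
  expect_equal(sc$raw_score, -log10(ss$p[match(sc$best_snp, ss$snp)]))

  ## best_p = 1 -> raw score 0; tie broken by lowest position
  ss2 <- mini_sumstats(c("a", "b"), c(1500, 1200), p = 1)
  sc2 <- score_genes(map_snps_to_genes(ss2, mini_annot("G1", 1000, 2000), 0))
  expect_equal(sc2$raw_score, 0)
  expect_identical(sc2$best_snp, "b")
  expect_identical(sc2$n_snps, 2L)
})

test_that("confounder residualization removes SNP-count dependence", {
  withr::with_seed(43, {
    n <- 2000
    ann <- mini_annot(sprintf("G%04d", 1:n), seq(1, by = 5e5, length.out = n),
                      seq(1, by = 5e5, length.out = n) + 50000)
    n_snps <- sample(1:50, n, replace = TRUE)
    ## raw score driven by SNP count plus noise
    best_p <- 10^-(2 * log10(n_snps) + rnorm(n, 0, 0.3))
  })
  rows <- lapply(seq_len(n), function(i) {
    k <- n_snps[i]
    data.frame(gene = ann$gene[i], snp = paste0("rs", i, "_", seq_len(k)),
               pos = ann$start[i] + seq_len(k), p = c(best_p[i],
                                                      rep(1, k - 1)),
               beta = 0.1, se = 0.05, gene_length = 50001L,
               stringsAsFactors = FALSE)
  })
  mapping <- do.call(rbind, rows)
  attr(mapping, "window_bp") <- 0L
  sc <- score_genes(mapping)
  expect_lt(abs(cor(sc$corrected_score, log10(sc$n_snps))), 0.05)
  expect_true(all(sc$percentile > 0 & sc$percentile <= 1))
})

test_that("cutoff enrichment matches the hypergeometric tail on rank scores", {
  ## scores are an exact permutation of ranks 1..100
  ann <- mini_annot(sprintf("G%03d", 1:100), seq(1, by = 2e6, length.out = 100),
                    seq(1, by = 2e6, length.out = 100) + 1000)
  ss <- mini_sumstats(sprintf("rs%03d", 1:100), ann$start + 500,
                      p = 10^-(1:100 / 10))
  sc <- score_genes(map_snps_to_genes(ss, ann, 100))
  top5 <- sc$gene[order(-sc$corrected_score)][1:5]
  set <- c(top5, sc$gene[order(-sc$corrected_score)][31:45])  # 20 genes
  ce <- cutoff_enrichment(sc, set, 0.95, n_sim = 20000, seed = 44)
  expect_identical(ce$observed_above, 5L)
  ## exact tail: P(X >= 5) drawing 20 from N=100 with K=5 successes
  p_exact <- phyper(4, 5, 95, 20, lower.tail = FALSE)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(ce$p_empirical$raw_freq - p_exact), 3 * mc_se)
  ## whole-universe set: observed equals expected exactly
  ce_all <- cutoff_enrichment(sc, sc$gene, 0.95, n_sim = 500, seed = 45)
  expect_equal(ce_all$observed_above, ce_all$expected_above)
  expect_gt(ce_all$p_empirical$p, 0.4)
  ## determinism
  ce2 <- cutoff_enrichment(sc, set, 0.95, n_sim = 1000, seed = 46)
  ce3 <- cutoff_enrichment(sc, set, 0.95, n_sim = 1000, seed = 46)
  expect_equal(ce2$p_empirical$p, ce3$p_empirical$p)
  expect_error(cutoff_enrichment(sc, "NOTSCORED", n_sim = 10, seed = 1),
               "no scored genes")
})

test_that("joint best-SNP statistic supports compound extremeness", {
  sc <- structure(data.frame(
    gene = sprintf("G%02d", 1:40), best_snp = sprintf("rs%02d", 1:40),
    best_p = withr::with_seed(47, runif(40)), raw_score = 1,
    corrected_score = 1, percentile = 0.5, gene_length = 1000L,
    n_snps = 1L, stringsAsFactors = FALSE),
    class = c("gene_scores", "data.frame"))
  const_stat <- function(rows) list(p = 0.5, beta = 1)
  res <- best_snp_joint_significance(sc, sc$gene[1:10], const_stat,
                                     n_sim = 100, seed = 48)
  expect_equal(res$p, 1)  # every null draw ties the observation
  strong <- function(rows)
    list(p = if (all(rows$gene %in% sc$gene[1:10])) 1e-10 else 0.5, beta = 1)
  res2 <- best_snp_joint_significance(sc, sc$gene[1:10], strong,
                                      n_sim = 100, seed = 49)
  expect_equal(res2$p, 1 / 101)
})

test_that("trait-locus overlap counts and calibrates against random sets", {
  ann <- mini_annot(sprintf("G%02d", 1:40), seq(1, by = 2e6, length.out = 40),
                    seq(1, by = 2e6, length.out = 40) + 50000)
  ## no catalog SNPs near anything -> observed 0, p = 1
  far <- data.frame(chrom = "9", pos = 1e6, trait = "t")
  r0 <- trait_locus_overlap(ann$gene[1:10], far, ann, 250000, 100, seed = 50)
  expect_identical(r0$observed, 0L)
  expect_equal(r0$p, 1)
  ## every gene near a SNP -> null saturates, p ~ 1
  near_all <- data.frame(chrom = "1", pos = ann$start + 100, trait = "t")
  r1 <- trait_locus_overlap(ann$gene[1:10], near_all, ann, 250000, 100,
                            seed = 51)
  expect_identical(r1$observed, 10L)
  expect_equal(r1$p, 1)
  ## catalog planted near the first 10 genes only
  planted <- data.frame(chrom = "1", pos = ann$start[1:10] + 100,
                        trait = "t")
  r2 <- trait_locus_overlap(ann$gene[1:10], planted, ann, 250000,
                            n_sim = 2000, seed = 52)
  expect_identical(r2$observed, 10L)  # brute-force count
  expect_lt(r2$p, 0.05)
})
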