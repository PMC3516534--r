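make_calls <- function(expressed, unexpressed = character()) {
  d <- data.frame(gene = c(expressed, unexpressed),
                  stringsAsFactors = FALSE)
  for (t in c("adipose", "muscle", "liver", "heart")) d[[t]] <- FALSE
  if (length(expressed)) d$liver[seq_along(expressed)] <- TRUE
  d
}

ppi_df <- function(a, b, labs) {
  data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b), source = "PPI",
             provenance = as.character(labs), lab_count = as.integer(labs),
             stringsAsFactors = FALSE)
}

test_that("two-lab filter requires lab count and tissue expression", {
  calls <- make_calls(c("A", "B", "C"), "D")
  e <- ppi_df(c("A", "A", "A", "E"), c("B", "C", "D", "B"), c(2, 1, 3, 2))
  suppressMessages(kept <- filter_ppi_high(e, calls))
  expect_identical(kept$gene_a, "A")   # labs=2, both expressed
  expect_identical(kept$source, "PPIhigh")
  # labs=1 excluded; A-D unexpressed partner; E absent from calls

  ## brute-force predicate oracle on 500 generated edges
  withr::with_seed(5, {
    g <- sprintf("G%03d", 1:60)
    expr_genes <- sample(g, 35)
    calls2 <- make_calls(expr_genes, setdiff(g, expr_genes))
    a <- sample(g[1:30], 500, replace = TRUE)
    b <- sample(g[31:60], 500, replace = TRUE)
    labs <- sample(1:4, 500, replace = TRUE)
  })
  e2 <- ppi_df(a, b, labs)
  suppressMessages(kept2 <- filter_ppi_high(e2, calls2))
  want <- labs >= 2 & a %in% expr_genes & b %in% expr_genes
  expect_identical(nrow(kept2), sum(want))
  expect_setequal(paste(kept2$gene_a, kept2$gene_b),
                  paste(pmin(a, b), pmax(a, b))[want])
})

test_that("co-expression rescue matches a closed-form t-transform oracle", {
  withr::with_seed(8, {
    n <- 30L  # samples
    genes <- sprintf("G%02d", 1:40)
    coexpr <- matrix(rnorm(40 * n), 40, n, dimnames = list(genes, NULL))
    ## plant strong correlation for the first 6 pairs
    for (i in 1:6) coexpr[2 * i, ] <- coexpr[2 * i - 1, ] + 0.2 * rnorm(n)
    a <- genes[seq(1, 39, 2)]
    b <- genes[seq(2, 40, 2)]
  })
  calls <- make_calls(genes)
  edges <- ppi_df(a, b, 1)
  kept <- derive_ppicorr(edges, coexpr, calls, alpha = 0.05)
  expect_true(all(kept$source == "PPIcorr"), info = "source tag")
  expect_true(all(kept$lab_count == 1L))

  ## independent oracle: t = r*sqrt(n-2)/sqrt(1-r^2), BH over all tested
  r <- vapply(seq_along(a), function(i)
    cor(coexpr[a[i], ], coexpr[b[i], ]), numeric(1))
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(tstat), n - 2)
  want <- p.adjust(p, "BH") < 0.05
  expect_setequal(paste(kept$gene_a, kept$gene_b),
                  paste(pmin(a, b), pmax(a, b))[want])
  expect_true(all(paste(pmin(a, b), pmax(a, b))[1:6] %in%
                    paste(kept$gene_a, kept$gene_b)))
})

test_that("co-expression rescue honours expression calls and sample floor", {
  coexpr <- matrix(rep(1:10, 2), 2, 10, byrow = TRUE,
                   dimnames = list(c("A", "B"), NULL))
  edges <- ppi_df("A", "B", 1)
  ## perfect correlation but unexpressed in all tissues -> dropped
  none <- derive_ppicorr(edges, coexpr, make_calls(character(), c("A", "B")))
  expect_identical(nrow(none), 0L)
  ## expressed + r = 1 -> kept
  kept <- derive_ppicorr(edges, coexpr, make_calls(c("A", "B")))
  expect_identical(nrow(kept), 1L)
  expect_error(derive_ppicorr(edges, coexpr[, 1:2], make_calls(c("A", "B"))),
               "insufficient samples")
})

test_that("complex clique expansion multiplies shared membership", {
  e <- complex_edges(list(c1 = c("A", "B", "C")))
  expect_identical(nrow(e), 3L)
  e2 <- complex_edges(list(c1 = c("A", "B"), c2 = c("A", "B")))
  expect_identical(nrow(e2), 2L)
  expect_identical(unique(paste(e2$gene_a, e2$gene_b)), "A B")
  expect_warning(e3 <- complex_edges(list(c1 = "A", c2 = c("X", "Y"))),
                 "< 2 members")
  expect_identical(nrow(e3), 1L)

  ## 20 random complexes vs brute-force double loop
  cx <- withr::with_seed(9, lapply(1:20, function(i)
    sample(sprintf("G%02d", 1:25), sample(2:6, 1))))
  names(cx) <- paste0("c", 1:20)
  got <- complex_edges(cx)
  bf <- do.call(rbind, lapply(cx, function(m) {
    out <- NULL
    for (i in seq_along(m)) for (j in seq_along(m))
      if (i < j) out <- rbind(out, sort(c(m[i], m[j])))
    out
  }))
  expect_identical(sort(paste(got$gene_a, got$gene_b)),
                   sort(paste(bf[, 1], bf[, 2])))
})

test_that("metabolic adjacency links reactions sharing non-currency metabolites", {
  rx <- data.frame(reaction_id = c("R1", "R2"), stringsAsFactors = FALSE)
  rx$substrates <- list("A_met", "B_met")
  rx$products <- list("B_met", "C_met")
  rx$genes <- list("E1", "E2")
  e <- metabolic_adjacency(rx)
  expect_identical(paste(e$gene_a, e$gene_b), "E1 E2")
  expect_match(e$provenance, "B_MET")

  ## shared metabolite on the currency list -> no edge
  rx2 <- rx
  rx2$substrates <- list("A_met", "ATP")
  rx2$products <- list("ATP", "C_met")
  expect_identical(nrow(metabolic_adjacency(rx2)), 0L)

  ## random 15-reaction network vs brute force over reaction pairs
  rxr <- withr::with_seed(10, {
    mets <- c(sprintf("M%02d", 1:12), "ATP", "H2O")
    data.frame(reaction_id = paste0("R", 1:15), stringsAsFactors = FALSE) |>
      within({
        substrates <- lapply(1:15, function(i) sample(mets, 2))
        products <- lapply(1:15, function(i) sample(mets, 2))
        genes <- lapply(1:15, function(i)
          sample(sprintf("E%02d", 1:10), sample(1:2, 1)))
      })
  })
  got <- metabolic_adjacency(rxr)
  cur <- c("ATP", "H2O")
  bf <- character()
  for (i in 1:14) for (j in (i + 1):15) {
    mi <- setdiff(toupper(unique(c(rxr$substrates[[i]], rxr$products[[i]]))), cur)
    mj <- setdiff(toupper(unique(c(rxr$substrates[[j]], rxr$products[[j]]))), cur)
    if (length(intersect(mi, mj)) == 0) next
    for (g1 in rxr$genes[[i]]) for (g2 in rxr$genes[[j]])
      if (g1 != g2) bf <- c(bf, paste(min(g1, g2), max(g1, g2)))
  }
  expect_setequal(unique(paste(got$gene_a, got$gene_b)), unique(bf))
})

test_that("pathway links deduplicate per pathway", {
  rel <- data.frame(gene_a = c("A", "B", "A"), gene_b = c("B", "A", "B"),
                    pathway = c("path1", "path1", "path2"),
                    stringsAsFactors = FALSE)
  e <- pathway_edges(rel)
  expect_identical(nrow(e), 2L)
  expect_setequal(e$provenance, c("path1", "path2"))

  rel2 <- withr::with_seed(12, data.frame(
    gene_a = sample(LETTERS[1:8], 60, TRUE),
    gene_b = sample(LETTERS[9:16], 60, TRUE),
    pathway = sample(paste0("pw", 1:4), 60, TRUE),
    stringsAsFactors = FALSE))
  got <- pathway_edges(rel2)
  bf <- unique(paste(pmin(rel2$gene_a, rel2$gene_b),
                     pmax(rel2$gene_a, rel2$gene_b), rel2$pathway))
  expect_identical(sort(paste(got$gene_a, got$gene_b, got$provenance)),
                   sort(bf))
})

test_that("assembly collapses pairs, keeps evidence, is order-insensitive", {
  e1 <- complex_edges(list(c1 = c("A", "B")))
  e2 <- pathway_edges(data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
                                 pathway = "pw1", stringsAsFactors = FALSE))
  suppressMessages({
    int <- assemble_interactome(e1, e2)
    int_rev <- assemble_interactome(e2, e1)
  })
  expect_identical(int, int_rev)
  expect_identical(nrow(int$pairs), 2L)
  expect_identical(int$pairs$n_evidence[int$pairs$gene_a == "A"], 2L)
  expect_setequal(int$universe, c("A", "B", "C", "D"))
  expect_identical(int$universe, sort(unique(c(int$evidence$gene_a,
                                               int$evidence$gene_b))))
  expect_error(assemble_interactome(), "empty interactome")
})

test_that("no surviving PPI edge involves an all-tissue-unexpressed gene", {
  withr::with_seed(21, {
    g <- sprintf("G%03d", 1:40)
    expr_genes <- sample(g, 20)
    a <- sample(g[1:20], 120, replace = TRUE)
    b <- sample(g[21:40], 120, replace = TRUE)
    labs <- sample(1:3, 120, replace = TRUE)
    coexpr <- matrix(rnorm(40 * 20), 40, 20, dimnames = list(g, NULL))
  })
  calls <- make_calls(expr_genes, setdiff(g, expr_genes))
  e <- ppi_df(a, b, labs)
  suppressMessages({
    high <- filter_ppi_high(e[e$lab_count >= 2, ], calls)
    corr <- derive_ppicorr(e[e$lab_count == 1, ], coexpr, calls, alpha = 0.5)
  })
  surv <- rbind(high, corr)
  expect_true(all(surv$gene_a %in% expr_genes),
              info = "gene_a tissue-expressed")
  expect_true(all(surv$gene_b %in% expr_genes),
              info = "gene_b tissue-expressed")
  expect_true(all(high$lab_count >= 2L))
  expect_true(all(corr$lab_count == 1L))
})
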