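## Synthetic-data generators. Every generator is a pure function of its seed
## and parameters and returns a `ledger` holding all planted ground truth,
## sufficient to verify recovery without external references.

#' Generate a synthetic multi-source interactome with planted internodes
#'
#' Emulates the structure of a two-system crosstalk study: two parts lists
#' (systems A and B), a set of planted internode genes each connected to
#' both systems, background genes connected to at most one system, and decoy
#' interactions designed to be removed by the quality filters (single-lab
#' PPIs without co-expression support, PPIs between tissue-unexpressed
#' genes). Evidence for every planted edge is spread over the five source
#' types; all source-specific input tables (PPI with lab counts, complex
#' memberships, metabolic reactions, pathway relations, tissue calls and a
#' co-expression matrix consistent with the planted PPIcorr survivors) are
#' produced, so the full pipeline can run from raw inputs.
#'
#' @param n_a,n_b Sizes of the two system parts lists.
#' @param n_internodes Number of planted linker genes.
#' @param n_background Genes attached to exactly one system.
#' @param n_direct Direct A-B edges to plant.
#' @param evidence_profile List with `max_partners` (partners per internode
#'   per side, drawn uniformly from 1..max), `max_evid_per_edge` (evidence
#'   records per edge, uniform 1..max) and `min_evid_side` (per-side total
#'   evidence floor per internode; topped up with complex evidence).
#' @param n_decoys Number of planted-to-fail PPI edges.
#' @param coexpr_samples Samples in the co-expression compendium (>= 3).
#' @param seed Integer seed.
#' @return List of class `interactome_sim`: `parts_a`, `parts_b` (parts
#'   lists), `ppi`, `complexes`, `reactions`, `pathways`, `calls`, `coexpr`
#'   (inputs in the formats the readers produce) and `ledger` (planted
#'   truth: internode genes, per-side link/evidence counts, direct pairs,
#'   decoys, parameters).
#' @export
gen_interactome <- function(n_a = 15L, n_b = 20L, n_internodes = 8L,
                            n_background = 30L, n_direct = 4L,
                            evidence_profile = list(max_partners = 3L,
                                                    max_evid_per_edge = 2L,
                                                    min_evid_side = 1L),
                            n_decoys = 10L, coexpr_samples = 200L, seed) {
  stopifnot(n_a >= 1L, n_b >= 1L, n_internodes >= 0L, n_background >= 0L)
  prof <- evidence_profile
  if (is.null(prof$max_partners) || is.null(prof$max_evid_per_edge) ||
      is.null(prof$min_evid_side) || prof$max_partners < 1L ||
      prof$max_evid_per_edge < 1L)
    stop("inconsistent evidence profile", call. = FALSE)
  if (prof$max_partners > min(n_a, n_b))
    stop("inconsistent evidence profile: max_partners exceeds system size",
         call. = FALSE)
  withr::with_seed(seed, {
    A <- sprintf("SYSA%03d", seq_len(n_a))
    B <- sprintf("SYSB%03d", seq_len(n_b))
    links <- sprintf("LNK%03d", seq_len(n_internodes))
    bg <- sprintf("BG%03d", seq_len(n_background))
    env <- new.env()
    env$ppi <- list(); env$complexes <- list(); env$reactions <- list()
    env$pathways <- list(); env$corr_pairs <- list()
    env$expressed <- character(); env$unexpressed <- character()
    env$counter <- 0L
    env$src_counts <- stats::setNames(
      integer(5), c("COMPLEX", "MET_adj", "PATH", "PPIcorr", "PPIhigh"))
    uid <- function() { env$counter <- env$counter + 1L; env$counter }

    add_evidence <- function(g1, g2, source) {
      id <- uid()
      tag <- if (source == "MET") "MET_adj" else source
      env$src_counts[[tag]] <- env$src_counts[[tag]] + 1L
      if (source == "PPIhigh") {
        env$ppi[[length(env$ppi) + 1L]] <-
          data.frame(geneA = g1, geneB = g2, source = "PPI",
                     provenance = as.character(sample(2:4, 1L)),
                     stringsAsFactors = FALSE)
        env$expressed <- c(env$expressed, g1, g2)
      } else if (source == "PPIcorr") {
        env$ppi[[length(env$ppi) + 1L]] <-
          data.frame(geneA = g1, geneB = g2, source = "PPI",
                     provenance = "1", stringsAsFactors = FALSE)
        env$expressed <- c(env$expressed, g1, g2)
        env$corr_pairs[[length(env$corr_pairs) + 1L]] <- c(g1, g2)
      } else if (source == "COMPLEX") {
        env$complexes[[paste0("CPX", id)]] <- c(g1, g2)
      } else if (source == "MET") {
        env$reactions[[length(env$reactions) + 1L]] <- list(
          data.frame(reaction_id = paste0("R", id, "a"),
                     substrates = paste0("MIN", id),
                     products = paste0("MSH", id),
                     genes = g1, stringsAsFactors = FALSE),
          data.frame(reaction_id = paste0("R", id, "b"),
                     substrates = paste0("MSH", id),
                     products = paste0("MOUT", id),
                     genes = g2, stringsAsFactors = FALSE))
      } else { # PATH
        env$pathways[[length(env$pathways) + 1L]] <-
          data.frame(geneA = g1, geneB = g2,
                     pathway = paste0("PW", id), stringsAsFactors = FALSE)
      }
      invisible(NULL)
    }

    ## one pair carries at most one PPI-type record; extra evidence comes
    ## from complexes / reactions / pathways
    plant_edge <- function(g1, g2, n_evid) {
      first <- sample(c("PPIhigh", "PPIcorr", "COMPLEX", "MET", "PATH"), 1L)
      add_evidence(g1, g2, first)
      if (n_evid > 1L)
        for (s in sample(c("COMPLEX", "MET", "PATH"), n_evid - 1L,
                         replace = TRUE))
          add_evidence(g1, g2, s)
      n_evid
    }

    truth <- NULL
    if (n_internodes > 0L) {
      truth <- do.call(rbind, lapply(links, function(g) {
        plant_side <- function(side_genes) {
          partners <- sample(side_genes, sample.int(prof$max_partners, 1L))
          evid <- sum(vapply(partners, function(p)
            plant_edge(g, p, sample.int(prof$max_evid_per_edge, 1L)),
            numeric(1)))
          while (evid < prof$min_evid_side) {
            add_evidence(g, partners[[1L]], "COMPLEX")
            evid <- evid + 1L
          }
          c(length(partners), evid)
        }
        sa <- as.integer(plant_side(A))
        sb <- as.integer(plant_side(B))
        data.frame(gene = g, links_a = sa[[1]], evid_a = sa[[2]],
                   links_b = sb[[1]], evid_b = sb[[2]],
                   stringsAsFactors = FALSE)
      }))
    }

    direct <- NULL
    if (n_direct > 0L) {
      da <- sample(A, n_direct, replace = n_direct > n_a)
      db <- sample(B, n_direct, replace = n_direct > n_b)
      dup <- duplicated(paste(da, db))
      da <- da[!dup]; db <- db[!dup]
      for (i in seq_along(da)) plant_edge(da[[i]], db[[i]], 1L)
      direct <- data.frame(gene_a = pmin(da, db), gene_b = pmax(da, db),
                           stringsAsFactors = FALSE)
    }

    ## background genes touch exactly one system
    if (n_background > 0L) {
      side <- rep(c("A", "B"), length.out = n_background)
      for (i in seq_len(n_background)) {
        partner <- if (side[[i]] == "A") sample(A, 1L) else sample(B, 1L)
        plant_edge(bg[[i]], partner, 1L)
      }
    }

    ## decoys: PPIs that must not survive filtering
    decoys <- character()
    if (n_decoys > 0L) {
      for (i in seq_len(n_decoys)) {
        d1 <- sprintf("DEC%03dX", i)
        d2 <- sprintf("DEC%03dY", i)
        labs <- if (i %% 2L == 0L) "1" else "2"
        env$ppi[[length(env$ppi) + 1L]] <-
          data.frame(geneA = d1, geneB = d2, source = "PPI",
                     provenance = labs, stringsAsFactors = FALSE)
        ## odd decoys listed as unexpressed, even ones absent from calls
        if (i %% 2L == 1L) env$unexpressed <- c(env$unexpressed, d1, d2)
        decoys <- c(decoys, d1, d2)
      }
    }

    ppi <- if (length(env$ppi))
      do.call(rbind, c(env$ppi, list(make.row.names = FALSE)))
    else data.frame(geneA = character(), geneB = character(),
                    source = character(), provenance = character(),
                    stringsAsFactors = FALSE)
    ppi$lab_count <- as.integer(ppi$provenance)
    names(ppi) <- c("geneA", "geneB", "source", "provenance", "lab_count")
    lo <- pmin(ppi$geneA, ppi$geneB); hi <- pmax(ppi$geneA, ppi$geneB)
    ppi <- data.frame(gene_a = lo, gene_b = hi, source = ppi$source,
                      provenance = ppi$provenance,
                      lab_count = ppi$lab_count, stringsAsFactors = FALSE)

    ## tissue calls: expressed genes TRUE in one tissue, decoys all FALSE
    expressed <- sort(unique(env$expressed))
    calls <- data.frame(gene = c(expressed, sort(unique(env$unexpressed))),
                        stringsAsFactors = FALSE)
    for (t in DEFAULT_TISSUES) calls[[t]] <- FALSE
    if (length(expressed)) {
      tis <- sample(DEFAULT_TISSUES, length(expressed), replace = TRUE)
      for (i in seq_along(expressed)) calls[i, tis[[i]]] <- TRUE
    }

    ## co-expression matrix: planted pairs share a latent factor
    corr_genes <- sort(unique(unlist(env$corr_pairs)))
    noise_genes <- sprintf("CXN%03d", seq_len(6L))
    all_cx <- c(corr_genes, noise_genes)
    coexpr <- matrix(stats::rnorm(length(all_cx) * coexpr_samples) * 0.2,
                     nrow = length(all_cx), ncol = coexpr_samples,
                     dimnames = list(all_cx,
                                     paste0("S", seq_len(coexpr_samples))))
    if (length(env$corr_pairs)) {
      for (pr in env$corr_pairs) {
        f <- stats::rnorm(coexpr_samples)
        for (g in pr) coexpr[g, ] <- coexpr[g, ] + f
      }
    }

    reactions <- if (length(env$reactions))
      do.call(rbind, c(unlist(env$reactions, recursive = FALSE),
                       list(make.row.names = FALSE)))
    else data.frame(reaction_id = character(), substrates = character(),
                    products = character(), genes = character(),
                    stringsAsFactors = FALSE)
    pathways <- if (length(env$pathways))
      do.call(rbind, c(env$pathways, list(make.row.names = FALSE)))
    else data.frame(geneA = character(), geneB = character(),
                    pathway = character(), stringsAsFactors = FALSE)

    structure(list(
      parts_a = parts_list(A, "systemA"),
      parts_b = parts_list(B, "systemB"),
      ppi = ppi,
      complexes = env$complexes,
      reactions = data.frame(
        reaction_id = reactions$reaction_id,
        substrates = I(as.list(reactions$substrates)),
        products = I(as.list(reactions$products)),
        genes = I(lapply(reactions$genes, identity)),
        stringsAsFactors = FALSE),
      pathways = data.frame(gene_a = pmin(pathways$geneA, pathways$geneB),
                            gene_b = pmax(pathways$geneA, pathways$geneB),
                            pathway = pathways$pathway,
                            stringsAsFactors = FALSE),
      calls = calls,
      coexpr = coexpr,
      ledger = list(seed = seed, n_a = n_a, n_b = n_b,
                    internodes = truth, direct = direct,
                    background = bg, decoys = decoys,
                    source_counts = env$src_counts[env$src_counts > 0L],
                    evidence_profile = prof)),
      class = "interactome_sim")
  })
}

#' Run the assembly filters on simulated (or file-loaded) inputs
#'
#' Applies the full per-source filter chain — two-lab PPI filter,
#' co-expression rescue of single-lab PPIs, complex clique expansion,
#' metabolic adjacency, pathway links — and assembles the surviving evidence
#' into one interactome.
#'
#' @param inputs A list with elements `ppi`, `complexes`, `reactions`,
#'   `pathways`, `calls`, `coexpr` (as produced by [gen_interactome()] or by
#'   the readers in this package).
#' @param corr_method,corr_fdr_alpha,tissues,currency_metabolites Filter
#'   configuration (see [derive_ppicorr()], [metabolic_adjacency()],
#'   [filter_ppi_high()]).
#' @return An `interactome` object.
#' @export
assemble_from_inputs <- function(inputs, corr_method = "pearson",
                                 corr_fdr_alpha = 0.05,
                                 tissues = DEFAULT_TISSUES,
                                 currency_metabolites = DEFAULT_CURRENCY) {
  ppi <- inputs$ppi
  multi <- ppi[ppi$lab_count >= 2L, , drop = FALSE]
  single <- ppi[ppi$lab_count == 1L, , drop = FALSE]
  ev <- list()
  if (nrow(multi))
    ev$high <- filter_ppi_high(multi, inputs$calls, tissues)
  if (nrow(single))
    ev$corr <- derive_ppicorr(single, inputs$coexpr, inputs$calls,
                              corr_method, corr_fdr_alpha, tissues)
  if (length(inputs$complexes))
    ev$complex <- complex_edges(inputs$complexes)
  if (nrow(inputs$reactions))
    ev$met <- metabolic_adjacency(inputs$reactions, currency_metabolites)
  if (nrow(inputs$pathways))
    ev$path <- pathway_edges(inputs$pathways)
  do.call(assemble_interactome, unname(ev))
}

#' Write simulated interactome inputs as pipeline-readable files
#'
#' Writes every input table of an [gen_interactome()] simulation in exactly
#' the formats the `read_*` functions consume: `ppi.tsv`, `complexes.tsv`,
#' `reactions.tsv`, `pathways.tsv`, `tissue_calls.tsv`, `coexpr.tsv`,
#' `parts_a.txt`, `parts_b.txt`.
#'
#' @param sim An `interactome_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of file paths.
#' @export
write_interactome_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) {
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(dir, f)
  }
  paths <- c(
    ppi = w(data.frame(geneA = sim$ppi$gene_a, geneB = sim$ppi$gene_b,
                       source = sim$ppi$source,
                       provenance = sim$ppi$provenance), "ppi.tsv"),
    complexes = w(data.frame(
      complex_id = rep(names(sim$complexes), lengths(sim$complexes)),
      gene = unlist(sim$complexes)), "complexes.tsv"),
    reactions = w(data.frame(
      reaction_id = sim$reactions$reaction_id,
      substrates = vapply(sim$reactions$substrates, paste, character(1),
                          collapse = ";"),
      products = vapply(sim$reactions$products, paste, character(1),
                        collapse = ";"),
      genes = vapply(sim$reactions$genes, paste, character(1),
                     collapse = ";")), "reactions.tsv"),
    pathways = w(data.frame(geneA = sim$pathways$gene_a,
                            geneB = sim$pathways$gene_b,
                            pathway = sim$pathways$pathway), "pathways.tsv"),
    calls = w(sim$calls, "tissue_calls.tsv"),
    coexpr = w(data.frame(gene = rownames(sim$coexpr), sim$coexpr,
                          check.names = FALSE), "coexpr.tsv"))
  writeLines(sim$parts_a$genes, file.path(dir, "parts_a.txt"))
  writeLines(sim$parts_b$genes, file.path(dir, "parts_b.txt"))
  paths <- c(paths, parts_a = file.path(dir, "parts_a.txt"),
             parts_b = file.path(dir, "parts_b.txt"))
  invisible(paths)
}

#' Generate expression data with planted differential gene sets
#'
#' Baseline expression is iid standard normal per gene and sample; each
#' signal set's genes are shifted by `effect_sd_units` standard deviations
#' (sign per set) in the second condition level, mirroring perturbation
#' experiments where a signature moves coherently up or down.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per condition group.
#' @param signal_sets Named list of gene index vectors or gene symbol
#'   vectors (symbols are `G0001`-style).
#' @param effect_sd_units Named numeric vector (one per signal set), in
#'   units of the within-group standard deviation; sign gives direction.
#' @param seed Integer seed.
#' @return List of class `expression_sim`: `expr` (an `expression_set`) and
#'   `ledger` (planted sets and effects).
#' @export
gen_expression <- function(n_genes = 2000L, n_per_group = 12L,
                           signal_sets = list(), effect_sd_units = numeric(),
                           seed) {
  genes <- sprintf("G%04d", seq_len(n_genes))
  sets <- lapply(signal_sets, function(s)
    if (is.numeric(s)) genes[s] else toupper(s))
  if (length(sets)) {
    stopifnot(length(effect_sd_units) == length(sets),
              identical(names(effect_sd_units), names(sets)))
    if (length(sets) > 1L) {
      for (i in seq_along(sets)[-1]) for (j in seq_len(i - 1L)) {
        shared <- intersect(sets[[i]], sets[[j]])
        if (length(shared) &&
            sign(effect_sd_units[[i]]) != sign(effect_sd_units[[j]]))
          stop("overlapping signal sets with conflicting signs",
               call. = FALSE)
      }
    }
  }
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_genes * 2L * n_per_group), nrow = n_genes,
                dimnames = list(genes,
                                paste0("S", seq_len(2L * n_per_group))))
    cond <- rep(c("control", "case"), each = n_per_group)
    case <- cond == "case"
    for (nm in names(sets))
      m[sets[[nm]], case] <- m[sets[[nm]], case] + effect_sd_units[[nm]]
    structure(list(expr = expression_set(m, factor(cond,
                                                   c("control", "case"))),
                   ledger = list(seed = seed, signal_sets = sets,
                                 effect_sd_units = effect_sd_units)),
              class = "expression_sim")
  })
}

#' Generate LD-free GWAS summary statistics with planted effects
#'
#' Lays out `n_genes` gene regions on one chromosome, spaced so that the
#' standard 500 kb mapping windows never overlap, places `snps_per_gene`
#' SNPs inside each gene body, simulates independent genotypes
#' `Binomial(2, maf)` for `n_individuals`, builds the phenotype as the sum
#' of planted per-allele effects plus standard normal noise, and computes
#' per-SNP marginal regressions (beta, se, p). The ledger records every
#' SNP's gene, its true effect, and the causal SNP of each effect gene.
#'
#' @param n_genes Number of gene regions.
#' @param snps_per_gene SNPs per gene.
#' @param effect_genes Named numeric vector: gene symbol (`GENE001`-style)
#'   -> per-allele effect planted on that gene's first SNP.
#' @param n_individuals Cohort size (>= 50; se estimates are unstable
#'   below).
#' @param maf_range Range for per-SNP minor allele frequencies.
#' @param gene_length_bp,gene_spacing_bp Region layout (defaults 50 kb genes
#'   every 2 Mb).
#' @param seed Integer seed.
#' @return List of class `sumstats_sim`: `sumstats`, `annotation` (reader
#'   formats) and `ledger` (snp->gene map, true effects, phenotype model).
#' @export
gen_sumstats <- function(n_genes = 50L, snps_per_gene = 10L,
                         effect_genes = numeric(), n_individuals = 5000L,
                         maf_range = c(0.1, 0.5), gene_length_bp = 50000L,
                         gene_spacing_bp = 2000000L, seed) {
  if (n_individuals < 50L)
    stop("n_individuals must be >= 50 (se estimates unstable)",
         call. = FALSE)
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  if (length(effect_genes))
    stopifnot(all(names(effect_genes) %in% genes))
  starts <- 1L + (seq_len(n_genes) - 1L) * gene_spacing_bp
  annotation <- data.frame(gene = genes, chrom = "1", start = starts,
                           end = starts + gene_length_bp - 1L,
                           strand = "+", stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    n_snps <- n_genes * snps_per_gene
    snp_gene <- rep(genes, each = snps_per_gene)
    offs <- vapply(seq_len(n_snps), function(i)
      sample.int(gene_length_bp, 1L), integer(1))
    ## the causal SNP of an effect gene is that gene's first SNP
    pos <- starts[rep(seq_len(n_genes), each = snps_per_gene)] + offs - 1L
    snp <- sprintf("rs%05d", seq_len(n_snps))
    maf <- stats::runif(n_snps, maf_range[[1]], maf_range[[2]])
    eff <- stats::setNames(numeric(n_snps), snp)
    causal <- character(0)
    if (length(effect_genes)) {
      idx <- match(names(effect_genes), genes)
      causal_idx <- (idx - 1L) * snps_per_gene + 1L
      eff[causal_idx] <- unname(effect_genes)
      causal <- snp[causal_idx]
    }
    G <- vapply(maf, function(f)
      stats::rbinom(n_individuals, 2L, f), numeric(n_individuals))
    y <- as.vector(G %*% eff) + stats::rnorm(n_individuals)
    ## vectorized marginal OLS per SNP
    n <- n_individuals
    xbar <- colMeans(G)
    Sxx <- colSums(G^2) - n * xbar^2
    Sxy <- colSums(G * y) - n * xbar * mean(y)
    Syy <- sum(y^2) - n * mean(y)^2
    beta <- Sxy / Sxx
    sigma2 <- pmax((Syy - beta * Sxy) / (n - 2), .Machine$double.eps)
    se <- sqrt(sigma2 / Sxx)
    tstat <- beta / se
    p <- pmin(pmax(2 * stats::pt(-abs(tstat), n - 2),
                   .Machine$double.xmin), 1)
    sumstats <- data.frame(snp = snp, chrom = "1", pos = pos,
                           effect_allele = "A", other_allele = "G",
                           beta = beta, se = se, p = p,
                           stringsAsFactors = FALSE)
    structure(list(sumstats = sumstats, annotation = annotation,
                   ledger = list(seed = seed, snp_gene = stats::setNames(
                     snp_gene, snp), true_effects = eff,
                     causal_snps = causal, maf = stats::setNames(maf, snp),
                     n_individuals = n_individuals,
                     genotype_score_oracle = if (length(effect_genes)) {
                       S <- rowSums(G[, causal_idx, drop = FALSE])
                       fit <- stats::lm(y ~ S)
                       list(beta = unname(stats::coef(fit)[[2]]),
                            se = unname(sqrt(diag(stats::vcov(fit)))[[2]]))
                     })),
              class = "sumstats_sim")
  })
}

#' Published 31-gene high-confidence internode table
#'
#' Returns the packaged transcription of the published table of strong
#' crosstalk candidates: 31 internode genes with their listed insulin
#' (system A) and mitochondria (system B) partner genes and the printed
#' per-system link and evidence counts. One row (RELA) lists a partner
#' twice in the source; the transcription is verbatim.
#'
#' @return Data.frame with columns `gene`, `total_links`, `total_evid`,
#'   `links_a`, `evid_a`, `links_b`, `evid_b`, `partners_a`, `partners_b`
#'   (`|`-joined), in published row order.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_internodes.tsv",
                      package = "internode", mustWork = TRUE)
  .read_tsv(path)
}
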