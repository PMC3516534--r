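#' Default pipeline configuration
#'
#' Returns the full configuration list with every threshold at its default:
#' `lab_count_min = 2`, `corr_fdr_alpha = 0.05`, `min_evidence = 3` (per
#' system, for the high-confidence subset), `window_bp = 500000`,
#' `catalog_window_bp = 250000`, `percentile_cutoff = 0.95`,
#' `n_sim = 10000`, `n_perm = 1000`, `alpha = 0.05`, `min_overlap = 10`.
#' Input paths are `NULL` placeholders; stages whose inputs are missing are
#' skipped.
#'
#' @param ... Named overrides of defaults (including `inputs`, a named list
#'   of file paths).
#' @return Configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    inputs = list(ppi = NULL, complexes = NULL, reactions = NULL,
                  pathways = NULL, tissue_calls = NULL, coexpr = NULL,
                  parts_a = NULL, parts_b = NULL, gmt = NULL,
                  expression = NULL, expression_labels = NULL,
                  sumstats = NULL, annotation = NULL,
                  annotation_dialect = "tsv", trait_sumstats = NULL,
                  catalog_snps = NULL),
    lab_count_min = 2L, corr_fdr_alpha = 0.05, corr_method = "pearson",
    min_evidence = 3L, window_bp = 500000L, catalog_window_bp = 250000L,
    percentile_cutoff = 0.95, n_sim = 10000L, n_perm = 1000L, alpha = 0.05,
    min_overlap = 10L, seed = 1L)
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm == "inputs") cfg$inputs[names(ov$inputs)] <- ov$inputs
    else cfg[[nm]] <- ov[[nm]]
  }
  .validate_config(cfg)
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the keys of [default_config()].
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

.validate_config <- function(cfg) {
  stopifnot(cfg$lab_count_min >= 1L,
            cfg$corr_fdr_alpha > 0, cfg$corr_fdr_alpha < 1,
            cfg$min_evidence >= 0L, cfg$window_bp >= 0L,
            cfg$catalog_window_bp >= 0L,
            cfg$percentile_cutoff > 0, cfg$percentile_cutoff < 1,
            cfg$n_sim >= 1L, cfg$n_perm >= 100L,
            cfg$alpha > 0, cfg$alpha < 1, cfg$min_overlap >= 0L)
  invisible(cfg)
}

.config_hash <- function(cfg) {
  ## order-independent digest of the serialized config
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                        null = "null")
  format(sum(utf8ToInt(as.character(s)) *
               (seq_len(nchar(as.character(s))) %% 977L)), scientific = FALSE)
}

.write_stage <- function(d, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash=", .config_hash(cfg), " seed=", cfg$seed),
             con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full crosstalk-discovery pipeline
#'
#' Executes, in order: interactome assembly, crosstalk extraction (direct
#' links, internodes, high-confidence subset, network export), gene-set
#' over-representation, expression GSEA, the gene-score GWAS enrichment
#' scan, and the multi-SNP risk score — skipping any stage whose inputs are
#' absent from the configuration (with a logged notice). All randomized
#' steps derive from `config$seed`; outputs are byte-identical across reruns
#' of the same configuration. Every output TSV carries a header comment with
#' the config hash and seed, and a machine-readable provenance record is
#' written alongside.
#'
#' @param config Configuration list from [default_config()] or
#'   [read_config()].
#' @param out Output directory.
#' @return Invisibly, a list with the main in-memory results
#'   (`interactome`, `crosstalk`, `enrichment`, `gsea`, `gene_scores`,
#'   `gwas_enrichment`, `risk_score`).
#' @export
run_pipeline <- function(config, out) {
  cfg <- .validate_config(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ip <- cfg$inputs
  need <- c("ppi", "tissue_calls", "parts_a", "parts_b")
  if (any(vapply(ip[need], is.null, logical(1))))
    stop("assembly stage requires inputs: ", paste(need, collapse = ", "),
         call. = FALSE)
  inputs <- list(
    ppi = read_edge_evidence(ip[["ppi"]]),
    complexes = if (!is.null(ip[["complexes"]])) read_complexes(ip[["complexes"]])
                else list(),
    reactions = if (!is.null(ip[["reactions"]])) read_reactions(ip[["reactions"]])
                else data.frame(reaction_id = character()),
    pathways = if (!is.null(ip[["pathways"]])) read_pathway_relations(ip[["pathways"]])
               else data.frame(gene_a = character(), gene_b = character(),
                               pathway = character()),
    calls = read_tissue_calls(ip[["tissue_calls"]]),
    coexpr = if (!is.null(ip[["coexpr"]])) {
      d <- .read_tsv(ip[["coexpr"]])
      m <- as.matrix(d[, -1, drop = FALSE]); rownames(m) <- d$gene
      storage.mode(m) <- "double"; m
    } else matrix(numeric(), 0, 0))
  interactome <- assemble_from_inputs(inputs, cfg$corr_method,
                                      cfg$corr_fdr_alpha)
  parts_a <- read_parts_list(ip[["parts_a"]], "systemA")
  parts_b <- read_parts_list(ip[["parts_b"]], "systemB")
  net <- build_crosstalk(interactome, parts_a, parts_b)
  .write_stage(net$internodes, file.path(out, "internodes.tsv"), cfg)
  .write_stage(high_confidence_subset(net$internodes, cfg$min_evidence,
                                      cfg$min_evidence),
               file.path(out, "internodes_high_confidence.tsv"), cfg)
  .write_stage(net$direct, file.path(out, "direct.tsv"), cfg)
  export_network(net, interactome, out)
  res <- list(interactome = interactome, crosstalk = net)

  if (!is.null(ip[["gmt"]])) {
    res$enrichment <- enrich_sets(net$internodes$gene, read_gmt(ip[["gmt"]]),
                                  interactome$universe,
                                  min_overlap = cfg$min_overlap,
                                  alpha = cfg$alpha)
    .write_stage(res$enrichment, file.path(out, "enrichment.tsv"), cfg)
  } else message("no GMT input; signature-enrichment stage skipped")

  if (!is.null(ip[["expression"]]) && !is.null(ip[["expression_labels"]])) {
    expr <- read_expression(ip[["expression"]], ip[["expression_labels"]])
    sigs <- list(internodes = net$internodes$gene,
                 system_a = intersect(parts_a$genes, interactome$universe),
                 system_b = intersect(parts_b$genes, interactome$universe))
    sigs <- sigs[vapply(sigs, function(s)
      length(intersect(s, rownames(expr$values))) > 0, logical(1))]
    res$gsea <- gsea(expr, sigs, n_perm = cfg$n_perm, seed = cfg$seed)
    .write_stage(as.data.frame(res$gsea), file.path(out, "gsea.tsv"), cfg)
  } else message("no expression input; GSEA stage skipped")

  if (!is.null(ip[["sumstats"]]) && !is.null(ip[["annotation"]])) {
    ss <- read_sumstats(ip[["sumstats"]])
    ann <- read_gene_annotation(ip[["annotation"]], ip[["annotation_dialect"]])
    mapping <- map_snps_to_genes(ss, ann, cfg$window_bp)
    res$gene_scores <- score_genes(mapping)
    .write_stage(as.data.frame(res$gene_scores),
                 file.path(out, "gene_scores.tsv"), cfg)
    set_scored <- intersect(net$internodes$gene, res$gene_scores$gene)
    if (length(set_scored)) {
      res$gwas_enrichment <- cutoff_enrichment(
        res$gene_scores, net$internodes$gene, cfg$percentile_cutoff,
        cfg$n_sim, cfg$seed)
      ce <- res$gwas_enrichment
      .write_stage(data.frame(set_size_scored = ce$set_size_scored,
                              observed_above = ce$observed_above,
                              expected_above = ce$expected_above,
                              p_empirical = ce$p_empirical$p),
                   file.path(out, "gwas_enrichment.tsv"), cfg)
      if (!is.null(ip[["trait_sumstats"]])) {
        trait <- read_sumstats(ip[["trait_sumstats"]])
        cutoff <- ce$cutoff_value
        top <- res$gene_scores[res$gene_scores$corrected_score > cutoff &
                                 res$gene_scores$gene %in% set_scored, ]
        if (nrow(top)) {
          res$risk_score <- score_test_for_gene_set(top$best_snp, trait)
          rs <- res$risk_score
          .write_stage(data.frame(n_snps = rs$n_snps,
                                  beta_score = rs$beta_score,
                                  se_score = rs$se_score, z = rs$z,
                                  p = rs$p),
                       file.path(out, "risk_score.tsv"), cfg)
        } else message("no internode genes above cutoff; ",
                       "risk-score stage skipped")
      } else message("no trait sumstats; risk-score stage skipped")
    } else message("no internode genes scored; GWAS enrichment skipped")
    if (!is.null(ip[["catalog_snps"]])) {
      cat_snps <- .read_tsv(ip[["catalog_snps"]])
      res$trait_overlap <- trait_locus_overlap(
        net$internodes$gene, cat_snps, ann, cfg$catalog_window_bp,
        cfg$n_sim, cfg$seed)
      .write_stage(data.frame(observed = res$trait_overlap$observed,
                              p_empirical = res$trait_overlap$p),
                   file.path(out, "trait_overlap.tsv"), cfg)
    }
  } else message("no GWAS inputs; gene-score stages skipped")

  prov <- list(config = cfg, config_hash = .config_hash(cfg),
               n_universe = length(interactome$universe),
               n_pairs = nrow(interactome$pairs),
               n_internodes = nrow(net$internodes),
               n_direct = nrow(net$direct))
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(res)
}
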