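## Filtered evidence source vocabulary. BiGG- and KEGG-derived metabolic
## adjacencies are both tagged MET_adj; the originating database lives in
## the provenance string.
EVIDENCE_SOURCES <- c("PPIhigh", "PPIcorr", "COMPLEX", "MET_adj", "PATH",
                      "RANDOM")

## Currency metabolites excluded from reaction-adjacency by default:
## without the exclusion ATP/NADH/water link nearly every enzyme pair.
DEFAULT_CURRENCY <- c("ATP", "ADP", "AMP", "NAD", "NADH", "NADP", "NADPH",
                      "H2O", "H+", "CO2", "PI", "COA")

.evidence_df <- function(gene_a = character(), gene_b = character(),
                         source = character(), provenance = character(),
                         lab_count = NA_integer_) {
  if (length(gene_a) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      source = character(), provenance = character(),
                      lab_count = integer(), stringsAsFactors = FALSE))
  }
  lo <- pmin(gene_a, gene_b)
  hi <- pmax(gene_a, gene_b)
  data.frame(gene_a = lo, gene_b = hi,
             source = as.character(source),
             provenance = as.character(provenance),
             lab_count = as.integer(lab_count),
             stringsAsFactors = FALSE)
}

.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

.expressed_any <- function(genes, calls, tissues) {
  ## genes absent from the call table count as not expressed
  idx <- match(genes, calls$gene)
  any_mat <- rowSums(as.matrix(calls[, tissues, drop = FALSE])) > 0
  out <- !is.na(idx) & any_mat[ifelse(is.na(idx), 1L, idx)]
  out[is.na(idx)] <- FALSE
  out
}

#' High-confidence PPI filter
#'
#' Keeps protein-protein interactions reported independently by at least two
#' laboratories whose both genes are expressed in at least one of the
#' insulin-sensitive tissues (adipose, muscle, liver, heart by default).
#' Genes absent from the call table are treated as not expressed.
#'
#' @param ppi_edges Raw evidence data.frame (source `PPI`) from
#'   [read_edge_evidence()], with integer `lab_count`.
#' @param calls Tissue-call data.frame from [read_tissue_calls()].
#' @param tissues Tissue columns to consult.
#' @param min_labs Minimum number of independent laboratories (default 2).
#' @return Evidence data.frame with source `PPIhigh`.
#' @export
filter_ppi_high <- function(ppi_edges, calls, tissues = DEFAULT_TISSUES,
                            min_labs = 2L) {
  stopifnot(all(ppi_edges$source == "PPI"), !anyNA(ppi_edges$lab_count))
  multi <- ppi_edges[ppi_edges$lab_count >= min_labs, , drop = FALSE]
  expr <- .expressed_any(multi$gene_a, calls, tissues) &
    .expressed_any(multi$gene_b, calls, tissues)
  n_drop <- sum(!expr)
  if (n_drop) message(n_drop, " multi-lab PPI edge(s) dropped: ",
                      "not tissue-expressed")
  kept <- multi[expr, , drop = FALSE]
  .evidence_df(kept$gene_a, kept$gene_b, rep("PPIhigh", nrow(kept)),
               paste0("labs=", kept$lab_count), kept$lab_count)
}

#' Co-expression rescue of single-laboratory PPIs
#'
#' Single-laboratory interactions are retained when both genes are
#' tissue-expressed and their expression profiles across a reference
#' co-expression compendium (427 healthy liver samples in the original
#' study) are significantly correlated at Benjamini-Hochberg FDR < `alpha`.
#' Positive and negative correlations both qualify. Pairs with either gene
#' missing from the compendium are dropped (they cannot gain co-expression
#' support by default).
#'
#' @param single_lab_edges Raw PPI evidence with `lab_count == 1`.
#' @param coexpr Numeric matrix, genes x samples (>= 3 samples).
#' @param calls Tissue-call data.frame.
#' @param corr_method `"pearson"` (default) or `"spearman"`.
#' @param alpha BH FDR threshold (default 0.05).
#' @param tissues Tissue columns to consult.
#' @return Evidence data.frame with source `PPIcorr` (correlation value in
#'   the provenance).
#' @export
derive_ppicorr <- function(single_lab_edges, coexpr, calls,
                           corr_method = c("pearson", "spearman"),
                           alpha = 0.05, tissues = DEFAULT_TISSUES) {
  corr_method <- match.arg(corr_method)
  stopifnot(all(single_lab_edges$source == "PPI"),
            all(single_lab_edges$lab_count == 1L))
  if (ncol(coexpr) < 3L)
    stop("insufficient samples for correlation", call. = FALSE)
  e <- single_lab_edges
  expr <- .expressed_any(e$gene_a, calls, tissues) &
    .expressed_any(e$gene_b, calls, tissues)
  e <- e[expr, , drop = FALSE]
  present <- e$gene_a %in% rownames(coexpr) & e$gene_b %in% rownames(coexpr)
  if (any(!present))
    message(sum(!present), " single-lab edge(s) dropped: ",
            "gene absent from co-expression matrix")
  e <- e[present, , drop = FALSE]
  if (nrow(e) == 0L) return(.evidence_df())
  r <- numeric(nrow(e))
  p <- numeric(nrow(e))
  for (i in seq_len(nrow(e))) {
    ct <- stats::cor.test(coexpr[e$gene_a[i], ], coexpr[e$gene_b[i], ],
                          method = corr_method, exact = FALSE)
    r[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  keep <- stats::p.adjust(p, method = "BH") < alpha
  keep[is.na(keep)] <- FALSE
  e <- e[keep, , drop = FALSE]
  .evidence_df(e$gene_a, e$gene_b, rep("PPIcorr", nrow(e)),
               sprintf("r=%.4f", r[keep]), 1L)
}

#' Clique expansion of protein complexes
#'
#' Two genes are functionally linked if they belong to a common complex;
#' every unordered pair within each complex yields one evidence record, so a
#' pair sharing k complexes carries k records.
#'
#' @param memberships Named list: complex id -> member genes.
#' @return Evidence data.frame with source `COMPLEX`.
#' @export
complex_edges <- function(memberships) {
  out <- list()
  for (cid in names(memberships)) {
    members <- unique(memberships[[cid]])
    if (length(members) < 2L) {
      warning("complex ", cid, " has < 2 members; skipped", call. = FALSE)
      next
    }
    idx <- utils::combn(sort(members), 2L)
    out[[cid]] <- .evidence_df(idx[1, ], idx[2, ],
                               rep("COMPLEX", ncol(idx)), cid)
  }
  if (!length(out)) return(.evidence_df())
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Gene pairs from adjacent metabolic reactions
#'
#' Two reactions are adjacent when they share at least one metabolite not on
#' the currency list (reaction direction is ignored: substrates and products
#' are pooled). For every adjacent reaction pair, all cross-reaction gene
#' pairs are emitted with the shared metabolite recorded in provenance.
#'
#' @param reactions Data.frame from [read_reactions()].
#' @param currency_metabolites Metabolite ids excluded from adjacency
#'   (case-insensitive). Default: ATP, ADP, AMP, NAD(H), NADP(H), H2O, H+,
#'   CO2, Pi, CoA.
#' @return Evidence data.frame with source `MET_adj`.
#' @export
metabolic_adjacency <- function(reactions,
                                currency_metabolites = DEFAULT_CURRENCY) {
  cur <- toupper(currency_metabolites)
  n <- nrow(reactions)
  mets <- vector("list", n)
  genes <- reactions$genes
  for (i in seq_len(n)) {
    m <- toupper(unique(c(reactions$substrates[[i]], reactions$products[[i]])))
    mets[[i]] <- setdiff(m, cur)
    if (length(genes[[i]]) == 0L)
      warning("reaction ", reactions$reaction_id[[i]],
              " has no genes; skipped", call. = FALSE)
  }
  out <- list()
  k <- 0L
  for (i in seq_len(max(n - 1L, 0L))) {
    if (length(genes[[i]]) == 0L) next
    for (j in (i + 1L):n) {
      if (length(genes[[j]]) == 0L) next
      shared <- intersect(mets[[i]], mets[[j]])
      if (length(shared) == 0L) next
      gp <- expand.grid(a = genes[[i]], b = genes[[j]],
                        stringsAsFactors = FALSE)
      gp <- gp[gp$a != gp$b, , drop = FALSE]
      if (nrow(gp) == 0L) next
      gp <- unique(data.frame(a = pmin(gp$a, gp$b), b = pmax(gp$a, gp$b),
                              stringsAsFactors = FALSE))
      k <- k + 1L
      out[[k]] <- .evidence_df(gp$a, gp$b, rep("MET_adj", nrow(gp)),
                               paste0(shared[[1]], ":",
                                      reactions$reaction_id[[i]], "~",
                                      reactions$reaction_id[[j]]))
    }
  }
  if (!k) return(.evidence_df())
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Gene pairs linked within signalling pathways
#'
#' Undirected relations de-duplicated per pathway: (A,B,path1) and
#' (B,A,path1) are one record, while (A,B,path1) and (A,B,path2) are two.
#'
#' @param relations Data.frame from [read_pathway_relations()].
#' @return Evidence data.frame with source `PATH`.
#' @export
pathway_edges <- function(relations) {
  if (nrow(relations) == 0L) return(.evidence_df())
  d <- data.frame(a = pmin(relations$gene_a, relations$gene_b),
                  b = pmax(relations$gene_a, relations$gene_b),
                  pathway = relations$pathway, stringsAsFactors = FALSE)
  d <- d[d$a != d$b, , drop = FALSE]
  d <- unique(d)
  .evidence_df(d$a, d$b, rep("PATH", nrow(d)), d$pathway)
}

#' Assemble the functional interactome
#'
#' Concatenates filtered evidence lists from all sources and collapses them
#' onto canonical gene pairs; each pair keeps its full evidence multiset.
#'
#' @param ... Evidence data.frames (from [filter_ppi_high()],
#'   [derive_ppicorr()], [complex_edges()], [metabolic_adjacency()],
#'   [pathway_edges()], or synthetic equivalents).
#' @return An object of class `interactome`: list with `evidence` (all
#'   records), `pairs` (one row per canonical pair with `n_evidence`) and
#'   `universe` (all incident genes).
#' @export
assemble_interactome <- function(...) {
  if (length(list(...)) == 0L) stop("empty interactome", call. = FALSE)
  ev <- do.call(rbind, c(lapply(list(...), function(x) {
    x[, c("gene_a", "gene_b", "source", "provenance", "lab_count"),
      drop = FALSE]
  }), list(make.row.names = FALSE)))
  if (is.null(ev) || nrow(ev) == 0L) stop("empty interactome", call. = FALSE)
  bad <- setdiff(unique(ev$source), EVIDENCE_SOURCES)
  if (length(bad))
    stop("unknown evidence source(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ## deterministic evidence order, independent of input list order
  ev <- ev[order(ev$gene_a, ev$gene_b, ev$source, ev$provenance), ,
           drop = FALSE]
  rownames(ev) <- NULL
  key <- .pair_key(ev$gene_a, ev$gene_b)
  tab <- table(key)
  first <- !duplicated(key)
  pairs <- data.frame(gene_a = ev$gene_a[first], gene_b = ev$gene_b[first],
                      stringsAsFactors = FALSE)
  pairs$n_evidence <- as.integer(tab[.pair_key(pairs$gene_a, pairs$gene_b)])
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  src_tab <- table(ev$source)
  message("interactome: ", nrow(pairs), " pairs, ", nrow(ev),
          " evidence records (",
          paste(names(src_tab), src_tab, sep = "=", collapse = ", "), ")")
  structure(list(evidence = ev, pairs = pairs,
                 universe = sort(unique(c(ev$gene_a, ev$gene_b)))),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat("Functional interactome\n")
  cat("  genes:    ", length(x$universe), "\n", sep = "")
  cat("  pairs:    ", nrow(x$pairs), "\n", sep = "")
  cat("  evidence: ", nrow(x$evidence), "\n", sep = "")
  src <- table(x$evidence$source)
  cat("  sources:  ", paste(names(src), src, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
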