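## Internode records are plain data.frames with one row per linker gene:
## gene, links_a, links_b, evid_a, evid_b, total_links, total_evid,
## partners_a, partners_b ("|"-joined). System A is the first parts list
## passed (insulin in the original study), system B the second.

.sort_internodes <- function(rec) {
  rec <- rec[order(-rec$total_evid, -rec$total_links, rec$gene), ,
             drop = FALSE]
  rownames(rec) <- NULL
  rec
}

.join_partners <- function(x) paste(sort(unique(x)), collapse = "|")

#' Direct links between two systems
#'
#' Extracts every interactome pair with one member in parts list A and the
#' other in parts list B. Genes present in both lists count for either side.
#'
#' @param interactome An `interactome` object.
#' @param parts_a,parts_b `parts_list` objects for the two systems.
#' @return Data.frame of direct pairs: `gene_a`, `gene_b`, `n_evidence`,
#'   `sources` (`;`-joined evidence source tags).
#' @export
find_direct_links <- function(interactome, parts_a, parts_b) {
  stopifnot(inherits(interactome, "interactome"))
  A <- parts_a$genes
  B <- parts_b$genes
  p <- interactome$pairs
  cross <- (p$gene_a %in% A & p$gene_b %in% B) |
    (p$gene_a %in% B & p$gene_b %in% A)
  out <- p[cross, , drop = FALSE]
  key <- .pair_key(interactome$evidence$gene_a, interactome$evidence$gene_b)
  src <- vapply(.pair_key(out$gene_a, out$gene_b), function(k)
    paste(sort(interactome$evidence$source[key == k]), collapse = ";"),
    character(1))
  out$sources <- unname(src)
  rownames(out) <- NULL
  out
}

#' Identify internode (linker) genes
#'
#' An internode is a gene outside both parts lists with at least one
#' interactome edge to each system. Each internode is reported with its
#' per-system partner sets, distinct-partner counts (`links_a`, `links_b`)
#' and total evidence-record counts (`evid_a`, `evid_b`), ranked by total
#' evidence, then total links, then symbol.
#'
#' Genes present in both parts lists are excluded from internode candidacy
#' (with a warning) — they are system members, not linkers.
#'
#' @inheritParams find_direct_links
#' @return Internode record data.frame (possibly 0 rows).
#' @export
find_internodes <- function(interactome, parts_a, parts_b) {
  stopifnot(inherits(interactome, "interactome"))
  A <- parts_a$genes
  B <- parts_b$genes
  both <- intersect(A, B)
  if (length(both))
    warning(length(both), " gene(s) present in both parts lists excluded ",
            "from internode candidacy: ", paste(both, collapse = ", "),
            call. = FALSE)
  AB <- union(A, B)
  p <- interactome$pairs
  ## candidate -> partner contributions from each pair orientation
  contrib <- function(system_genes) {
    s1 <- !(p$gene_a %in% AB) & p$gene_b %in% system_genes
    s2 <- !(p$gene_b %in% AB) & p$gene_a %in% system_genes
    data.frame(cand = c(p$gene_a[s1], p$gene_b[s2]),
               partner = c(p$gene_b[s1], p$gene_a[s2]),
               evid = c(p$n_evidence[s1], p$n_evidence[s2]),
               stringsAsFactors = FALSE)
  }
  ca <- contrib(A)
  cb <- contrib(B)
  cand <- intersect(unique(ca$cand), unique(cb$cand))
  if (length(cand) == 0L) return(.empty_internodes())
  rec <- do.call(rbind, lapply(sort(cand), function(g) {
    ga <- ca[ca$cand == g, , drop = FALSE]
    gb <- cb[cb$cand == g, , drop = FALSE]
    data.frame(gene = g,
               links_a = length(unique(ga$partner)),
               links_b = length(unique(gb$partner)),
               evid_a = sum(ga$evid), evid_b = sum(gb$evid),
               partners_a = .join_partners(ga$partner),
               partners_b = .join_partners(gb$partner),
               stringsAsFactors = FALSE)
  }))
  rec$total_links <- rec$links_a + rec$links_b
  rec$total_evid <- rec$evid_a + rec$evid_b
  .sort_internodes(rec[, .internode_cols()])
}

.internode_cols <- function() {
  c("gene", "total_links", "total_evid", "links_a", "evid_a", "links_b",
    "evid_b", "partners_a", "partners_b")
}

.empty_internodes <- function() {
  data.frame(gene = character(), total_links = integer(),
             total_evid = integer(), links_a = integer(), evid_a = integer(),
             links_b = integer(), evid_b = integer(),
             partners_a = character(), partners_b = character(),
             stringsAsFactors = FALSE)
}

#' Summarize internode records from listed partner sets
#'
#' Recomputes link counts from explicit per-system partner lists (the format
#' of the published candidate table): `links_a`/`links_b` are the distinct
#' partner counts and `total_links` their sum. Duplicate partners within a
#' cell are de-duplicated with a warning. Evidence columns, when present in
#' the input, are carried through and summed into `total_evid`.
#'
#' @param partner_table Data.frame with columns `gene`, `partners_a`,
#'   `partners_b` (partners joined by `|` or `;`), and optionally `evid_a`,
#'   `evid_b`.
#' @return Internode record data.frame.
#' @export
internode_partner_summary <- function(partner_table) {
  stopifnot(all(c("gene", "partners_a", "partners_b") %in%
                  names(partner_table)))
  parse_cell <- function(cell, gene, side) {
    v <- toupper(trimws(strsplit(cell, "[|;]")[[1]]))
    v <- v[nzchar(v)]
    if (anyDuplicated(v))
      warning("duplicate partner(s) for ", gene, " (", side, "): ",
              paste(unique(v[duplicated(v)]), collapse = ", "),
              call. = FALSE)
    unique(v)
  }
  n <- nrow(partner_table)
  rec <- data.frame(gene = toupper(partner_table$gene),
                    links_a = integer(n), links_b = integer(n),
                    partners_a = character(n), partners_b = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pa <- parse_cell(partner_table$partners_a[[i]], rec$gene[[i]], "A")
    pb <- parse_cell(partner_table$partners_b[[i]], rec$gene[[i]], "B")
    rec$links_a[[i]] <- length(pa)
    rec$links_b[[i]] <- length(pb)
    rec$partners_a[[i]] <- .join_partners(pa)
    rec$partners_b[[i]] <- .join_partners(pb)
  }
  rec$total_links <- rec$links_a + rec$links_b
  if (all(c("evid_a", "evid_b") %in% names(partner_table))) {
    rec$evid_a <- as.integer(partner_table$evid_a)
    rec$evid_b <- as.integer(partner_table$evid_b)
    rec$total_evid <- rec$evid_a + rec$evid_b
  } else {
    rec$evid_a <- rec$evid_b <- rec$total_evid <- NA_integer_
  }
  .sort_internodes(rec[, .internode_cols()])
}

#' High-confidence internode subset
#'
#' Keeps internodes with at least `min_evid_a` evidence records linking them
#' to system A and at least `min_evid_b` to system B (three and three in the
#' original study, yielding its 31-gene confident subset). Input order is
#' preserved.
#'
#' @param records Internode record data.frame.
#' @param min_evid_a,min_evid_b Minimum per-system evidence counts.
#' @return Filtered internode record data.frame.
#' @export
high_confidence_subset <- function(records, min_evid_a = 3L,
                                   min_evid_b = 3L) {
  keep <- records$evid_a >= min_evid_a & records$evid_b >= min_evid_b
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene indirect connectivity between systems
#'
#' For each gene of one system, counts the distinct (internode, gene of the
#' other system) bridging pairs it participates in — i.e. length-2 paths
#' through an internode. Returned sorted descending.
#'
#' @inheritParams find_direct_links
#' @return List with named integer vectors `a` (indirect connections of each
#'   system-A gene to system B) and `b` (the reverse).
#' @export
system_connectivity <- function(interactome, parts_a, parts_b) {
  rec <- suppressWarnings(find_internodes(interactome, parts_a, parts_b))
  count_side <- function(own, opp) {
    acc <- stats::setNames(integer(length(own)), own)
    for (i in seq_len(nrow(rec))) {
      mine <- strsplit(rec[[own_col]][i], "|", fixed = TRUE)[[1]]
      n_opp <- length(strsplit(rec[[opp_col]][i], "|", fixed = TRUE)[[1]])
      acc[mine] <- acc[mine] + n_opp
    }
    sort(acc, decreasing = TRUE)
  }
  own_col <- "partners_a"; opp_col <- "partners_b"
  a <- count_side(parts_a$genes, parts_b$genes)
  own_col <- "partners_b"; opp_col <- "partners_a"
  b <- count_side(parts_b$genes, parts_a$genes)
  list(a = a, b = b)
}

#' Build the full crosstalk network between two systems
#'
#' Combines direct system-to-system links and internode-mediated indirect
#' links into one summary object, with per-source contribution counts for
#' both the direct and indirect partitions (tallied both per evidence record
#' and per pair, since the two accountings differ).
#'
#' @inheritParams find_direct_links
#' @return An object of class `crosstalk`.
#' @export
build_crosstalk <- function(interactome, parts_a, parts_b) {
  direct <- find_direct_links(interactome, parts_a, parts_b)
  internodes <- find_internodes(interactome, parts_a, parts_b)
  ev <- interactome$evidence
  key <- .pair_key(ev$gene_a, ev$gene_b)
  direct_key <- .pair_key(direct$gene_a, direct$gene_b)
  bridge <- .bridging_pairs(internodes, parts_a, parts_b)
  bridge_key <- .pair_key(bridge$gene_a, bridge$gene_b)
  tally <- function(keys) {
    sel <- key %in% keys
    list(evidence = table(factor(ev$source[sel], levels = EVIDENCE_SOURCES)),
         pairs = table(factor(ev$source[sel & !duplicated(key)],
                              levels = EVIDENCE_SOURCES)))
  }
  structure(list(direct = direct, internodes = internodes,
                 bridge_edges = bridge,
                 parts_a = parts_a, parts_b = parts_b,
                 contributions = list(direct = tally(direct_key),
                                      indirect = tally(bridge_key))),
            class = "crosstalk")
}

## All (internode, system gene) edges implied by the internode records.
.bridging_pairs <- function(internodes, parts_a, parts_b) {
  if (nrow(internodes) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(internodes)), function(i) {
    g <- internodes$gene[[i]]
    ps <- c(strsplit(internodes$partners_a[[i]], "|", fixed = TRUE)[[1]],
            strsplit(internodes$partners_b[[i]], "|", fixed = TRUE)[[1]])
    data.frame(gene_a = pmin(g, ps), gene_b = pmax(g, ps),
               stringsAsFactors = FALSE)
  })
  unique(do.call(rbind, rows))
}

#' @export
print.crosstalk <- function(x, ...) {
  n_genes <- length(unique(c(x$direct$gene_a, x$direct$gene_b,
                             x$bridge_edges$gene_a, x$bridge_edges$gene_b)))
  cat("Crosstalk network: ", x$parts_a$name, " <-> ", x$parts_b$name, "\n",
      sep = "")
  cat("  genes:         ", n_genes, "\n", sep = "")
  cat("  direct links:  ", nrow(x$direct), "\n", sep = "")
  cat("  internodes:    ", nrow(x$internodes), "\n", sep = "")
  cat("  bridge edges:  ", nrow(x$bridge_edges), "\n", sep = "")
  invisible(x)
}

#' @export
summary.crosstalk <- function(object, ...) {
  print(object)
  if (nrow(object$internodes)) {
    cat("  mean partners per internode: A=",
        round(mean(object$internodes$links_a), 2), ", B=",
        round(mean(object$internodes$links_b), 2), "\n", sep = "")
    cat("top internodes by evidence:\n")
    print(utils::head(object$internodes[, c("gene", "total_links",
                                            "total_evid")], 5))
  }
  invisible(object)
}

#' Export a crosstalk network as node/edge tables
#'
#' Writes `nodes.tsv` (gene, role in `{A, B, internode}`) and `edges.tsv`
#' (pair, `;`-joined sources, evidence count), importable by graph viewers.
#' The node table always contains the parts-list genes present in the
#' interactome, even when no internodes were found.
#'
#' @param network A `crosstalk` object.
#' @param interactome The `interactome` the network was built from.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the two files written.
#' @export
export_network <- function(network, interactome, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  A <- intersect(network$parts_a$genes, interactome$universe)
  B <- intersect(network$parts_b$genes, interactome$universe)
  nodes <- rbind(
    data.frame(gene = A, role = rep("A", length(A)),
               stringsAsFactors = FALSE),
    data.frame(gene = setdiff(B, A),
               role = rep("B", length(setdiff(B, A))),
               stringsAsFactors = FALSE),
    data.frame(gene = network$internodes$gene,
               role = rep("internode", nrow(network$internodes)),
               stringsAsFactors = FALSE))
  nodes <- nodes[order(nodes$role, nodes$gene), , drop = FALSE]
  edges <- unique(rbind(network$direct[, c("gene_a", "gene_b")],
                        network$bridge_edges))
  ev <- interactome$evidence
  key <- .pair_key(ev$gene_a, ev$gene_b)
  ekey <- .pair_key(edges$gene_a, edges$gene_b)
  edges$sources <- vapply(ekey, function(k)
    paste(sort(unique(ev$source[key == k])), collapse = ";"), character(1))
  edges$n_evidence <- vapply(ekey, function(k) sum(key == k), integer(1))
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  node_path <- file.path(dir, "nodes.tsv")
  edge_path <- file.path(dir, "edges.tsv")
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nodes = node_path, edges = edge_path))
}
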