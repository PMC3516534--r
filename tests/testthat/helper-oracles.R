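# Brute-force oracles and tiny builders used across the suite. Oracles work
# on plain edge lists, independently of the package's graph representation.

rand_graph_edges <- function(n_nodes, n_edges, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("N%03d", seq_len(n_nodes))
    all_pairs <- t(utils::combn(nodes, 2))
    idx <- sample(nrow(all_pairs), min(n_edges, nrow(all_pairs)))
    data.frame(gene_a = all_pairs[idx, 1], gene_b = all_pairs[idx, 2],
               stringsAsFactors = FALSE)
  })
}

toy_interactome <- function(edges) {
  ev <- data.frame(gene_a = pmin(edges$gene_a, edges$gene_b),
                   gene_b = pmax(edges$gene_a, edges$gene_b),
                   source = "PATH",
                   provenance = paste0("p", seq_len(nrow(edges))),
                   lab_count = NA_integer_, stringsAsFactors = FALSE)
  suppressMessages(assemble_interactome(ev))
}

neighbours <- function(edges, g) {
  c(edges$gene_b[edges$gene_a == g], edges$gene_a[edges$gene_b == g])
}

# definition check per node: outside both lists, >=1 edge to each system
bf_internodes <- function(edges, A, B) {
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  cands <- setdiff(nodes, union(A, B))
  hits <- Filter(function(g) {
    nb <- neighbours(edges, g)
    any(nb %in% A) && any(nb %in% B)
  }, cands)
  sort(unlist(hits, use.names = FALSE))
}

bf_direct <- function(edges, A, B) {
  sel <- (edges$gene_a %in% A & edges$gene_b %in% B) |
    (edges$gene_a %in% B & edges$gene_b %in% A)
  e <- edges[sel, , drop = FALSE]
  sort(paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b)))
}

# random disjoint parts lists over a node universe
rand_parts <- function(nodes, n_a, n_b, seed) {
  withr::with_seed(seed, {
    a <- sample(nodes, n_a)
    b <- sample(setdiff(nodes, a), n_b)
    list(a = parts_list(a, "A"), b = parts_list(b, "B"))
  })
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
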