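test_that("direct links are exactly the cross-system pairs", {
  int <- toy_interactome(data.frame(gene_a = c("A1", "A1"),
                                    gene_b = c("M1", "X")))
  A <- parts_list("A1", "ins")
  B <- parts_list("M1", "mito")
  d <- find_direct_links(int, A, B)
  expect_identical(paste(d$gene_a, d$gene_b), "A1 M1")

  int2 <- toy_interactome(data.frame(gene_a = c("X", "Y"),
                                     gene_b = c("Z", "W")))
  expect_identical(nrow(find_direct_links(int2, A, B)), 0L)

  ## brute-force membership scan on a random 60-node interactome
  edges <- rand_graph_edges(60, 150, seed = 31)
  parts <- rand_parts(unique(c(edges$gene_a, edges$gene_b)), 12, 12, 32)
  got <- find_direct_links(toy_interactome(edges), parts$a, parts$b)
  expect_identical(sort(paste(got$gene_a, got$gene_b)),
                   bf_direct(edges, parts$a$genes, parts$b$genes))
})

test_that("internode detection matches the brute-force definition", {
  int <- toy_interactome(data.frame(gene_a = c("A1", "X"),
                                    gene_b = c("X", "M1")))
  A <- parts_list("A1", "ins")
  B <- parts_list("M1", "mito")
  rec <- find_internodes(int, A, B)
  expect_identical(rec$gene, "X")
  expect_identical(rec$links_a, 1L)
  expect_identical(rec$links_b, 1L)
  expect_identical(rec$total_links, 2L)

  int1 <- toy_interactome(data.frame(gene_a = "A1", gene_b = "X"))
  expect_identical(nrow(find_internodes(int1, A, B)), 0L)

  for (s in 1:30) {
    edges <- rand_graph_edges(sample(20:60, 1), sample(30:120, 1), seed = s)
    nodes <- unique(c(edges$gene_a, edges$gene_b))
    parts <- rand_parts(nodes, min(8, length(nodes) %/% 3),
                        min(8, length(nodes) %/% 3), s + 1000)
    rec <- find_internodes(toy_interactome(edges), parts$a, parts$b)
    expect_identical(sort(rec$gene),
                     bf_internodes(edges, parts$a$genes, parts$b$genes))
  }
})

test_that("internode records satisfy definition soundness and evid >= links", {
  edges <- rand_graph_edges(40, 90, seed = 77)
  parts <- rand_parts(unique(c(edges$gene_a, edges$gene_b)), 8, 8, 78)
  rec <- find_internodes(toy_interactome(edges), parts$a, parts$b)
  expect_true(all(rec$evid_a >= rec$links_a))
  expect_true(all(rec$evid_b >= rec$links_b))
  expect_true(all(!rec$gene %in% union(parts$a$genes, parts$b$genes)))
  ## ranking is total_evid desc, then total_links desc, then symbol
  expect_identical(rec, rec[order(-rec$total_evid, -rec$total_links,
                                  rec$gene), ])
})

test_that("adding an edge never removes an internode", {
  edges <- rand_graph_edges(30, 50, seed = 41)
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  parts <- rand_parts(nodes, 6, 6, 42)
  before <- find_internodes(toy_interactome(edges), parts$a, parts$b)$gene
  extra <- data.frame(gene_a = "ZZNEW", gene_b = nodes[1])
  after <- find_internodes(toy_interactome(rbind(edges, extra)),
                           parts$a, parts$b)$gene
  expect_true(all(before %in% after))
})

test_that("partner-list summaries count distinct partners per system", {
  tab <- data.frame(
    gene = c("TRAF2", "SOLO"),
    partners_a = c("MAP3K1|CAV1|MAPK10|MTOR", "P1"),
    partners_b = c("CASP8|MAP3K5", "Q1"),
    stringsAsFactors = FALSE)
  s <- internode_partner_summary(tab)
  expect_identical(s$total_links[s$gene == "TRAF2"], 6L)
  expect_identical(s$links_a[s$gene == "TRAF2"], 4L)
  expect_identical(s$links_b[s$gene == "TRAF2"], 2L)
  expect_identical(s$total_links[s$gene == "SOLO"], 2L)

  dup <- data.frame(gene = "RELA", partners_a = "IKBKB|CALM1|IKBKB|PRKCZ",
                    partners_b = "ETHE1|MTIF2|ESR1", stringsAsFactors = FALSE)
  expect_warning(sd <- internode_partner_summary(dup), "duplicate partner")
  expect_identical(sd$links_a, 3L)  # distinct partners, not listed count
})

test_that("high-confidence filter is the exact >= threshold predicate", {
  expect_identical(nrow(high_confidence_subset(find_internodes(
    toy_interactome(data.frame(gene_a = "A1", gene_b = "X")),
    parts_list("A1", "a"), parts_list("M1", "b")))), 0L)

  rec <- withr::with_seed(55, data.frame(
    gene = sprintf("G%02d", 1:50),
    total_links = 2L, total_evid = 4L,
    links_a = 1L, evid_a = sample(1:6, 50, TRUE),
    links_b = 1L, evid_b = sample(1:6, 50, TRUE),
    partners_a = "P", partners_b = "Q", stringsAsFactors = FALSE))
  got <- high_confidence_subset(rec, 3, 3)
  expect_identical(got$gene, rec$gene[rec$evid_a >= 3 & rec$evid_b >= 3])
})

test_that("system connectivity counts length-2 bridging paths", {
  int <- toy_interactome(data.frame(gene_a = c("A1", "X", "X"),
                                    gene_b = c("X", "M1", "M2")))
  A <- parts_list("A1", "a")
  B <- parts_list(c("M1", "M2"), "b")
  sc <- system_connectivity(int, A, B)
  expect_identical(unname(sc$a["A1"]), 2L)

  ## no internodes -> all zeros
  int0 <- toy_interactome(data.frame(gene_a = "A1", gene_b = "M1"))
  sc0 <- system_connectivity(int0, A, B)
  expect_true(all(sc0$a == 0L) && all(sc0$b == 0L))

  ## brute-force path-of-length-2 enumeration through internodes
  edges <- rand_graph_edges(40, 100, seed = 61)
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  parts <- rand_parts(nodes, 8, 8, 62)
  sc2 <- system_connectivity(toy_interactome(edges), parts$a, parts$b)
  AB <- union(parts$a$genes, parts$b$genes)
  for (a in parts$a$genes) {
    n_bf <- 0L
    for (x in setdiff(nodes, AB)) {
      nb <- neighbours(edges, x)
      if (a %in% nb && any(nb %in% parts$a$genes) &&
          any(nb %in% parts$b$genes))
        n_bf <- n_bf + length(unique(intersect(nb, parts$b$genes)))
    }
    expect_identical(unname(sc2$a[a]), n_bf)
  }
})

test_that("network export writes importable node and edge tables", {
  int <- toy_interactome(data.frame(gene_a = c("A1", "X"),
                                    gene_b = c("X", "M1")))
  net <- build_crosstalk(int, parts_list("A1", "a"), parts_list("M1", "b"))
  dir <- withr::local_tempdir()
  export_network(net, int, dir)
  nodes <- read.delim(file.path(dir, "nodes.tsv"))
  edges <- read.delim(file.path(dir, "edges.tsv"))
  expect_identical(nrow(nodes), 3L)
  expect_identical(nrow(edges), 2L)
  expect_setequal(nodes$role, c("A", "B", "internode"))

  ## no internodes: parts-list genes still exported
  int0 <- toy_interactome(data.frame(gene_a = "A1", gene_b = "M1"))
  net0 <- build_crosstalk(int0, parts_list("A1", "a"), parts_list("M1", "b"))
  dir0 <- withr::local_tempdir()
  export_network(net0, int0, dir0)
  nodes0 <- read.delim(file.path(dir0, "nodes.tsv"))
  expect_setequal(nodes0$gene, c("A1", "M1"))
})

test_that("crosstalk object reports direct/indirect source contributions", {
  int <- toy_interactome(data.frame(gene_a = c("A1", "A1", "X"),
                                    gene_b = c("M1", "X", "M1")))
  net <- build_crosstalk(int, parts_list("A1", "a"), parts_list("M1", "b"))
  expect_identical(nrow(net$direct), 1L)
  expect_identical(nrow(net$internodes), 1L)
  expect_identical(sum(net$contributions$direct$evidence), 1L)
  expect_identical(sum(net$contributions$indirect$evidence), 2L)
  expect_output(print(net), "internodes")
})
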