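#' Degree-preserving (or density-matched) rewiring of an interactome
#'
#' Produces a randomized control interactome. The default mode applies
#' repeated double-edge swaps to the collapsed pair graph, preserving every
#' node's degree exactly while randomizing which pairs are connected; no
#' self-loops or duplicate pairs are introduced. The alternative mode draws
#' an Erdos-Renyi graph on the same node set with the same edge count
#' (matched density, degrees not preserved). Each rewired pair carries one
#' synthetic evidence record with source `RANDOM`.
#'
#' @param interactome An `interactome` object with at least 2 pairs.
#' @param n_swaps Number of double-edge swap attempts (default 10x the edge
#'   count). Ignored in `"erdos_renyi"` mode.
#' @param seed Integer seed; required, no global RNG state is consumed.
#' @param mode `"degree_preserving"` (default) or `"erdos_renyi"`.
#' @return A rewired `interactome`.
#' @export
rewire_interactome <- function(interactome, n_swaps = NULL, seed,
                               mode = c("degree_preserving", "erdos_renyi")) {
  mode <- match.arg(mode)
  stopifnot(inherits(interactome, "interactome"))
  p <- interactome$pairs
  if (nrow(p) < 2L) stop("graph too small to swap", call. = FALSE)
  if (is.null(n_swaps)) n_swaps <- 10L * nrow(p)
  if (n_swaps < 1L) stop("n_swaps must be >= 1", call. = FALSE)
  g <- igraph::graph_from_data_frame(p[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = interactome$universe)
  rg <- withr::with_seed(seed, {
    if (mode == "degree_preserving") {
      igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                               niter = n_swaps))
    } else {
      igraph::sample_gnm(igraph::vcount(g), igraph::ecount(g))
    }
  })
  el <- igraph::as_edgelist(rg, names = mode == "degree_preserving")
  if (mode == "erdos_renyi") {
    nm <- interactome$universe
    el <- cbind(nm[as.integer(el[, 1])], nm[as.integer(el[, 2])])
  }
  ev <- .evidence_df(el[, 1], el[, 2], rep("RANDOM", nrow(el)),
                     "rewired")
  suppressMessages(assemble_interactome(ev))
}

#' Size-matched random gene sets
#'
#' Draws `n_sets` gene sets of a given size without replacement from a
#' universe, independently across sets and deterministically under the seed.
#'
#' @param universe Character vector to sample from.
#' @param size Set size (must not exceed the universe size).
#' @param n_sets Number of sets to draw.
#' @param seed Integer seed.
#' @return List of `n_sets` character vectors.
#' @export
sample_gene_sets <- function(universe, size, n_sets, seed) {
  if (size > length(universe))
    stop("size exceeds universe size", call. = FALSE)
  withr::with_seed(seed,
    lapply(seq_len(n_sets), function(i) sample(universe, size)))
}

#' Empirical p-value from null draws
#'
#' Computes the add-one smoothed empirical p-value
#' `p = (n_as_extreme + 1) / (n_sim + 1)`, which is never exactly zero at
#' finite simulation counts. The raw frequency `n_as_extreme / n_sim` is
#' also reported. Direction `"greater"` counts null draws `>= observed`,
#' `"less"` counts `<= observed`; alternatively a predicate function taking
#' one null draw and returning TRUE when it is at least as extreme as the
#' observation supports compound extremeness conditions (e.g. "p smaller AND
#' effect positive").
#'
#' @param observed Observed statistic (scalar).
#' @param null_draws Numeric vector (or list, when using a predicate) of
#'   null statistics.
#' @param direction `"greater"`, `"less"`, or a predicate function.
#' @return Object of class `empirical_p`: list with `observed`, `n_sim`,
#'   `n_as_extreme`, `p`, `raw_freq`.
#' @export
empirical_p <- function(observed, null_draws, direction = "greater") {
  n <- length(null_draws)
  if (n < 1L) stop("empty null draws", call. = FALSE)
  if (is.function(direction)) {
    extreme <- vapply(null_draws, direction, logical(1))
  } else if (identical(direction, "greater")) {
    extreme <- unlist(null_draws) >= observed
  } else if (identical(direction, "less")) {
    extreme <- unlist(null_draws) <= observed
  } else {
    stop("direction must be 'greater', 'less', or a predicate function",
         call. = FALSE)
  }
  b <- sum(extreme)
  structure(list(observed = observed, n_sim = n, n_as_extreme = b,
                 p = (b + 1) / (n + 1), raw_freq = b / n),
            class = "empirical_p")
}

#' @export
print.empirical_p <- function(x, ...) {
  cat("Empirical p-value: ", format(x$p, digits = 4), " (", x$n_as_extreme,
      "/", x$n_sim, " null draws as extreme; raw frequency ",
      format(x$raw_freq, digits = 4), ")\n", sep = "")
  invisible(x)
}
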