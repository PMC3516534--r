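## Raw evidence source vocabulary as it appears on disk; the assembled
## interactome uses the filtered vocabulary (see interactome.R).
RAW_SOURCES <- c("PPI", "COMPLEX", "MET", "PATH")
DEFAULT_TISSUES <- c("adipose", "muscle", "liver", "heart")

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "", check.names = FALSE, ...)
}

.check_symbols <- function(x, what = "gene symbol") {
  x <- trimws(x)
  if (any(!nzchar(x))) stop("blank ", what, " encountered", call. = FALSE)
  toupper(x)
}

#' Read a parts list (one gene symbol per line)
#'
#' A parts list names one biological system (for example the insulin
#' signalling cascade or the mitochondrial proteome) by the set of gene
#' symbols it comprises. Lines starting with `#` are ignored; symbols are
#' upper-cased and de-duplicated.
#'
#' @param path Path to a text file, one symbol per line.
#' @param name Short label for the system (e.g. `"insulin"`).
#' @return An object of class `parts_list`: a list with elements `name` and
#'   `genes` (character vector of unique, uppercase symbols).
#' @export
read_parts_list <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty parts list: ", path, call. = FALSE)
  parts_list(.check_symbols(lines), name = name)
}

#' Construct a parts list from a character vector
#'
#' @param genes Character vector of gene symbols (upper-cased, de-duplicated).
#' @param name Short label for the system.
#' @return A `parts_list` object.
#' @export
parts_list <- function(genes, name) {
  genes <- unique(.check_symbols(as.character(genes)))
  if (length(genes) == 0L) stop("empty parts list", call. = FALSE)
  structure(list(name = name, genes = genes), class = "parts_list")
}

#' @export
print.parts_list <- function(x, ...) {
  cat("Parts list '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Read a GMT gene-set collection
#'
#' Standard MSigDB dialect: `name TAB description TAB gene1 TAB gene2 ...`.
#' Genes are upper-cased and de-duplicated within each set; set order is
#' preserved.
#'
#' @param path Path to a .gmt file.
#' @return Named list of character vectors (one per gene set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    nms[[i]] <- f[[1]]
    sets[[i]] <- unique(.check_symbols(f[-(1:2)]))
  }
  names(sets) <- nms
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[[i]], "na", sets[[i]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Read raw edge-evidence records
#'
#' TSV with columns `geneA`, `geneB`, `source` (one of PPI, COMPLEX, MET,
#' PATH) and `provenance` (free text; for PPI rows the integer count of
#' independent laboratories reporting the interaction). Self-loops are
#' dropped with a warning; pairs are stored in canonical (lexicographically
#' sorted) order. Duplicate rows are kept — evidence multiplicity is
#' meaningful.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `gene_a`, `gene_b`, `source`,
#'   `provenance`, `lab_count` (integer, `NA` for non-PPI rows).
#' @export
read_edge_evidence <- function(path) {
  d <- .read_tsv(path)
  need <- c("geneA", "geneB", "source", "provenance")
  if (!all(need %in% names(d)))
    stop("edge-evidence file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(d$source), RAW_SOURCES)
  if (length(bad))
    stop("unknown source tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  a <- .check_symbols(d$geneA)
  b <- .check_symbols(d$geneB)
  lab <- rep(NA_integer_, nrow(d))
  is_ppi <- d$source == "PPI"
  if (any(is_ppi)) {
    raw <- suppressWarnings(as.numeric(d$provenance[is_ppi]))
    if (any(is.na(raw)) || any(raw != as.integer(raw)))
      stop("non-integer lab count for PPI row(s)", call. = FALSE)
    lab[is_ppi] <- as.integer(raw)
  }
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped", call. = FALSE)
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  out <- data.frame(gene_a = lo, gene_b = hi, source = d$source,
                    provenance = as.character(d$provenance),
                    lab_count = lab, stringsAsFactors = FALSE)
  out <- out[!self, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write raw edge-evidence records
#'
#' Inverse of [read_edge_evidence()] on valid data.
#'
#' @param edges Data.frame as returned by [read_edge_evidence()].
#' @param path Output path.
#' @export
write_edge_evidence <- function(edges, path) {
  d <- data.frame(geneA = edges$gene_a, geneB = edges$gene_b,
                  source = edges$source, provenance = edges$provenance,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read GWAS summary statistics
#'
#' TSV with header `snp, chr, pos, a1, a2, beta, se, p`: per-SNP marginal
#' effect sizes from a (meta-)analysis. `a1` is the effect allele.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `snp`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `p`.
#' @export
read_sumstats <- function(path) {
  d <- .read_tsv(path)
  need <- c("snp", "chr", "pos", "a1", "a2", "beta", "se", "p")
  if (!all(need %in% names(d)))
    stop("sumstats file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad_se <- which(!(d$se > 0))
  if (length(bad_se))
    stop("se <= 0 at row ", bad_se[[1]], call. = FALSE)
  bad_p <- which(!(d$p > 0 & d$p <= 1))
  if (length(bad_p))
    stop("p outside (0,1] at row ", bad_p[[1]], call. = FALSE)
  if (anyDuplicated(d$snp))
    stop("duplicate SNP id: ", d$snp[duplicated(d$snp)][[1]], call. = FALSE)
  data.frame(snp = as.character(d$snp), chrom = as.character(d$chr),
             pos = as.integer(d$pos),
             effect_allele = as.character(d$a1),
             other_allele = as.character(d$a2),
             beta = as.numeric(d$beta), se = as.numeric(d$se),
             p = as.numeric(d$p), stringsAsFactors = FALSE)
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_sumstats()] on valid data.
#'
#' @param ss Data.frame as returned by [read_sumstats()].
#' @param path Output path.
#' @export
write_sumstats <- function(ss, path) {
  d <- data.frame(snp = ss$snp, chr = ss$chrom, pos = ss$pos,
                  a1 = ss$effect_allele, a2 = ss$other_allele,
                  beta = ss$beta, se = ss$se, p = ss$p,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read gene annotation (transcript boundaries)
#'
#' Two dialects, selected explicitly (never sniffed): `"tsv"` is 1-based
#' inclusive with columns `gene, chrom, start, end` (optional `strand`);
#' `"bed"` is 0-based half-open with columns `chrom, start, end, gene` and is
#' converted to 1-based inclusive (`start + 1`).
#'
#' @param path Path to the annotation file.
#' @param dialect Either `"tsv"` or `"bed"`.
#' @return A data.frame with columns `gene`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`, `"-"` or `"*"`), 1-based inclusive coordinates.
#' @export
read_gene_annotation <- function(path, dialect = c("tsv", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    d <- .read_tsv(path)
    need <- c("gene", "chrom", "start", "end")
    if (!all(need %in% names(d)))
      stop("annotation TSV must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    out <- data.frame(gene = .check_symbols(d$gene),
                      chrom = as.character(d$chrom),
                      start = as.integer(d$start), end = as.integer(d$end),
                      strand = if ("strand" %in% names(d))
                        as.character(d$strand) else "*",
                      stringsAsFactors = FALSE)
  } else {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(d) < 4L) stop("BED annotation needs >= 4 columns", call. = FALSE)
    out <- data.frame(gene = .check_symbols(d[[4]]),
                      chrom = as.character(d[[1]]),
                      start = as.integer(d[[2]]) + 1L,
                      end = as.integer(d[[3]]),
                      strand = if (ncol(d) >= 6L) as.character(d[[6]]) else "*",
                      stringsAsFactors = FALSE)
  }
  out$strand[!out$strand %in% c("+", "-")] <- "*"
  bad <- which(!(out$start <= out$end) | out$start < 1L)
  if (length(bad))
    stop("invalid coordinates at row ", bad[[1]], call. = FALSE)
  if (anyDuplicated(out$gene))
    stop("duplicate gene in annotation: ",
         out$gene[duplicated(out$gene)][[1]], call. = FALSE)
  out
}

#' Read an expression matrix with condition labels
#'
#' The matrix file is TSV, genes in rows (first column `gene`), samples in
#' columns, values assumed normalized (log scale). Labels map each sample to
#' one of two condition levels.
#'
#' @param path Path to the expression TSV.
#' @param labels Either a path to a two-column TSV (`sample`, `condition`) or
#'   a data.frame with those columns.
#' @return An `expression_set`: list with `values` (numeric matrix, genes x
#'   samples) and `condition` (factor, one level per sample).
#' @export
read_expression <- function(path, labels) {
  d <- .read_tsv(path)
  if (names(d)[[1]] != "gene")
    stop("expression matrix must have first column 'gene'", call. = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- .check_symbols(d$gene)
  storage.mode(m) <- "double"
  if (is.character(labels)) labels <- .read_tsv(labels)
  if (!all(c("sample", "condition") %in% names(labels)))
    stop("labels need columns sample, condition", call. = FALSE)
  idx <- match(colnames(m), labels$sample)
  if (anyNA(idx))
    stop("samples missing from labels: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  expression_set(m, labels$condition[idx])
}

#' Construct an expression set
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param condition Vector of two condition labels, one per sample.
#' @return An `expression_set` object.
#' @export
expression_set <- function(values, condition) {
  stopifnot(is.matrix(values), ncol(values) == length(condition))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs row and column labels", call. = FALSE)
  cond <- factor(condition)
  if (nlevels(cond) != 2L)
    stop("exactly two condition levels required", call. = FALSE)
  structure(list(values = values, condition = cond), class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("Expression set: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", paste(levels(x$condition), table(x$condition),
                          sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read boolean tissue-expression calls
#'
#' TSV with a `gene` column plus one logical (TRUE/FALSE or 1/0) column per
#' tissue. The default tissue panel is the four classic insulin-sensitive
#' tissues: adipose, muscle, liver, heart.
#'
#' @param path Path to the TSV file.
#' @param tissues Character vector of tissue column names expected.
#' @return A data.frame: `gene` plus one logical column per tissue.
#' @export
read_tissue_calls <- function(path, tissues = DEFAULT_TISSUES) {
  d <- .read_tsv(path)
  if (!all(c("gene", tissues) %in% names(d)))
    stop("tissue-call file must have columns gene, ",
         paste(tissues, collapse = ", "), call. = FALSE)
  out <- data.frame(gene = .check_symbols(d$gene), stringsAsFactors = FALSE)
  for (t in tissues) out[[t]] <- as.logical(d[[t]])
  out
}

#' Read complex memberships
#'
#' TSV with columns `complex_id`, `gene` (one row per member).
#'
#' @param path Path to the TSV file.
#' @return Named list: complex id -> character vector of member genes.
#' @export
read_complexes <- function(path) {
  d <- .read_tsv(path)
  if (!all(c("complex_id", "gene") %in% names(d)))
    stop("complex file must have columns complex_id, gene", call. = FALSE)
  split(.check_symbols(d$gene), as.character(d$complex_id))
}

#' Read a metabolic reaction table
#'
#' TSV with columns `reaction_id`, `substrates`, `products`, `genes`; the
#' last three are `;`-joined lists.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with list-columns `substrates`, `products`, `genes`.
#' @export
read_reactions <- function(path) {
  d <- .read_tsv(path)
  need <- c("reaction_id", "substrates", "products", "genes")
  if (!all(need %in% names(d)))
    stop("reaction file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  split_field <- function(x) {
    lapply(strsplit(as.character(x), ";", fixed = TRUE),
           function(v) trimws(v[nzchar(trimws(v))]))
  }
  out <- data.frame(reaction_id = as.character(d$reaction_id),
                    stringsAsFactors = FALSE)
  out$substrates <- split_field(d$substrates)
  out$products <- split_field(d$products)
  out$genes <- lapply(split_field(d$genes), .check_symbols)
  out
}

#' Read pathway relation records
#'
#' TSV with columns `geneA`, `geneB`, `pathway`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `gene_a`, `gene_b`, `pathway`.
#' @export
read_pathway_relations <- function(path) {
  d <- .read_tsv(path)
  if (!all(c("geneA", "geneB", "pathway") %in% names(d)))
    stop("pathway file must have columns geneA, geneB, pathway", call. = FALSE)
  data.frame(gene_a = .check_symbols(d$geneA), gene_b = .check_symbols(d$geneB),
             pathway = as.character(d$pathway), stringsAsFactors = FALSE)
}
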