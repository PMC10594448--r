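# Overrepresentation analysis of gene lists against gene-set collections:
# hypergeometric upper-tail p-values against a protein-coding reference
# universe, Benjamini-Hochberg FDR per collection, GMT I/O.

#' Construct a gene-set collection
#'
#' @param genes Named list of character vectors (one non-empty vector of
#'   gene symbols per set; names must be unique).
#' @param descriptions Optional character vector of set descriptions,
#'   recycled / matched by set name.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(genes, descriptions = NULL) {
  if (!is.list(genes) || is.null(names(genes)) || any(!nzchar(names(genes))))
    .stopf("'genes' must be a named list of gene vectors")
  if (anyDuplicated(names(genes)))
    .stopf("duplicate gene-set name(s): %s",
           paste(unique(names(genes)[duplicated(names(genes))]),
                 collapse = ", "))
  genes <- lapply(genes, function(g) unique(as.character(g)))
  if (any(lengths(genes) == 0L))
    .stopf("every gene set must contain at least one gene")
  if (is.null(descriptions)) descriptions <- rep("", length(genes))
  descriptions <- rep_len(as.character(descriptions), length(genes))
  names(descriptions) <- names(genes)
  structure(list(genes = genes, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, set sizes %d-%d\n",
              length(x$genes), min(lengths(x$genes)),
              max(lengths(x$genes))))
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' GMT is tab-separated: set name, description, then one gene per field.
#' Duplicate genes within a line are dropped; duplicate set names or lines
#' with fewer than three fields are errors.
#'
#' @param path GMT file path.
#' @param collection A [gene_set_collection()].
#' @return `read_gmt` returns a `gene_set_collection`; `write_gmt` returns
#'   `path` invisibly.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(gene_set_collection(stats::setNames(list(), character(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    .stopf("GMT parse error: line %d has fewer than 3 fields", short[1])
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    .stopf("GMT parse error: duplicate set name '%s'",
           nm[duplicated(nm)][1])
  desc <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(genes) <- nm
  gene_set_collection(genes, desc)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$genes), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$genes[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; output order matches
#' input order. Thin validated wrapper around [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    .stopf("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric overrepresentation analysis
#'
#' Tests each gene set for overrepresentation in `query` relative to
#' `universe`. Genes outside the universe are dropped (with a message
#' reporting the count); sets are restricted to the universe and filtered
#' to `[min_size, max_size]`. The p-value is the hypergeometric upper
#' tail `P[X >= k]` including the observed overlap; FDR is
#' Benjamini-Hochberg across all tested sets of the collection.
#'
#' @param query Character vector of gene symbols (the gene list of
#'   interest, e.g. the top-ranked targets).
#' @param universe Character vector: the reference (protein-coding) list.
#' @param sets A [gene_set_collection()].
#' @param min_size,max_size Set-size bounds after restriction to the
#'   universe (defaults 5 and 2000).
#' @return A data.table with columns `set_name`, `k` (overlap), `m` (set
#'   size in universe), `q` (query size in universe), `N` (universe
#'   size), `enrichment_ratio` (`(k/q)/(m/N)`), `p_value`, `fdr`; sorted
#'   by `p_value` ascending, ties by `set_name`.
#' @export
ora <- function(query, universe, sets, min_size = 5L, max_size = 2000L) {
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) .stopf("'universe' must be non-empty")
  query0 <- unique(as.character(query))
  query <- intersect(query0, universe)
  dropped <- length(query0) - length(query)
  if (dropped > 0)
    message(sprintf("ora: dropped %d query gene(s) not in the universe",
                    dropped))
  if (!length(query)) .stopf("query is empty after universe intersection")

  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(sets$genes), function(nm) {
    g <- intersect(sets$genes[[nm]], universe)
    m <- length(g)
    if (m < min_size || m > max_size) return(NULL)
    k <- length(intersect(g, query))
    p <- stats::phyper(k - 1L, m, N - m, q, lower.tail = FALSE)
    data.table::data.table(set_name = nm, k = k, m = m, q = q, N = N,
                           enrichment_ratio = (k / q) / (m / N),
                           p_value = p)
  })
  res <- data.table::rbindlist(rows)
  if (!nrow(res))
    return(data.table::data.table(set_name = character(0), k = integer(0),
                                  m = integer(0), q = integer(0),
                                  N = integer(0),
                                  enrichment_ratio = numeric(0),
                                  p_value = numeric(0), fdr = numeric(0)))
  res[, fdr := bh_fdr(p_value)]
  res <- res[order(res$p_value, res$set_name), ]
  res[]
}

#' Filter ORA results at an FDR threshold
#'
#' @param results Table from [ora()].
#' @param fdr_threshold Keep rows with `fdr` strictly below this value
#'   (default 0.1).
#' @return The filtered table, original order preserved.
#' @export
ora_significant <- function(results, fdr_threshold = 0.1) {
  results[results$fdr < fdr_threshold, ]
}
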