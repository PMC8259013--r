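#' Two-sided Fisher's exact test for a 2x2 over-representation table
#'
#' Tests whether `k` query hits in a gene set of size `K`, from a query of
#' size `n_query` drawn from a universe of size `N`, deviate from the
#' hypergeometric expectation. The two-sided P sums the hypergeometric
#' probabilities of all tables with the same margins whose probability does
#' not exceed that of the observed table (minimum-likelihood rule; ties
#' within a relative 1e-7 are treated as equal, the usual convention).
#'
#' @param k observed overlap (query intersect set).
#' @param n_query query size.
#' @param K set size in the universe.
#' @param N universe size.
#' @return two-sided P value in (0, 1\].
#' @export
fisher_exact <- function(k, n_query, K, N) {
  if (length(k) > 1)
    return(mapply(fisher_exact, k, n_query, K, N))
  if (k < 0 || K < 0 || n_query < 0 || N < 0 ||
      k > min(n_query, K) || n_query > N || K > N ||
      k < n_query + K - N)
    stopf("fisher_exact: margins violated (k=%s n=%s K=%s N=%s)",
          k, n_query, K, N)
  lo <- max(0, n_query + K - N)
  hi <- min(n_query, K)
  d <- dhyper(lo:hi, K, N - K, n_query)
  min(1, sum(d[d <= d[k - lo + 1] * (1 + 1e-7)]))
}

#' Read / write gene sets in GMT format
#'
#' `read_gmt()` wraps `fgsea::gmtPathways()`; `write_gmt()` writes the
#' standard three-plus columns (name, description, tab-separated symbols).
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional character vector (recycled `"na"`).
#' @return `read_gmt()`: named list of symbol vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set over-representation of a query list
#'
#' Tests each set against the query with [fisher_exact()] after intersecting
#' both with the universe. Results carry the enrichment score
#' `-log10(P)` and are ranked by score (descending), ties broken by set
#' name. Significance is flagged at raw `p < alpha`; the BH column is
#' informational only.
#'
#' @param query character vector of gene symbols (out-of-universe symbols
#'   are dropped with a count in the `n_dropped` attribute).
#' @param sets named list of symbol vectors.
#' @param universe character vector of eligible symbols (see
#'   [build_universe()]).
#' @param alpha significance level.
#' @return data frame of class `enrichment_results`: set, k, n_query, K, N,
#'   p, bh, score, significant.
#' @export
enrich <- function(query, sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  N <- length(universe)
  q0 <- unique(query)
  q <- intersect(q0, universe)
  n_dropped <- length(q0) - length(q)
  if (n_dropped > 0) message(n_dropped, " query symbols outside the universe dropped")
  if (length(q) == 0) {
    warning("empty query after universe intersection", call. = FALSE)
    out <- data.frame(set = character(), k = integer(), n_query = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      bh = numeric(), score = numeric(),
                      significant = logical())
    attr(out, "n_dropped") <- n_dropped
    class(out) <- c("enrichment_results", "data.frame")
    return(out)
  }
  sets_u <- lapply(sets, intersect, y = universe)
  sets_u <- sets_u[lengths(sets_u) > 0]
  K <- lengths(sets_u)
  k <- vapply(sets_u, function(s) length(intersect(q, s)), integer(1))
  p <- vapply(seq_along(sets_u),
              function(i) fisher_exact(k[i], length(q), K[i], N), numeric(1))
  out <- data.frame(set = names(sets_u), k = k, n_query = length(q),
                    K = K, N = N, p = p, bh = p.adjust(p, "BH"),
                    score = -log10(p), significant = p < alpha,
                    row.names = NULL)
  out <- out[order(-out$score, out$set), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("enrichment_results", "data.frame")
  out
}

#' Build the enrichment universe
#'
#' Default mode `"array_genesets"`: coding-gene symbols represented on the
#' array that appear in at least one gene set (the most defensible
#' array-aware background). Alternatives: all array gene symbols
#' (`"array"`), or all symbols in the GMT (`"gmt"`).
#'
#' @param annotation probe annotation data frame.
#' @param sets named list of symbol vectors.
#' @param mode universe mode.
#' @return character vector of symbols.
#' @export
build_universe <- function(annotation, sets,
                           mode = c("array_genesets", "array", "gmt")) {
  mode <- match.arg(mode)
  array_genes <- unique(annotation$gene_symbol[annotation$rna_class == "mRNA"])
  gmt_genes <- unique(unlist(sets, use.names = FALSE))
  switch(mode,
         array_genesets = intersect(array_genes, gmt_genes),
         array = array_genes,
         gmt = gmt_genes)
}

#' Enrichment of quadrant-defined gene groups
#'
#' Runs [enrich()] on configured unions of quadrants per comparison, e.g.
#' all upregulated m6A-associated genes (Hyper-Up plus Hypo-Up) or single
#' quadrants split by methylation direction.
#'
#' @param quadrants an [assign_quadrants()] result.
#' @param sets,universe,alpha passed to [enrich()].
#' @param groups named list mapping group name to quadrant labels; the
#'   default mirrors the common reporting splits.
#' @return named list of `enrichment_results`, with attribute `group_sizes`.
#' @export
enrich_quadrant_groups <- function(quadrants, sets, universe,
                                   groups = list(
                                     up = c("Hyper-Up", "Hypo-Up"),
                                     down = c("Hyper-Down", "Hypo-Down"),
                                     hyper_up = "Hyper-Up",
                                     hypo_up = "Hypo-Up"),
                                   alpha = 0.05) {
  bad <- setdiff(unlist(groups), quadrant_levels)
  if (length(bad)) stopf("unknown quadrant in group spec: %s",
                         paste(bad, collapse = ", "))
  out <- lapply(groups, function(quads) {
    genes <- unique(quadrants$gene_symbol[quadrants$quadrant %in% quads])
    if (length(intersect(genes, universe)) == 0) {
      message("empty quadrant group after universe intersection; ",
              "empty enrichment returned")
      return(suppressWarnings(suppressMessages(
        enrich(genes, sets, universe, alpha))))
    }
    enrich(genes, sets, universe, alpha)
  })
  attr(out, "group_sizes") <- vapply(groups, function(quads) {
    length(unique(quadrants$gene_symbol[quadrants$quadrant %in% quads]))
  }, integer(1))
  out
}
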