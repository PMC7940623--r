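# Hypergeometric pathway overrepresentation with the size filter applied
# after intersecting each set with the analysis universe.

#' Filter pathways by post-intersection size
#'
#' A pathway is tested only if the number of its genes present in the
#' analysis universe lies within `[min_size, max_size]` (both bounds
#' inclusive; defaults 10 and 1000). Sizes are always counted after
#' intersection with the universe, so a large pathway with few genes in
#' the universe can still qualify.
#'
#' @param db named list of gene sets (e.g. from [simulate_pathways()] or
#'   [read_gmt()]).
#' @param universe character vector: the analysis gene universe.
#' @param min_size,max_size inclusive size bounds.
#' @return The filtered database (same class as `db`).
#' @export
filter_pathways_by_size <- function(db, universe, min_size = 10,
                                    max_size = 1000) {
  sizes <- vapply(db, function(s) length(intersect(s, universe)), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) warning("no pathway passes the size filter")
  out <- db[keep]
  class(out) <- class(db)
  out
}

#' Hypergeometric overrepresentation of a gene list in pathways
#'
#' For each pathway, tests whether the gene list contains more pathway
#' genes than expected from drawing `n = |list|` genes from the universe
#' without replacement: p = P(X >= k) with X hypergeometric on
#' (N = |universe|, K = |pathway in universe|, n). The upper tail includes
#' the observed overlap. q-values are Benjamini-Hochberg across the tested
#' pathways.
#'
#' @param gene_list character vector, must be a subset of `universe`.
#' @param db named list of gene sets (already size-filtered if desired).
#' @param universe character vector: the analysis gene universe.
#' @return data.frame: `pathway_id`, `N`, `K`, `n`, `k`, `p`, `q`, sorted
#'   by increasing p.
#' @export
hypergeom_overrepresentation <- function(gene_list, db, universe) {
  offenders <- setdiff(gene_list, universe)
  if (length(offenders)) {
    stop("gene list contains genes outside the universe: ",
         paste(head(offenders, 10), collapse = ", "), call. = FALSE)
  }
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(db), function(id) {
    set <- intersect(db[[id]], universe)
    K <- length(set)
    k <- length(intersect(set, gene_list))
    data.frame(pathway_id = id, N = N, K = K, n = n, k = k,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(pathway_id = character(), N = integer(),
                      K = integer(), n = integer(), k = integer(),
                      p = numeric(), q = numeric()))
  }
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$pathway_id), ]
  rownames(out) <- NULL
  out
}
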