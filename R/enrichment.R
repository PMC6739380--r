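#' Hypergeometric upper-tail probability
#'
#' Over-representation p-value: the probability of drawing at least `k`
#' successes in `n` draws, without replacement, from a universe of `N` genes
#' of which `K` belong to the set. Computed as an exact tail sum of
#' hypergeometric point masses (no normal approximation).
#'
#' @param k Observed overlap.
#' @param K Gene-set size (within the universe).
#' @param n Query size (within the universe).
#' @param N Universe size.
#' @return `P(X >= k)`; 1 when `k <= 0`.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (K > N || n > N) stop("inconsistent counts: K and n must be <= N")
  if (k > min(K, n)) stop("inconsistent counts: k must be <= min(K, n)")
  if (k < 0) stop("k must be >= 0")
  lo <- max(k, 0L, K + n - N)
  hi <- min(K, n)
  if (k <= max(0L, K + n - N)) return(1)
  i <- lo:hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment:
#' `q_(i) = min_(j >= i) p_(j) * m / j` over the sorted p-values, returned in
#' the input order. Invariant under permutation of the input (up to the same
#' reordering) and always in (0, 1].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric test of a query gene list against each gene set,
#' within a declared universe, with Benjamini-Hochberg correction across all
#' tested sets. Query genes outside the universe are dropped with a warning.
#' Sets whose universe intersection falls outside `[min_size, max_size]` are
#' skipped (declared in the result's attributes).
#'
#' @param query Character vector of query gene symbols.
#' @param genesets Named list of gene vectors (see [read_genesets()]).
#' @param universe Character vector: the background gene universe. The
#'   pipeline default is every gene carrying at least one post-cascade
#'   variant.
#' @param min_size,max_size Set-size window after universe intersection
#'   (defaults 3 and 500).
#' @return Data frame sorted by p: `set_id, description, k, K, n, N, p, q`,
#'   with attributes `universe_size`, `query_size`, `skipped_sets`.
#' @export
run_ora <- function(query, genesets, universe, min_size = 3, max_size = 500) {
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped: ",
            paste(utils::head(outside, 5), collapse = ", "),
            if (length(outside) > 5) ", ..." else "")
    query <- intersect(query, universe)
  }
  empty <- data.frame(set_id = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(query)) {
    warning("empty query; no enrichment computed")
    return(empty)
  }
  N <- length(universe)
  n <- length(query)
  trimmed <- lapply(genesets, intersect, universe)
  sizes <- lengths(trimmed)
  keep <- sizes >= min_size & sizes <= max_size
  skipped <- names(genesets)[!keep]
  trimmed <- trimmed[keep]
  if (!length(trimmed)) {
    attr(empty, "skipped_sets") <- skipped
    return(empty)
  }
  res <- data.frame(
    set_id = names(trimmed),
    description = vapply(names(trimmed), function(s)
      attr(genesets[[s]], "description") %||% s, ""),
    k = vapply(trimmed, function(s) length(intersect(s, query)), 0L),
    K = lengths(trimmed),
    n = n, N = N,
    stringsAsFactors = FALSE)
  res$p <- vapply(seq_len(nrow(res)), function(i)
    hypergeom_upper(res$k[i], res$K[i], res$n[i], res$N[i]), 0)
  res$q <- bh_fdr(res$p)
  res <- res[order(res$p, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "universe_size") <- N
  attr(res, "query_size") <- n
  attr(res, "skipped_sets") <- skipped
  res
}

#' Build an enrichment-map network
#'
#' Nodes are gene sets passing the significance cutoff; edges connect sets
#' whose gene-overlap similarity reaches `similarity_cutoff`. The default
#' similarity is the overlap coefficient `|A n B| / min(|A|, |B|)` with the
#' conventional enrichment-map cutoff of 0.375; Jaccard is available by flag.
#'
#' @param results ORA results from [run_ora()].
#' @param genesets The gene-set list the results were computed from.
#' @param q_cutoff Significance cutoff on q (default 0.05).
#' @param similarity_cutoff Minimum edge similarity (default 0.375).
#' @param metric `"overlap"` (default) or `"jaccard"`.
#' @return List of class `sibseg_enrichment_map`: `nodes` (`set_id, q, size`),
#'   `edges` (`set_a, set_b, similarity`), plus the cutoffs used.
#' @export
build_enrichment_map <- function(results, genesets, q_cutoff = 0.05,
                                 similarity_cutoff = 0.375,
                                 metric = c("overlap", "jaccard")) {
  metric <- match.arg(metric)
  sig <- results[!is.na(results$q) & results$q <= q_cutoff, , drop = FALSE]
  nodes <- data.frame(set_id = sig$set_id, q = sig$q, size = sig$K,
                      stringsAsFactors = FALSE)
  edges <- data.frame(set_a = character(), set_b = character(),
                      similarity = numeric(), stringsAsFactors = FALSE)
  ids <- nodes$set_id
  if (length(ids) >= 2L) {
    sets <- lapply(genesets[ids], unique)
    pairs <- utils::combn(seq_along(ids), 2)
    sim <- apply(pairs, 2, function(ij) {
      a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
      ov <- length(intersect(a, b))
      if (metric == "overlap") ov / min(length(a), length(b)) else
        ov / length(union(a, b))
    })
    keep <- sim >= similarity_cutoff
    edges <- data.frame(set_a = ids[pairs[1, keep]],
                        set_b = ids[pairs[2, keep]],
                        similarity = sim[keep], stringsAsFactors = FALSE)
  }
  out <- list(nodes = nodes, edges = edges, q_cutoff = q_cutoff,
              similarity_cutoff = similarity_cutoff, metric = metric)
  class(out) <- "sibseg_enrichment_map"
  out
}

#' @export
print.sibseg_enrichment_map <- function(x, ...) {
  cat(sprintf("Enrichment map: %d node(s), %d edge(s) [%s >= %.3f, q <= %g]\n",
              nrow(x$nodes), nrow(x$edges), x$metric, x$similarity_cutoff,
              x$q_cutoff))
  invisible(x)
}

#' Write an enrichment map as SIF plus edge attributes
#'
#' The SIF file (`node relationship node`) loads in standard graph viewers;
#' edge similarities go to a companion TSV. Isolated nodes are written as
#' single-column SIF lines.
#'
#' @param map A `sibseg_enrichment_map`.
#' @param sif_path Output SIF path.
#' @param edge_attr_path Optional edge-attribute TSV path (default: `sif_path`
#'   with `.edges.tsv`).
#' @return `sif_path`, invisibly.
#' @export
write_sif <- function(map, sif_path, edge_attr_path = NULL) {
  if (is.null(edge_attr_path)) {
    edge_attr_path <- paste0(tools::file_path_sans_ext(sif_path), ".edges.tsv")
  }
  linked <- unique(c(map$edges$set_a, map$edges$set_b))
  iso <- setdiff(map$nodes$set_id, linked)
  lines <- c(
    if (nrow(map$edges))
      paste(map$edges$set_a, "geneset_overlap", map$edges$set_b, sep = "\t"),
    iso)
  writeLines(lines, sif_path)
  utils::write.table(map$edges, edge_attr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sif_path)
}

#' Write ORA results as TSV
#'
#' @param results ORA results data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
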