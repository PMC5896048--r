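#' One-sided hypergeometric over-representation p-value
#'
#' Probability of observing \code{k} or more category genes in a sample of
#' \code{n} genes drawn without replacement from a universe of \code{N} genes
#' of which \code{K} are in the category; the upper tail of Fisher's exact
#' test for a 2x2 table.
#'
#' @param k cluster genes in the category.
#' @param n cluster size.
#' @param K universe genes in the category.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
fisher_upper <- function(k, n, K, N) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (k < 0 || k > n || n > N || K > N || k > K) {
    stop(sprintf("inconsistent counts: k=%d n=%d K=%d N=%d", k, n, K, N))
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: sort p ascending, \code{adj_i = min_{j>=i}(p_j * m/j)}
#' capped at 1, returned in the input order. Delegates to
#' [stats::p.adjust()] after validation.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

## Ancestor closure of dotted category codes: "34.19.2" -> c("34", "34.19",
## "34.19.2"). Vectorised over codes.
expand_category_codes <- function(codes) {
  unique(unlist(lapply(codes, function(code) {
    parts <- strsplit(code, ".", fixed = TRUE)[[1]]
    vapply(seq_along(parts), function(d) paste(parts[1:d], collapse = "."), "")
  })))
}

## gene -> character vector of codes (closure applied); returns a named list
## category code -> character vector of gene ids.
category_gene_sets <- function(annotation) {
  stopifnot(is.data.frame(annotation), all(c("gene", "category") %in% names(annotation)))
  if (any(!nzchar(annotation$category))) stop("empty category code")
  per_gene <- split(annotation$category, annotation$gene)
  closed <- lapply(per_gene, expand_category_codes)
  genes <- rep(names(closed), lengths(closed))
  codes <- unlist(closed, use.names = FALSE)
  split(genes, codes)
}

run_enrichment <- function(members, sets, universe, fdr_threshold) {
  n <- length(members)
  N <- length(universe)
  rows <- lapply(names(sets), function(code) {
    set <- intersect(sets[[code]], universe)
    K <- length(set)
    if (K < 2L) return(NULL)   # untestable margin
    k <- sum(members %in% set)
    if (k == 0L) return(NULL)
    data.frame(category = code, k = k, n = n, K = K, N = N,
               p = fisher_upper(k, n, K, N), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(category = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      fdr = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$enriched <- out$fdr < fdr_threshold
  out[order(out$fdr, out$category), , drop = FALSE]
}

#' Functional-category enrichment of a co-expression cluster
#'
#' Tests every hierarchical category with at least one cluster member for
#' over-representation against the universe of measured genes, one Fisher
#' upper-tail test per category at every hierarchy depth (a gene annotated
#' "34.19" also counts under "34"), with Benjamini-Hochberg adjustment across
#' the categories tested within this cluster.
#'
#' @param cluster a [top_k_cluster()] result, or a character vector of
#'   member gene ids.
#' @param annotation data.frame with columns \code{gene}, \code{category}
#'   (dotted hierarchical codes such as "34.19").
#' @param universe character vector of all measured gene ids (the cluster
#'   must be a subset).
#' @param fdr_threshold significance cutoff on the adjusted value; default
#'   0.05 for functional categories.
#' @param include_guide if \code{cluster} carries a guide attribute, whether
#'   to add the guide to the tested set. Default \code{FALSE}: the tested set
#'   is what is co-expressed with the guide.
#' @return data.frame with columns \code{category}, \code{k}, \code{n},
#'   \code{K}, \code{N}, \code{p}, \code{fdr}, \code{enriched}, sorted by
#'   \code{fdr} then code. Categories with fewer than 2 universe genes are
#'   skipped (untestable margins).
#' @export
enrich_categories <- function(cluster, annotation, universe,
                              fdr_threshold = 0.05, include_guide = FALSE) {
  members <- if (is.data.frame(cluster)) cluster$gene else as.character(cluster)
  if (include_guide && !is.null(attr(cluster, "guide"))) {
    members <- union(members, attr(cluster, "guide"))
  }
  if (length(members) == 0L) stop("empty cluster")
  if (!all(members %in% universe)) stop("cluster members must be a subset of the universe")
  sets <- category_gene_sets(annotation)
  run_enrichment(members, sets, universe, fdr_threshold)
}

#' CRE-presence enrichment of a co-expression cluster
#'
#' Same machinery as [enrich_categories()] with the "category" being the set
#' of genes whose promoter contains at least one hit of a motif. Cluster
#' genes without a promoter in the presence table are excluded with a
#' warning (reducing \code{n}).
#'
#' @param cluster member gene ids (vector or [top_k_cluster()] result).
#' @param presence logical gene x motif matrix (rownames = gene ids,
#'   colnames = motif ids), as produced by [presence_matrix()].
#' @param universe all measured gene ids.
#' @param fdr_threshold default 0.01 for CREs.
#' @return data.frame as in [enrich_categories()], \code{category} holding
#'   motif ids.
#' @export
enrich_cres <- function(cluster, presence, universe, fdr_threshold = 0.01) {
  members <- if (is.data.frame(cluster)) cluster$gene else as.character(cluster)
  if (length(members) == 0L) stop("empty cluster")
  if (ncol(presence) == 0L || nrow(presence) == 0L) {
    return(run_enrichment(members, list(), universe, fdr_threshold))
  }
  missing <- setdiff(members, rownames(presence))
  if (length(missing) > 0L) {
    warning(sprintf("%d cluster gene(s) missing a promoter; excluded", length(missing)))
    members <- setdiff(members, missing)
  }
  universe <- intersect(universe, rownames(presence))
  sets <- lapply(colnames(presence), function(m) rownames(presence)[presence[, m]])
  names(sets) <- colnames(presence)
  run_enrichment(members, sets, universe, fdr_threshold)
}

#' Summarise enrichment across guide networks and platforms
#'
#' Counts, per category, how many guide-gene networks are enriched on each
#' of two expression platforms (e.g. microarray and RNA-seq) and the total
#' frequency across both. Categories enriched nowhere are omitted.
#'
#' @param results_a,results_b named lists of enrichment data.frames, one per
#'   guide network, from [enrich_categories()] or [enrich_cres()].
#' @return data.frame with columns \code{category}, \code{n_platform_a},
#'   \code{n_platform_b}, \code{frequency}, sorted by descending frequency
#'   then code.
#' @export
composite_summary <- function(results_a, results_b) {
  count_enriched <- function(results) {
    cats <- unlist(lapply(results, function(r) unique(r$category[r$enriched])))
    table(cats)
  }
  ta <- count_enriched(results_a)
  tb <- count_enriched(results_b)
  cats <- sort(union(names(ta), names(tb)))
  if (length(cats) == 0L) {
    return(data.frame(category = character(), n_platform_a = integer(),
                      n_platform_b = integer(), frequency = integer(),
                      stringsAsFactors = FALSE))
  }
  na <- ifelse(cats %in% names(ta), as.integer(ta[cats]), 0L)
  nb <- ifelse(cats %in% names(tb), as.integer(tb[cats]), 0L)
  out <- data.frame(category = cats, n_platform_a = na, n_platform_b = nb,
                    frequency = na + nb, stringsAsFactors = FALSE)
  out[order(-out$frequency, out$category), , drop = FALSE]
}
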