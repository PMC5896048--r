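#' Log-transform an expression matrix
#'
#' Applies \code{log2(x + offset)} cell-wise. FPKM-like abundance values are
#' conventionally analysed on the log scale; the default offset of 1 maps
#' zero abundance to zero.
#'
#' @param x numeric matrix of non-negative abundances, genes in rows
#'   (rownames = gene ids), conditions in columns.
#' @param offset positive pseudocount added before taking logs. Default 1.
#' @return matrix of the same shape and dimnames, values \code{log2(x + offset)}.
#' @examples
#' m <- matrix(c(0, 3, 1, 7), 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' log_transform(m)
#' @export
log_transform <- function(x, offset = 1) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (offset <= 0) stop("offset must be > 0")
  bad <- which(x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    g <- if (is.null(rownames(x))) bad[1, 1] else rownames(x)[bad[1, 1]]
    cc <- if (is.null(colnames(x))) bad[1, 2] else colnames(x)[bad[1, 2]]
    stop(sprintf("negative expression value at gene '%s', condition '%s'", g, cc))
  }
  log2(x + offset)
}

#' Fragments per kilobase of transcript per million mapped reads
#'
#' \code{FPKM = counts * 1e9 / (gene_length_bp * library_size)}.
#'
#' @param counts non-negative integer read counts.
#' @param gene_length_bp transcript lengths in base pairs, recycled against
#'   \code{counts}.
#' @param library_size total mapped reads in the library (scalar).
#' @return numeric vector of FPKM values.
#' @export
fpkm <- function(counts, gene_length_bp, library_size) {
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(gene_length_bp <= 0)) stop("gene lengths must be > 0")
  if (length(library_size) != 1L || library_size <= 0) {
    stop("library_size must be a single positive number")
  }
  counts * 1e9 / (gene_length_bp * library_size)
}

#' Pearson correlation matrix over genes
#'
#' Row-wise (gene-wise) Pearson correlation. Genes with zero variance cannot
#' be correlated; their rows/columns are set to \code{NA} and flagged, and
#' downstream ranking excludes them.
#'
#' @param x numeric matrix, genes in rows; typically log-transformed
#'   abundances. At least 3 columns (conditions) are required.
#' @return symmetric correlation matrix with attribute \code{"usable"}, a
#'   logical vector marking genes with non-zero variance.
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 3L) stop("need at least 3 conditions to correlate")
  if (anyNA(x)) stop("expression matrix contains missing values")
  v <- apply(x, 1L, stats::var)
  usable <- v > 0
  if (any(!usable)) {
    warning(sprintf("%d zero-variance gene(s) excluded from correlation ranking",
                    sum(!usable)))
  }
  r <- matrix(NA_real_, nrow(x), nrow(x), dimnames = list(rownames(x), rownames(x)))
  if (sum(usable) >= 2L) {
    r[usable, usable] <- stats::cor(t(x[usable, , drop = FALSE]))
  }
  diag(r)[usable] <- 1
  attr(r, "usable") <- usable
  r
}

## Directed correlation ranks: rank_mat[a, b] = position of b among a's
## correlators sorted by descending r, self excluded, ties broken by
## ascending gene id. Rows are permutations of 1..(G-1) over usable genes.
correlation_ranks <- function(r, usable) {
  ids <- rownames(r)
  g <- nrow(r)
  rk <- matrix(NA_real_, g, g, dimnames = dimnames(r))
  idx <- which(usable)
  for (a in idx) {
    others <- setdiff(idx, a)
    o <- others[order(-r[a, others], ids[others])]
    rk[a, o] <- seq_along(o)
  }
  rk
}

#' Fit a mutual-rank co-expression network
#'
#' The central model object of the package. Expression values are
#' log-transformed (\code{log2(x + offset)}), gene-gene Pearson correlations
#' computed, and each gene's correlators ranked by descending r (self
#' excluded, ties broken by ascending gene id). The mutual rank of a pair is
#' the geometric mean of the two directed ranks,
#' \deqn{MR(A,B) = \sqrt{R(A \to B) \cdot R(B \to A)},}
#' so MR = 1 means reciprocal best correlators and low MR means strong
#' co-expression. Zero-variance (silent) genes are retained in the object but
#' excluded from ranking.
#'
#' @param x non-negative expression matrix (genes x conditions, rownames =
#'   gene ids). Raw abundance scale; the log transform is applied internally.
#' @param log whether to log-transform first. Set \code{FALSE} if \code{x}
#'   is already on the log scale.
#' @param offset pseudocount for the log transform.
#' @return an object of class \code{"mr_network"}: list with elements
#'   \code{mr} (symmetric MR matrix, NA for unusable genes), \code{ranks}
#'   (directed rank matrix), \code{cor} (Pearson matrix), \code{usable}
#'   (logical), \code{gene_ids}, \code{n_conditions}.
#' @seealso [top_k_cluster()], [mr_edge_list()]
#' @examples
#' set.seed(1)
#' m <- matrix(rexp(60), 6, 10, dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
#' net <- mr_network(m)
#' net
#' top_k_cluster(net, "g1", k = 3)
#' @export
mr_network <- function(x, log = TRUE, offset = 1) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("g%d", seq_len(nrow(x)))
  lx <- if (log) log_transform(x, offset) else x
  r <- pearson_matrix(lx)
  usable <- attr(r, "usable")
  if (sum(usable) < 2L) stop("need at least 2 usable (non-constant) genes")
  rk <- correlation_ranks(r, usable)
  mr <- sqrt(rk * t(rk))
  diag(mr) <- NA_real_
  structure(list(mr = mr, ranks = rk, cor = r, usable = usable,
                 gene_ids = rownames(x), n_conditions = ncol(x)),
            class = "mr_network")
}

#' @export
print.mr_network <- function(x, ...) {
  cat(sprintf("Mutual-rank co-expression network: %d genes (%d usable), %d conditions\n",
              length(x$gene_ids), sum(x$usable), x$n_conditions))
  invisible(x)
}

#' @export
summary.mr_network <- function(object, ...) {
  mrv <- object$mr[upper.tri(object$mr)]
  mrv <- mrv[!is.na(mrv)]
  out <- list(n_genes = length(object$gene_ids),
              n_usable = sum(object$usable),
              n_conditions = object$n_conditions,
              mr_quantiles = stats::quantile(mrv, c(0, .25, .5, .75, 1)),
              n_reciprocal_best = sum(mrv == 1))
  class(out) <- "summary.mr_network"
  out
}

#' @export
print.summary.mr_network <- function(x, ...) {
  cat(sprintf("Mutual-rank network: %d genes (%d usable), %d conditions\n",
              x$n_genes, x$n_usable, x$n_conditions))
  cat(sprintf("Reciprocal-best pairs (MR = 1): %d\n", x$n_reciprocal_best))
  cat("MR quantiles:\n")
  print(round(x$mr_quantiles, 2))
  invisible(x)
}

#' @export
as.matrix.mr_network <- function(x, ...) x$mr

#' @importFrom graphics hist
#' @export
plot.mr_network <- function(x, ...) {
  mrv <- x$mr[upper.tri(x$mr)]
  graphics::hist(mrv[!is.na(mrv)], breaks = 50,
                 main = "Mutual rank distribution", xlab = "MR", ...)
  invisible(x)
}

#' Gene-centric top-k co-expression cluster
#'
#' The k nearest neighbours of a guide gene by ascending mutual rank (lower
#' MR = stronger co-expression), ties broken by ascending gene id; the guide
#' itself is excluded.
#'
#' @param network an [mr_network()] fit.
#' @param guide guide gene id (must be a usable gene in the network).
#' @param k neighbourhood size; default 100. If k exceeds the number of
#'   usable co-genes, all are returned with a warning.
#' @return data.frame of class \code{"coexpression_cluster"} with columns
#'   \code{gene}, \code{mr}, \code{rank}; attribute \code{guide}.
#' @export
top_k_cluster <- function(network, guide, k = 100) {
  stopifnot(inherits(network, "mr_network"))
  if (!guide %in% network$gene_ids) stop(sprintf("unknown guide gene '%s'", guide))
  if (!network$usable[[guide]]) stop(sprintf("guide gene '%s' has zero variance", guide))
  if (k < 1) stop("k must be >= 1")
  mr <- network$mr[guide, ]
  cand <- names(mr)[!is.na(mr)]
  cand <- setdiff(cand, guide)
  avail <- length(cand)
  if (k > avail) {
    warning(sprintf("k = %d exceeds %d available neighbours; returning all", k, avail))
    k <- avail
  }
  o <- cand[order(mr[cand], cand)][seq_len(k)]
  out <- data.frame(gene = o, mr = unname(mr[o]), rank = seq_len(k),
                    stringsAsFactors = FALSE)
  attr(out, "guide") <- guide
  class(out) <- c("coexpression_cluster", "data.frame")
  out
}

#' @export
print.coexpression_cluster <- function(x, ...) {
  cat(sprintf("Co-expression cluster of guide '%s' (%d members)\n",
              attr(x, "guide"), nrow(x)))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat(sprintf("... %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Network edge list
#'
#' Long-format MR edges (each unordered pair once), optionally truncated to
#' each gene's best \code{k} neighbours; importable by generic network tools.
#'
#' @param network an [mr_network()].
#' @param max_mr keep edges with MR below this value (default Inf = all).
#' @return data.frame with columns \code{gene_a}, \code{gene_b}, \code{mr}.
#' @export
mr_edge_list <- function(network, max_mr = Inf) {
  stopifnot(inherits(network, "mr_network"))
  mr <- network$mr
  ut <- which(upper.tri(mr) & !is.na(mr) & mr <= max_mr, arr.ind = TRUE)
  data.frame(gene_a = rownames(mr)[ut[, 1]],
             gene_b = colnames(mr)[ut[, 2]],
             mr = mr[ut],
             stringsAsFactors = FALSE)
}

#' Row-wise Z-score normalisation
#'
#' Per gene: \code{(x - mean(x)) / sd(x)} with sample sd (divisor n-1); the
#' standard row scaling behind expression heatmaps. Constant rows are emitted
#' as all-zero with a warning.
#'
#' @param x numeric matrix, genes in rows.
#' @return matrix of the same shape; each non-constant row has mean ~0 and
#'   sample sd 1.
#' @export
row_zscore <- function(x) {
  x <- as.matrix(x)
  m <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  const <- s == 0 | is.na(s)
  if (any(const)) {
    warning(sprintf("%d constant row(s) set to zero", sum(const)))
    s[const] <- 1
  }
  z <- (x - m) / s
  z[const, ] <- 0
  z
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of genes with either correlation distance
#' (\code{1 - r}) or Euclidean distance, and average or complete linkage.
#' A thin wrapper around [stats::hclust()] with the distance conventions
#' used for expression-profile dendrograms.
#'
#' @param x numeric matrix, genes in rows (>= 2 rows).
#' @param metric \code{"correlation"} (distance \code{1 - r}) or
#'   \code{"euclidean"}.
#' @param linkage \code{"average"} or \code{"complete"}.
#' @return an object of class \code{"hclust"}.
#' @export
hierarchical_cluster <- function(x, metric = c("correlation", "euclidean"),
                                 linkage = c("average", "complete")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to cluster")
  d <- if (metric == "correlation") {
    stats::as.dist(1 - stats::cor(t(x)))
  } else {
    stats::dist(x)
  }
  stats::hclust(d, method = linkage)
}
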