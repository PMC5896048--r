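#' Rank genes along chromosomes
#'
#' Assigns each gene a 1-based rank within its chromosome by ascending start
#' coordinate, ties broken by ascending gene id. Rank differences, not base
#' distances, drive the tandem/proximal definitions.
#'
#' @param positions data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{gene} (BED-like, 0-based half-open coordinates).
#' @return the positions with a \code{rank} column, sorted by chromosome and
#'   rank.
#' @export
assign_ranks <- function(positions) {
  stopifnot(is.data.frame(positions),
            all(c("chrom", "start", "end", "gene") %in% names(positions)))
  if (anyDuplicated(positions$gene)) {
    stop(sprintf("duplicate gene id '%s' in position table",
                 positions$gene[duplicated(positions$gene)][1]))
  }
  o <- order(positions$chrom, positions$start, positions$gene)
  positions <- positions[o, , drop = FALSE]
  positions$rank <- stats::ave(seq_len(nrow(positions)), positions$chrom,
                               FUN = seq_along)
  rownames(positions) <- NULL
  positions
}

## Symmetrised homologous pairs above the e-value ceiling, self-hits dropped.
## Returns a two-column character matrix of unordered pairs (a < b).
homolog_pairs <- function(hits, evalue_max) {
  keep <- hits$evalue <= evalue_max & hits$query != hits$subject
  if (!any(keep)) return(matrix(character(0), 0, 2))
  a <- pmin(hits$query[keep], hits$subject[keep])
  b <- pmax(hits$query[keep], hits$subject[keep])
  unique(cbind(a, b))
}

#' Detect collinear blocks by anchor chaining
#'
#' For every chromosome pair, homology hits define candidate anchors
#' (gene-rank pairs). A dynamic-programming chain finds runs of anchors whose
#' ranks are strictly monotone on both chromosomes -- increasing/increasing
#' for parallel blocks, increasing/decreasing for antiparallel (inverted)
#' blocks -- with consecutive rank gaps at most \code{max_gap} on both sides.
#' Chains are extracted greedily by length (ties by earliest anchor), each
#' anchor joining at most one block; chains shorter than
#' \code{min_block_size} are discarded. Anchor genes of the retained blocks
#' are the segmental-duplication candidates.
#'
#' @param positions ranked position table from [assign_ranks()].
#' @param hits homology hit data.frame with columns \code{query},
#'   \code{subject}, \code{evalue}, \code{bitscore}.
#' @param min_block_size minimum anchors per block; default 5.
#' @param max_gap maximum rank gap between consecutive anchors, per side;
#'   default 25.
#' @param evalue_max hit filter ceiling; default 1e-5.
#' @return data.frame with one row per anchor: \code{block_id},
#'   \code{chrom_a}, \code{chrom_b}, \code{gene_a}, \code{gene_b},
#'   \code{rank_a}, \code{rank_b}, \code{orientation}, \code{size}.
#' @export
detect_collinear_blocks <- function(positions, hits, min_block_size = 5,
                                    max_gap = 25, evalue_max = 1e-5) {
  if (!"rank" %in% names(positions)) positions <- assign_ranks(positions)
  chrom <- stats::setNames(positions$chrom, positions$gene)
  rank <- stats::setNames(positions$rank, positions$gene)
  pairs <- homolog_pairs(hits, evalue_max)
  unknown <- setdiff(c(pairs), positions$gene)
  if (length(unknown) > 0) {
    stop(sprintf("hit references unknown gene '%s'", unknown[1]))
  }
  if (nrow(pairs) == 0) return(empty_blocks())

  # orient each pair so chrom_a <= chrom_b (rank_a breaks same-chromosome ties)
  ca <- chrom[pairs[, 1]]; cb <- chrom[pairs[, 2]]
  flip <- ca > cb | (ca == cb & rank[pairs[, 1]] > rank[pairs[, 2]])
  ga <- ifelse(flip, pairs[, 2], pairs[, 1])
  gb <- ifelse(flip, pairs[, 1], pairs[, 2])
  anchors <- data.frame(gene_a = ga, gene_b = gb,
                        chrom_a = chrom[ga], chrom_b = chrom[gb],
                        rank_a = rank[ga], rank_b = rank[gb],
                        stringsAsFactors = FALSE)
  out <- list()
  block_id <- 0L
  for (key in unique(paste(anchors$chrom_a, anchors$chrom_b))) {
    sub <- anchors[paste(anchors$chrom_a, anchors$chrom_b) == key, , drop = FALSE]
    repeat {
      chain <- best_chain(sub, max_gap)
      if (is.null(chain) || nrow(chain$rows) < min_block_size) break
      block_id <- block_id + 1L
      rows <- chain$rows
      rows$block_id <- block_id
      rows$orientation <- chain$orientation
      rows$size <- nrow(rows)
      out[[block_id]] <- rows
      used <- paste(rows$gene_a, rows$gene_b)
      sub <- sub[!paste(sub$gene_a, sub$gene_b) %in% used, , drop = FALSE]
      if (nrow(sub) == 0) break
    }
  }
  if (length(out) == 0) return(empty_blocks())
  res <- do.call(rbind, out)
  res <- res[, c("block_id", "chrom_a", "chrom_b", "gene_a", "gene_b",
                 "rank_a", "rank_b", "orientation", "size")]
  rownames(res) <- NULL
  res
}

empty_blocks <- function() {
  data.frame(block_id = integer(), chrom_a = character(), chrom_b = character(),
             gene_a = character(), gene_b = character(), rank_a = integer(),
             rank_b = integer(), orientation = character(), size = integer(),
             stringsAsFactors = FALSE)
}

## Longest monotone chain of anchors under the gap constraint, over both
## orientations; O(m^2) DP, adequate at the scales this package targets.
## Returns list(rows, orientation) for the single best chain, or NULL.
best_chain <- function(anchors, max_gap) {
  m <- nrow(anchors)
  if (m == 0) return(NULL)
  o <- order(anchors$rank_a, anchors$rank_b)
  a <- anchors[o, , drop = FALSE]
  best <- NULL
  for (orientation in c("parallel", "antiparallel")) {
    len <- rep(1L, m); prev <- rep(NA_integer_, m)
    for (j in seq_len(m)) {
      for (i in seq_len(j - 1L)) {
        gap_a <- a$rank_a[j] - a$rank_a[i]
        if (gap_a < 1L || gap_a > max_gap) next
        gap_b <- if (orientation == "parallel") a$rank_b[j] - a$rank_b[i]
                 else a$rank_b[i] - a$rank_b[j]
        if (gap_b < 1L || gap_b > max_gap) next
        if (len[i] + 1L > len[j]) {
          len[j] <- len[i] + 1L
          prev[j] <- i
        }
      }
    }
    end <- which.max(len)  # ties: earliest terminal anchor
    chain <- end
    while (!is.na(prev[chain[1]])) chain <- c(prev[chain[1]], chain)
    cand <- list(rows = a[chain, , drop = FALSE], orientation = orientation)
    if (is.null(best) || nrow(cand$rows) > nrow(best$rows)) best <- cand
  }
  best
}

#' Classify gene duplication modes
#'
#' Reproduces the MCScanX-style rule set. Every gene starts as a singleton;
#' genes with at least one (filtered, non-self) homology hit become
#' dispersed; a homologous pair on the same chromosome with rank difference
#' exactly 1 is tandem, and with rank difference below \code{proximal_window}
#' (strictly) is proximal; anchor genes of collinear blocks are
#' WGD/segmental. When a gene qualifies for several classes the highest
#' priority wins: segmental > tandem > proximal > dispersed.
#'
#' @param positions position table (ranked or not; see [assign_ranks()]).
#' @param hits homology hits (\code{query}, \code{subject}, \code{evalue},
#'   \code{bitscore}).
#' @param blocks optional precomputed [detect_collinear_blocks()] output;
#'   computed from \code{positions}/\code{hits} if missing.
#' @param proximal_window strict upper bound on the rank difference for
#'   proximal pairs; default 20.
#' @param evalue_max e-value ceiling for hits; default 1e-5.
#' @param ... passed to [detect_collinear_blocks()] when \code{blocks} is
#'   not supplied.
#' @return object of class \code{"duplication_assignment"}: data.frame with
#'   columns \code{gene}, \code{class}, \code{partner} (one supporting
#'   partner, NA for singletons), \code{block_id} (segmental genes only);
#'   attribute \code{blocks}.
#' @export
classify_duplications <- function(positions, hits, blocks = NULL,
                                  proximal_window = 20, evalue_max = 1e-5, ...) {
  positions <- if ("rank" %in% names(positions)) positions else assign_ranks(positions)
  genes <- positions$gene
  unknown <- setdiff(unique(c(hits$query, hits$subject)), genes)
  if (length(unknown) > 0) stop(sprintf("hit references unknown gene '%s'", unknown[1]))
  if (is.null(blocks)) {
    blocks <- detect_collinear_blocks(positions, hits, evalue_max = evalue_max, ...)
  }
  chrom <- stats::setNames(positions$chrom, genes)
  rank <- stats::setNames(positions$rank, genes)
  pairs <- homolog_pairs(hits, evalue_max)

  cls <- stats::setNames(rep("singleton", length(genes)), genes)
  partner <- stats::setNames(rep(NA_character_, length(genes)), genes)
  block_of <- stats::setNames(rep(NA_integer_, length(genes)), genes)

  set_if_higher <- function(g, new, p, prio) {
    if (prio[[new]] > prio[[cls[[g]]]]) {
      cls[g] <<- new
      partner[g] <<- p
    }
  }
  prio <- c(singleton = 0, dispersed = 1, proximal = 2, tandem = 3, segmental = 4)

  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      set_if_higher(a, "dispersed", b, prio)
      set_if_higher(b, "dispersed", a, prio)
      if (chrom[[a]] == chrom[[b]]) {
        dr <- abs(rank[[a]] - rank[[b]])
        if (dr == 1) {
          set_if_higher(a, "tandem", b, prio)
          set_if_higher(b, "tandem", a, prio)
        } else if (dr < proximal_window) {
          set_if_higher(a, "proximal", b, prio)
          set_if_higher(b, "proximal", a, prio)
        }
      }
    }
  }
  if (nrow(blocks) > 0) {
    for (i in seq_len(nrow(blocks))) {
      a <- blocks$gene_a[i]; b <- blocks$gene_b[i]
      set_if_higher(a, "segmental", b, prio)
      set_if_higher(b, "segmental", a, prio)
      block_of[a] <- blocks$block_id[i]
      block_of[b] <- blocks$block_id[i]
    }
  }
  out <- data.frame(gene = genes, class = unname(cls[genes]),
                    partner = unname(partner[genes]),
                    block_id = unname(block_of[genes]),
                    stringsAsFactors = FALSE)
  out$block_id[out$class != "segmental"] <- NA_integer_
  attr(out, "blocks") <- blocks
  class(out) <- c("duplication_assignment", "data.frame")
  out
}

#' @export
print.duplication_assignment <- function(x, ...) {
  cat("Duplication mode assignment\n")
  print(table(factor(x$class, levels = c("singleton", "dispersed", "proximal",
                                         "tandem", "segmental"))))
  invisible(x)
}

#' @export
summary.duplication_assignment <- function(object, ...) {
  tab <- table(factor(object$class,
                      levels = c("singleton", "dispersed", "proximal",
                                 "tandem", "segmental")))
  blocks <- attr(object, "blocks")
  list(class_counts = tab,
       n_blocks = if (nrow(blocks) > 0) length(unique(blocks$block_id)) else 0L)
}

#' Tandem and proximal duplicate groups
#'
#' Connected components of the tandem (and, separately, proximal) pair
#' relations among genes carrying that class.
#'
#' @param assignment a [classify_duplications()] result.
#' @param positions ranked position table.
#' @param hits homology hits.
#' @param evalue_max e-value ceiling; default 1e-5.
#' @return data.frame with columns \code{group_id}, \code{kind}
#'   (tandem/proximal), \code{gene}.
#' @export
tandem_proximal_groups <- function(assignment, positions, hits, evalue_max = 1e-5) {
  positions <- if ("rank" %in% names(positions)) positions else assign_ranks(positions)
  chrom <- stats::setNames(positions$chrom, positions$gene)
  rank <- stats::setNames(positions$rank, positions$gene)
  pairs <- homolog_pairs(hits, evalue_max)
  out <- list()
  gid <- 0L
  for (kind in c("tandem", "proximal")) {
    members <- assignment$gene[assignment$class == kind]
    if (length(members) == 0) next
    keep <- pairs[, 1] %in% members & pairs[, 2] %in% members &
      chrom[pairs[, 1]] == chrom[pairs[, 2]]
    sub <- pairs[keep, , drop = FALSE]
    # union-find over the pair relation
    parent <- stats::setNames(members, members)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    if (nrow(sub) > 0) {
      for (i in seq_len(nrow(sub))) {
        ra <- find(sub[i, 1]); rb <- find(sub[i, 2])
        if (ra != rb) parent[ra] <- rb
      }
    }
    roots <- vapply(members, find, "")
    for (r in unique(roots)) {
      grp <- sort(members[roots == r])
      if (length(grp) < 2) next
      gid <- gid + 1L
      out[[gid]] <- data.frame(group_id = gid, kind = kind, gene = grp,
                               stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(group_id = integer(), kind = character(),
                      gene = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Reciprocal best hits between two gene sets
#'
#' A pair (a, b) is reported when b is a's best hit in the A-to-B table and a
#' is b's best hit in the B-to-A table. Best = lowest e-value, ties broken by
#' highest bitscore then ascending subject id.
#'
#' @param hits_ab,hits_ba directed hit tables (\code{query}, \code{subject},
#'   \code{evalue}, \code{bitscore}).
#' @return data.frame with columns \code{gene_a}, \code{gene_b}.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  best_of <- function(h) {
    h <- h[h$query != h$subject, , drop = FALSE]
    if (nrow(h) == 0) return(stats::setNames(character(0), character(0)))
    o <- order(h$query, h$evalue, -h$bitscore, h$subject)
    h <- h[o, , drop = FALSE]
    h <- h[!duplicated(h$query), , drop = FALSE]
    stats::setNames(h$subject, h$query)
  }
  ba <- best_of(hits_ab)
  bb <- best_of(hits_ba)
  a <- names(ba)
  mutual <- a[!is.na(bb[ba[a]]) & bb[ba[a]] == a]
  data.frame(gene_a = sort(mutual),
             gene_b = unname(ba[sort(mutual)]),
             stringsAsFactors = FALSE)
}
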