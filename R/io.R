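## Readers and writers for every external format the pipeline touches.
## Convention: TSV with optional '#'-prefixed metadata header lines; BED
## coordinates 0-based half-open; all user-facing promoter positions are
## 1-based TSS distances. Readers reject malformed input with line numbers.

meta_header <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("mrgcn"))
  h <- sprintf("# mrgcn %s", v)
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %s", seed))
  h
}

#' Write / read an expression matrix as TSV
#'
#' Header row carries condition ids; the first column ("gene") carries gene
#' ids. Reading validates shape and content and reports the offending line on
#' error; write-then-read round-trips values and orderings.
#'
#' @param x genes x conditions numeric matrix with dimnames.
#' @param path file path.
#' @return \code{read_expression} returns the matrix.
#' @export
write_expression <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(c("gene", colnames(x)), collapse = "\t"),
               vapply(seq_len(nrow(x)), function(i) {
                 paste(c(rownames(x)[i], format(x[i, ], digits = 10, trim = TRUE,
                                                scientific = FALSE)),
                       collapse = "\t")
               }, "")), con)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2) stop(sprintf("%s: empty expression table", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol_exp <- length(header)
  conditions <- header[-1]
  genes <- character(length(fields) - 1L)
  vals <- matrix(NA_real_, length(fields) - 1L, ncol_exp - 1L)
  for (i in 2:length(fields)) {
    f <- fields[[i]]
    if (length(f) != ncol_exp) {
      stop(sprintf("%s line %d: expected %d fields, found %d",
                   path, lineno[i], ncol_exp, length(f)))
    }
    genes[i - 1L] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop(sprintf("%s line %d: non-numeric expression value",
                               path, lineno[i]))
    vals[i - 1L, ] <- v
  }
  dup <- which(duplicated(genes))
  if (length(dup) > 0) {
    stop(sprintf("%s line %d: duplicate gene id '%s'",
                 path, lineno[dup[1] + 1L], genes[dup[1]]))
  }
  dimnames(vals) <- list(genes, conditions)
  vals
}

#' Write / read promoter sequences as FASTA
#'
#' One record per gene, sequence written 5' to 3' ending at the TSS. Reading
#' uppercases sequences, uses the record id up to the first whitespace as the
#' gene id, and enforces the uniform-length contract: records whose length
#' differs from the modal length are excluded with a warning.
#'
#' @param promoters named character vector of sequences.
#' @param path file path.
#' @return \code{read_promoters} returns a named character vector with
#'   attribute \code{"L"} (the common length).
#' @export
write_promoters <- function(promoters, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(promoters), path)
  invisible(path)
}

#' @rdname write_promoters
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicate record id '%s'", path, ids[duplicated(ids)][1]))
  }
  seqs <- toupper(stats::setNames(as.character(ss), ids))
  lens <- nchar(seqs)
  L <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  off <- lens != L
  if (any(off)) {
    warning(sprintf("%d record(s) not of length %d excluded: %s",
                    sum(off), L, paste(utils::head(ids[off], 3), collapse = ", ")))
    seqs <- seqs[!off]
  }
  attr(seqs, "L") <- L
  seqs
}

#' Write / read gene positions (BED-like)
#'
#' Columns: chrom, start, end, gene id, score placeholder, strand; 0-based
#' half-open coordinates, no header.
#'
#' @param positions data.frame with columns chrom, start, end, gene and
#'   optionally strand.
#' @param path file path.
#' @return \code{read_bed} returns the positions data.frame.
#' @export
write_bed <- function(positions, path) {
  strand <- if ("strand" %in% names(positions)) positions$strand else "+"
  utils::write.table(
    data.frame(positions$chrom, positions$start, positions$end,
               positions$gene, 0L, strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) stop(sprintf("%s: empty BED file", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4)) {
    stop(sprintf("%s line %d: BED needs at least 4 columns", path, which(nf < 4)[1]))
  }
  out <- data.frame(
    chrom = vapply(fields, `[`, "", 1),
    start = suppressWarnings(as.integer(vapply(fields, `[`, "", 2))),
    end = suppressWarnings(as.integer(vapply(fields, `[`, "", 3))),
    gene = vapply(fields, `[`, "", 4),
    strand = vapply(fields, function(f) if (length(f) >= 6) f[6] else "+", ""),
    stringsAsFactors = FALSE)
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad) > 0) stop(sprintf("%s line %d: non-integer coordinate", path, bad[1]))
  if (anyDuplicated(out$gene)) {
    stop(sprintf("%s: duplicate gene id '%s'", path, out$gene[duplicated(out$gene)][1]))
  }
  out
}

BLAST6_COLS <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Write / read homology hits (BLAST tabular, outfmt 6)
#'
#' Twelve columns, no header: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore. Self-hits are dropped on read.
#'
#' @param hits data.frame with the 12 outfmt-6 columns.
#' @param path file path.
#' @return \code{read_blast_hits} returns the hit data.frame.
#' @export
write_blast_hits <- function(hits, path) {
  utils::write.table(hits[, BLAST6_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_blast_hits
#' @export
read_blast_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad) > 0) {
    stop(sprintf("%s line %d: expected 12 tab-separated columns", path, bad[1]))
  }
  if (length(fields) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12), BLAST6_COLS),
                         stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, fields)
    out <- data.frame(m, stringsAsFactors = FALSE)
    names(out) <- BLAST6_COLS
  }
  num <- c("pident", "evalue", "bitscore")
  int <- c("length", "mismatch", "gapopen", "qstart", "qend", "sstart", "send")
  out[num] <- lapply(out[num], as.numeric)
  out[int] <- lapply(out[int], as.integer)
  if (anyNA(out$evalue)) stop(sprintf("%s: non-numeric e-value", path))
  out[out$query != out$subject, , drop = FALSE]
}

#' Write / read gene annotation (gene, category TSV)
#'
#' @param annotation data.frame with columns gene, category.
#' @param path file path.
#' @return \code{read_annotation} returns the annotation data.frame.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation[, c("gene", "category")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) < 1) stop(sprintf("%s: empty annotation table", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  has_header <- identical(fields[[1]][1:2], c("gene", "category"))
  rows <- fields[(1 + has_header):length(fields)]
  bad <- which(lengths(rows) != 2L)
  if (length(bad) > 0) {
    stop(sprintf("%s line %d: expected 2 columns", path, bad[1] + has_header))
  }
  data.frame(gene = vapply(rows, `[`, "", 1),
             category = vapply(rows, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Write a motif list (id, iupac TSV)
#' @param motifs data.frame with columns id, iupac.
#' @param path file path.
#' @return \code{read_motifs} returns the motif data.frame.
#' @export
write_motifs <- function(motifs, path) {
  utils::write.table(motifs[, c("id", "iupac")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_motifs
#' @export
read_motifs <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "iupac") %in% names(out))) {
    stop(sprintf("%s: motif table needs columns 'id' and 'iupac'", path))
  }
  out$iupac <- vapply(out$iupac, validate_motif, "")
  out
}

write_tsv_with_meta <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(seed), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE,
                                      append = TRUE))
  invisible(path)
}

#' Run the whole pipeline on one set of inputs
#'
#' Chains the stages: (optional) synthetic-data generation, mutual-rank
#' network construction and top-k cluster extraction for the requested guide
#' genes, promoter motif scanning with position-bias ranking, functional and
#' CRE enrichment of every guide cluster, and duplication classification.
#' Every output TSV carries '#' metadata header lines (tool version, seed).
#'
#' @param expression path to an expression TSV, or a matrix.
#' @param guides guide gene ids, or \code{"all"}.
#' @param promoters path to a promoter FASTA, or a named character vector.
#' @param motifs path to a motif TSV, or a data.frame (id, iupac).
#' @param annotation path to an annotation TSV, or a data.frame.
#' @param positions path to a BED file, or a data.frame.
#' @param hits path to a BLAST outfmt-6 file, or a data.frame.
#' @param outdir output directory (created if needed).
#' @param k cluster size; default 100.
#' @param fdr_categories,fdr_cres significance thresholds (defaults 0.05 and
#'   0.01).
#' @param strand_mode promoter scan mode, "forward" or "both".
#' @param central central position statistic, "median" or "mean".
#' @param min_block_size,max_gap,evalue_max duplication parameters.
#' @param seed recorded in output headers (the pipeline itself is
#'   deterministic given its inputs).
#' @return (invisibly) a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(expression, guides = "all", promoters = NULL,
                         motifs = NULL, annotation = NULL, positions = NULL,
                         hits = NULL, outdir, k = 100, fdr_categories = 0.05,
                         fdr_cres = 0.01, strand_mode = "forward",
                         central = "median", min_block_size = 5, max_gap = 25,
                         evalue_max = 1e-5, seed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  x <- if (is.character(expression)) read_expression(expression) else expression
  net <- mr_network(x)
  res$network <- net
  guide_set <- if (identical(guides, "all")) net$gene_ids[net$usable] else guides
  res$clusters <- lapply(guide_set, function(g) top_k_cluster(net, g, k))
  names(res$clusters) <- guide_set
  cluster_tab <- do.call(rbind, lapply(guide_set, function(g) {
    cbind(guide = g, as.data.frame(res$clusters[[g]]))
  }))
  write_tsv_with_meta(cluster_tab, file.path(outdir, "clusters.tsv"), seed)
  write_tsv_with_meta(mr_edge_list(net, max_mr = 100),
                      file.path(outdir, "edges.tsv"), seed)

  if (!is.null(promoters) && !is.null(motifs)) {
    prom <- if (is.character(promoters) && length(promoters) == 1 &&
                file.exists(promoters)) read_promoters(promoters) else promoters
    mot <- if (is.character(motifs)) read_motifs(motifs) else motifs
    L <- attr(prom, "L") %||% nchar(prom[[1]])
    hits_tab <- scan_motif_set(prom, mot, strand_mode)
    res$motif_hits <- hits_tab
    res$cre_ranking <- summarize_motif_set(hits_tab, mot, L, central)
    res$presence <- presence_matrix(hits_tab, names(prom), mot$id)
    write_tsv_with_meta(hits_tab, file.path(outdir, "motif_hits.tsv"), seed)
    write_tsv_with_meta(as.data.frame(res$cre_ranking),
                        file.path(outdir, "cre_ranking.tsv"), seed)
    pres_df <- data.frame(gene = rownames(res$presence),
                          res$presence, check.names = FALSE)
    write_tsv_with_meta(pres_df, file.path(outdir, "cre_presence.tsv"), seed)
  }

  universe <- net$gene_ids
  if (!is.null(annotation)) {
    annot <- if (is.character(annotation)) read_annotation(annotation) else annotation
    res$category_enrichment <- lapply(res$clusters, enrich_categories,
                                      annotation = annot, universe = universe,
                                      fdr_threshold = fdr_categories)
    tab <- do.call(rbind, lapply(names(res$category_enrichment), function(g) {
      r <- res$category_enrichment[[g]]
      if (nrow(r) == 0) NULL else cbind(cluster = g, r)
    }))
    if (!is.null(tab)) {
      write_tsv_with_meta(tab, file.path(outdir, "category_enrichment.tsv"), seed)
    }
  }
  if (!is.null(res$presence)) {
    res$cre_enrichment <- lapply(res$clusters, enrich_cres,
                                 presence = res$presence, universe = universe,
                                 fdr_threshold = fdr_cres)
    tab <- do.call(rbind, lapply(names(res$cre_enrichment), function(g) {
      r <- res$cre_enrichment[[g]]
      if (nrow(r) == 0) NULL else cbind(cluster = g, r)
    }))
    if (!is.null(tab)) {
      write_tsv_with_meta(tab, file.path(outdir, "cre_enrichment.tsv"), seed)
    }
  }

  if (!is.null(positions) && !is.null(hits)) {
    pos <- if (is.character(positions)) read_bed(positions) else positions
    ht <- if (is.character(hits)) read_blast_hits(hits) else hits
    ranked <- assign_ranks(pos)
    blocks <- detect_collinear_blocks(ranked, ht, min_block_size, max_gap,
                                      evalue_max)
    assign <- classify_duplications(ranked, ht, blocks,
                                    evalue_max = evalue_max)
    res$blocks <- blocks
    res$duplication <- assign
    res$groups <- tandem_proximal_groups(assign, ranked, ht, evalue_max)
    write_tsv_with_meta(as.data.frame(assign),
                        file.path(outdir, "duplication.tsv"), seed)
    write_tsv_with_meta(blocks, file.path(outdir, "blocks.tsv"), seed)
    write_tsv_with_meta(res$groups, file.path(outdir, "duplicate_groups.tsv"), seed)
  }
  invisible(res)
}
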