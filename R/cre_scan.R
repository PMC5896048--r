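## IUPAC degeneracy table. N deliberately expands to ACGT only: an N in a
## promoter sequence (unknown base) never satisfies a match.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N")

#' Does a base satisfy an IUPAC code?
#'
#' @param code single IUPAC symbol (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @param base single concrete base in A,C,G,T.
#' @return logical.
#' @export
iupac_match <- function(code, base) {
  code <- toupper(code)
  base <- toupper(base)
  if (!code %in% names(IUPAC_SETS)) stop(sprintf("unknown IUPAC symbol '%s'", code))
  if (!base %in% c("A", "C", "G", "T")) stop(sprintf("'%s' is not a concrete base", base))
  base %in% IUPAC_SETS[[code]]
}

## Number of concrete bases an IUPAC symbol admits (match degeneracy).
iupac_degeneracy <- function(code) {
  vapply(strsplit(toupper(code), "")[[1]], function(s) {
    if (!s %in% names(IUPAC_SETS)) stop(sprintf("unknown IUPAC symbol '%s'", s))
    length(IUPAC_SETS[[s]])
  }, 1L)
}

validate_motif <- function(iupac) {
  iupac <- toupper(iupac)
  syms <- strsplit(iupac, "")[[1]]
  bad <- setdiff(syms, names(IUPAC_SETS))
  if (length(bad) > 0) stop(sprintf("invalid IUPAC symbol(s): %s", paste(bad, collapse = ",")))
  iupac
}

#' Reverse complement of an IUPAC string
#' @param iupac motif string.
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(iupac) {
  syms <- strsplit(validate_motif(iupac), "")[[1]]
  paste(rev(unname(IUPAC_COMPLEMENT[syms])), collapse = "")
}

iupac_regex <- function(iupac) {
  syms <- strsplit(validate_motif(iupac), "")[[1]]
  paste(vapply(syms, function(s) {
    set <- IUPAC_SETS[[s]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, ""), collapse = "")
}

## All (overlapping) match start positions of an IUPAC motif on a concrete
## sequence, via a zero-width lookahead so overlapping windows all count.
match_starts <- function(seq, iupac) {
  m <- gregexpr(paste0("(?=", iupac_regex(iupac), ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Scan promoters for an IUPAC motif
#'
#' Every window position is tested independently, so overlapping matches all
#' count. Match positions are reported as 1-based TSS distances: sequences
#' are written 5' to 3' with the last base adjacent to the transcription
#' start site, and the distance is measured from the TSS to the motif's
#' TSS-proximal (3'-most) base, so distance 1 means the motif abuts the TSS.
#' In \code{"both"} mode, a reverse-complement match is reported at the
#' coordinates of the forward-strand window it occupies. An N in a sequence
#' matches nothing.
#'
#' @param promoters named character vector of promoter sequences (alphabet
#'   A,C,G,T,N), or a \code{Biostrings::DNAStringSet}.
#' @param motif IUPAC string (or a single-row data.frame with columns
#'   \code{id}, \code{iupac}).
#' @param strand_mode \code{"forward"} (default) or \code{"both"}.
#' @param motif_id label used in the output; defaults to the motif string.
#' @return data.frame with columns \code{gene}, \code{motif},
#'   \code{tss_distance}, \code{strand}.
#' @export
scan_promoters <- function(promoters, motif, strand_mode = c("forward", "both"),
                           motif_id = NULL) {
  strand_mode <- match.arg(strand_mode)
  if (inherits(promoters, "DNAStringSet")) {
    promoters <- stats::setNames(as.character(promoters), names(promoters))
  }
  if (is.null(names(promoters)) || anyDuplicated(names(promoters))) {
    stop("promoters must be uniquely named by gene id")
  }
  if (is.data.frame(motif)) {
    motif_id <- motif$id[1]
    motif <- motif$iupac[1]
  }
  motif <- validate_motif(motif)
  if (is.null(motif_id)) motif_id <- motif
  seqs <- toupper(promoters)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop(sprintf("sequence '%s' contains characters outside {A,C,G,T,N}",
                 names(seqs)[bad][1]))
  }
  l <- nchar(motif)
  hits <- lapply(names(seqs), function(g) {
    s <- seqs[[g]]
    L <- nchar(s)
    if (L < l) return(NULL)
    fw <- match_starts(s, motif)
    strand <- rep("forward", length(fw))
    starts <- fw
    if (strand_mode == "both") {
      rv <- match_starts(s, reverse_complement(motif))
      starts <- c(starts, rv)
      strand <- c(strand, rep("reverse", length(rv)))
    }
    if (length(starts) == 0) return(NULL)
    # window [start, start + l - 1]; TSS-proximal base is the window end
    d <- L - (starts + l - 1L) + 1L
    o <- order(d, strand)
    data.frame(gene = g, motif = motif_id, tss_distance = d[o],
               strand = strand[o], stringsAsFactors = FALSE)
  })
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (length(hits) == 0) {
    return(data.frame(gene = character(), motif = character(),
                      tss_distance = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Scan promoters for a set of motifs
#'
#' @param promoters as in [scan_promoters()].
#' @param motifs data.frame with columns \code{id}, \code{iupac}.
#' @inheritParams scan_promoters
#' @return row-bound hit table over all motifs.
#' @export
scan_motif_set <- function(promoters, motifs, strand_mode = c("forward", "both")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(is.data.frame(motifs), all(c("id", "iupac") %in% names(motifs)))
  do.call(rbind, lapply(seq_len(nrow(motifs)), function(i) {
    scan_promoters(promoters, motifs$iupac[i], strand_mode, motif_id = motifs$id[i])
  }))
}

#' Gene x motif presence matrix
#'
#' Marks, per gene and motif, whether at least one hit occurs in its
#' promoter; the input to [enrich_cres()].
#'
#' @param hits hit table from [scan_motif_set()].
#' @param genes all promoter gene ids (rows; genes without hits get FALSE).
#' @param motifs all motif ids (columns).
#' @return logical matrix, genes x motifs.
#' @export
presence_matrix <- function(hits, genes, motifs) {
  m <- matrix(FALSE, length(genes), length(motifs),
              dimnames = list(genes, motifs))
  if (nrow(hits) > 0) {
    keep <- hits$gene %in% genes & hits$motif %in% motifs
    m[cbind(hits$gene[keep], hits$motif[keep])] <- TRUE
  }
  m
}

#' Position-bias Z-score for a promoter motif
#'
#' Measures how far the central hit position of a motif sits from the middle
#' of the promoter, in standard errors, under the null that hit positions are
#' uniform on \code{1..(L - l + 1)}. The default \code{"corrected"} variant
#' is the standard Z statistic for the mean of n draws from that discrete
#' uniform:
#' \deqn{Z = \frac{L/2 - p}{\sqrt{((L - l + 1)^2 - 1) / (12 n)}},}
#' positive when hits crowd towards the TSS (small p). The \code{"printed"}
#' variant, \code{(L/2 + p) / sqrt(((L - l + 1)^2 - 1)/n)}, is retained for
#' comparability with literature that reports it; note its sign grows with
#' TSS-distal positions and its variance term omits the uniform-distribution
#' divisor 12.
#'
#' @param L promoter length in bases.
#' @param l motif length in bases.
#' @param n total number of hits across all promoters (>= 1).
#' @param p central hit position as a TSS distance, in [1, L - l + 1].
#' @param variant \code{"corrected"} (default) or \code{"printed"}.
#' @return Z-score (numeric scalar).
#' @export
position_z <- function(L, l, n, p, variant = c("corrected", "printed")) {
  variant <- match.arg(variant)
  if (n < 1) stop("Z-score undefined for n = 0")
  if (p < 1 || p > L - l + 1) stop("central position outside [1, L - l + 1]")
  span2 <- (L - l + 1)^2 - 1
  switch(variant,
         corrected = (L / 2 - p) / sqrt(span2 / (12 * n)),
         printed   = (L / 2 + p) / sqrt(span2 / n))
}

#' Summarise motif hits into position-bias statistics
#'
#' @param hits hit table for one motif ([scan_promoters()]).
#' @param L promoter length.
#' @param l motif length.
#' @param central central statistic for the position, \code{"median"}
#'   (default; even counts average the middle two) or \code{"mean"}. Both are
#'   always reported; \code{central} selects which feeds the Z-scores.
#' @return one-row data.frame: \code{motif}, \code{n},
#'   \code{promoters_with_hit}, \code{p_median}, \code{p_mean}, \code{p}
#'   (the selected central statistic), \code{z_printed}, \code{z_corrected}.
#'   For n = 0 the position and Z fields are NA.
#' @export
summarize_hits <- function(hits, L, l, central = c("median", "mean")) {
  central <- match.arg(central)
  motif_id <- if (nrow(hits) > 0) hits$motif[1] else NA_character_
  n <- nrow(hits)
  if (n == 0) {
    return(data.frame(motif = motif_id, n = 0L, promoters_with_hit = 0L,
                      p_median = NA_real_, p_mean = NA_real_, p = NA_real_,
                      z_printed = NA_real_, z_corrected = NA_real_,
                      stringsAsFactors = FALSE))
  }
  p_med <- stats::median(hits$tss_distance)
  p_mean <- mean(hits$tss_distance)
  p <- if (central == "median") p_med else p_mean
  data.frame(motif = motif_id, n = n,
             promoters_with_hit = length(unique(hits$gene)),
             p_median = p_med, p_mean = p_mean, p = p,
             z_printed = position_z(L, l, n, p, "printed"),
             z_corrected = position_z(L, l, n, p, "corrected"),
             stringsAsFactors = FALSE)
}

#' Summarise and rank a motif set by position bias
#'
#' @param hits hit table from [scan_motif_set()].
#' @param motifs data.frame with columns \code{id}, \code{iupac}.
#' @param L promoter length.
#' @inheritParams summarize_hits
#' @return data.frame of per-motif summaries (class \code{"cre_ranking"}),
#'   one row per motif, ranked by [rank_cres()].
#' @export
summarize_motif_set <- function(hits, motifs, L, central = c("median", "mean")) {
  central <- match.arg(central)
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    h <- hits[hits$motif == motifs$id[i], , drop = FALSE]
    s <- summarize_hits(h, L, nchar(motifs$iupac[i]), central)
    s$motif <- motifs$id[i]
    s
  })
  rank_cres(do.call(rbind, rows))
}

#' Rank motifs by position-bias Z-score
#'
#' Descending by the selected Z variant (motifs without hits sort last),
#' ties broken by descending hit count then ascending motif id.
#'
#' @param summaries data.frame of [summarize_hits()] rows.
#' @param variant which Z column ranks: \code{"corrected"} or \code{"printed"}.
#' @return the summaries with a \code{rank} column, sorted.
#' @export
rank_cres <- function(summaries, variant = c("corrected", "printed")) {
  variant <- match.arg(variant)
  if (nrow(summaries) == 0 || all(summaries$n == 0)) {
    if (nrow(summaries) > 0 && all(summaries$n == 0)) {
      summaries$rank <- seq_len(nrow(summaries))
      return(summaries)
    }
    stop("need at least one summary with n >= 1")
  }
  z <- summaries[[paste0("z_", variant)]]
  z[is.na(z)] <- -Inf
  o <- order(-z, -summaries$n, summaries$motif)
  out <- summaries[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("cre_ranking", "data.frame")
  out
}

#' @export
print.cre_ranking <- function(x, ...) {
  cat(sprintf("Position-bias ranking of %d motif(s)\n", nrow(x)))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) round(v, 3))
  print.data.frame(utils::head(df, 15))
  if (nrow(df) > 15) cat(sprintf("... %d more\n", nrow(df) - 15))
  invisible(x)
}
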