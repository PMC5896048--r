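# Independent brute-force oracles. Each re-derives a quantity from first
# principles by a different route than the implementation under test.

# Mutual ranks by explicit per-gene sorting of a correlation matrix:
# rank of b among a's correlators (descending r, ties by ascending id),
# MR = sqrt(rank(a->b) * rank(b->a)).
oracle_mutual_rank <- function(r) {
  ids <- rownames(r)
  g <- length(ids)
  rk <- matrix(NA_real_, g, g, dimnames = dimnames(r))
  for (a in seq_len(g)) {
    others <- setdiff(seq_len(g), a)
    ord <- others[order(-r[a, others], ids[others])]
    for (pos in seq_along(ord)) rk[a, ord[pos]] <- pos
  }
  mr <- matrix(NA_real_, g, g, dimnames = dimnames(r))
  for (a in seq_len(g)) for (b in seq_len(g)) {
    if (a != b) mr[a, b] <- sqrt(rk[a, b] * rk[b, a])
  }
  mr
}

# Upper-tail hypergeometric p by direct summation of the pmf via
# binomial coefficients on the log scale.
oracle_hyper_upper <- function(k, n, K, N) {
  xs <- k:min(n, K)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# BH step-up by the textbook definition (no p.adjust).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Naive window scanner: test every window position with iupac_match,
# per base. Returns sorted TSS distances of forward-strand matches.
oracle_scan_distances <- function(seq, motif) {
  seq <- toupper(seq)
  motif <- toupper(motif)
  L <- nchar(seq)
  l <- nchar(motif)
  if (L < l) return(integer(0))
  mchars <- strsplit(motif, "")[[1]]
  schars <- strsplit(seq, "")[[1]]
  hits <- integer(0)
  for (s in 1:(L - l + 1)) {
    ok <- TRUE
    for (j in 1:l) {
      base <- schars[s + j - 1]
      if (base == "N" || !iupac_match(mchars[j], base)) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, L - (s + l - 1L) + 1L)
  }
  sort(hits)
}

# Random IUPAC motif (biased towards concrete bases so matches stay rare
# but degenerate codes are exercised).
random_iupac <- function(l) {
  syms <- c(rep(c("A", "C", "G", "T"), 4), "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")
  paste(sample(syms, l, replace = TRUE), collapse = "")
}

random_dna <- function(L, with_n = FALSE) {
  alph <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alph, L, replace = TRUE), collapse = "")
}

# Random expression-like matrix with gene/condition names.
random_expr <- function(g, nc) {
  m <- matrix(stats::rexp(g * nc, rate = 0.2), g, nc,
              dimnames = list(sprintf("g%03d", seq_len(g)),
                              sprintf("c%02d", seq_len(nc))))
  m
}

# Brute-force reciprocal best hits by double scan.
oracle_rbh <- function(hits_ab, hits_ba) {
  best <- function(h, q) {
    hh <- h[h$query == q & h$subject != q, , drop = FALSE]
    if (nrow(hh) == 0) return(NA_character_)
    hh <- hh[order(hh$evalue, -hh$bitscore, hh$subject), , drop = FALSE]
    hh$subject[1]
  }
  out <- list()
  for (q in sort(unique(hits_ab$query))) {
    b <- best(hits_ab, q)
    if (!is.na(b) && identical(best(hits_ba, b), q)) {
      out[[length(out) + 1]] <- data.frame(gene_a = q, gene_b = b,
                                           stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
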