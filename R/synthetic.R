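#' Configure a synthetic study
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' The generator plants known structure -- co-expressed modules,
#' position-biased promoter motifs, enriched annotation categories, and
#' tandem/proximal/segmental duplications -- and records it as ground truth,
#' so each pipeline stage can be tested for recovery.
#'
#' Stage functions reseed from \code{seed} plus a fixed per-stage offset, so
#' each stage is individually reproducible and insensitive to the order in
#' which stages run.
#'
#' @param n_genes total genes. Default 1000.
#' @param n_conditions expression conditions. Default 60.
#' @param modules list of module specs, each \code{list(size=, base_correlation=)};
#'   module sizes must sum to at most \code{n_genes}. Default one 40-gene
#'   module at base correlation 0.8.
#' @param noise_sd member-gene noise sd on the log2 scale. \code{NULL}
#'   (default) derives it per module from \code{base_correlation} so the
#'   expected within-module Pearson r of log values equals the target.
#' @param latent_sd sd of a module's latent condition profile (log2 scale).
#' @param background_sd sd of background (non-module) gene noise (log2 scale).
#' @param baseline mean log2 abundance around which profiles vary.
#' @param promoter_length promoter length L in bases; default 1000
#'   (1 kb upstream of the TSS).
#' @param planted_motifs list of \code{list(id=, iupac=, genes=, dist=)};
#'   \code{dist} is \code{list(kind = "uniform")} or
#'   \code{list(kind = "gaussian", mean =, sd =)} over TSS distances.
#' @param n_chromosomes,genes_per_chromosome synthetic genome shape. Their
#'   product must be at least \code{n_genes} used for positions (the genome
#'   uses its own gene count \code{n_chromosomes * genes_per_chromosome}).
#' @param planted_duplications list of \code{list(kind = "tandem")},
#'   \code{list(kind = "proximal", gap =)} (rank difference, 2..19) or
#'   \code{list(kind = "segmental", size =, orientation =)} events.
#' @param n_noise_hits random homology hits between otherwise uninvolved
#'   genes (never same-chromosome within rank difference 20, so planted
#'   tandem/proximal truth stays unambiguous).
#' @param planted_categories list of \code{list(code =, genes =, fraction =,
#'   background_rate =)}; \code{fraction} of the gene set is annotated with
#'   the dotted code, other genes at \code{background_rate}.
#' @param decoy_categories list of \code{list(code =, rate =)} unstructured
#'   categories annotated uniformly at random.
#' @param seed integer master seed.
#' @return validated list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_genes = 1000,
                              n_conditions = 60,
                              modules = list(list(size = 40, base_correlation = 0.8)),
                              noise_sd = NULL,
                              latent_sd = 2,
                              background_sd = 2,
                              baseline = 6,
                              promoter_length = 1000,
                              planted_motifs = list(),
                              n_chromosomes = 2,
                              genes_per_chromosome = 200,
                              planted_duplications = list(),
                              n_noise_hits = 20,
                              planted_categories = list(),
                              decoy_categories = list(),
                              seed = 1) {
  stopifnot(n_genes > 0, n_conditions > 0, promoter_length > 0,
            n_chromosomes > 0, genes_per_chromosome > 0, n_noise_hits >= 0)
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be non-negative")
  sizes <- vapply(modules, function(m) m$size, 1)
  if (sum(sizes) > n_genes) stop("module sizes exceed n_genes")
  for (m in modules) {
    if (m$base_correlation <= 0 || m$base_correlation >= 1) {
      stop("base_correlation must lie in (0, 1)")
    }
  }
  for (pm in planted_motifs) {
    validate_motif(pm$iupac)
    if (nchar(pm$iupac) > promoter_length) stop("planted motif longer than promoter")
  }
  for (pc in planted_categories) {
    if (pc$fraction < 0 || pc$fraction > 1) stop("category fraction outside [0, 1]")
    if (!is.null(pc$background_rate) &&
        (pc$background_rate < 0 || pc$background_rate > 1)) {
      stop("background_rate outside [0, 1]")
    }
  }
  structure(list(n_genes = n_genes, n_conditions = n_conditions,
                 modules = modules, noise_sd = noise_sd, latent_sd = latent_sd,
                 background_sd = background_sd, baseline = baseline,
                 promoter_length = promoter_length,
                 planted_motifs = planted_motifs,
                 n_chromosomes = n_chromosomes,
                 genes_per_chromosome = genes_per_chromosome,
                 planted_duplications = planted_duplications,
                 n_noise_hits = n_noise_hits,
                 planted_categories = planted_categories,
                 decoy_categories = decoy_categories,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' The package's reference synthetic study
#'
#' A fixed study design exercising every pipeline stage: 1000 genes x 60
#' conditions with one 40-gene co-expressed module at base correlation 0.8;
#' the hierarchical category "34.19" annotated on 80% of the module versus a
#' 2% background rate (plus unstructured decoy categories); an 8-mer CRE
#' planted near the TSS (Gaussian, mean 250, sd 80) in 60% of module
#' promoters and uniformly in 3% of background promoters; and a synthetic
#' genome of 2 chromosomes x 200 genes carrying one 10-anchor segmental
#' block, 3 tandem pairs, 2 proximal pairs and 20 dispersed noise hits, the
#' rest singletons. The module occupies the first 40 gene ids, so
#' \code{g0001} serves as the guide gene.
#'
#' An 8-mer is used for the planted CRE because its background match rate in
#' 1 kb of uniform sequence (~1.5% of promoters) is low enough for a planted
#' 3% background presence to be meaningful; short degenerate 6-mers hit most
#' random promoters at least once.
#'
#' @param seed master seed.
#' @return a [simulation_config()].
#' @export
study_config <- function(seed = 1) {
  module_genes <- gene_ids(40)
  background_genes <- setdiff(gene_ids(1000), module_genes)
  # deterministic sub-seeding for the planted gene sets themselves
  set.seed(seed + 5L)
  cre_module <- sample(module_genes, 24)       # 60% of the module
  cre_background <- sample(background_genes, 29)  # ~3% of the background
  simulation_config(
    n_genes = 1000, n_conditions = 60,
    modules = list(list(size = 40, base_correlation = 0.8)),
    promoter_length = 1000,
    planted_motifs = list(
      list(id = "CRE1", iupac = "ACGTGTCC", genes = cre_module,
           dist = list(kind = "gaussian", mean = 250, sd = 80)),
      list(id = "CRE1", iupac = "ACGTGTCC", genes = cre_background,
           dist = list(kind = "uniform"))),
    n_chromosomes = 2, genes_per_chromosome = 200,
    planted_duplications = c(
      list(list(kind = "segmental", size = 10)),
      rep(list(list(kind = "tandem")), 3),
      rep(list(list(kind = "proximal")), 2)),
    n_noise_hits = 20,
    planted_categories = list(
      list(code = "34.19", genes = module_genes, fraction = 0.8,
           background_rate = 0.02)),
    decoy_categories = list(list(code = "1", rate = 0.05),
                            list(code = "2.1", rate = 0.03),
                            list(code = "27.3", rate = 0.04)),
    seed = seed)
}

#' Simulate an expression matrix with planted co-expressed modules
#'
#' Each module has a latent log2 condition profile; member genes equal the
#' latent profile plus Gaussian noise, background genes are independent
#' noise. Values are emitted on the raw FPKM-like scale (\code{2^z - 1},
#' truncated at zero) so the pipeline's own log transform is exercised; the
#' module structure lives on the log scale.
#'
#' @param config a [simulation_config()].
#' @return list with \code{matrix} (genes x conditions, non-negative) and
#'   \code{truth} (\code{module_membership}: named integer vector, 0 =
#'   background).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  g <- config$n_genes
  nc <- config$n_conditions
  ids <- gene_ids(g)
  membership <- stats::setNames(rep(0L, g), ids)
  z <- matrix(NA_real_, g, nc, dimnames = list(ids, sprintf("cond%02d", seq_len(nc))))
  next_gene <- 1L
  for (mi in seq_along(config$modules)) {
    spec <- config$modules[[mi]]
    idx <- next_gene:(next_gene + spec$size - 1L)
    next_gene <- next_gene + spec$size
    membership[idx] <- mi
    latent <- stats::rnorm(nc, 0, config$latent_sd)
    sd_m <- if (is.null(config$noise_sd)) {
      config$latent_sd * sqrt((1 - spec$base_correlation) / spec$base_correlation)
    } else config$noise_sd
    for (i in idx) {
      z[i, ] <- config$baseline + latent + stats::rnorm(nc, 0, sd_m)
    }
  }
  bg <- which(membership == 0L)
  bg_sd <- if (is.null(config$noise_sd)) config$background_sd else config$noise_sd
  for (i in bg) {
    z[i, ] <- stats::runif(1, config$baseline - 2, config$baseline + 2) +
      stats::rnorm(nc, 0, bg_sd)
  }
  x <- pmax(2^z - 1, 0)
  list(matrix = x, truth = list(module_membership = membership))
}

sample_tss_distance <- function(dist, max_d) {
  kind <- dist$kind %||% "uniform"
  if (kind == "uniform") {
    sample.int(max_d, 1L)
  } else if (kind == "gaussian") {
    d <- round(stats::rnorm(1, dist$mean, dist$sd))
    min(max(d, 1L), max_d)
  } else stop(sprintf("unknown position distribution '%s'", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Draw one concrete realisation of an IUPAC motif.
instantiate_motif <- function(iupac) {
  syms <- strsplit(toupper(iupac), "")[[1]]
  paste(vapply(syms, function(s) {
    set <- IUPAC_SETS[[s]]
    if (length(set) == 1) set else sample(set, 1L)
  }, ""), collapse = "")
}

#' Simulate promoter sequences with planted motifs
#'
#' Background composition is uniform i.i.d. A/C/G/T (so background hit rates
#' have a simple binomial form). Planted motif instances overwrite the
#' background at TSS distances drawn from the configured distribution;
#' insertions within one promoter never overlap (rejection sampling), and
#' every insertion is recorded in the truth.
#'
#' @param config a [simulation_config()].
#' @return list with \code{promoters} (named character vector, all of length
#'   \code{promoter_length}) and \code{truth} (\code{motif_positions}:
#'   data.frame gene / motif / tss_distance).
#' @export
simulate_promoters <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  L <- config$promoter_length
  ids <- gene_ids(config$n_genes)
  seqs <- vapply(ids, function(g) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
  planted <- list()
  occupied <- stats::setNames(vector("list", length(ids)), ids)
  for (pm in config$planted_motifs) {
    l <- nchar(pm$iupac)
    max_d <- L - l + 1L
    for (g in pm$genes) {
      for (attempt in 1:100) {
        d <- sample_tss_distance(pm$dist %||% list(kind = "uniform"), max_d)
        s <- L - l + 2L - d        # window start from TSS distance
        win <- s:(s + l - 1L)
        if (!any(win %in% occupied[[g]])) break
        if (attempt == 100) stop("could not place planted motif without overlap")
      }
      occupied[[g]] <- c(occupied[[g]], win)
      inst <- instantiate_motif(pm$iupac)
      substr(seqs[[g]], s, s + l - 1L) <- inst
      planted[[length(planted) + 1L]] <-
        data.frame(gene = g, motif = pm$id %||% pm$iupac, tss_distance = d,
                   stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(planted) > 0) do.call(rbind, planted) else
    data.frame(gene = character(), motif = character(),
               tss_distance = integer(), stringsAsFactors = FALSE)
  list(promoters = seqs, truth = list(motif_positions = truth))
}

#' Simulate a genome with planted duplication events
#'
#' Lays \code{n_chromosomes * genes_per_chromosome} genes along chromosomes
#' and plants duplication events on free rank slots: tandem pairs (rank
#' difference 1), proximal pairs (rank difference 2..19), and segmental
#' blocks (runs of consecutive anchor pairs between two chromosomes, parallel
#' or antiparallel). Every planted pair gets a strong homology hit; noise
#' hits connect otherwise uninvolved genes and never fall on the same
#' chromosome within rank difference 20. Genes untouched by any hit are
#' singletons.
#'
#' @param config a [simulation_config()].
#' @return list with \code{positions} (chrom/start/end/gene/strand, 0-based
#'   half-open), \code{hits} (12-column BLAST-tabular-style data.frame) and
#'   \code{truth} (\code{duplication_labels}: named character vector;
#'   \code{events}: list of planted events with gene ids).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 3L)
  nchr <- config$n_chromosomes
  m <- config$genes_per_chromosome
  chroms <- sprintf("chr%d", seq_len(nchr))
  n <- nchr * m
  ids <- gene_ids(n)
  chrom <- rep(chroms, each = m)
  rank <- rep(seq_len(m), nchr)
  start <- as.integer((rank - 1L) * 5000L + 1000L)
  positions <- data.frame(chrom = chrom, start = start, end = start + 1000L,
                          gene = ids, strand = "+", stringsAsFactors = FALSE)
  gene_at <- function(ch, r) ids[(match(ch, chroms) - 1L) * m + r]

  free <- lapply(chroms, function(ch) seq_len(m))
  names(free) <- chroms
  take_run <- function(ch, len, gap = 0L) {
    # a run of `len` ranks spaced gap+1 apart, all free, with a one-rank
    # buffer on each side so planted events never become rank-adjacent
    span <- (len - 1L) * (gap + 1L) + 1L
    cand <- free[[ch]]
    starts <- cand[cand + span - 1L <= m]
    starts <- starts[sample.int(length(starts))]
    for (s in starts) {
      run <- s + (0:(len - 1L)) * (gap + 1L)
      buffer <- unique(pmin(pmax(c(run - 1L, run + 1L), 1L), m))
      if (all(run %in% free[[ch]]) && all(buffer %in% c(free[[ch]], run))) {
        free[[ch]] <<- setdiff(free[[ch]], c(run, buffer))
        return(run)
      }
    }
    stop("could not place planted event; chromosome too crowded")
  }

  labels <- stats::setNames(rep("singleton", n), ids)
  hits <- list()
  events <- list()
  seg_zones <- list()
  add_hit <- function(a, b, evalue, bitscore) {
    hits[[length(hits) + 1L]] <<- data.frame(
      query = a, subject = b, pident = round(stats::runif(1, 70, 99), 1),
      length = 300L, mismatch = 10L, gapopen = 1L, qstart = 1L, qend = 300L,
      sstart = 1L, send = 300L, evalue = evalue, bitscore = bitscore,
      stringsAsFactors = FALSE)
  }

  for (ev in config$planted_duplications) {
    kind <- ev$kind
    if (kind == "tandem") {
      ch <- ev$chrom %||% sample(chroms, 1L)
      r <- take_run(ch, 2L)
      a <- gene_at(ch, r[1]); b <- gene_at(ch, r[2])
      add_hit(a, b, 1e-80, 500)
      labels[c(a, b)] <- "tandem"
      events[[length(events) + 1L]] <- list(kind = "tandem", genes = c(a, b))
    } else if (kind == "proximal") {
      gap <- ev$gap %||% sample(2:19, 1L)
      if (gap < 2 || gap > 19) stop("proximal gap must be in 2..19")
      ch <- ev$chrom %||% sample(chroms, 1L)
      r <- take_run(ch, 2L, gap = gap - 1L)
      a <- gene_at(ch, r[1]); b <- gene_at(ch, r[2])
      add_hit(a, b, 1e-60, 400)
      labels[c(a, b)] <- "proximal"
      events[[length(events) + 1L]] <- list(kind = "proximal", genes = c(a, b),
                                            gap = gap)
    } else if (kind == "segmental") {
      size <- ev$size %||% 10L
      orientation <- ev$orientation %||% "parallel"
      pair <- ev$chroms %||% sample(chroms, 2L)
      ra <- take_run(pair[1], size)
      rb <- take_run(pair[2], size)
      if (orientation == "antiparallel") rb <- rev(rb)
      ga <- gene_at(pair[1], ra); gb <- gene_at(pair[2], rb)
      for (i in seq_len(size)) add_hit(ga[i], gb[i], 1e-100, 600)
      labels[c(ga, gb)] <- "segmental"
      seg_zones[[length(seg_zones) + 1L]] <- list(
        chrom_a = pair[1], range_a = range(ra) + c(-26L, 26L),
        chrom_b = pair[2], range_b = range(rb) + c(-26L, 26L))
      events[[length(events) + 1L]] <- list(kind = "segmental",
                                            genes_a = ga, genes_b = gb,
                                            orientation = orientation)
    } else stop(sprintf("unknown duplication kind '%s'", kind))
  }

  # dispersed noise hits between uninvolved genes: never same-chromosome
  # within rank difference < 20 (planted tandem/proximal stay unambiguous)
  # and never with both ends flanking a planted segmental run (so noise
  # cannot chain onto a planted block)
  near_block <- function(a, b) {
    ca <- chrom[match(a, ids)]; cb <- chrom[match(b, ids)]
    ra <- rank[match(a, ids)]; rb <- rank[match(b, ids)]
    for (z in seg_zones) {
      in_a <- function(cc, rr) cc == z$chrom_a &&
        rr >= z$range_a[1] && rr <= z$range_a[2]
      in_b <- function(cc, rr) cc == z$chrom_b &&
        rr >= z$range_b[1] && rr <= z$range_b[2]
      if ((in_a(ca, ra) && in_b(cb, rb)) || (in_a(cb, rb) && in_b(ca, ra))) {
        return(TRUE)
      }
    }
    FALSE
  }
  if (config$n_noise_hits > 0) {
    pool <- ids[labels == "singleton"]
    for (i in seq_len(config$n_noise_hits)) {
      if (length(pool) < 2L) break
      ok <- FALSE
      for (try in 1:1000) {
        ab <- sample(pool, 2L)
        same <- chrom[match(ab[1], ids)] == chrom[match(ab[2], ids)]
        dr <- abs(rank[match(ab[1], ids)] - rank[match(ab[2], ids)])
        if ((!same || dr >= 20L) && !near_block(ab[1], ab[2])) { ok <- TRUE; break }
      }
      if (!ok) break
      add_hit(ab[1], ab[2], 1e-10, 80)
      labels[ab] <- "dispersed"
      pool <- setdiff(pool, ab)
    }
  }

  hits <- if (length(hits) > 0) do.call(rbind, hits) else
    data.frame(query = character(), subject = character(), pident = numeric(),
               length = integer(), mismatch = integer(), gapopen = integer(),
               qstart = integer(), qend = integer(), sstart = integer(),
               send = integer(), evalue = numeric(), bitscore = numeric(),
               stringsAsFactors = FALSE)
  list(positions = positions, hits = hits,
       truth = list(duplication_labels = labels, events = events))
}

#' Simulate hierarchical category annotation with planted enrichment
#'
#' Each planted category annotates the stated fraction of its target gene set
#' plus background genes at the background rate; decoy categories annotate
#' genes uniformly at random. Dotted codes imply ancestor membership at query
#' time (handled by the enrichment machinery, not materialised here).
#'
#' @param config a [simulation_config()].
#' @return list with \code{annotation} (data.frame gene / category) and
#'   \code{truth} (\code{category_genes}: named list of annotated gene ids
#'   per planted code).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 4L)
  ids <- gene_ids(config$n_genes)
  rows <- list()
  truth <- list()
  for (pc in config$planted_categories) {
    targets <- pc$genes
    n_on <- round(pc$fraction * length(targets))
    annotated <- sample(targets, n_on)
    rate <- pc$background_rate %||% 0
    others <- setdiff(ids, targets)
    bg <- others[stats::runif(length(others)) < rate]
    members <- c(annotated, bg)
    if (length(members) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(gene = members,
                                              category = pc$code,
                                              stringsAsFactors = FALSE)
    }
    truth[[pc$code]] <- sort(members)
  }
  for (dc in config$decoy_categories) {
    members <- ids[stats::runif(length(ids)) < dc$rate]
    if (length(members) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(gene = members,
                                              category = dc$code,
                                              stringsAsFactors = FALSE)
    }
  }
  annotation <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene = character(), category = character(), stringsAsFactors = FALSE)
  list(annotation = annotation, truth = list(category_genes = truth))
}

#' Run every generator stage of a synthetic study
#'
#' Convenience wrapper: expression, promoters, genome and annotation from one
#' config, with the combined ground truth. If \code{outdir} is given, all
#' inputs and the truth are also written to disk in the pipeline's file
#' formats (see [write_expression()], [write_promoters()], [write_bed()],
#' [write_blast_hits()], [write_annotation()]).
#'
#' @param config a [simulation_config()].
#' @param outdir optional output directory.
#' @return list with \code{expression}, \code{promoters}, \code{positions},
#'   \code{hits}, \code{annotation}, \code{truth}.
#' @export
simulate_study <- function(config, outdir = NULL) {
  expr <- simulate_expression(config)
  prom <- simulate_promoters(config)
  geno <- simulate_genome(config)
  annot <- simulate_annotation(config)
  truth <- c(expr$truth, prom$truth, geno$truth, annot$truth)
  out <- list(expression = expr$matrix, promoters = prom$promoters,
              positions = geno$positions, hits = geno$hits,
              annotation = annot$annotation, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_expression(out$expression, file.path(outdir, "expression.tsv"))
    write_promoters(out$promoters, file.path(outdir, "promoters.fa"))
    write_bed(out$positions, file.path(outdir, "positions.bed"))
    write_blast_hits(out$hits, file.path(outdir, "homology.tsv"))
    write_annotation(out$annotation, file.path(outdir, "annotation.tsv"))
    jsonlite::write_json(serializable_truth(truth),
                         file.path(outdir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  out
}

serializable_truth <- function(truth) {
  truth$module_membership <- as.list(truth$module_membership)
  truth$duplication_labels <- as.list(truth$duplication_labels)
  truth
}
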