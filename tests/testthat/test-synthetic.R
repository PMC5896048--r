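test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config(n_genes = 50, n_conditions = 10, seed = 1,
                           modules = list(list(size = 10, base_correlation = 0.7)),
                           planted_motifs = list(
                             list(id = "m", iupac = "RYCGAC",
                                  genes = sprintf("g%04d", 1:5),
                                  dist = list(kind = "uniform"))),
                           planted_duplications = list(list(kind = "tandem")))
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$promoters, b$promoters)
  expect_identical(a$hits, b$hits)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  # different seed changes the draw
  cfg2 <- simulation_config(n_genes = 50, n_conditions = 10, seed = 2,
                            modules = list(list(size = 10, base_correlation = 0.7)))
  expect_false(identical(simulate_expression(cfg2)$matrix, a$expression))
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(n_genes = 20,
                                 modules = list(list(size = 30, base_correlation = 0.5))),
               "exceed")
  expect_error(simulation_config(modules = list(list(size = 5, base_correlation = 1.2))),
               "base_correlation")
  expect_error(simulation_config(planted_motifs = list(
    list(id = "m", iupac = "ACGTXX", genes = "g0001"))), "IUPAC")
  expect_error(simulation_config(promoter_length = 4, planted_motifs = list(
    list(id = "m", iupac = "ACGTAC", genes = "g0001"))), "longer")
  expect_error(simulation_config(planted_categories = list(
    list(code = "34", genes = "g0001", fraction = 1.5))), "fraction")
})

test_that("noiseless module members are perfectly correlated on the log scale", {
  cfg <- simulation_config(n_genes = 10, n_conditions = 8, noise_sd = 0,
                           modules = list(list(size = 5, base_correlation = 0.8)),
                           seed = 3)
  sim <- simulate_expression(cfg)
  expect_true(all(sim$matrix >= 0))
  expect_equal(dim(sim$matrix), c(10, 8))
  lx <- log_transform(sim$matrix)
  r <- cor(t(lx[1:5, ]))
  expect_equal(unname(r), matrix(1, 5, 5), tolerance = 1e-12)
  expect_equal(unname(sim$truth$module_membership[1:5]), rep(1L, 5))
  expect_equal(unname(sim$truth$module_membership[6:10]), rep(0L, 5))
})

test_that("within-module correlation matches the generative target", {
  rs <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_genes = 60, n_conditions = 60,
                             modules = list(list(size = 40, base_correlation = 0.8)),
                             seed = 100 + s)
    lx <- log_transform(simulate_expression(cfg)$matrix)
    r <- cor(t(lx[1:40, ]))
    mean(r[upper.tri(r)])
  }, 1)
  expect_lt(abs(mean(rs) - 0.8), 0.1)
})

test_that("planted promoter motifs are recovered at their planted distances", {
  cfg <- simulation_config(n_genes = 30, n_conditions = 5, modules = list(),
                           planted_motifs = list(
                             list(id = "m", iupac = "RYCGAC",
                                  genes = "g0001",
                                  dist = list(kind = "gaussian", mean = 50, sd = 0))),
                           seed = 9)
  sim <- simulate_promoters(cfg)
  expect_true(all(nchar(sim$promoters) == 1000))
  expect_equal(sim$truth$motif_positions$tss_distance, 50)
  hits <- scan_promoters(sim$promoters["g0001"], "RYCGAC")
  expect_true(50 %in% hits$tss_distance)   # planted = recovered
  # every planted position is recoverable from the emitted sequences
  cfg2 <- simulation_config(n_genes = 40, n_conditions = 5,
                            planted_motifs = list(
                              list(id = "m", iupac = "ACGTGKC",
                                   genes = sprintf("g%04d", 1:20),
                                   dist = list(kind = "gaussian", mean = 250, sd = 80))),
                            seed = 10)
  sim2 <- simulate_promoters(cfg2)
  hits2 <- scan_promoters(sim2$promoters, "ACGTGKC")
  tt <- sim2$truth$motif_positions
  for (i in seq_len(nrow(tt))) {
    expect_true(any(hits2$gene == tt$gene[i] &
                    hits2$tss_distance == tt$tss_distance[i]))
  }
  # gaussian planting: sample mean of planted distances near the target
  expect_lt(abs(mean(tt$tss_distance) - 250), 60)
})

test_that("planted genome events have the promised rank structure", {
  cfg <- simulation_config(n_chromosomes = 2, genes_per_chromosome = 100,
                           n_genes = 200,
                           planted_duplications = list(
                             list(kind = "tandem"),
                             list(kind = "proximal", gap = 6),
                             list(kind = "segmental", size = 10)),
                           n_noise_hits = 0, seed = 12)
  g <- simulate_genome(cfg)
  ranked <- assign_ranks(g$positions)
  rk <- setNames(ranked$rank, ranked$gene)
  ch <- setNames(ranked$chrom, ranked$gene)
  ev <- g$truth$events
  tandem <- ev[[which(vapply(ev, function(e) e$kind == "tandem", TRUE))]]
  expect_equal(abs(diff(rk[tandem$genes])), 1, ignore_attr = TRUE)
  expect_equal(length(unique(ch[tandem$genes])), 1)
  prox <- ev[[which(vapply(ev, function(e) e$kind == "proximal", TRUE))]]
  expect_equal(abs(diff(rk[prox$genes])), 6, ignore_attr = TRUE)
  seg <- ev[[which(vapply(ev, function(e) e$kind == "segmental", TRUE))]]
  expect_equal(nrow(g$hits), 12)   # 10 anchors + tandem + proximal
  # anchor ranks are consecutive on both chromosomes
  expect_equal(unname(diff(rk[seg$genes_a])), rep(1, 9))
  expect_equal(abs(unname(diff(rk[seg$genes_b]))), rep(1, 9))
})

test_that("noise hits never fall on one chromosome within rank distance 20", {
  cfg <- simulation_config(n_chromosomes = 2, genes_per_chromosome = 60,
                           n_genes = 120, planted_duplications = list(),
                           n_noise_hits = 30, seed = 14)
  g <- simulate_genome(cfg)
  ranked <- assign_ranks(g$positions)
  rk <- setNames(ranked$rank, ranked$gene)
  ch <- setNames(ranked$chrom, ranked$gene)
  same <- ch[g$hits$query] == ch[g$hits$subject]
  if (any(same)) {
    expect_true(all(abs(rk[g$hits$query[same]] - rk[g$hits$subject[same]]) >= 20))
  }
  expect_equal(sort(unique(unname(g$truth$duplication_labels))),
               c("dispersed", "singleton"))
})

test_that("annotation planting honours fractions, background rate and hierarchy", {
  targets <- sprintf("g%04d", 1:40)
  cfg <- simulation_config(n_genes = 1000, n_conditions = 5,
                           planted_categories = list(
                             list(code = "34.19", genes = targets,
                                  fraction = 0.8, background_rate = 0)),
                           seed = 15)
  sim <- simulate_annotation(cfg)
  members <- sim$annotation$gene[sim$annotation$category == "34.19"]
  expect_equal(length(members), 32)          # exactly 80% of 40
  expect_true(all(members %in% targets))     # background_rate 0 -> targets only
  expect_equal(sort(members), sim$truth$category_genes[["34.19"]])
  # with background, rate is approximately honoured
  cfg2 <- simulation_config(n_genes = 1000, n_conditions = 5,
                            planted_categories = list(
                              list(code = "34.19", genes = targets,
                                   fraction = 0.8, background_rate = 0.02)),
                            seed = 16)
  sim2 <- simulate_annotation(cfg2)
  bg <- setdiff(sim2$annotation$gene[sim2$annotation$category == "34.19"], targets)
  expect_lt(abs(length(bg) - 0.02 * 960), 3 * sqrt(960 * 0.02 * 0.98))
})

test_that("simulate_study writes byte-identical files for identical configs", {
  cfg <- simulation_config(n_genes = 30, n_conditions = 6, seed = 17,
                           modules = list(list(size = 5, base_correlation = 0.7)),
                           planted_motifs = list(
                             list(id = "m", iupac = "RYCGAC",
                                  genes = sprintf("g%04d", 1:3))),
                           planted_duplications = list(list(kind = "tandem")),
                           planted_categories = list(
                             list(code = "34.19", genes = sprintf("g%04d", 1:5),
                                  fraction = 0.8, background_rate = 0.02)))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(cfg, outdir = d1)
  simulate_study(cfg, outdir = d2)
  files <- list.files(d1)
  expect_setequal(files, c("annotation.tsv", "expression.tsv", "homology.tsv",
                           "positions.bed", "promoters.fa", "truth.json"))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})
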