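mk_hits <- function(pairs, evalue = 1e-50, bitscore = 300) {
  data.frame(query = vapply(pairs, `[`, "", 1),
             subject = vapply(pairs, `[`, "", 2),
             pident = 90, length = 300L, mismatch = 5L, gapopen = 0L,
             qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}

mk_positions <- function(chrom, genes) {
  data.frame(chrom = chrom,
             start = unlist(lapply(table(chrom)[unique(chrom)], function(m)
               seq(0, by = 1000, length.out = m))),
             end = unlist(lapply(table(chrom)[unique(chrom)], function(m)
               seq(500, by = 1000, length.out = m))),
             gene = genes, stringsAsFactors = FALSE)
}

test_that("assign_ranks orders genes within chromosomes with id tie-breaks", {
  pos <- data.frame(chrom = "chr1", start = c(100L, 50L, 200L),
                    end = c(150L, 90L, 240L), gene = c("a", "b", "c"),
                    stringsAsFactors = FALSE)
  r <- assign_ranks(pos)
  expect_equal(r$rank[match(c("a", "b", "c"), r$gene)], c(2L, 1L, 3L))
  # two chromosomes rank independently from 1
  pos2 <- rbind(pos, data.frame(chrom = "chr2", start = c(10L, 5L),
                                end = c(20L, 8L), gene = c("d", "e")))
  r2 <- assign_ranks(pos2)
  expect_equal(sort(r2$rank[r2$chrom == "chr2"]), 1:2)
  # equal starts -> lexicographic gene order
  pos3 <- data.frame(chrom = "chr1", start = c(100L, 100L), end = c(1L, 1L),
                     gene = c("z", "a"), stringsAsFactors = FALSE)
  r3 <- assign_ranks(pos3)
  expect_equal(r3$gene[r3$rank == 1], "a")
  expect_error(assign_ranks(rbind(pos, pos[1, ])), "duplicate gene")
})

test_that("collinear block chaining recovers planted parallel and antiparallel blocks", {
  genes <- c(sprintf("a%02d", 1:20), sprintf("b%02d", 1:20))
  pos <- mk_positions(rep(c("chr1", "chr2"), each = 20), genes)
  # parallel 10-anchor block: a03..a12 <-> b05..b14
  pairs <- lapply(1:10, function(i) c(sprintf("a%02d", i + 2), sprintf("b%02d", i + 4)))
  blocks <- detect_collinear_blocks(pos, mk_hits(pairs))
  expect_equal(nrow(blocks), 10)
  expect_equal(unique(blocks$orientation), "parallel")
  expect_setequal(paste(blocks$gene_a, blocks$gene_b),
                  vapply(pairs, paste, "", collapse = " "))
  # antiparallel (inverted) 6-anchor block
  inv <- lapply(1:6, function(i) c(sprintf("a%02d", i), sprintf("b%02d", 8 - i)))
  b2 <- detect_collinear_blocks(pos, mk_hits(inv))
  expect_equal(nrow(b2), 6)
  expect_equal(unique(b2$orientation), "antiparallel")
  # 4 anchors below min_block_size -> nothing
  b3 <- detect_collinear_blocks(pos, mk_hits(pairs[1:4]))
  expect_equal(nrow(b3), 0)
  # gap constraint: a gap of 30 ranks splits the chain
  far <- lapply(1:10, function(i) {
    if (i <= 5) c(sprintf("a%02d", i), sprintf("b%02d", i))
    else c(sprintf("a%02d", i + 9), sprintf("b%02d", i + 9))
  })
  b4 <- detect_collinear_blocks(pos, mk_hits(far), min_block_size = 5, max_gap = 8)
  expect_equal(sort(unique(b4$size)), 5)
})

test_that("emitted blocks satisfy the monotonicity invariants", {
  cfg <- simulation_config(n_chromosomes = 3, genes_per_chromosome = 100,
                           n_genes = 300,
                           planted_duplications = list(
                             list(kind = "segmental", size = 10),
                             list(kind = "segmental", size = 7,
                                  orientation = "antiparallel"),
                             list(kind = "tandem")),
                           n_noise_hits = 15, seed = 6)
  g <- simulate_genome(cfg)
  blocks <- detect_collinear_blocks(assign_ranks(g$positions), g$hits)
  for (id in unique(blocks$block_id)) {
    b <- blocks[blocks$block_id == id, ]
    expect_gte(nrow(b), 5)
    expect_true(all(diff(b$rank_a) >= 1 & diff(b$rank_a) <= 25))
    db <- diff(b$rank_b)
    if (b$orientation[1] == "parallel") {
      expect_true(all(db >= 1 & db <= 25))
    } else {
      expect_true(all(db <= -1 & db >= -25))
    }
  }
})

test_that("classification follows the tandem/proximal definitions and priority order", {
  genes <- sprintf("g%02d", 1:30)
  pos <- mk_positions(rep("chr1", 30), genes)
  # rank difference 1 -> tandem (both genes)
  a1 <- classify_duplications(pos, mk_hits(list(c("g05", "g06"))))
  expect_equal(a1$class[a1$gene %in% c("g05", "g06")], rep("tandem", 2))
  expect_equal(a1$class[a1$gene == "g01"], "singleton")
  # rank difference 2 (one intervening gene) -> proximal
  a2 <- classify_duplications(pos, mk_hits(list(c("g10", "g12"))))
  expect_equal(a2$class[a2$gene %in% c("g10", "g12")], rep("proximal", 2))
  # rank difference 19 -> proximal; 20 -> dispersed (strict < 20)
  a3 <- classify_duplications(pos, mk_hits(list(c("g01", "g20"), c("g02", "g22"))))
  expect_equal(a3$class[a3$gene == "g01"], "proximal")
  expect_equal(a3$class[a3$gene == "g02"], "dispersed")
  # hits above the e-value ceiling are ignored
  a4 <- classify_duplications(pos, mk_hits(list(c("g05", "g06")), evalue = 1e-3))
  expect_equal(unique(a4$class), "singleton")
  expect_error(classify_duplications(pos, mk_hits(list(c("g05", "nope")))),
               "unknown gene")
})

test_that("a gene satisfying several classes gets the highest-priority one", {
  genes <- c(sprintf("a%02d", 1:30), sprintf("b%02d", 1:30))
  pos <- mk_positions(rep(c("chr1", "chr2"), each = 30), genes)
  # a10..a14 anchor a 5-block with b10..b14; a10 also tandem with a11 and
  # proximal with a13
  pairs <- c(lapply(1:5, function(i) c(sprintf("a%02d", i + 9), sprintf("b%02d", i + 9))),
             list(c("a10", "a11"), c("a10", "a13")))
  a <- classify_duplications(pos, mk_hits(pairs))
  expect_equal(a$class[a$gene == "a10"], "segmental")
  # drop the block: tandem beats proximal
  a2 <- classify_duplications(pos, mk_hits(list(c("a10", "a11"), c("a10", "a13"))))
  expect_equal(a2$class[a2$gene == "a10"], "tandem")
  expect_equal(a2$class[a2$gene == "a13"], "proximal")
  # every gene gets exactly one class
  expect_setequal(a$gene, genes)
  expect_true(all(a$class %in% c("singleton", "dispersed", "proximal",
                                 "tandem", "segmental")))
})

test_that("planted duplication labels are recovered exactly on the reference genome", {
  cfg <- study_config(seed = 5)
  g <- simulate_genome(cfg)
  assign <- classify_duplications(g$positions, g$hits)
  truth <- g$truth$duplication_labels
  expect_equal(unname(truth[assign$gene]), assign$class)
  tab <- table(assign$class)
  expect_equal(unname(tab["segmental"]), 20L)   # 10 anchor pairs
  expect_equal(unname(tab["tandem"]), 6L)
  expect_equal(unname(tab["proximal"]), 4L)
  expect_equal(unname(tab["dispersed"]), 40L)
  expect_gte(unname(tab["singleton"]), 50L)
})

test_that("tandem and proximal groups are connected components of the pair relation", {
  genes <- sprintf("g%02d", 1:30)
  pos <- mk_positions(rep("chr1", 30), genes)
  # chain g01-g02-g03 mutual tandem homologs; separate pair g10-g11
  hits <- mk_hits(list(c("g01", "g02"), c("g02", "g03"), c("g10", "g11")))
  assign <- classify_duplications(pos, hits)
  grp <- tandem_proximal_groups(assign, pos, hits)
  tg <- grp[grp$kind == "tandem", ]
  expect_equal(length(unique(tg$group_id)), 2)
  chain <- tg$group_id[tg$gene == "g01"]
  expect_setequal(tg$gene[tg$group_id == chain], c("g01", "g02", "g03"))
  # no tandem genes -> empty output
  none <- classify_duplications(pos, mk_hits(list(c("g01", "g25"))))
  expect_equal(nrow(tandem_proximal_groups(none, pos,
                                           mk_hits(list(c("g01", "g25"))))), 0)
})

test_that("reciprocal_best_hits matches a brute-force double scan", {
  ab <- mk_hits(list(c("a1", "b1"), c("a1", "b2"), c("a2", "b2")))
  ab$evalue <- c(1e-50, 1e-10, 1e-40)
  ba <- mk_hits(list(c("b1", "a1"), c("b2", "a1")))
  ba$evalue <- c(1e-45, 1e-30)
  rbh <- reciprocal_best_hits(ab, ba)
  expect_equal(rbh, data.frame(gene_a = "a1", gene_b = "b1",
                               stringsAsFactors = FALSE))
  # a2's best is b2 but b2's best is a1 -> no pair for a2
  expect_false("a2" %in% rbh$gene_a)
  set.seed(41)
  for (i in 1:10) {
    qa <- sprintf("a%d", 1:6); qb <- sprintf("b%d", 1:6)
    ab <- mk_hits(lapply(1:15, function(j) c(sample(qa, 1), sample(qb, 1))))
    ba <- mk_hits(lapply(1:15, function(j) c(sample(qb, 1), sample(qa, 1))))
    ab$evalue <- 10^-sample(5:60, 15, replace = TRUE)
    ba$evalue <- 10^-sample(5:60, 15, replace = TRUE)
    ab <- ab[!duplicated(ab[c("query", "subject")]), ]
    ba <- ba[!duplicated(ba[c("query", "subject")]), ]
    expect_equal(reciprocal_best_hits(ab, ba), oracle_rbh(ab, ba))
  }
})
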