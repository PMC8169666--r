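test_that("gene loci load from GFF3 with per-chromosome ranks and unplaced flags", {
  loci <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     chromosome = c("chr1", "chr1", "chr1", "ChrUn_scaff"),
                     start = c(100L, 50L, 200L, 10L),
                     end = c(150L, 80L, 260L, 40L),
                     strand = c("+", "-", "+", "+"))
  gff <- tempfile(fileext = ".gff3")
  write_gene_map_gff3(loci, gff)
  got <- load_gene_loci(gff)
  expect_equal(got$rank[match(c("g1", "g2", "g3"), got$gene_id)], c(2L, 1L, 3L))
  expect_true(got$unplaced[got$gene_id == "g4"])
  expect_false(any(got$unplaced[got$gene_id != "g4"]))

  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(load_gene_loci(empty)), 0)
})

test_that("chromosome distribution percentages round half-up to one decimal", {
  loci <- data.frame(gene_id = sprintf("g%04d", 1:1238),
                     chromosome = c(rep("chr4B", 43), rep("chrOther", 1195)),
                     start = 1:1238, end = 1:1238 + 10, strand = "+",
                     unplaced = FALSE)
  d <- chrom_distribution(loci)
  expect_equal(d$pct[d$chromosome == "chr4B"], 3.5)  # 100*43/1238 = 3.47 -> 3.5
  one <- chrom_distribution(loci[loci$chromosome == "chr4B", ])
  expect_equal(one$pct, 100.0)
})

test_that("mean adjacent distance matches direct recomputation", {
  loci <- data.frame(gene_id = c("a", "b"), chromosome = "chr1",
                     start = c(1000000L, 8600000L), end = c(1000100L, 8600100L),
                     strand = "+", unplaced = FALSE)
  expect_equal(mean_adjacent_distance(loci)$mean_mb, 7.6)

  even <- data.frame(gene_id = letters[1:5], chromosome = "chr2",
                     start = seq(0L, 40000000L, by = 10000000L),
                     end = seq(0L, 40000000L, by = 10000000L) + 10L,
                     strand = "+", unplaced = FALSE)
  expect_equal(mean_adjacent_distance(even)$mean_mb, 10.0)

  single <- even[1, ]
  expect_true(is.na(mean_adjacent_distance(single)$mean_mb))

  set.seed(3)
  rnd <- data.frame(gene_id = sprintf("r%02d", 1:20), chromosome = "chr3",
                    start = sort(sample.int(9e7, 20)), strand = "+",
                    unplaced = FALSE)
  rnd$end <- rnd$start + 100L
  got <- mean_adjacent_distance(rnd, digits = 6)$mean_mb
  expect_equal(got, round_half_up(mean(diff(rnd$start)) / 1e6, 6))
})

test_that("collinear block chaining finds blocks and respects min_anchors", {
  mk_loci <- function(n, chrom) {
    data.frame(gene_id = sprintf("%s_g%02d", chrom, 1:n), chromosome = chrom,
               start = (1:n) * 1000L, end = (1:n) * 1000L + 100L, strand = "+",
               rank = 1:n, unplaced = FALSE)
  }
  loci <- rbind(mk_loci(30, "cA"), mk_loci(30, "cB"))
  perfect <- data.frame(gene_a = sprintf("cA_g%02d", 1:5),
                        gene_b = sprintf("cB_g%02d", 1:5))
  b <- chain_collinear_blocks(perfect, loci)
  expect_equal(length(unique(b$block_id)), 1)
  expect_equal(nrow(b), 5)

  four <- perfect[1:4, ]
  expect_equal(nrow(chain_collinear_blocks(four, loci)), 0)

  # two interleaved blocks: 6 anchors ascending, 5 anchors descending on B
  inter <- rbind(
    data.frame(gene_a = sprintf("cA_g%02d", c(1, 3, 5, 7, 9, 11)),
               gene_b = sprintf("cB_g%02d", c(1, 3, 5, 7, 9, 11))),
    data.frame(gene_a = sprintf("cA_g%02d", c(2, 4, 6, 8, 10)),
               gene_b = sprintf("cB_g%02d", c(28, 26, 24, 22, 20))))
  b2 <- chain_collinear_blocks(inter, loci)
  expect_equal(sort(table(b2$block_id), decreasing = TRUE), sort(c(6L, 5L), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_equal(nrow(b2), 11)
})

test_that("block chaining agrees with the exhaustive oracle on small instances", {
  set.seed(5)
  params <- dup_params(min_anchors = 3, max_anchor_rank_gap = 10)
  for (rep in 1:25) {
    nA <- 25; nB <- 25
    loci <- rbind(
      data.frame(gene_id = sprintf("A%02d", 1:nA), chromosome = "cA",
                 start = (1:nA) * 100L, end = (1:nA) * 100L + 10L, strand = "+",
                 rank = 1:nA, unplaced = FALSE),
      data.frame(gene_id = sprintf("B%02d", 1:nB), chromosome = "cB",
                 start = (1:nB) * 100L, end = (1:nB) * 100L + 10L, strand = "+",
                 rank = 1:nB, unplaced = FALSE))
    n <- sample(6:14, 1)
    pairs <- data.frame(gene_a = sprintf("A%02d", sample(nA, n)),
                        gene_b = sprintf("B%02d", sample(nB, n)))
    got <- chain_collinear_blocks(pairs, loci, params)
    exp <- oracle_blocks(pairs, loci, params)
    got_sizes <- sort(as.integer(table(got$block_id)), decreasing = TRUE)
    exp_sizes <- sort(vapply(exp, nrow, 1L), decreasing = TRUE)
    expect_equal(got_sizes, exp_sizes)
  }
})

test_that("duplication classification follows the documented priority", {
  loci <- data.frame(gene_id = c("s", "t1", "t2", "p1", "p2", "d1", "d2"),
                     chromosome = c("c1", "c1", "c1", "c1", "c1", "c1", "c2"),
                     start = c(100, 2000, 3000, 9000, 14000, 30000, 500),
                     end = c(110, 2010, 3010, 9010, 14010, 30010, 510),
                     strand = "+", rank = c(1L, 2L, 3L, 4L, 8L, 30L, 1L),
                     unplaced = FALSE)
  pairs <- data.frame(gene_a = c("t1", "p1", "d1"), gene_b = c("t2", "p2", "d2"))
  calls <- classify_duplications(loci, pairs)
  got <- stats::setNames(calls$class, calls$gene_id)
  expect_identical(unname(got[c("s", "t1", "t2", "p1", "p2", "d1", "d2")]),
                   c("singleton", "tandem", "tandem", "proximal", "proximal",
                     "dispersed", "dispersed"))
  expect_error(classify_duplications(loci, data.frame(gene_a = "t1", gene_b = "nope")),
               "unknown gene")
})

test_that("a planted duplication-class plan is recovered exactly", {
  plan <- c(singleton = 4, dispersed = 9, proximal = 5, tandem = 10,
            WGD_segmental = 20)
  map <- gen_gene_map(plan, n_chroms = 5, seed = 3)
  fam <- map$loci[map$loci$gene_id %in% map$family_genes, ]
  calls <- classify_duplications(fam, map$pairs, all_loci = map$loci)
  expect_equal(duplication_class_counts(calls), plan[names(duplication_class_counts(calls))],
               ignore_attr = TRUE)
  truth <- map$truth$dup_classes
  expect_identical(unname(truth[calls$gene_id]), calls$class)
})

test_that("raising min_anchors only demotes genes out of WGD_segmental", {
  plan <- c(dispersed = 4, tandem = 6, WGD_segmental = 24)
  map <- gen_gene_map(plan, n_chroms = 4, seed = 9,
                      params = dup_params(min_anchors = 4))
  fam <- map$loci[map$loci$gene_id %in% map$family_genes, ]
  lo <- classify_duplications(fam, map$pairs, all_loci = map$loci,
                              params = dup_params(min_anchors = 4))
  hi <- classify_duplications(fam, map$pairs, all_loci = map$loci,
                              params = dup_params(min_anchors = 8))
  lo_wgd <- lo$gene_id[lo$class == "WGD_segmental"]
  hi_wgd <- hi$gene_id[hi$class == "WGD_segmental"]
  expect_true(all(hi_wgd %in% lo_wgd))
  # classes always partition the family
  expect_equal(sum(duplication_class_counts(hi)), nrow(fam))
})
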