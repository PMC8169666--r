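test_that("expressed calls use a strict threshold", {
  m <- matrix(c(0, 0.5, 0.51, 2), 2, 2)
  got <- call_expressed(m, 0.5)
  expect_identical(as.vector(got), c(FALSE, FALSE, TRUE, TRUE))
  expect_false(any(call_expressed(matrix(0, 3, 3), 0.5)))
})

test_that("venn partition equals brute-force set algebra and conserves totals", {
  expect_error(venn_partition(matrix(TRUE, 2, 2)), "3 stage")
  one <- matrix(TRUE, 1, 3, dimnames = list("g1", NULL))
  vp1 <- venn_partition(one)
  expect_equal(unname(vp1$counts["all3"]), 1)
  expect_equal(vp1$total_expressed, 1)

  set.seed(8)
  for (i in 1:10) {
    m <- matrix(runif(500 * 3) > 0.5, 500, 3,
                dimnames = list(sprintf("g%03d", 1:500), NULL))
    vp <- venn_partition(m)
    s1 <- which(m[, 1]); s2 <- which(m[, 2]); s3 <- which(m[, 3])
    expect_equal(unname(vp$counts["all3"]), length(intersect(intersect(s1, s2), s3)))
    expect_equal(unname(vp$counts["s1_s2"]),
                 length(setdiff(intersect(s1, s2), s3)))
    expect_equal(unname(vp$counts["s1_only"]),
                 length(setdiff(s1, union(s2, s3))))
    expect_equal(vp$total_expressed, length(union(union(s1, s2), s3)))
    expect_equal(sum(vp$counts), vp$total_expressed)
  }
})

test_that("uncentered Pearson distance has the documented geometry", {
  x <- c(2, 5, 1)
  expect_equal(uncentered_pearson_distance(x, x), 0)
  expect_equal(uncentered_pearson_distance(x, -x), 2)
  expect_equal(uncentered_pearson_distance(c(1, 2, 3), c(3, 2, 1)), 1 - 10 / 14)
  expect_warning(d0 <- uncentered_pearson_distance(c(0, 0), c(1, 2)), "zero-norm")
  expect_equal(d0, 1)
  set.seed(4)
  for (i in 1:20) {
    a <- runif(4); b <- runif(4)
    d <- uncentered_pearson_distance(a, b)
    expect_gte(d, 0); expect_lte(d, 2)
    expect_equal(d, uncentered_pearson_distance(b, a))
  }
})

test_that("complete-linkage merges follow the hand-computed trace on n = 3", {
  m <- rbind(a = c(1, 0, 0), b = c(0.9, 0.1, 0), c = c(0, 0, 1))
  # d(a,b) = 1 - 0.9/sqrt(0.82); d(a,c) = d(b,c) = 1
  dab <- 1 - 0.9 / sqrt(1 * (0.81 + 0.01))
  tree <- hcluster_complete(m)
  expect_equal(tree$height, c(dab, 1))
  first <- sort(tree$labels[-tree$merge[1, ]])
  expect_identical(first, c("a", "b"))
  # identical profiles merge at height 0
  m2 <- rbind(x = c(1, 2, 3), y = c(1, 2, 3), z = c(9, 0, 0))
  expect_equal(hcluster_complete(m2)$height[1], 0)
})

test_that("planted archetype profiles are recovered as four clusters", {
  set.seed(12)
  arch <- list(early = c(10, 1, 1), late = c(1, 1, 10),
               bimodal = c(10, 1, 10), mid = c(1, 10, 1))
  m <- do.call(rbind, lapply(names(arch), function(a) {
    x <- matrix(rep(arch[[a]], each = 10), 10, 3) + rnorm(30, 0, 0.3)
    rownames(x) <- sprintf("%s_%02d", a, 1:10)
    x
  }))
  grp <- cut_clusters(hcluster_complete(m), k = 4)
  planted <- sub("_.*", "", names(grp))
  # every planted archetype maps to exactly one recovered cluster
  expect_equal(unname(apply(table(planted, grp) > 0, 1, sum)), rep(1L, 4))
  expect_error(cut_clusters(hcluster_complete(m), k = 100), "exceeds")
})

test_that("subgroup labelling orders groups by expression stage", {
  set.seed(13)
  m <- rbind(matrix(rep(c(10, 1, 1), each = 6), 6) + rnorm(18, 0, 0.2),
             matrix(rep(c(5, 5, 5), each = 6), 6) + rnorm(18, 0, 0.2),
             matrix(rep(c(1, 8, 4), each = 6), 6) + rnorm(18, 0, 0.2),
             matrix(rep(c(1, 1, 10), each = 6), 6) + rnorm(18, 0, 0.2))
  rownames(m) <- sprintf("g%02d", 1:24)
  out <- expression_groups(m, k = 4)
  expect_setequal(unique(out$group), c("I", "II", "III", "IV"))
  expect_true(all(grepl("^(III|IV)[AB]$", out$subgroup[out$group %in% c("III", "IV")])))
})

test_that("DEG filtering applies the strict fold-change and inclusive p rules", {
  rec <- data.frame(gene = c("k", "d1", "d2", "b"),
                    group = "Group1",
                    log2fc = c(2.81, 0.9, 1.5, -1.2),
                    pvalue = c(0.01, 0.001, 0.06, 0.05))
  kept <- deg_filter(rec)
  expect_setequal(kept$gene, c("k", "b"))   # |FC| > 1 and p <= 0.05
  # monotone in both thresholds
  set.seed(6)
  tab <- data.frame(gene = sprintf("g%03d", 1:200),
                    log2fc = runif(200, -4, 4), pvalue = runif(200))
  strict <- deg_filter(tab, 1.5, 0.01)
  loose <- deg_filter(tab, 1, 0.05)
  expect_true(all(strict$gene %in% loose$gene))
})
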