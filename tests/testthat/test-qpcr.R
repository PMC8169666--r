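mk_ct <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r[[1]], genotype = r[[2]], stage = 7, biorep = 1,
               techrep = 1, ct = as.numeric(r[[3]]), stringsAsFactors = FALSE)
  }))
}

test_that("ddct implements the Livak identity", {
  flat <- mk_ct(list("G", "mut", 20), list("G", "ctl", 20),
                list("ARF", "mut", 20), list("ARF", "ctl", 20))
  expect_equal(ddct(flat, "G", "mut", "ctl", 7)$log2fc, 0)

  up2 <- mk_ct(list("G", "mut", 18), list("G", "ctl", 20),
               list("ARF", "mut", 20), list("ARF", "ctl", 20))
  expect_equal(ddct(up2, "G", "mut", "ctl", 7)$log2fc, 2)

  # antisymmetry under swapping genotypes
  expect_equal(ddct(up2, "G", "mut", "ctl", 7)$log2fc,
               -ddct(up2, "G", "ctl", "mut", 7)$log2fc)

  # adding a constant to every Ct of one run leaves the estimate unchanged
  shifted <- up2
  shifted$ct[shifted$genotype == "mut"] <- shifted$ct[shifted$genotype == "mut"] + 3.7
  expect_equal(ddct(shifted, "G", "mut", "ctl", 7)$log2fc, 2)

  expect_error(ddct(up2, "G", "mut", "ctl", 14), "missing Ct cell.*stage=14")
})

test_that("replicate aggregation averages techreps within bioreps", {
  tab <- rbind(
    data.frame(gene = "G", genotype = "mut", stage = 7, biorep = c(1, 1, 2),
               techrep = c(1, 2, 1), ct = c(17, 19, 18)),
    data.frame(gene = "G", genotype = "ctl", stage = 7, biorep = c(1, 2),
               techrep = 1, ct = c(20, 20)),
    data.frame(gene = "ARF", genotype = c("mut", "mut", "ctl", "ctl"), stage = 7,
               biorep = c(1, 2, 1, 2), techrep = 1, ct = 20))
  d <- ddct(tab, "G", "mut", "ctl", 7)
  expect_equal(d$log2fc, 2)          # biorep means 18, 18 -> mean 18
  expect_equal(d$n_bioreps, 2)
  expect_equal(d$sd, stats::sd(c(2, 2)))
})

test_that("profile classification follows the consistency-and-magnitude rule", {
  expect_identical(profile_classify(c(-2.5, -2.2, -1.1, -1.0)), "down_candidate")
  expect_identical(profile_classify(c(-0.5, -0.6, -0.4, -0.7)), "consistent_only")
  expect_identical(profile_classify(c(3, -1, 2, 2)), "mixed")
  expect_identical(profile_classify(c(2.5, 2.5, 2.5, 2.5)), "up_candidate")
  expect_identical(profile_classify(c(0, 0, 0, 0)), "mixed")
  # configurable magnitude rule
  expect_identical(profile_classify(c(-1.5, -1.5, -1, -1), magnitude_min = 1.2),
                   "down_candidate")
})

test_that("candidate counting recovers a planted 8-down/3-up panel", {
  plan <- ringminer:::gen_qpcr_plan(36, 8, 3, seed = 4)
  q <- gen_qpcr(plan, noise_sd = 0, replicates = 3, seed = 5)
  prof <- fc_profiles(q$table, "TAC75", "C306")
  cand <- count_candidates(prof)
  expect_equal(cand$n_down, 8)
  expect_equal(cand$n_up, 3)
  expect_length(cand$down_ids, 8)

  none <- data.frame(gene = rep(c("a", "b"), each = 2), stage = c(7, 14),
                     log2fc = c(1, -1, 2, -2))
  expect_equal(count_candidates(none)$n_down + count_candidates(none)$n_up, 0)

  single <- data.frame(gene = "u", stage = c(7, 14, 21, 28), log2fc = 2.5)
  expect_equal(count_candidates(single)$n_up, 1)
})

test_that("noise-free generator round-trip is exact", {
  plan <- ringminer:::gen_qpcr_plan(10, 3, 2, seed = 6)
  q <- gen_qpcr(plan, noise_sd = 0, replicates = 3, seed = 7)
  prof <- fc_profiles(q$table, "TAC75", "C306")
  truth <- plan$log2fc[match(paste(prof$gene, prof$stage),
                             paste(plan$gene, plan$stage))]
  expect_lt(max(abs(prof$log2fc - truth)), 1e-9)
})
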