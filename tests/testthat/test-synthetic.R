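rs <- default_ruleset()

test_that("planted domains satisfy their subtype rules and are deterministic", {
  p1 <- gen_proteome(rs, 5, domain_plan = c("RING-H2" = 2, "RING-v" = 1), seed = 21)
  p2 <- gen_proteome(rs, 5, domain_plan = c("RING-H2" = 2, "RING-v" = 1), seed = 21)
  expect_identical(p1, p2)
  p3 <- gen_proteome(rs, 5, domain_plan = c("RING-H2" = 2, "RING-v" = 1), seed = 22)
  expect_false(identical(p1$proteins, p3$proteins))
  td <- p1$truth$planted_domains
  for (i in seq_len(nrow(td))) {
    rule <- rs$subtypes[[td$subtype[i]]]
    gaps <- diff(as.integer(td[i, paste0("p", 1:8)])) - 1L
    expect_true(all(gaps >= rule$gaps[, 1] & gaps <= rule$gaps[, 2]))
    res <- as.character(td[i, paste0("r", 1:8)])
    expect_true(all(mapply(function(r, set) r %in% set, res, rule$residues)))
  }
})

test_that("a single planted domain is recovered; four domains get four truth rows", {
  one <- gen_proteome(rs, 1, domain_plan = list("RING-H2"), seed = 7)
  expect_equal(nrow(one$truth$planted_domains), 1)
  h <- scan_proteome(one$proteins, rs)
  h <- h[h$subtype != "INCOMPLETE", ]
  expect_equal(h$start, one$truth$planted_domains$start)
  expect_equal(h$subtype, "RING-H2")

  four <- gen_proteome(rs, 1, domain_plan = list(rep("RING-H2", 4)), seed = 8)
  expect_equal(nrow(four$truth$planted_domains), 4)
  expect_equal(unique(four$truth$planted_domains$protein_id), "P0001")
})

test_that("generator errors on infeasible or unknown plans", {
  expect_error(gen_proteome(rs, 2, domain_plan = c("RING-Z" = 1), seed = 1),
               "unknown subtype")
  expect_error(gen_proteome(rs, 1, domain_plan = c("RING-H2" = 3), seed = 1),
               "n_proteins")
})

test_that("expression generator realizes the Venn spec exactly", {
  spec <- c(10, 4, 3, 2, 5, 1, 0)
  ex <- gen_expression(spec, n_silent = 6, seed = 3)
  vp <- venn_partition(call_expressed(ex$matrix, 0.5))
  expect_equal(unname(vp$counts), spec)
  expect_equal(vp$total_expressed, sum(spec))
  expect_equal(nrow(ex$matrix), sum(spec) + 6)

  z <- gen_expression(rep(0, 7), n_silent = 10, seed = 1)
  expect_equal(venn_partition(call_expressed(z$matrix, 0.5))$total_expressed, 0)

  one <- gen_expression(c(1, 0, 0, 0, 0, 0, 0), seed = 1)
  vp1 <- venn_partition(call_expressed(one$matrix, 0.5))
  expect_equal(unname(vp1$counts["all3"]), 1)

  expect_error(gen_expression(c(-1, 0, 0, 0, 0, 0, 0)), "non-negative")
  expect_identical(gen_expression(spec, 6, seed = 9), gen_expression(spec, 6, seed = 9))
})

test_that("qPCR generator is Livak-invertible and noise degrades gracefully", {
  plan <- data.frame(gene = "Q1", genotype = "TAC75", stage = c(7, 14, 21, 28),
                     log2fc = c(0, 0, 0, 0))
  q <- gen_qpcr(plan, noise_sd = 0, seed = 1)
  for (s in c(7, 14, 21, 28)) {
    expect_equal(ddct(q$table, "Q1", "TAC75", "C306", s)$log2fc, 0)
  }
  plan$log2fc <- 2.81  # roughly seven-fold
  q2 <- gen_qpcr(plan, noise_sd = 0, seed = 1)
  expect_equal(ddct(q2$table, "Q1", "TAC75", "C306", 14)$log2fc, 2.81,
               tolerance = 1e-12)
  # noisy recovery: mean absolute error stays well under 3 * noise_sd
  set.seed(1)
  plan36 <- ringminer:::gen_qpcr_plan(36, 8, 3, seed = 1)
  errs <- vapply(1:20, function(k) {
    qn <- gen_qpcr(plan36, noise_sd = 0.1, replicates = 3, seed = k)
    prof <- fc_profiles(qn$table, "TAC75", "C306")
    truth <- plan36$log2fc[match(paste(prof$gene, prof$stage),
                                 paste(plan36$gene, plan36$stage))]
    mean(abs(prof$log2fc - truth))
  }, 1)
  expect_lt(mean(errs), 0.3)
})

test_that("gene-map generator rejects infeasible class plans", {
  expect_error(gen_gene_map(c(WGD_segmental = 9)), "even")
  expect_error(gen_gene_map(c(WGD_segmental = 6), params = dup_params(min_anchors = 5)),
               "min_anchors")
  expect_error(gen_gene_map(c(tandem = 1)), "donor")
  expect_error(gen_gene_map(c(badclass = 2)), "unknown duplication class")
})

test_that("variant generator plants single effects verifiably", {
  toy <- toy_gene_models(n_genes = 4, seed = 5)
  gv <- gen_variants(toy, c(missense = 1, frameshift = 3), seed = 2)
  ann <- annotate_variants(gv$variants, toy$models, toy$ref)
  expect_equal(sum(ann$category == "missense"), 1)
  expect_equal(sum(ann$category == "frameshift"), 3)
  fs <- gv$variants[gv$truth$category == "frameshift", ]
  indel_len <- abs(nchar(fs$ref) - nchar(fs$alt))
  expect_true(all(indel_len %% 3 != 0))
  expect_error(gen_variants(toy, c(nonsense_category = 1)), "no site pool")
})
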