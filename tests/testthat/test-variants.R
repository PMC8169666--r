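toy <- toy_gene_models(n_genes = 4, seed = 17)

test_that("canonical examples annotate to the expected category and impact", {
  # intergenic SNP far from any window
  g1 <- toy$models$genes[1, ]
  pos <- g1$end + 6000L
  v <- list(chrom = "chrV1", pos = pos,
            ref = substr(toy$ref[["chrV1"]], pos, pos), alt = "A")
  if (v$ref == "A") v$alt <- "C"
  a <- annotate_variant(v, toy$models, toy$ref)
  expect_identical(a$category, "intergenic")
  expect_identical(a$impact, "MODIFIER")

  # 1-bp deletion in the CDS: frameshift, HIGH
  gv <- gen_variants(toy, c(frameshift = 1), seed = 1)
  a2 <- annotate_variants(gv$variants, toy$models, toy$ref)
  expect_identical(a2$category, "frameshift")
  expect_identical(a2$impact, "HIGH")
  expect_identical(a2$type, "deletion")

  # SNP in the first two intron bases: splice_donor&intron, HIGH
  gv3 <- gen_variants(toy, c(`splice_donor&intron` = 2), seed = 2)
  a3 <- annotate_variants(gv3$variants, toy$models, toy$ref)
  expect_true(all(a3$category == "splice_donor&intron"))
  expect_true(all(a3$impact == "HIGH"))

  # 3-bp insertion at a codon boundary: conservative inframe, MODERATE
  info <- ringminer:::transcript_info(toy$models, toy$ref, "TG001")
  cds2 <- toy$models$cds[toy$models$cds$gene_id == "TG001", ]
  cds2 <- cds2[order(cds2$start), ][2, ]
  anchor <- Find(function(p) {
    o <- info$g2o(p)
    !is.na(o) && o %% 3 == 0
  }, (cds2$start + 10):(cds2$end - 10))
  rb <- substr(toy$ref[["chrV1"]], anchor, anchor)
  a4 <- annotate_variant(list(chrom = "chrV1", pos = anchor, ref = rb,
                              alt = paste0(rb, "GGG")),
                         toy$models, toy$ref)
  expect_identical(a4$category, "conservative_inframe_insertion")
  expect_identical(a4$impact, "MODERATE")
})

test_that("variant validation errors are explicit", {
  expect_error(annotate_variant(list(chrom = "chrBad", pos = 5, ref = "A", alt = "T"),
                                toy$models, toy$ref), "unknown chromosome")
  expect_error(annotate_variant(list(chrom = "chrV1", pos = 10^9, ref = "A", alt = "T"),
                                toy$models, toy$ref), "outside the reference")
  expect_error(annotate_variant(list(chrom = "chrV1", pos = 5, ref = "A", alt = "A"),
                                toy$models, toy$ref), "identical")
  bad_cds <- toy$models
  bad_cds$cds$end[1] <- bad_cds$cds$end[1] + 1L
  expect_error(gene_models(bad_cds$genes, bad_cds$exons, bad_cds$cds),
               "CDS phase")
})

test_that("a planted multi-category plan is reproduced exactly", {
  plan <- c(intergenic = 5, upstream_gene = 4, downstream_gene = 3,
            `3_prime_UTR` = 2, `5_prime_UTR` = 2,
            `5_prime_UTR_premature_start_codon_gain` = 2,
            intron = 6, `splice_donor&intron` = 2, `splice_acceptor&intron` = 2,
            `splice_region&intron` = 3, `splice_donor&splice_region&intron` = 1,
            missense = 4, synonymous = 4, `missense&splice_region` = 2,
            frameshift = 2, `frameshift&splice_region` = 1,
            conservative_inframe_deletion = 2, disruptive_inframe_insertion = 2,
            `disruptive_inframe_insertion&splice_region` = 1)
  gv <- gen_variants(toy, plan, seed = 3)
  ann <- annotate_variants(gv$variants, toy$models, toy$ref)
  expect_identical(ann$category[match(gv$truth$id, ann$id)], gv$truth$category)
  ds <- distribution_summary(ann)
  expect_equal(ds$total, sum(plan))
  got <- stats::setNames(ds$by_category$n, ds$by_category$category)
  expect_equal(got[names(plan)], plan, ignore_attr = TRUE)
  # percentages sum to ~100 within rounding slack
  expect_lt(abs(sum(ds$by_category$pct) - 100), 0.1 * nrow(ds$by_category))
})

test_that("coding calls match the translate-and-diff oracle", {
  plan <- c(missense = 6, synonymous = 6, frameshift = 4,
            conservative_inframe_deletion = 2, disruptive_inframe_insertion = 2)
  gv <- gen_variants(toy, plan, seed = 9)
  ann <- annotate_variants(gv$variants, toy$models, toy$ref)
  for (i in seq_len(nrow(gv$variants))) {
    got <- ann$primary[ann$id == gv$variants$id[i]]
    exp <- oracle_coding_effect(gv$variants[i, ], toy)
    if (exp == "inframe") {
      expect_match(got, "inframe")
    } else {
      expect_identical(got, exp)
    }
  }
})

test_that("SNP categories are invariant under reverse-complementing the genome", {
  plan <- c(missense = 3, synonymous = 3, intron = 3,
            `splice_donor&intron` = 2, `splice_acceptor&intron` = 2,
            `3_prime_UTR` = 2, upstream_gene = 2, intergenic = 2)
  gv <- gen_variants(toy, plan, seed = 11)
  ann <- annotate_variants(gv$variants, toy$models, toy$ref)

  L <- nchar(toy$ref[["chrV1"]])
  flip_pos <- function(s, e) c(L - e + 1L, L - s + 1L)
  rc_models <- toy$models
  for (part in c("genes", "exons", "cds")) {
    se <- t(mapply(flip_pos, rc_models[[part]]$start, rc_models[[part]]$end))
    rc_models[[part]]$start <- se[, 1]
    rc_models[[part]]$end <- se[, 2]
  }
  rc_models$genes$strand <- ifelse(rc_models$genes$strand == "+", "-", "+")
  rc_ref <- c(chrV1 = ringminer:::revcomp(toy$ref[["chrV1"]]))
  rc_var <- gv$variants
  rc_var$pos <- L - rc_var$pos + 1L
  rc_var$ref <- chartr("ACGT", "TGCA", rc_var$ref)
  rc_var$alt <- chartr("ACGT", "TGCA", rc_var$alt)
  ann_rc <- annotate_variants(rc_var, rc_models, rc_ref)
  expect_identical(ann_rc$category[match(gv$variants$id, ann_rc$id)],
                   ann$category[match(gv$variants$id, ann$id)])
})

test_that("empty input summarizes to zeros and VCF round-trips", {
  ds <- distribution_summary(NULL)
  expect_equal(ds$total, 0)
  expect_equal(sum(ds$by_impact), 0)

  gv <- gen_variants(toy, c(missense = 2, frameshift = 1), seed = 5)
  f <- tempfile(fileext = ".vcf")
  write_vcf_lite(gv$variants, f)
  back <- read_vcf_lite(f)
  expect_equal(back$pos, gv$variants$pos)
  expect_equal(back$ref, gv$variants$ref)
})
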