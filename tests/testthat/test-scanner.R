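rs <- default_ruleset()

test_that("a planted canonical chain is found exactly once at its positions", {
  # C-x2-C-x12-C-x2-H-x3-H-x2-C-x10-C-x2-C
  s <- mk_chain(H2_RES, c(2, 12, 2, 3, 2, 10, 2), lead = 10)
  h <- scan_domains(s, rs)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 11)
  expect_equal(h$span, 8 + sum(c(2, 12, 2, 3, 2, 10, 2)))  # 41 residues
  expect_equal(unlist(h[1, paste0("p", 1:8)], use.names = FALSE),
               11 + cumsum(c(0, c(2, 12, 2, 3, 2, 10, 2) + 1)))
  # brute-force enumeration agrees and confirms uniqueness
  expect_equal(nrow(oracle_scan_complete(s, rs)), 1)
})

test_that("degenerate inputs behave as documented", {
  expect_equal(nrow(scan_domains(paste(rep("ALMA", 30), collapse = ""), rs)), 0)
  expect_equal(nrow(scan_domains("", rs)), 0)
  expect_error(scan_domains("ACD-EF", rs), "non amino-acid")
  # X occupies space but never matches a ligand
  s <- mk_chain(H2_RES, VALID_GAPS)
  sx <- chartr("C", "X", s)
  expect_equal(nrow(scan_domains(sx, rs)), 0)
})

test_that("two non-overlapping planted chains are returned ordered by start", {
  one <- mk_chain(H2_RES, VALID_GAPS, lead = 5, trail = 0)
  two <- mk_chain(HC_RES, VALID_GAPS, lead = 110, trail = 5)
  h <- scan_domains(paste0(one, two), rs)
  expect_equal(nrow(h), 2)
  expect_true(h$start[1] < h$start[2])
  cl <- classify_hits(h, rs)
  expect_identical(cl$subtype, c("RING-H2", "RING-HC"))
})

test_that("classification assigns subtypes, RBX flag and INCOMPLETE correctly", {
  g <- c(2, 12, 2, 3, 2, 10, 2)
  expect_identical(classify_hit(c("C","C","C","H","H","C","C","C"), g, rs)$subtype,
                   "RING-H2")
  expect_identical(classify_hit(c("C","C","C","H","C","C","C","C"), g, rs)$subtype,
                   "RING-HC")
  rbx <- classify_hit(c("C","C","C","H","H","C","C","D"), g, rs)
  expect_identical(rbx$subtype, "RING-H2")
  expect_true(rbx$rbx)
  inc <- classify_hit(c("C","C","C","H","H","C","C","A"), g, rs)
  expect_identical(inc$subtype, "INCOMPLETE")
  expect_identical(inc$missing_ligands, 8L)
  # gaps valid only for the RING-v rule but residues matching RING-H2:
  # no subtype fits; ligand slots all match the best gap-consistent rule
  vgaps <- c(2, 12, 2, 1, 2, 3, 2)
  cl <- classify_hit(c("C","C","C","C","H","C","C","C"), vgaps, rs)
  expect_identical(cl$subtype, "RING-v")
})

test_that("multi-domain proteins get alphabetic suffixes in start order", {
  h <- data.frame(protein_id = c("P1", "P2", "P2", "P3", "P3", "P3", "P3"),
                  start = c(5, 90, 10, 40, 10, 70, 100))
  out <- assign_domain_names(h)
  expect_identical(out$domain_name[out$protein_id == "P1"], "P1")
  expect_identical(sort(out$domain_name[out$protein_id == "P2"]), c("P2a", "P2b"))
  expect_identical(out$domain_name[out$protein_id == "P2" & out$start == 10], "P2a")
  expect_identical(sort(out$domain_name[out$protein_id == "P3"]),
                   c("P3a", "P3b", "P3c", "P3d"))
})

test_that("group summaries compute half-up percentages over classified domains", {
  sg <- summarize_groups(c("RING-H2" = 875, "RING-HC" = 323,
                           "RING-v" = 67, "RING-G" = 7))
  expect_equal(unname(sg$percentages), c(68.79, 25.39, 5.27, 0.55))
  expect_equal(sg$total_domains, 1272)
  single <- data.frame(protein_id = "P1", subtype = "RING-H2")
  sg1 <- summarize_groups(single, total_proteins = 1)
  expect_equal(unname(sg1$percentages), 100)
  expect_warning(sg0 <- summarize_groups(c("RING-H2" = 0)), "no classified")
  expect_equal(unname(sg0$percentages), 0)
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(42)
  rs_drop <- rs
  rs_drop$incomplete_policy <- "drop"
  for (i in 1:40) {
    s <- random_protein(sample(30:200, 1))
    got <- scan_domains(s, rs_drop)
    exp <- oracle_scan_complete(s, rs_drop)
    expect_equal(nrow(got), nrow(exp))
    if (nrow(got)) {
      expect_equal(unname(as.matrix(got[, paste0("p", 1:8)])),
                   unname(exp), ignore_attr = TRUE)
    }
  }
})

test_that("widening a gap range never decreases the number of hits", {
  set.seed(7)
  seqs <- replicate(15, random_protein(150))
  wide <- default_ruleset()
  for (nm in names(wide$subtypes)) {
    wide$subtypes[[nm]]$gaps[2, 2] <- 45L   # widen ML2-ML3
    wide$subtypes[[nm]]$gaps[6, 1] <- 2L    # widen ML6-ML7
  }
  for (s in seqs) {
    expect_gte(nrow(scan_domains(s, wide)), nrow(scan_domains(s, rs)))
  }
})

test_that("classified spans respect the feasible range", {
  # minimal-gap chain spans exactly 30 residues
  smin <- mk_chain(H2_RES, c(2, 9, 1, 2, 2, 4, 2))
  h <- scan_domains(smin, rs)
  expect_equal(h$span, 30)
  # a chain whose gaps are legal but whose span exceeds the cap is never
  # reported as a complete domain
  stoolong <- mk_chain(H2_RES, c(2, 39, 3, 3, 2, 48, 2))  # span 107 > 102
  h2 <- scan_domains(stoolong, rs)
  expect_equal(sum(h2$n_matched == 8), 0)
})

test_that("classified plus incomplete hits partition all emitted hits", {
  set.seed(11)
  prot <- gen_proteome(rs, 30, domain_plan = c("RING-H2" = 10, "RING-HC" = 5),
                       decoy_rate = 0.5, seed = 99)
  hits <- scan_proteome(prot$proteins, rs)
  n_inc <- sum(hits$subtype == "INCOMPLETE")
  n_cls <- sum(hits$subtype != "INCOMPLETE")
  expect_equal(n_inc + n_cls, nrow(hits))
  expect_false(any(hits$subtype == "INCOMPLETE" & hits$n_matched == 8 &
                     hits$rbx))
  # no hit carries two labels and every hit has one
  expect_true(all(nchar(hits$subtype) > 0))
})
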