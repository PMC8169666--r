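# End-to-end pipeline orchestration over the synthetic study conditions,
# plus the arithmetic consistency checker for printed count partitions.

#' Default pipeline configuration
#'
#' The defaults reproduce the study conditions of the wheat RING family
#' analysis: subtype plan 875/323/67/7 over 1255 proteins (12 proteins with
#' two domains, one each with three and four), duplication plan
#' 4/49/15/90/1080 over 21 chromosomes, the 7-region Venn specification
#' (306, 22, 3, 156, 152, 5, 54) with 557 silent genes, a 36-gene qPCR
#' panel with 8 down- and 3 up-regulated candidates, the two mutant-line
#' variant plans, and a correlation panel with per-target sets of 7 and 8
#' overlapping in 5. `scale` (0 < scale <= 1) shrinks the proteome and gene
#' map proportionally for quick runs.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param scale optional down-scaling of the proteome/gene-map stages.
#' @return named list of stage configurations.
#' @export
pipeline_config <- function(seed = 1L, scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  sc <- function(x) {
    out <- pmax(as.integer(round(x * scale)), 1L)
    stats::setNames(out, names(x))
  }
  domain_counts <- c("RING-H2" = 875L, "RING-HC" = 323L,
                     "RING-v" = 67L, "RING-G" = 7L)
  dup_plan <- c(singleton = 4L, dispersed = 49L, proximal = 15L, tandem = 90L,
                WGD_segmental = 1080L)
  if (scale < 1) {
    domain_counts <- sc(domain_counts)
    dup_plan <- sc(dup_plan)
    dup_plan["WGD_segmental"] <- max(2L * (dup_plan[["WGD_segmental"]] %/% 2L), 10L)
    dup_plan["dispersed"] <- 2L * (dup_plan[["dispersed"]] %/% 2L)
    dup_plan["proximal"] <- 2L * (dup_plan[["proximal"]] %/% 2L)
    dup_plan["tandem"] <- 2L * (dup_plan[["tandem"]] %/% 2L)
  }
  list(
    seed = as.integer(seed),
    scan = list(domain_counts = domain_counts,
                multi_domain = c(two = 12L, three = 1L, four = 1L),
                decoy_rate = 0),
    dup = list(class_plan = dup_plan, n_chroms = 21L),
    expression = list(venn_spec = c(306L, 22L, 3L, 156L, 152L, 5L, 54L),
                      n_silent = 557L, threshold = 0.5),
    deg = list(n_group1 = 9L, n_group2 = 6L, n_tested = 698L),
    qpcr = list(n_genes = 36L, n_down = 8L, n_up = 3L, replicates = 3L,
                noise_sd = 0),
    variants = list(plan_tac75 = NULL, plan_tac6 = NULL),  # filled by run_pipeline
    correlation = list(n_genes = 36L, n_a = 7L, n_b = 8L, n_overlap = 5L)
  )
}

# The two mutant-line variant effect plans (region-category counts).
variant_plans <- function() {
  cats <- c("3_prime_UTR", "5_prime_UTR_premature_start_codon_gain",
            "5_prime_UTR", "conservative_inframe_deletion",
            "disruptive_inframe_insertion",
            "disruptive_inframe_insertion&splice_region", "downstream_gene",
            "frameshift", "frameshift&splice_region", "intergenic", "intron",
            "missense", "missense&splice_region", "splice_acceptor&intron",
            "splice_donor&intron", "splice_donor&splice_region&intron",
            "splice_region&intron", "synonymous", "upstream_gene")
  list(TAC75 = stats::setNames(c(18L, 1L, 2L, 0L, 1L, 1L, 32L, 3L, 0L, 133L,
                                 53L, 18L, 1L, 16L, 7L, 0L, 19L, 33L, 119L), cats),
       TAC6 = stats::setNames(c(17L, 2L, 14L, 1L, 1L, 0L, 48L, 4L, 1L, 191L,
                                105L, 24L, 0L, 9L, 7L, 2L, 18L, 35L, 188L), cats))
}

# Build the proteome domain plan (per-protein subtype lists) from subtype
# counts and a multi-domain allocation.
build_domain_plan <- function(domain_counts, multi_domain) {
  pool <- unlist(mapply(rep, names(domain_counts), domain_counts,
                        SIMPLIFY = FALSE), use.names = FALSE)
  n_multi_domains <- 2L * multi_domain[["two"]] + 3L * multi_domain[["three"]] +
    4L * multi_domain[["four"]]
  if (n_multi_domains > length(pool)) abort("multi-domain plan exceeds domain counts")
  plan <- list()
  take <- function(k) {
    got <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    got
  }
  for (i in seq_len(multi_domain[["four"]])) plan <- c(plan, list(take(4L)))
  for (i in seq_len(multi_domain[["three"]])) plan <- c(plan, list(take(3L)))
  for (i in seq_len(multi_domain[["two"]])) plan <- c(plan, list(take(2L)))
  plan <- c(plan, lapply(pool, identity))
  plan
}

# Synthetic DEG table: n1/n2 passing records per group among n_tested genes.
gen_deg_table <- function(n_group1, n_group2, n_tested, seed = 1L) {
  with_seed(seed, {
    genes <- sprintf("D%05d", seq_len(n_tested))
    mk <- function(group, n_pass) {
      pass_idx <- sample(n_tested, n_pass)
      log2fc <- stats::runif(n_tested, -0.9, 0.9)
      pvalue <- stats::runif(n_tested, 0.06, 1)
      log2fc[pass_idx] <- sample(c(-1, 1), n_pass, TRUE) * stats::runif(n_pass, 1.1, 3.5)
      pvalue[pass_idx] <- stats::runif(n_pass, 0, 0.05)
      data.frame(gene = genes, group = group, log2fc = log2fc, pvalue = pvalue,
                 stringsAsFactors = FALSE)
    }
    rbind(mk("Group1", n_group1), mk("Group2", n_group2))
  })
}

# Planted qPCR fold-change profiles: n_down consistent-down and n_up
# consistent-up candidate genes (strong at >= 2 stages), the rest mixed.
gen_qpcr_plan <- function(n_genes, n_down, n_up, stages = c(7, 14, 21, 28),
                          genotype = "TAC75", seed = 1L) {
  with_seed(seed, {
    genes <- sprintf("Q%03d", seq_len(n_genes))
    rows <- lapply(seq_len(n_genes), function(i) {
      fc <- if (i <= n_down) {
        -c(stats::runif(2, 2.2, 3.5), stats::runif(2, 0.4, 1.8))
      } else if (i <= n_down + n_up) {
        c(stats::runif(2, 2.2, 3.5), stats::runif(2, 0.4, 1.8))
      } else {
        c(stats::runif(1, 0.3, 1.5), -stats::runif(1, 0.3, 1.5),
          stats::runif(2, -1, 1))
      }
      data.frame(gene = genes[i], genotype = genotype, stage = stages,
                 log2fc = fc, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Run the full synthetic pipeline
#'
#' Executes every stage over generated inputs with planted truth: proteome
#' scan and subtype summary; duplication classification; expression Venn,
#' clustering and DEG filter; qPCR candidate screen; variant annotation for
#' both mutant lines; correlation screen. Returns one report with every
#' count and percentage, plus the planted-truth consistency ledger.
#'
#' @param config a [pipeline_config()] list.
#' @param out_dir optional directory for the JSON report and stage TSVs.
#' @param ruleset rule set for the scan stage.
#' @param quiet suppress progress messages.
#' @return report list (invisibly writes `report.json` and TSVs when
#'   `out_dir` is given).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         ruleset = default_ruleset(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed
  report <- list()
  t0 <- proc.time()[["elapsed"]]
  stage_time <- function(label) {
    t1 <- proc.time()[["elapsed"]]
    say("[%s] done in %.1fs", label, t1 - t0)
    t0 <<- t1
  }

  # --- RING scan ---
  plan <- build_domain_plan(config$scan$domain_counts, config$scan$multi_domain)
  prot <- gen_proteome(ruleset, n_proteins = length(plan), domain_plan = plan,
                       decoy_rate = config$scan$decoy_rate, seed = seed)
  hits <- scan_proteome(prot$proteins, ruleset)
  summary_groups <- summarize_groups(hits, total_proteins = length(prot$proteins))
  report$scan <- list(counts = as.list(summary_groups$counts),
                      percentages = as.list(summary_groups$percentages),
                      total_domains = summary_groups$total_domains,
                      total_proteins = length(prot$proteins))
  stage_time("scan")

  # --- duplication classes ---
  map <- gen_gene_map(config$dup$class_plan, n_chroms = config$dup$n_chroms,
                      seed = seed + 1L)
  fam <- map$loci[map$loci$gene_id %in% map$family_genes, , drop = FALSE]
  blocks <- chain_collinear_blocks(map$pairs, map$loci)
  calls <- classify_duplications(fam, map$pairs, blocks, all_loci = map$loci)
  report$duplication <- as.list(duplication_class_counts(calls))
  report$duplication$total <- nrow(fam)
  stage_time("duplication")

  # --- expression ---
  ex <- gen_expression(config$expression$venn_spec, config$expression$n_silent,
                       threshold = config$expression$threshold, seed = seed + 2L)
  vp <- venn_partition(call_expressed(ex$matrix, config$expression$threshold))
  expressed <- ex$matrix[rowSums(call_expressed(ex$matrix,
                                                config$expression$threshold)) > 0, ,
                         drop = FALSE]
  groups <- expression_groups(expressed)
  deg <- gen_deg_table(config$deg$n_group1, config$deg$n_group2,
                       config$deg$n_tested, seed = seed + 3L)
  kept <- deg_filter(deg)
  report$expression <- list(venn = as.list(vp$counts),
                            total_expressed = vp$total_expressed,
                            silent = nrow(ex$matrix) - vp$total_expressed,
                            cluster_sizes = as.list(table(groups$group)),
                            deg_kept = nrow(kept),
                            deg_by_group = as.list(table(kept$group)))
  stage_time("expression")

  # --- qPCR candidates ---
  qplan <- gen_qpcr_plan(config$qpcr$n_genes, config$qpcr$n_down,
                         config$qpcr$n_up, seed = seed + 4L)
  q <- gen_qpcr(qplan, noise_sd = config$qpcr$noise_sd,
                replicates = config$qpcr$replicates, seed = seed + 5L)
  prof <- fc_profiles(q$table, mutant = "TAC75", control = "C306")
  cand <- count_candidates(prof)
  report$qpcr <- list(n_down = cand$n_down, n_up = cand$n_up,
                      n_candidates = cand$n_down + cand$n_up)
  stage_time("qpcr")

  # --- variants ---
  toy <- toy_gene_models(seed = seed + 6L)
  plans <- variant_plans()
  report$variants <- list()
  for (line in names(plans)) {
    gv <- gen_variants(toy, plans[[line]], seed = seed + 7L + match(line, names(plans)))
    ann <- annotate_variants(gv$variants, toy$models, toy$ref)
    ds <- distribution_summary(ann, digits = 2)
    report$variants[[line]] <- list(total = ds$total,
                                    by_impact = as.list(ds$by_impact),
                                    by_category = ds$by_category)
  }
  stage_time("variants")

  # --- correlation screen ---
  panel <- gen_correlation_panel(config$correlation$n_genes,
                                 config$correlation$n_a, config$correlation$n_b,
                                 config$correlation$n_overlap, seed = seed + 10L)
  say("correlating over 4 stage means (2 df); low power is inherent to the design")
  res <- suppressWarnings(correlation_screen(panel$expr))
  sel <- select_correlated_candidates(res)
  report$correlation <- list(n_a = sel$n_a, n_b = sel$n_b,
                             n_overlap = sel$n_overlap, n_union = sel$n_union)
  stage_time("correlation")

  report$consistency <- consistency_report(list(
    list(name = "subtype_groups", parts = summary_groups$counts,
         total = summary_groups$total_domains),
    list(name = "duplication_classes", parts = duplication_class_counts(calls),
         total = nrow(fam)),
    list(name = "venn_regions", parts = vp$counts, total = vp$total_expressed)
  ))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_tsv_file(hits, file.path(out_dir, "ring_hits.tsv"))
    write_tsv_file(calls, file.path(out_dir, "duplication_calls.tsv"))
    write_tsv_file(groups, file.path(out_dir, "expression_groups.tsv"))
    write_tsv_file(prof, file.path(out_dir, "qpcr_profiles.tsv"))
    write_tsv_file(res, file.path(out_dir, "correlation_results.tsv"))
  }
  report
}

#' Check count partitions and printed percentages for arithmetic consistency
#'
#' Each entry of `groups` is a list with `name`, `parts` (named numeric
#' vector), `total`, and optionally `percentages`: a data frame with
#' columns `part`, `printed`, `digits` giving a printed percentage to verify
#' against `round_half_up(100 * parts[part] / total, digits)`.
#'
#' @param groups list of partition descriptions.
#' @return data frame ledger with `name`, `check`, `expected`, `got`,
#'   `pass`, `delta`.
#' @export
consistency_report <- function(groups) {
  rows <- list()
  for (g in groups) {
    got <- sum(g$parts)
    rows[[length(rows) + 1L]] <- data.frame(
      name = g$name, check = "partition_sum", expected = g$total, got = got,
      pass = got == g$total, delta = got - g$total, stringsAsFactors = FALSE)
    if (!is.null(g$percentages)) {
      for (i in seq_len(nrow(g$percentages))) {
        p <- g$percentages[i, ]
        got_pct <- round_half_up(100 * g$parts[[p$part]] / g$total, p$digits)
        rows[[length(rows) + 1L]] <- data.frame(
          name = g$name, check = paste0("pct_", p$part), expected = p$printed,
          got = got_pct, pass = isTRUE(all.equal(got_pct, p$printed)),
          delta = got_pct - p$printed, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
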