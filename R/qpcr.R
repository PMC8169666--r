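# Livak delta-delta-Ct fold changes and candidate screening from qRT-PCR
# Ct tables.
#
# A Ct table is a long data frame with columns gene, genotype, stage,
# biorep, techrep, ct. Replicates are aggregated as: mean of technical
# replicates within a biological replicate, then mean over biological
# replicates; the SD is taken over per-biological-replicate ddCt values.

ct_cell <- function(table, gene, genotype, stage) {
  rows <- table[table$gene == gene & table$genotype == genotype &
                  table$stage == stage, , drop = FALSE]
  if (!nrow(rows)) {
    abort("missing Ct cell: gene=%s genotype=%s stage=%s", gene, genotype, stage)
  }
  per_bio <- tapply(rows$ct, rows$biorep, mean)   # mean of techreps
  per_bio
}

#' Delta-delta-Ct log2 fold change
#'
#' Livak method: `log2FC = -[(Ct_target,mut - Ct_ref,mut) -
#' (Ct_target,ctl - Ct_ref,ctl)]`, with technical replicates averaged within
#' each biological replicate first. The SD is computed over biological
#' replicates (each contributing its own ddCt); bioreps must be shared
#' across the four cells for the SD (otherwise only the point estimate is
#' returned).
#'
#' @param table long Ct table (`gene, genotype, stage, biorep, techrep, ct`).
#' @param gene target gene.
#' @param mutant,control genotype labels of the comparison.
#' @param stage stage label.
#' @param ref_gene reference (internal-control) gene, e.g. `ARF`.
#' @return list with `log2fc`, `sd`, `n_bioreps`.
#' @export
ddct <- function(table, gene, mutant, control, stage, ref_gene = "ARF") {
  tm <- ct_cell(table, gene, mutant, stage)
  rm_ <- ct_cell(table, ref_gene, mutant, stage)
  tc <- ct_cell(table, gene, control, stage)
  rc <- ct_cell(table, ref_gene, control, stage)
  est <- -((mean(tm) - mean(rm_)) - (mean(tc) - mean(rc)))
  common <- Reduce(intersect, list(names(tm), names(rm_), names(tc), names(rc)))
  sd_val <- if (length(common) >= 2) {
    stats::sd(-((tm[common] - rm_[common]) - (tc[common] - rc[common])))
  } else NA_real_
  list(log2fc = est, sd = sd_val, n_bioreps = length(common))
}

#' Per-gene, per-stage fold-change profiles
#'
#' Runs [ddct()] for every target gene and stage of one mutant-vs-control
#' comparison.
#'
#' @param table long Ct table.
#' @param mutant,control genotype labels.
#' @param genes target genes (default: all genes except the reference).
#' @param stages stage labels (default: all stages in the table, in order of
#'   appearance).
#' @param ref_gene reference gene.
#' @return data frame `gene, stage, log2fc, sd`.
#' @export
fc_profiles <- function(table, mutant, control, genes = NULL, stages = NULL,
                        ref_gene = "ARF") {
  if (is.null(genes)) genes <- setdiff(unique(table$gene), ref_gene)
  if (is.null(stages)) stages <- unique(table$stage)
  out <- expand.grid(gene = genes, stage = stages, stringsAsFactors = FALSE)
  res <- mapply(function(g, s) {
    d <- ddct(table, g, mutant, control, s, ref_gene)
    c(d$log2fc, d$sd)
  }, out$gene, out$stage)
  out$log2fc <- res[1, ]
  out$sd <- res[2, ]
  out[order(match(out$gene, genes), match(out$stage, stages)), , drop = FALSE]
}

#' Classify a fold-change profile
#'
#' A profile is a candidate when its log2 fold changes have a consistent
#' sign at all stages and reach `magnitude_min` in absolute value at at
#' least `min_strong_stages` stages; consistent-sign profiles below the
#' magnitude rule are `consistent_only`; anything else (including exact
#' zeros) is `mixed`.
#'
#' @param log2fc numeric vector of per-stage log2 fold changes.
#' @param magnitude_min strong-stage magnitude bound (default 2, i.e.
#'   four-fold).
#' @param min_strong_stages number of stages required at the bound.
#' @return one of `down_candidate`, `up_candidate`, `consistent_only`,
#'   `mixed`.
#' @export
profile_classify <- function(log2fc, magnitude_min = 2, min_strong_stages = 2) {
  stopifnot(length(log2fc) >= 1, !anyNA(log2fc))
  if (all(log2fc > 0)) dir <- "up"
  else if (all(log2fc < 0)) dir <- "down"
  else return("mixed")
  strong <- sum(abs(log2fc) >= magnitude_min)
  if (strong >= min_strong_stages) paste0(dir, "_candidate") else "consistent_only"
}

#' Count candidate genes in a set of fold-change profiles
#'
#' @param profiles data frame from [fc_profiles()] (`gene, stage, log2fc`).
#' @param magnitude_min,min_strong_stages see [profile_classify()].
#' @return list with `n_down`, `n_up`, `down_ids`, `up_ids`, `status`
#'   (named vector over genes).
#' @export
count_candidates <- function(profiles, magnitude_min = 2, min_strong_stages = 2) {
  status <- vapply(split(profiles$log2fc, profiles$gene), profile_classify,
                   "", magnitude_min = magnitude_min,
                   min_strong_stages = min_strong_stages)
  list(n_down = sum(status == "down_candidate"),
       n_up = sum(status == "up_candidate"),
       down_ids = names(status)[status == "down_candidate"],
       up_ids = names(status)[status == "up_candidate"],
       status = status)
}

#' Generate a qRT-PCR Ct table with planted fold-change profiles
#'
#' The Ct model is Livak-invertible by construction:
#' `Ct_target = ref_gene_ct + base_offset(gene) - log2FC(gene, genotype,
#' stage)` with the fold-change component zero for the control genotype, the
#' reference gene constant at `ref_gene_ct`, and Gaussian noise (SD
#' `noise_sd`) added independently to every measurement. With `noise_sd = 0`
#' [ddct()] recovers the planted profiles exactly.
#'
#' @param fc_profiles data frame `gene, genotype, stage, log2fc` of planted
#'   per-stage log2 fold changes for each mutant genotype (stages default to
#'   7/14/21/28 DAA when a plain per-gene list is supplied).
#' @param ref_gene_ct Ct level of the reference gene.
#' @param noise_sd Gaussian replicate noise SD (cycles).
#' @param replicates biological replicates.
#' @param techreps technical replicates per biological replicate.
#' @param control control genotype label.
#' @param ref_gene reference gene label.
#' @param seed integer seed.
#' @return list with `table` (long Ct data frame) and `truth`
#'   (`fc_profiles`).
#' @export
gen_qpcr <- function(fc_profiles, ref_gene_ct = 20, noise_sd = 0,
                     replicates = 3L, techreps = 1L, control = "C306",
                     ref_gene = "ARF", seed = 1L) {
  stopifnot(is.data.frame(fc_profiles),
            all(c("gene", "genotype", "stage", "log2fc") %in% names(fc_profiles)),
            is_count(replicates, 1), is_count(techreps, 1), noise_sd >= 0)
  genes <- unique(fc_profiles$gene)
  genotypes <- c(control, unique(fc_profiles$genotype))
  stages <- unique(fc_profiles$stage)
  with_seed(seed, {
    base_offset <- stats::setNames(stats::runif(length(genes), 2, 8), genes)
    grid <- expand.grid(gene = c(ref_gene, genes), genotype = genotypes,
                        stage = stages, biorep = seq_len(replicates),
                        techrep = seq_len(techreps),
                        stringsAsFactors = FALSE)
    fc_key <- paste(fc_profiles$gene, fc_profiles$genotype, fc_profiles$stage)
    fc_of <- stats::setNames(fc_profiles$log2fc, fc_key)
    comp <- fc_of[paste(grid$gene, grid$genotype, grid$stage)]
    comp[is.na(comp)] <- 0                      # control genotype / reference gene
    base <- ifelse(grid$gene == ref_gene, 0, base_offset[grid$gene])
    grid$ct <- ref_gene_ct + base - comp +
      if (noise_sd > 0) stats::rnorm(nrow(grid), 0, noise_sd) else 0
    list(table = grid, truth = list(fc_profiles = fc_profiles))
  })
}
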