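# Independent oracles used by the property suites. Each re-derives the
# expected answer by a different route than the implementation (expand-and-
# filter enumeration, exhaustive chain search, full translate-and-diff).

# Brute-force RING scan: enumerate every complete 8-position ligand tuple by
# iterative cross-join over per-slot candidate positions, filter by the gap
# envelope and span, then apply the same greedy overlap resolution
# (leftmost start, shortest span).
oracle_scan_complete <- function(sequence, ruleset) {
  u <- ringminer:::ruleset_union(ruleset)
  chars <- strsplit(toupper(sequence), "")[[1]]
  cand <- lapply(1:8, function(s) which(chars %in% u$residues[[s]]))
  if (!length(cand[[1]])) return(matrix(integer(0), 0, 8))
  chains <- matrix(cand[[1]], ncol = 1)
  for (s in 2:8) {
    rows <- list()
    for (i in seq_len(nrow(chains))) {
      prev <- chains[i, s - 1]
      gap <- cand[[s]] - prev - 1L
      qs <- cand[[s]][gap >= u$gap_min[s - 1] & gap <= u$gap_max[s - 1]]
      for (q in qs) rows[[length(rows) + 1L]] <- c(chains[i, ], q)
    }
    if (!length(rows)) return(matrix(integer(0), 0, 8))
    chains <- do.call(rbind, rows)
  }
  span <- chains[, 8] - chains[, 1] + 1L
  chains <- chains[span <= ruleset$max_domain_span, , drop = FALSE]
  if (!nrow(chains)) return(chains)
  ord <- do.call(order, c(list(chains[, 1], chains[, 8] - chains[, 1]),
                          lapply(2:7, function(j) chains[, j])))
  chains <- chains[ord, , drop = FALSE]
  keep <- integer(0)
  occ <- matrix(integer(0), 0, 2)
  for (i in seq_len(nrow(chains))) {
    s <- chains[i, 1]; e <- chains[i, 8]
    if (!nrow(occ) || !any(s <= occ[, 2] & e >= occ[, 1])) {
      keep <- c(keep, i)
      occ <- rbind(occ, c(s, e))
    }
  }
  chains[keep, , drop = FALSE]
}

# Exhaustive collinear-chain search: depth-first enumeration of every valid
# chain in one chromosome-pair group, greedy longest-first extraction.
oracle_blocks <- function(pairs, loci, params) {
  anc <- ringminer:::anchor_table(pairs, loci)
  all_chains <- function(grp) {
    n <- nrow(grp)
    o <- order(grp$rank_a, grp$rank_b)
    ra <- grp$rank_a[o]; rb <- grp$rank_b[o]
    best <- list(len = 0L, chain = integer(0))
    extend <- function(chain, dir) {
      if (length(chain) > best$len) best <<- list(len = length(chain), chain = chain)
      i <- chain[length(chain)]
      for (j in seq_len(n)) {
        if (j <= i) next
        if (ra[j] <= ra[i] || ra[j] - ra[i] > params$max_anchor_rank_gap) next
        db <- dir * (rb[j] - rb[i])
        if (db <= 0 || db > params$max_anchor_rank_gap) next
        extend(c(chain, j), dir)
      }
    }
    for (dir in c(1L, -1L)) for (i in seq_len(n)) extend(i, dir)
    o[best$chain]
  }
  blocks <- list()
  for (grp in split(anc, paste(anc$chrom_a, anc$chrom_b))) {
    while (nrow(grp) >= params$min_anchors) {
      chain <- all_chains(grp)
      if (length(chain) < params$min_anchors) break
      blocks[[length(blocks) + 1L]] <- grp[chain, , drop = FALSE]
      grp <- grp[-chain, , drop = FALSE]
    }
  }
  blocks
}

# Full translate-and-diff oracle for coding variants: apply the variant to
# the chromosome, shift downstream feature coordinates, rebuild and
# translate the CDS, and classify by comparing the two proteins.
oracle_coding_effect <- function(variant, toy) {
  models <- toy$models; ref <- toy$ref
  chrom <- variant$chrom
  pos <- variant$pos; refa <- variant$ref; alta <- variant$alt
  L <- nchar(alta) - nchar(refa)
  seqs <- ref[[chrom]]
  alt_seq <- paste0(substr(seqs, 1, pos - 1), alta,
                    substr(seqs, pos + nchar(refa), nchar(seqs)))
  shift <- function(x) ifelse(x > pos, x + L, x)
  alt_models <- models
  alt_models$genes$start <- shift(models$genes$start)
  alt_models$genes$end <- shift(models$genes$end)
  alt_models$exons$start <- shift(models$exons$start)
  alt_models$exons$end <- shift(models$exons$end)
  alt_models$cds$start <- shift(models$cds$start)
  alt_models$cds$end <- shift(models$cds$end)
  gid <- models$genes$gene_id[models$genes$start <= pos & models$genes$end >= pos]
  stopifnot(length(gid) == 1)
  ref_cds <- ringminer:::transcript_info(models, ref, gid)$cds_seq
  alt_ref <- stats::setNames(alt_seq, chrom)
  alt_cds <- tryCatch(
    ringminer:::transcript_info(alt_models, alt_ref, gid)$cds_seq,
    error = function(e) NULL)
  if (nchar(alt_cds) %% 3L != 0L) return("frameshift")
  tr <- function(s) as.character(Biostrings::translate(Biostrings::DNAString(s)))
  p_ref <- tr(ref_cds); p_alt <- tr(alt_cds)
  if (L == 0) {
    if (p_ref == p_alt) "synonymous" else "missense"
  } else {
    "inframe"
  }
}

# Evaluate an expression under a temporary RNG seed.
with_seed_int <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic random protein sequence over the full 20-letter alphabet.
random_protein <- function(len) {
  paste(sample(ringminer:::AA_ALPHABET20, len, replace = TRUE), collapse = "")
}
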