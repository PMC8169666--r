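# Chromosomal mapping and duplication-class analysis.
#
# Duplication classes follow the duplicate-gene-classifier convention:
# rank gaps are counted over all genes on a chromosome (family and
# non-family alike), and WGD/segmental evidence is a chain of collinear
# anchor pairs.

#' Duplication-classification parameters
#'
#' @param tandem_max_rank_gap maximum gene-rank gap for a tandem pair.
#' @param proximal_max_rank_gap maximum gene-rank gap for a proximal pair.
#' @param min_anchors minimum anchor pairs for a collinear block.
#' @param max_anchor_rank_gap maximum rank gap between consecutive anchors of
#'   a block, on both chromosomes.
#' @return validated list of class `dup_params`.
#' @export
dup_params <- function(tandem_max_rank_gap = 1L, proximal_max_rank_gap = 10L,
                       min_anchors = 5L, max_anchor_rank_gap = 25L) {
  stopifnot(is_count(tandem_max_rank_gap, 1), is_count(proximal_max_rank_gap, 1),
            is_count(min_anchors, 2), is_count(max_anchor_rank_gap, 1))
  if (tandem_max_rank_gap >= proximal_max_rank_gap) {
    abort("tandem_max_rank_gap must be < proximal_max_rank_gap")
  }
  structure(list(tandem_max_rank_gap = as.integer(tandem_max_rank_gap),
                 proximal_max_rank_gap = as.integer(proximal_max_rank_gap),
                 min_anchors = as.integer(min_anchors),
                 max_anchor_rank_gap = as.integer(max_anchor_rank_gap)),
            class = "dup_params")
}

#' Load gene loci from a GFF3 file
#'
#' Reads gene features, assigns per-chromosome ranks by ascending start
#' position, and flags genes on unassembled scaffolds (these are excluded
#' from downstream chromosome mapping but keep their records).
#'
#' @param gff path to a GFF3 file.
#' @param unplaced_pattern regular expression matching unassembled
#'   chromosome/scaffold names.
#' @return data frame with `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `rank`, `unplaced`.
#' @export
load_gene_loci <- function(gff, unplaced_pattern = "(?i)^(chrun|scaffold|un)") {
  gr <- rtracklayer::import(gff)
  gr <- gr[gr$type == "gene"]
  df <- data.frame(gene_id = gr$ID,
                   chromosome = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end)) {
    abort("gene record(s) with missing coordinates: rows %s",
          paste(which(is.na(df$start) | is.na(df$end)), collapse = ","))
  }
  if (nrow(df) == 0) {
    df$rank <- integer(0); df$unplaced <- logical(0)
    return(df)
  }
  df$unplaced <- grepl(unplaced_pattern, df$chromosome, perl = TRUE)
  df$rank <- stats::ave(df$start, df$chromosome,
                        FUN = function(x) rank(x, ties.method = "first"))
  df$rank <- as.integer(df$rank)
  df[order(df$chromosome, df$rank), , drop = FALSE]
}

#' Per-chromosome gene counts and percentages
#'
#' @param loci gene loci (unplaced genes are ignored).
#' @param digits decimals for the percentage (default 1, printed convention).
#' @return data frame with `chromosome`, `n`, `pct`.
#' @export
chrom_distribution <- function(loci, digits = 1) {
  loci <- loci[!isTRUE_vec(loci$unplaced), , drop = FALSE]
  stopifnot(nrow(loci) > 0)
  tab <- table(loci$chromosome)
  data.frame(chromosome = names(tab), n = as.integer(tab),
             pct = round_half_up(100 * as.integer(tab) / nrow(loci), digits),
             row.names = NULL, stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' Mean distance between adjacent family genes, per chromosome
#'
#' Mean of start-to-start distances between consecutive genes of the family
#' along each chromosome, in Mb. Chromosomes with fewer than two genes get
#' `NA`.
#'
#' @param loci gene loci of the family (unplaced genes ignored).
#' @param digits decimals for the reported value (default 1).
#' @return data frame with `chromosome`, `n_genes`, `mean_mb`.
#' @export
mean_adjacent_distance <- function(loci, digits = 1) {
  loci <- loci[!isTRUE_vec(loci$unplaced), , drop = FALSE]
  out <- lapply(split(loci, loci$chromosome), function(d) {
    mb <- if (nrow(d) < 2) NA_real_ else
      round_half_up(mean(diff(sort(d$start))) / 1e6, digits)
    data.frame(chromosome = d$chromosome[1], n_genes = nrow(d), mean_mb = mb,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Anchor table for a pair list: ranks/chromosomes of both genes, oriented so
# side A sorts before side B (by chromosome name, then rank).
anchor_table <- function(pairs, loci) {
  idx <- stats::setNames(seq_len(nrow(loci)), loci$gene_id)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(idx))
  if (length(missing)) {
    abort("pair(s) reference unknown gene(s): %s",
          paste(utils::head(missing, 5), collapse = ","))
  }
  ia <- idx[pairs$gene_a]; ib <- idx[pairs$gene_b]
  swap <- loci$chromosome[ia] > loci$chromosome[ib] |
    (loci$chromosome[ia] == loci$chromosome[ib] & loci$rank[ia] > loci$rank[ib])
  tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
  data.frame(gene_a = loci$gene_id[ia], gene_b = loci$gene_id[ib],
             chrom_a = loci$chromosome[ia], chrom_b = loci$chromosome[ib],
             rank_a = loci$rank[ia], rank_b = loci$rank[ib],
             stringsAsFactors = FALSE)
}

# Longest chain in one chrom-pair anchor group: strictly increasing rank_a,
# monotonic rank_b, consecutive rank gaps bounded on both sides. Returns row
# indices (into `anc`) of the lexicographically earliest longest chain,
# preferring the increasing-B direction on length ties.
longest_chain <- function(anc, max_gap) {
  n <- nrow(anc)
  o <- order(anc$rank_a, anc$rank_b)
  ra <- anc$rank_a[o]; rb <- anc$rank_b[o]
  best <- NULL
  for (dir in c(1L, -1L)) {
    f <- rep(1L, n)             # f[i]: longest chain starting at i
    nxt <- rep(NA_integer_, n)
    for (i in n:1) {
      for (j in seq_len(n)) {
        if (j <= i) next
        if (ra[j] <= ra[i] || ra[j] - ra[i] > max_gap) next
        db <- dir * (rb[j] - rb[i])
        if (db <= 0 || db > max_gap) next
        if (f[j] + 1L > f[i]) { f[i] <- f[j] + 1L; nxt[i] <- j }
      }
    }
    len <- max(f)
    # rebuild lexicographically earliest chain of maximal length
    chain <- integer(0); need <- len; prev <- NULL
    for (step in seq_len(len)) {
      cand <- which(f == need)
      if (!is.null(prev)) {
        ok <- vapply(cand, function(j) {
          j > prev && ra[j] > ra[prev] && ra[j] - ra[prev] <= max_gap &&
            dir * (rb[j] - rb[prev]) > 0 && dir * (rb[j] - rb[prev]) <= max_gap
        }, TRUE)
        cand <- cand[ok]
      }
      prev <- min(cand)
      chain <- c(chain, prev)
      need <- need - 1L
    }
    if (is.null(best) || length(chain) > length(best)) best <- o[chain]
  }
  best
}

#' Chain homolog pairs into collinear blocks
#'
#' Greedy extraction of collinear anchor chains: within each chromosome pair,
#' repeatedly take the longest chain of anchor pairs with strictly increasing
#' rank on one chromosome, monotonic rank on the other, and consecutive
#' anchors within `max_anchor_rank_gap` on both sides; chains shorter than
#' `min_anchors` are discarded and each anchor is consumed at most once.
#'
#' @param pairs data frame with `gene_a`, `gene_b`.
#' @param loci gene loci (all genes of the genome, for ranks).
#' @param params a [dup_params()] object.
#' @return data frame of block anchors: `block_id`, `chrom_a`, `chrom_b`,
#'   `gene_a`, `gene_b`, `rank_a`, `rank_b` (zero rows if no block).
#' @export
chain_collinear_blocks <- function(pairs, loci, params = dup_params()) {
  stopifnot(inherits(params, "dup_params"))
  empty <- data.frame(block_id = integer(0), chrom_a = character(0),
                      chrom_b = character(0), gene_a = character(0),
                      gene_b = character(0), rank_a = integer(0),
                      rank_b = integer(0), stringsAsFactors = FALSE)
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)
  anc <- anchor_table(pairs, loci)
  blocks <- list()
  bid <- 0L
  for (grp in split(anc, paste(anc$chrom_a, anc$chrom_b))) {
    while (nrow(grp) >= params$min_anchors) {
      chain <- longest_chain(grp, params$max_anchor_rank_gap)
      if (length(chain) < params$min_anchors) break
      bid <- bid + 1L
      blocks[[bid]] <- cbind(block_id = bid, grp[chain, , drop = FALSE])
      grp <- grp[-chain, , drop = FALSE]
    }
  }
  if (!length(blocks)) return(empty)
  out <- do.call(rbind, blocks)
  out <- out[, c("block_id", "chrom_a", "chrom_b", "gene_a", "gene_b",
                 "rank_a", "rank_b")]
  rownames(out) <- NULL
  out
}

#' Classify genes into duplication classes
#'
#' Priority per gene: any pair in a collinear block -> `WGD_segmental`; else
#' any same-chromosome pair with rank gap at most `tandem_max_rank_gap` ->
#' `tandem`; else rank gap at most `proximal_max_rank_gap` -> `proximal`;
#' else any pair -> `dispersed`; no pair -> `singleton`. Every gene in
#' `loci` receives exactly one class.
#'
#' @param loci loci of the genes to classify (typically the gene family,
#'   with ranks computed over the full genome by [load_gene_loci()]).
#' @param pairs homolog pair table (`gene_a`, `gene_b`); pairs may reference
#'   genes outside `loci` only if `all_loci` is supplied for rank lookup.
#' @param blocks collinear blocks from [chain_collinear_blocks()].
#' @param params a [dup_params()] object.
#' @param all_loci optional full gene set for rank lookups (defaults to
#'   `loci`).
#' @return data frame with `gene_id`, `class`, `evidence`.
#' @export
classify_duplications <- function(loci, pairs, blocks = NULL,
                                  params = dup_params(), all_loci = loci) {
  stopifnot(inherits(params, "dup_params"))
  if (is.null(blocks)) blocks <- chain_collinear_blocks(pairs, all_loci, params)
  block_genes <- unique(c(blocks$gene_a, blocks$gene_b))
  block_of <- c(stats::setNames(blocks$block_id, blocks$gene_a),
                stats::setNames(blocks$block_id, blocks$gene_b))
  has_pairs <- !is.null(pairs) && nrow(pairs) > 0
  if (has_pairs) anc <- anchor_table(pairs, all_loci)

  classify_one <- function(g) {
    if (g %in% block_genes) {
      return(c("WGD_segmental", sprintf("block_%d", block_of[[g]])))
    }
    if (has_pairs) {
      rows <- anc[anc$gene_a == g | anc$gene_b == g, , drop = FALSE]
      if (nrow(rows)) {
        same <- rows$chrom_a == rows$chrom_b
        gap <- ifelse(same, abs(rows$rank_b - rows$rank_a), NA_integer_)
        partner <- ifelse(rows$gene_a == g, rows$gene_b, rows$gene_a)
        if (any(same & gap <= params$tandem_max_rank_gap)) {
          return(c("tandem", partner[which(same & gap <= params$tandem_max_rank_gap)[1]]))
        }
        if (any(same & gap <= params$proximal_max_rank_gap)) {
          return(c("proximal", partner[which(same & gap <= params$proximal_max_rank_gap)[1]]))
        }
        return(c("dispersed", partner[1]))
      }
    }
    c("singleton", "")
  }
  res <- t(vapply(loci$gene_id, classify_one, character(2)))
  data.frame(gene_id = loci$gene_id, class = res[, 1], evidence = res[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tabulate duplication classes
#'
#' @param calls output of [classify_duplications()].
#' @return named integer vector over the five classes.
#' @export
duplication_class_counts <- function(calls) {
  lv <- c("singleton", "dispersed", "proximal", "tandem", "WGD_segmental")
  tab <- table(factor(calls$class, levels = lv))
  stats::setNames(as.integer(tab), lv)
}
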