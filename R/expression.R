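# Stage-wise expression analysis: expressed calls, 3-stage Venn partition,
# hierarchical clustering with uncentered Pearson distance, DEG filtering.

#' Call expressed genes from a stage-wise expression matrix
#'
#' An entry is called expressed iff its value is strictly greater than the
#' threshold.
#'
#' @param mat numeric matrix, genes x stages, non-negative.
#' @param threshold expression threshold (default 0.5 TPM).
#' @return logical matrix of the same shape.
#' @export
call_expressed <- function(mat, threshold = 0.5) {
  stopifnot(is.matrix(mat), threshold >= 0)
  mat > threshold
}

VENN_REGIONS <- c("all3", "s1_s2", "s2_s3", "s1_s3", "s1_only", "s2_only", "s3_only")

#' Three-stage Venn partition of expressed genes
#'
#' Partitions the expressed genes into the seven disjoint Venn regions of a
#' three-stage design: expressed at all three stages, at exactly two
#' (`s1_s2`, `s2_s3`, `s1_s3`), or at exactly one (`s1_only`, `s2_only`,
#' `s3_only`).
#'
#' @param expressed logical matrix with exactly 3 stage columns (from
#'   [call_expressed()]).
#' @return list with `counts` (named integer vector over the 7 regions),
#'   `total_expressed`, and `genes` (named list of gene ids per region, if
#'   the matrix has row names).
#' @export
venn_partition <- function(expressed) {
  stopifnot(is.logical(expressed))
  if (ncol(expressed) != 3) abort("venn_partition needs exactly 3 stage columns")
  s1 <- expressed[, 1]; s2 <- expressed[, 2]; s3 <- expressed[, 3]
  region <- list(all3 = s1 & s2 & s3,
                 s1_s2 = s1 & s2 & !s3,
                 s2_s3 = !s1 & s2 & s3,
                 s1_s3 = s1 & !s2 & s3,
                 s1_only = s1 & !s2 & !s3,
                 s2_only = !s1 & s2 & !s3,
                 s3_only = !s1 & !s2 & s3)
  counts <- vapply(region, sum, 1L)
  genes <- if (!is.null(rownames(expressed))) {
    lapply(region, function(m) rownames(expressed)[m])
  }
  list(counts = counts, total_expressed = sum(counts), genes = genes)
}

#' Uncentered Pearson correlation distance
#'
#' `d = 1 - sum(x*y) / sqrt(sum(x^2) * sum(y^2))`, in `[0, 2]`. Unlike the
#' centered Pearson distance the profiles are not mean-centered, so overall
#' expression level matters, matching the clustering convention of classic
#' expression-heatmap tools. A zero-norm vector yields distance 1 with a
#' warning.
#'
#' @param x,y numeric profiles of equal length (>= 2).
#' @return distance in `[0, 2]`.
#' @export
uncentered_pearson_distance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("zero-norm profile; distance defined as 1")
    return(1)
  }
  1 - sum(x * y) / (nx * ny)
}

# Full pairwise uncentered-Pearson distance matrix (vectorized).
uncentered_pearson_distmat <- function(mat) {
  norms <- sqrt(rowSums(mat^2))
  zero <- norms == 0
  if (any(zero)) {
    warning(sprintf("%d zero-norm profile(s); distances to them set to 1", sum(zero)))
    norms[zero] <- 1
  }
  s <- (mat / norms) %*% t(mat / norms)
  d <- 1 - s
  if (any(zero)) {
    d[zero, ] <- 1; d[, zero] <- 1
  }
  diag(d) <- 0
  d[d < 0] <- 0   # numerical guard
  d
}

#' Complete-linkage hierarchical clustering of expression profiles
#'
#' Agglomerative clustering with complete linkage over the uncentered
#' Pearson correlation distance. Rows are ordered by name before clustering
#' so that ties merge deterministically (lexicographically smallest member
#' first).
#'
#' @param mat numeric matrix, genes x stages, with row names.
#' @return an [stats::hclust] tree.
#' @export
hcluster_complete <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  if (!is.null(rownames(mat))) mat <- mat[order(rownames(mat)), , drop = FALSE]
  d <- stats::as.dist(uncentered_pearson_distmat(mat))
  stats::hclust(d, method = "complete")
}

#' Cut a dendrogram into groups
#'
#' @param tree an [stats::hclust] tree.
#' @param k number of groups (or `NULL`).
#' @param h cut height (used when `k` is `NULL`).
#' @return named integer vector of group assignments.
#' @export
cut_clusters <- function(tree, k = NULL, h = NULL) {
  if (!is.null(k) && k > length(tree$labels)) abort("k exceeds the number of profiles")
  stats::cutree(tree, k = k, h = h)
}

#' Major expression groups with subgroup splits
#'
#' Cuts the tree at `k` major groups, relabels them `I`, `II`, ... in order
#' of the expression-weighted mean stage index of their members (early
#' groups first), and sub-cuts the groups named in `subsplit` into `A`/`B`
#' subgroups (two-way cut within the group, `A` = earlier mean stage).
#'
#' @param mat genes x stages matrix with row names.
#' @param k number of major groups (default 4).
#' @param subsplit roman labels of groups to split in two (default III, IV).
#' @return data frame with `gene`, `group`, `subgroup`.
#' @export
expression_groups <- function(mat, k = 4, subsplit = c("III", "IV")) {
  tree <- hcluster_complete(mat)
  grp <- cut_clusters(tree, k = k)
  mean_stage <- function(ids) {
    m <- mat[ids, , drop = FALSE]
    w <- rowSums(m)
    mean(as.vector(m %*% seq_len(ncol(m))) / ifelse(w == 0, 1, w))
  }
  ord <- order(vapply(split(names(grp), grp), mean_stage, 1))
  roman <- as.character(utils::as.roman(seq_len(k)))
  relabel <- stats::setNames(roman, names(split(names(grp), grp))[ord])
  group <- relabel[as.character(grp)]
  out <- data.frame(gene = names(grp), group = unname(group),
                    subgroup = unname(group), stringsAsFactors = FALSE)
  for (g in intersect(subsplit, unique(out$group))) {
    ids <- out$gene[out$group == g]
    if (length(ids) < 2) next
    sub <- cut_clusters(hcluster_complete(mat[ids, , drop = FALSE]), k = 2)
    ab <- if (mean_stage(names(sub)[sub == 1]) <= mean_stage(names(sub)[sub == 2])) {
      c("A", "B")
    } else c("B", "A")
    out$subgroup[match(names(sub), out$gene)] <- paste0(g, ab[sub])
  }
  out
}

#' Filter differential-expression records
#'
#' Keeps records with `|log2fc|` strictly greater than `min_abs_log2fc` and
#' `pvalue` at most `max_p` (the conventional `log2FC > 1 and p <= 0.05`
#' criterion by default).
#'
#' @param records data frame with columns `log2fc` and `pvalue` (other
#'   columns, e.g. `gene` and `group`, are carried through).
#' @param min_abs_log2fc fold-change bound (strict, on absolute value).
#' @param max_p p-value bound (inclusive).
#' @return filtered data frame.
#' @export
deg_filter <- function(records, min_abs_log2fc = 1, max_p = 0.05) {
  stopifnot(all(c("log2fc", "pvalue") %in% names(records)))
  stopifnot(all(records$pvalue >= 0 & records$pvalue <= 1))
  records[abs(records$log2fc) > min_abs_log2fc & records$pvalue <= max_p, ,
          drop = FALSE]
}

#' Generate a stage-wise expression matrix realizing a Venn specification
#'
#' Builds a genes x 3-stage TPM matrix whose [call_expressed()] /
#' [venn_partition()] output equals `venn_spec` exactly, plus `n_silent`
#' genes below threshold at every stage. Expressed entries are drawn
#' Uniform(threshold + 0.5, 100) and silent entries Uniform(0,
#' threshold / 2), so calls are unambiguous.
#'
#' @param venn_spec 7 non-negative region counts in the order `all3, s1_s2,
#'   s2_s3, s1_s3, s1_only, s2_only, s3_only`.
#' @param n_silent genes silent at all stages.
#' @param threshold expressed-call TPM threshold.
#' @param stages stage column labels.
#' @param seed integer seed.
#' @return list with `matrix` (genes x stages) and `truth` (list with
#'   `venn_spec` and per-region gene ids).
#' @export
gen_expression <- function(venn_spec, n_silent = 0L, threshold = 0.5,
                           stages = c("2DAA", "14DAA", "30DAA"), seed = 1L) {
  if (length(venn_spec) != 7 || any(venn_spec < 0)) {
    abort("venn_spec must be 7 non-negative counts")
  }
  venn_spec <- stats::setNames(as.integer(venn_spec), VENN_REGIONS)
  membership <- rbind(all3 = c(TRUE, TRUE, TRUE),
                      s1_s2 = c(TRUE, TRUE, FALSE),
                      s2_s3 = c(FALSE, TRUE, TRUE),
                      s1_s3 = c(TRUE, FALSE, TRUE),
                      s1_only = c(TRUE, FALSE, FALSE),
                      s2_only = c(FALSE, TRUE, FALSE),
                      s3_only = c(FALSE, FALSE, TRUE))
  n <- sum(venn_spec) + n_silent
  with_seed(seed, {
    ids <- sprintf("G%05d", seq_len(n))
    region_of <- c(rep(VENN_REGIONS, venn_spec), rep("silent", n_silent))
    region_of <- sample(region_of)   # shuffle gene order
    mat <- matrix(stats::runif(n * 3, 0, threshold / 2), n, 3,
                  dimnames = list(ids, stages))
    for (r in VENN_REGIONS) {
      rows <- which(region_of == r)
      cols <- which(membership[r, ])
      if (length(rows)) {
        mat[rows, cols] <- stats::runif(length(rows) * length(cols),
                                        threshold + 0.5, 100)
      }
    }
    truth_genes <- split(ids, region_of)
    list(matrix = mat,
         truth = list(venn_spec = venn_spec, region_genes = truth_genes,
                      threshold = threshold))
  })
}
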