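# Pearson correlation screen of family genes against starch-pathway
# targets (GBSSI, SBEIIa).

#' Pearson correlation with a t-based significance test
#'
#' `r` is the standard Pearson coefficient; the two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` against a t distribution with
#' `n - 2` degrees of freedom. With the typical design of four stage means
#' (`n = 4`, 2 df) the test has little power; a warning is emitted for
#' `n < 5`.
#'
#' @param x,y numeric vectors (stage means), length >= 3.
#' @param warn_small warn when `n < 5`.
#' @return list with `r`, `r_squared`, `p`, `n` (`r` is `NA` with a warning
#'   if either vector has zero variance).
#' @export
pearson_with_p <- function(x, y, warn_small = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 3, !anyNA(x), !anyNA(y))
  n <- length(x)
  if (warn_small && n < 5) warning("correlation over fewer than 5 points has little power")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 0))
  p <- if (is.infinite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, r_squared = r^2, p = p, n = n)
}

#' Bin a correlation by strength
#'
#' @param r_squared squared Pearson coefficient.
#' @param very_strong_min,strong_min inclusive lower bounds of the
#'   `very_strong` and `strong` bins.
#' @return `"very_strong"`, `"strong"` or `"moderate_or_weak"`.
#' @export
strength_bin <- function(r_squared, very_strong_min = 0.80, strong_min = 0.60) {
  stopifnot(!is.na(r_squared))
  if (r_squared >= very_strong_min) "very_strong"
  else if (r_squared >= strong_min) "strong"
  else "moderate_or_weak"
}

#' Correlate every gene against the target genes
#'
#' @param expr matrix of per-stage mean values (rows = genes incl. the
#'   targets, columns = stages).
#' @param targets target gene row names (default GBSSI and SBEIIa).
#' @return data frame `gene, target, r, r_squared, p, strength, sign`.
#' @export
correlation_screen <- function(expr, targets = c("GBSSI", "SBEIIa")) {
  stopifnot(is.matrix(expr), all(targets %in% rownames(expr)))
  genes <- setdiff(rownames(expr), targets)
  if (ncol(expr) < 5) warning("screening over fewer than 5 stages has little power")
  out <- do.call(rbind, lapply(targets, function(tg) {
    do.call(rbind, lapply(genes, function(g) {
      res <- pearson_with_p(expr[g, ], expr[tg, ])
      data.frame(gene = g, target = tg, r = res$r, r_squared = res$r_squared,
                 p = res$p,
                 strength = if (is.na(res$r)) NA_character_ else
                   strength_bin(res$r_squared),
                 sign = if (is.na(res$r)) NA_character_ else
                   if (res$r >= 0) "positive" else "negative",
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Select genes significantly correlated with the targets
#'
#' A gene is selected for a target when `p <= p_max` and
#' `r_squared >= min_r2` (either sign); the candidate set is the union over
#' both targets.
#'
#' @param results output of [correlation_screen()] with exactly two targets.
#' @param p_max significance bound (inclusive).
#' @param min_r2 strength bound (inclusive).
#' @return list with `per_target` (named list of gene id vectors),
#'   `n_a`, `n_b`, `n_overlap`, `n_union`, `candidates`.
#' @export
select_correlated_candidates <- function(results, p_max = 0.05, min_r2 = 0.60) {
  targets <- unique(results$target)
  stopifnot(length(targets) == 2)
  sel <- lapply(targets, function(tg) {
    d <- results[results$target == tg & !is.na(results$r), , drop = FALSE]
    sort(d$gene[d$p <= p_max & d$r_squared >= min_r2])
  })
  names(sel) <- targets
  a <- sel[[1]]; b <- sel[[2]]
  list(per_target = sel,
       n_a = length(a), n_b = length(b),
       n_overlap = length(intersect(a, b)),
       n_union = length(union(a, b)),
       candidates = sort(union(a, b)))
}

#' Generate a stage-mean expression panel with a planted correlation design
#'
#' Builds per-stage mean profiles for a panel of family genes plus two
#' target genes such that exactly `n_a` genes pass the significance/strength
#' screen against the first target, `n_b` against the second, with
#' `n_overlap` genes passing both. The construction is geometric: the two
#' target profiles span a plane with correlation `r_targets`; single-target
#' genes are exact scalar multiples of one target (perfectly correlated with
#' it, and with the other only at `r_targets`, which fails the significance
#' bound at four stages); both-target genes lie on the bisector of the two
#' profiles; all remaining genes are built exactly orthogonal to the plane,
#' so their correlation with either target is 0.
#'
#' @param n_genes panel size (excluding targets).
#' @param n_a,n_b,n_overlap planted set sizes (per target and overlap).
#' @param targets the two target row names.
#' @param stages number of stages (>= 4).
#' @param r_targets correlation between the two target profiles.
#' @param seed integer seed.
#' @return list with `expr` (matrix genes+targets x stages) and `truth`
#'   (list of planted per-target gene sets).
#' @export
gen_correlation_panel <- function(n_genes = 36L, n_a = 7L, n_b = 8L,
                                  n_overlap = 5L,
                                  targets = c("GBSSI", "SBEIIa"),
                                  stages = 4L, r_targets = 0.9, seed = 1L) {
  stopifnot(n_overlap <= min(n_a, n_b), n_a + n_b - n_overlap <= n_genes,
            stages >= 4, r_targets > 0, r_targets < 1)
  # orthonormal zero-sum contrasts in stage space
  cmat <- stats::contr.poly(stages)
  e1 <- cmat[, 1]; e2 <- cmat[, 2]; e3 <- cmat[, 3]
  u <- e1
  v <- r_targets * e1 + sqrt(1 - r_targets^2) * e2
  w <- (u + v) / sqrt(sum((u + v)^2))
  with_seed(seed, {
    ids <- sprintf("RQ%03d", seq_len(n_genes))
    only_a <- ids[seq_len(n_a - n_overlap)]
    only_b <- ids[n_a - n_overlap + seq_len(n_b - n_overlap)]
    both <- ids[n_a + n_b - 2L * n_overlap + seq_len(n_overlap)]
    rest <- setdiff(ids, c(only_a, only_b, both))
    profile <- function(dir) {
      s <- sample(c(-1, 1), 1) * stats::runif(1, 2, 6)
      stats::runif(1, 8, 14) + s * dir
    }
    expr <- matrix(0, n_genes + 2L, stages,
                   dimnames = list(c(ids, targets), paste0("stage", seq_len(stages))))
    expr[targets[1], ] <- 12 + 5 * u
    expr[targets[2], ] <- 12 + 5 * v
    for (g in only_a) expr[g, ] <- profile(u)
    for (g in only_b) expr[g, ] <- profile(v)
    for (g in both) expr[g, ] <- profile(w)
    for (g in rest) expr[g, ] <- profile(e3)
    list(expr = expr,
         truth = stats::setNames(list(sort(c(only_a, both)), sort(c(only_b, both))),
                                 targets))
  })
}
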