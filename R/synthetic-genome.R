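# Synthetic gene-map generator with planted duplication classes.
#
# Family genes are laid out among filler genes so that, with the same
# parameters, classify_duplications() recovers the planted class plan
# exactly. Structures (blocks, tandem/proximal/dispersed pairs, singletons)
# are separated by max_anchor_rank_gap+1 filler genes so no unplanned
# chain or rank-window relation can arise. Odd class counts are realized by
# pairing the odd gene with a donor gene of a strictly higher-priority
# class, which leaves the donor's own class unchanged.

#' Generate a synthetic gene map with a planted duplication-class plan
#'
#' @param class_plan named counts over
#'   `singleton, dispersed, proximal, tandem, WGD_segmental` (missing names
#'   count as 0).
#' @param n_chroms number of chromosomes (at least 2 if cross-chromosome
#'   structures are requested, 3 if an odd dispersed count is).
#' @param params a [dup_params()] object; blocks are built with
#'   `min_anchors` anchors.
#' @param seed integer seed.
#' @return list with `loci` (all genes incl. fillers, ranked), `pairs`
#'   (homolog pairs), `family_genes` (character vector) and `truth`
#'   (list with `dup_classes`, a named vector over the family genes).
#' @export
gen_gene_map <- function(class_plan, n_chroms = 3L, params = dup_params(),
                         seed = 1L) {
  stopifnot(inherits(params, "dup_params"), is_count(n_chroms, 1))
  lv <- c("singleton", "dispersed", "proximal", "tandem", "WGD_segmental")
  plan <- stats::setNames(rep(0L, length(lv)), lv)
  unknown <- setdiff(names(class_plan), lv)
  if (length(unknown)) abort("unknown duplication class(es): %s",
                             paste(unknown, collapse = ","))
  plan[names(class_plan)] <- as.integer(class_plan)
  if (any(plan < 0)) abort("negative class counts")
  W <- plan[["WGD_segmental"]]; Tn <- plan[["tandem"]]
  P <- plan[["proximal"]]; D <- plan[["dispersed"]]; S <- plan[["singleton"]]

  if (W %% 2L == 1L) abort("WGD_segmental count must be even (anchor pairs)")
  if (W > 0 && W / 2 < params$min_anchors) {
    abort("WGD block infeasible: %d anchor pairs < min_anchors = %d",
          W / 2, params$min_anchors)
  }
  if (Tn %% 2L == 1L && W == 0) {
    abort("odd tandem count needs a WGD donor gene")
  }
  if (P %% 2L == 1L && Tn < 2 && W == 0) {
    abort("odd proximal count needs a tandem or WGD donor gene")
  }
  if (D %% 2L == 1L && (W == 0 || n_chroms < 3)) {
    abort("odd dispersed count needs a WGD donor and >= 3 chromosomes")
  }
  needs_cross <- W > 0 || D > 0
  if (needs_cross && n_chroms < 2) abort("cross-chromosome structures need >= 2 chromosomes")

  sep <- params$max_anchor_rank_gap + 1L
  env <- new.env()
  env$chrom <- stats::setNames(rep(list(character(0)), n_chroms),
                               sprintf("chr%02d", seq_len(n_chroms)))
  env$nfam <- 0L; env$nfill <- 0L
  env$pairs <- list()
  env$classes <- character(0)
  new_fam <- function(class) {
    env$nfam <- env$nfam + 1L
    id <- sprintf("RG%05d", env$nfam)
    env$classes[id] <- class
    id
  }
  new_fill <- function(n) {
    if (n == 0) return(character(0))
    ids <- sprintf("FG%05d", env$nfill + seq_len(n))
    env$nfill <- env$nfill + n
    ids
  }
  # append a structure (ordered gene ids) to a chromosome, separated from
  # whatever precedes it
  put <- function(chrom, ids) {
    cur <- env$chrom[[chrom]]
    if (length(cur)) cur <- c(cur, new_fill(sep))
    env$chrom[[chrom]] <- c(cur, ids)
  }
  add_pair <- function(a, b) env$pairs[[length(env$pairs) + 1L]] <- c(a, b)
  chrom_names <- names(env$chrom)
  env$ci <- 0L
  next_chrom <- function(avoid = character(0)) {
    repeat {
      env$ci <- env$ci %% length(chrom_names) + 1L
      nm <- chrom_names[env$ci]
      if (!nm %in% avoid) return(nm)
    }
  }

  with_seed(seed, {
    donors <- list(wgd = NULL)  # list(gene=, chrom=, block_chroms=)

    # --- WGD/segmental blocks ---
    if (W > 0) {
      n_pairs <- W %/% 2L
      a <- params$min_anchors
      nb <- n_pairs %/% a
      sizes <- rep(a, nb)
      sizes[nb] <- sizes[nb] + n_pairs - nb * a
      for (k in seq_len(nb)) {
        ca <- next_chrom(); cb <- next_chrom(avoid = ca)
        ga <- vapply(seq_len(sizes[k]), function(i) new_fam("WGD_segmental"), "")
        gb <- vapply(seq_len(sizes[k]), function(i) new_fam("WGD_segmental"), "")
        interleave <- function(ids) {
          out <- character(0)
          for (i in seq_along(ids)) {
            out <- c(out, ids[i], if (i < length(ids)) new_fill(1L))
          }
          out
        }
        put(ca, interleave(ga))
        put(cb, interleave(gb))
        for (i in seq_len(sizes[k])) add_pair(ga[i], gb[i])
        if (k == 1) donors$wgd <- list(gene = ga[1], chrom = ca,
                                       block_chroms = c(ca, cb))
      }
    }

    # --- tandem pairs (+ odd attachment to a WGD anchor) ---
    tandem_donor <- NULL
    for (k in seq_len(Tn %/% 2L)) {
      cc <- next_chrom()
      t1 <- new_fam("tandem"); t2 <- new_fam("tandem")
      put(cc, c(t1, t2))
      add_pair(t1, t2)
      if (is.null(tandem_donor)) tandem_donor <- list(gene = t1, chrom = cc,
                                                      pos_after = t2)
    }
    if (Tn %% 2L == 1L) {
      x <- new_fam("tandem")
      d <- donors$wgd
      # adjacent (rank gap 1) to the first anchor of the first block
      cur <- env$chrom[[d$chrom]]
      i <- match(d$gene, cur)
      env$chrom[[d$chrom]] <- append(cur, x, after = i)
      add_pair(x, d$gene)
    }

    # --- proximal pairs (+ odd attachment) ---
    for (k in seq_len(P %/% 2L)) {
      cc <- next_chrom()
      x <- new_fam("proximal"); y <- new_fam("proximal")
      put(cc, c(x, new_fill(params$tandem_max_rank_gap), y))
      add_pair(x, y)
    }
    if (P %% 2L == 1L) {
      x <- new_fam("proximal")
      if (!is.null(tandem_donor)) {
        cur <- env$chrom[[tandem_donor$chrom]]
        i <- match(tandem_donor$pos_after, cur)
        env$chrom[[tandem_donor$chrom]] <-
          append(cur, c(new_fill(params$tandem_max_rank_gap), x), after = i)
        add_pair(x, tandem_donor$gene)
      } else {
        d <- donors$wgd
        cur <- env$chrom[[d$chrom]]
        i <- match(d$gene, cur)
        env$chrom[[d$chrom]] <-
          append(cur, c(new_fill(params$tandem_max_rank_gap), x), after = i - 1L)
        add_pair(x, d$gene)
      }
    }

    # --- dispersed pairs (cross-chromosome; odd gene attached to WGD) ---
    for (k in seq_len(D %/% 2L)) {
      ca <- next_chrom(); cb <- if (n_chroms >= 2) next_chrom(avoid = ca) else ca
      x <- new_fam("dispersed"); y <- new_fam("dispersed")
      put(ca, x); put(cb, y)
      add_pair(x, y)
    }
    if (D %% 2L == 1L) {
      x <- new_fam("dispersed")
      d <- donors$wgd
      cx <- next_chrom(avoid = d$block_chroms)
      put(cx, x)
      add_pair(x, d$gene)
    }

    # --- singletons ---
    for (k in seq_len(S)) put(next_chrom(), new_fam("singleton"))

    # --- coordinates ---
    loci <- do.call(rbind, lapply(names(env$chrom), function(cc) {
      ids <- env$chrom[[cc]]
      if (!length(ids)) return(NULL)
      gap <- sample(50000:500000, length(ids), replace = TRUE)
      start <- cumsum(gap) + (seq_along(ids) - 1L) * 2000L
      data.frame(gene_id = ids, chromosome = cc, start = start,
                 end = start + 1999L,
                 strand = sample(c("+", "-"), length(ids), replace = TRUE),
                 rank = seq_along(ids), unplaced = FALSE,
                 stringsAsFactors = FALSE)
    }))
    rownames(loci) <- NULL
    pairs <- if (length(env$pairs)) {
      m <- do.call(rbind, env$pairs)
      data.frame(gene_a = m[, 1], gene_b = m[, 2], stringsAsFactors = FALSE)
    } else data.frame(gene_a = character(0), gene_b = character(0))

    list(loci = loci, pairs = pairs,
         family_genes = names(env$classes),
         truth = list(dup_classes = env$classes))
  })
}

#' Write a gene map as GFF3
#'
#' @param loci loci data frame (`gene_id`, `chromosome`, `start`, `end`,
#'   `strand`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_map_gff3 <- function(loci, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tringminer\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     loci$chromosome, loci$start, loci$end, loci$strand,
                     loci$gene_id, loci$gene_id))
  writeLines(lines, path)
  invisible(path)
}
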