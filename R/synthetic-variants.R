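# Toy gene models and variant generator with planted effect categories.
#
# The toy genome is a single chromosome of multi-exon genes (5'UTR, CDS in
# four exons, 3'UTR, three 60-bp introns) on alternating strands, spaced so
# that upstream/downstream windows and intergenic space never overlap.
# gen_variants() places variants so that annotate_variants() reproduces the
# requested effect plan exactly.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Build toy gene models with a reference sequence
#'
#' Each gene has a 30-bp 5'UTR (carrying one planted ACG site that a C>T
#' SNP turns into a premature ATG), a 300-bp CDS split over four exons (45,
#' 90, 90, 75 bp; ATG start, TAA stop, no internal stops), three 60-bp
#' introns with canonical GT..AG ends, and a 30-bp 3'UTR. Genes alternate
#' between + and - strand and are separated by 13-kb spacers (upstream and
#' downstream windows of 5 kb never touch).
#'
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @return list with `models` (a [gene_models()] object), `ref` (named
#'   character vector with one chromosome), and `utr5_acg` (data frame of
#'   the planted premature-start sites: gene, genomic pos of the mutable
#'   base, required alt).
#' @export
toy_gene_models <- function(n_genes = 12L, seed = 1L) {
  stopifnot(is_count(n_genes, 1))
  utr_len <- 30L; cds_lens <- c(45L, 90L, 90L, 75L); intron_len <- 60L
  gene_len <- 2L * utr_len + sum(cds_lens) + 3L * intron_len
  spacer <- 13000L
  with_seed(seed, {
    sample_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")
    strip_atg <- function(s) {
      repeat {
        i <- regexpr("ATG", s, fixed = TRUE)
        if (i < 0) return(s)
        substr(s, i + 1L, i + 1L) <- "C"
      }
    }
    genes <- exons <- cds <- list()
    utr5_acg <- list()
    chrom_parts <- character(0)
    cursor <- 0L
    append_seq <- function(s) {
      chrom_parts <<- c(chrom_parts, s)
      cursor <<- cursor + nchar(s)
    }
    append_seq(sample_dna(spacer %/% 2L))
    for (gi in seq_len(n_genes)) {
      gid <- sprintf("TG%03d", gi)
      strand <- if (gi %% 2L == 1L) "+" else "-"
      # transcript-order pieces
      utr5 <- strip_atg(sample_dna(utr_len))
      substr(utr5, 10L, 12L) <- "ACG"
      body_codons <- sample(setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS),
                            98L, replace = TRUE)
      cds_seq <- paste(c("ATG", body_codons, "TAA"), collapse = "")
      cds_parts <- substring(cds_seq, cumsum(c(1L, cds_lens[-4])),
                             cumsum(cds_lens))
      introns <- vapply(1:3, function(i) {
        s <- sample_dna(intron_len)
        substr(s, 1L, 2L) <- "GT"
        substr(s, intron_len - 1L, intron_len) <- "AG"
        s
      }, "")
      utr3 <- sample_dna(utr_len)
      tx_segments <- list(
        list(seq = paste0(utr5, cds_parts[1]), exon = TRUE, cds_off = utr_len),
        list(seq = introns[1], exon = FALSE),
        list(seq = cds_parts[2], exon = TRUE, cds_off = 0L),
        list(seq = introns[2], exon = FALSE),
        list(seq = cds_parts[3], exon = TRUE, cds_off = 0L),
        list(seq = introns[3], exon = FALSE),
        list(seq = paste0(cds_parts[4], utr3), exon = TRUE, cds_off = 0L,
             cds_len = cds_lens[4]))
      gstart <- cursor + 1L
      # lay segments onto the genome: transcript order for +, reversed and
      # reverse-complemented for -
      segs <- if (strand == "+") tx_segments else rev(tx_segments)
      for (sg in segs) {
        s <- cursor + 1L
        piece <- if (strand == "+") sg$seq else revcomp(sg$seq)
        append_seq(piece)
        e <- cursor
        if (sg$exon) {
          exons[[length(exons) + 1L]] <- data.frame(gene_id = gid, start = s, end = e)
          seg_len <- e - s + 1L
          cds_here <- if (!is.null(sg$cds_len)) sg$cds_len else seg_len - sg$cds_off
          if (cds_here > 0L) {
            # cds occupies the transcript-5' part after cds_off
            if (strand == "+") {
              cs <- s + (sg$cds_off %||% 0L); ce <- cs + cds_here - 1L
            } else {
              ce <- e - (sg$cds_off %||% 0L); cs <- ce - cds_here + 1L
            }
            cds[[length(cds) + 1L]] <- data.frame(gene_id = gid, start = cs, end = ce)
          }
        }
      }
      gend <- cursor
      genes[[gi]] <- data.frame(gene_id = gid, chrom = "chrV1", start = gstart,
                                end = gend, strand = strand,
                                stringsAsFactors = FALSE)
      # genomic position of the mutable base of the planted ACG (UTR pos 11)
      acg_pos <- if (strand == "+") gstart + 10L else gend - 10L
      utr5_acg[[gi]] <- data.frame(gene_id = gid, pos = acg_pos,
                                   alt = if (strand == "+") "T" else "A",
                                   stringsAsFactors = FALSE)
      append_seq(sample_dna(spacer))
    }
    models <- gene_models(do.call(rbind, genes), do.call(rbind, exons),
                          do.call(rbind, cds))
    list(models = models,
         ref = c(chrV1 = paste(chrom_parts, collapse = "")),
         utr5_acg = do.call(rbind, utr5_acg))
  })
}

# Candidate variant sites for one effect category on the toy models.
# Returns a data frame chrom,pos,ref,alt (one candidate per row) or NULL.
variant_site_pool <- function(category, toy, windows = variant_windows()) {
  models <- toy$models; ref <- toy$ref
  chrom <- models$genes$chrom[1]
  chrom_seq <- ref[[chrom]]
  base_at <- function(p) substr(chrom_seq, p, p)
  other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  snp_rows <- function(pos, alt = NULL) {
    if (!length(pos)) return(NULL)
    rb <- vapply(pos, base_at, "")
    if (is.null(alt)) alt <- vapply(rb, other_base, "")
    data.frame(chrom = chrom, pos = pos, ref = rb, alt = alt,
               stringsAsFactors = FALSE)
  }
  del_rows <- function(anchor, len) {
    if (!length(anchor)) return(NULL)
    data.frame(chrom = chrom, pos = anchor,
               ref = vapply(anchor, function(a) substr(chrom_seq, a, a + len), ""),
               alt = vapply(anchor, base_at, ""), stringsAsFactors = FALSE)
  }
  ins_rows <- function(anchor, insert = "AAA") {
    if (!length(anchor)) return(NULL)
    rb <- vapply(anchor, base_at, "")
    data.frame(chrom = chrom, pos = anchor, ref = rb,
               alt = paste0(rb, insert), stringsAsFactors = FALSE)
  }

  genes <- models$genes
  gaps_pool <- function(side) {
    out <- integer(0)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      w <- if ((side == "upstream") == (g$strand == "+")) {
        c(g$start - windows$upstream, g$start - 1L)
      } else {
        c(g$end + 1L, g$end + windows$upstream)
      }
      out <- c(out, (w[1] + 10L):(w[2] - 10L))
    }
    out
  }

  if (category == "intergenic") {
    zones <- rbind(cbind(genes$start - windows$upstream, genes$end + windows$downstream))
    pool <- integer(0)
    bounds <- c(1L, nchar(chrom_seq))
    starts <- c(bounds[1], zones[, 2] + 1L)
    ends <- c(zones[, 1] - 1L, bounds[2])
    for (i in seq_along(starts)) {
      if (ends[i] - starts[i] > 100L) pool <- c(pool, (starts[i] + 50L):(ends[i] - 50L))
    }
    return(snp_rows(pool))
  }
  if (category == "upstream_gene") return(snp_rows(gaps_pool("upstream")))
  if (category == "downstream_gene") return(snp_rows(gaps_pool("downstream")))

  rows <- list()
  for (gid in genes$gene_id) {
    info <- transcript_info(models, ref, gid)
    intr <- info$introns
    band <- windows$splice_region_exon
    # exon-side splice_region bases (genomic)
    ex <- info$exons
    exon_band <- integer(0)
    for (j in seq_len(nrow(ex))) {
      if (j > 1) exon_band <- c(exon_band, ex$start[j]:(ex$start[j] + band - 1L))
      if (j < nrow(ex)) exon_band <- c(exon_band, (ex$end[j] - band + 1L):ex$end[j])
    }
    cds_pos <- unlist(mapply(seq, info$cds$start, info$cds$end, SIMPLIFY = FALSE))
    interior_codon <- function(p) {
      o <- info$g2o(p)
      !is.na(o) && o > 3L && o <= nchar(info$cds_seq) - 3L
    }
    codon_change <- function(p, want_same) {
      o <- info$g2o(p)
      ci <- (o - 1L) %/% 3L + 1L
      wi <- (o - 1L) %% 3L + 1L
      from_cod <- substr(info$cds_seq, ci * 3L - 2L, ci * 3L)
      from <- translate_codon(from_cod)
      for (alt in setdiff(c("A", "C", "G", "T"), base_at(p))) {
        tb <- if (info$strand == "-") chartr("ACGT", "TGCA", alt) else alt
        to_cod <- from_cod
        substr(to_cod, wi, wi) <- tb
        to <- translate_codon(to_cod)
        if (want_same && to == from) return(alt)
        if (!want_same && to != from && to != "*") return(alt)
      }
      NA_character_
    }
    pick_snps <- function(pos, want_same) {
      alt <- vapply(pos, codon_change, "", want_same = want_same)
      keep <- !is.na(alt)
      if (any(keep)) snp_rows(pos[keep], alt[keep]) else NULL
    }

    r <- switch(
      category,
      "intron" = {
        pool <- unlist(lapply(seq_len(nrow(intr)), function(i) {
          (intr$start[i] + 8L):(intr$end[i] - 8L)
        }))
        snp_rows(pool)
      },
      "splice_donor&intron" = {
        pool <- unlist(lapply(seq_len(nrow(intr)), function(i) {
          if (info$strand == "+") intr$start[i]:(intr$start[i] + 1L)
          else (intr$end[i] - 1L):intr$end[i]
        }))
        snp_rows(pool)
      },
      "splice_acceptor&intron" = {
        pool <- unlist(lapply(seq_len(nrow(intr)), function(i) {
          if (info$strand == "+") (intr$end[i] - 1L):intr$end[i]
          else intr$start[i]:(intr$start[i] + 1L)
        }))
        snp_rows(pool)
      },
      "splice_region&intron" = {
        sr <- windows$splice_region_intron
        pool <- unlist(lapply(seq_len(nrow(intr)), function(i) {
          c((intr$start[i] + sr[1] - 1L):(intr$start[i] + sr[2] - 1L),
            (intr$end[i] - sr[2] + 1L):(intr$end[i] - sr[1] + 1L))
        }))
        snp_rows(pool)
      },
      "splice_donor&splice_region&intron" = {
        # delete transcript-side intron bases 1..4
        anchors <- vapply(seq_len(nrow(intr)), function(i) {
          if (info$strand == "+") intr$start[i] - 1L else intr$end[i] - 4L
        }, 1L)
        del_rows(anchors, 4L)
      },
      "synonymous" = {
        pool <- Filter(function(p) interior_codon(p) && !p %in% exon_band, cds_pos)
        pick_snps(unlist(pool), want_same = TRUE)
      },
      "missense" = {
        pool <- Filter(function(p) interior_codon(p) && !p %in% exon_band, cds_pos)
        pick_snps(unlist(pool), want_same = FALSE)
      },
      "missense&splice_region" = {
        pool <- Filter(function(p) interior_codon(p) && p %in% exon_band, cds_pos)
        pick_snps(unlist(pool), want_same = FALSE)
      },
      "frameshift" = {
        # 1-bp deletion: deleted base pos+1 in CDS interior, off the bands
        anchors <- Filter(function(a) {
          interior_codon(a + 1L) && !(a + 1L) %in% exon_band && !is.na(info$g2o(a))
        }, cds_pos)
        del_rows(unlist(anchors), 1L)
      },
      "frameshift&splice_region" = {
        anchors <- Filter(function(a) {
          interior_codon(a + 1L) && (a + 1L) %in% exon_band
        }, cds_pos)
        del_rows(unlist(anchors), 1L)
      },
      "conservative_inframe_deletion" = {
        # delete one whole codon lying inside one exon, off the bands
        anchors <- Filter(function(a) {
          span <- (a + 1L):(a + 3L)
          if (!all(span %in% cds_pos) || any(span %in% exon_band)) return(FALSE)
          offs <- vapply(span, info$g2o, 1L)
          if (anyNA(offs) || max(offs) - min(offs) != 2L) return(FALSE)
          min(offs) %% 3L == 1L && max(offs) %% 3L == 0L &&
            min(offs) > 3L && max(offs) <= nchar(info$cds_seq) - 3L
        }, cds_pos)
        del_rows(unlist(anchors), 3L)
      },
      "disruptive_inframe_insertion" = {
        anchors <- Filter(function(a) {
          o_up <- if (info$strand == "+") info$g2o(a) else info$g2o(a + 1L)
          interior_codon(a) && interior_codon(a + 1L) &&
            !a %in% exon_band && !(a + 1L) %in% exon_band &&
            !is.na(o_up) && o_up %% 3L != 0L
        }, cds_pos)
        ins_rows(unlist(anchors))
      },
      "disruptive_inframe_insertion&splice_region" = {
        anchors <- Filter(function(a) {
          o_up <- if (info$strand == "+") info$g2o(a) else info$g2o(a + 1L)
          interior_codon(a) && interior_codon(a + 1L) &&
            a %in% exon_band && (a + 1L) %in% exon_band &&
            !is.na(o_up) && o_up %% 3L != 0L
        }, cds_pos)
        ins_rows(unlist(anchors))
      },
      "5_prime_UTR_premature_start_codon_gain" = {
        row <- toy$utr5_acg[toy$utr5_acg$gene_id == gid, , drop = FALSE]
        snp_rows(row$pos, row$alt)
      },
      "5_prime_UTR" = {
        u <- info$utr[info$utr$label == "5_prime_UTR", , drop = FALSE]
        acg <- toy$utr5_acg$pos[toy$utr5_acg$gene_id == gid]
        pool <- setdiff(u$start:u$end, (acg - 3L):(acg + 3L))
        alt <- vapply(pool, function(p) {
          for (a in setdiff(c("A", "C", "G", "T"), base_at(p))) {
            if (!utr5_start_gain(info, p, a)) return(a)
          }
          NA_character_
        }, "")
        keep <- !is.na(alt)
        if (any(keep)) snp_rows(pool[keep], alt[keep]) else NULL
      },
      "3_prime_UTR" = {
        u <- info$utr[info$utr$label == "3_prime_UTR", , drop = FALSE]
        snp_rows(unlist(mapply(seq, u$start, u$end, SIMPLIFY = FALSE)))
      },
      abort("no site pool for category '%s'", category))
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  }
  if (!length(rows)) NULL else do.call(rbind, rows)
}

#' Generate variants realizing a planted effect plan
#'
#' Places variants on the toy gene models so that [annotate_variants()]
#' reproduces `effect_plan` exactly: for every category (full compound
#' label) the requested number of variants is sampled from the pool of
#' genomic sites that realize that category, without footprint overlaps.
#'
#' @param toy output of [toy_gene_models()].
#' @param effect_plan named counts over annotation categories (compound
#'   labels as produced by [annotate_variants()]).
#' @param seed integer seed.
#' @return list with `variants` (data frame `chrom, pos, id, ref, alt`) and
#'   `truth` (data frame `id, category`).
#' @export
gen_variants <- function(toy, effect_plan, seed = 1L) {
  stopifnot(is.numeric(effect_plan), !is.null(names(effect_plan)),
            all(effect_plan >= 0))
  with_seed(seed, {
    used <- integer(0)
    out <- list()
    for (cat in names(effect_plan)) {
      n <- as.integer(effect_plan[[cat]])
      if (n == 0L) next
      pool <- variant_site_pool(cat, toy)
      if (is.null(pool) || nrow(pool) == 0L) {
        abort("category '%s' is not realizable on these gene models", cat)
      }
      pool <- pool[sample(nrow(pool)), , drop = FALSE]
      taken <- 0L
      for (i in seq_len(nrow(pool))) {
        if (taken == n) break
        fp <- pool$pos[i]:(pool$pos[i] + nchar(pool$ref[i]))
        if (any(fp %in% used)) next
        used <- c(used, fp)
        taken <- taken + 1L
        out[[length(out) + 1L]] <- cbind(pool[i, , drop = FALSE], category = cat)
      }
      if (taken < n) {
        abort("category '%s': only %d of %d requested sites available",
              cat, taken, n)
      }
    }
    v <- do.call(rbind, out)
    v <- v[order(v$pos), , drop = FALSE]
    v$id <- sprintf("var%05d", seq_len(nrow(v)))
    rownames(v) <- NULL
    list(variants = v[, c("chrom", "pos", "id", "ref", "alt")],
         truth = v[, c("id", "category")])
  })
}
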