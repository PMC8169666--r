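# Rule-based variant effect annotation on gene models.
#
# Region categories use the conventional annotator vocabulary: a variant's
# label is the precedence-ordered compound of every genomic zone its
# affected bases overlap (e.g. an SNP in the first two intron bases is
# "splice_donor&intron"); coding zones are refined to the concrete coding
# effect by local codon comparison on the strand-corrected CDS.

CODING_EFFECTS <- c("frameshift", "start_lost", "stop_gained", "stop_lost",
                    "missense", "synonymous",
                    "conservative_inframe_deletion", "disruptive_inframe_deletion",
                    "conservative_inframe_insertion", "disruptive_inframe_insertion")

CATEGORY_PRECEDENCE <- c(CODING_EFFECTS,
                         "splice_donor", "splice_acceptor", "splice_region",
                         "5_prime_UTR_premature_start_codon_gain",
                         "5_prime_UTR", "3_prime_UTR", "intron",
                         "upstream_gene", "downstream_gene", "intergenic")

#' Default impact-tier mapping
#'
#' @return named character vector mapping primary categories to
#'   `HIGH`/`MODERATE`/`LOW`/`MODIFIER`.
#' @export
impact_map <- function() {
  c(frameshift = "HIGH", splice_donor = "HIGH", splice_acceptor = "HIGH",
    start_lost = "HIGH", stop_gained = "HIGH", stop_lost = "HIGH",
    missense = "MODERATE",
    conservative_inframe_deletion = "MODERATE",
    disruptive_inframe_deletion = "MODERATE",
    conservative_inframe_insertion = "MODERATE",
    disruptive_inframe_insertion = "MODERATE",
    "5_prime_UTR_premature_start_codon_gain" = "MODERATE",
    synonymous = "LOW", splice_region = "LOW",
    "5_prime_UTR" = "MODIFIER", "3_prime_UTR" = "MODIFIER",
    intron = "MODIFIER", upstream_gene = "MODIFIER",
    downstream_gene = "MODIFIER", intergenic = "MODIFIER")
}

#' Annotation window configuration
#'
#' @param upstream,downstream bp from TSS/TES for up/downstream calls.
#' @param splice_site intron bases at each junction called donor/acceptor.
#' @param splice_region_intron intron bases (range from the junction) called
#'   splice region.
#' @param splice_region_exon exon bases adjacent to a junction called splice
#'   region.
#' @return named list.
#' @export
variant_windows <- function(upstream = 5000L, downstream = 5000L,
                            splice_site = 2L, splice_region_intron = c(3L, 8L),
                            splice_region_exon = 3L) {
  list(upstream = upstream, downstream = downstream, splice_site = splice_site,
       splice_region_intron = splice_region_intron,
       splice_region_exon = splice_region_exon)
}

#' Assemble a validated gene-model set
#'
#' @param genes data frame `gene_id, chrom, start, end, strand`.
#' @param exons data frame `gene_id, start, end`.
#' @param cds data frame `gene_id, start, end`.
#' @return list of class `gene_models`.
#' @export
gene_models <- function(genes, exons, cds) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  for (g in genes$gene_id) {
    len <- sum(cds$end[cds$gene_id == g] - cds$start[cds$gene_id == g] + 1L)
    if (len %% 3L != 0L) {
      abort("gene %s has inconsistent CDS phase (CDS length %d not a multiple of 3)",
            g, len)
    }
  }
  structure(list(genes = genes, exons = exons, cds = cds), class = "gene_models")
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Strand-corrected transcript machinery for one gene.
transcript_info <- function(models, ref, gid) {
  g <- models$genes[models$genes$gene_id == gid, , drop = FALSE]
  ex <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
  cds <- models$cds[models$cds$gene_id == gid, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  strand <- g$strand
  chrom_seq <- ref[[g$chrom]]
  seg_seq <- function(s, e) {
    x <- substr(chrom_seq, s, e)
    if (strand == "-") revcomp(x) else x
  }
  tx_order <- function(df) if (strand == "+") df else df[rev(seq_len(nrow(df))), , drop = FALSE]
  cds_t <- tx_order(cds)
  cds_seq <- paste(mapply(seg_seq, cds_t$start, cds_t$end), collapse = "")
  introns <- if (nrow(ex) > 1) {
    data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
  } else data.frame(start = integer(0), end = integer(0))
  # UTR ranges: exon bases outside the CDS span, sided by strand
  cds_lo <- min(cds$start); cds_hi <- max(cds$end)
  utr <- do.call(rbind, lapply(seq_len(nrow(ex)), function(i) {
    out <- NULL
    if (ex$start[i] < cds_lo) {
      out <- rbind(out, data.frame(start = ex$start[i],
                                   end = min(ex$end[i], cds_lo - 1L), side = "left"))
    }
    if (ex$end[i] > cds_hi) {
      out <- rbind(out, data.frame(start = max(ex$start[i], cds_hi + 1L),
                                   end = ex$end[i], side = "right"))
    }
    out
  }))
  if (is.null(utr)) utr <- data.frame(start = integer(0), end = integer(0),
                                      side = character(0))
  utr$label <- ifelse((utr$side == "left") == (strand == "+"),
                      "5_prime_UTR", "3_prime_UTR")
  # genomic position -> 1-based CDS offset (transcript orientation)
  cum <- cumsum(c(0L, cds_t$end - cds_t$start + 1L))
  g2o <- function(gpos) {
    for (i in seq_len(nrow(cds_t))) {
      if (gpos >= cds_t$start[i] && gpos <= cds_t$end[i]) {
        return(if (strand == "+") cum[i] + (gpos - cds_t$start[i] + 1L)
               else cum[i] + (cds_t$end[i] - gpos + 1L))
      }
    }
    NA_integer_
  }
  list(gene = g, strand = strand, exons = ex, cds = cds, introns = introns,
       utr = utr, cds_seq = cds_seq, g2o = g2o, seg_seq = seg_seq)
}

# Precomputed per-gene transcript machinery and zone tables.
annotation_cache <- function(models, ref, windows = variant_windows()) {
  infos <- lapply(models$genes$gene_id, function(g) transcript_info(models, ref, g))
  names(infos) <- models$genes$gene_id
  zones <- lapply(infos, gene_zones, windows = windows)
  list(infos = infos, zones = zones)
}

# Zone table (label, start, end) for one gene, genomic coordinates.
gene_zones <- function(info, windows) {
  z <- list()
  add <- function(label, s, e) {
    if (length(s) && all(e >= s)) {
      z[[length(z) + 1L]] <<- data.frame(label = label, start = s, end = e)
    }
  }
  intr <- info$introns
  if (nrow(intr)) {
    for (i in seq_len(nrow(intr))) {
      is <- intr$start[i]; ie <- intr$end[i]
      add("intron", is, ie)
      ss <- windows$splice_site
      if (info$strand == "+") {
        add("splice_donor", is, is + ss - 1L)
        add("splice_acceptor", ie - ss + 1L, ie)
      } else {
        add("splice_donor", ie - ss + 1L, ie)
        add("splice_acceptor", is, is + ss - 1L)
      }
      sr <- windows$splice_region_intron
      add("splice_region", is + sr[1] - 1L, min(is + sr[2] - 1L, ie))
      add("splice_region", max(ie - sr[2] + 1L, is), ie - sr[1] + 1L)
    }
    ex <- info$exons
    k <- windows$splice_region_exon
    for (j in seq_len(nrow(ex))) {
      if (j > 1) add("splice_region", ex$start[j], ex$start[j] + k - 1L)
      if (j < nrow(ex)) add("splice_region", ex$end[j] - k + 1L, ex$end[j])
    }
  }
  for (i in seq_len(nrow(info$cds))) add("CDS", info$cds$start[i], info$cds$end[i])
  for (i in seq_len(nrow(info$utr))) {
    add(info$utr$label[i], info$utr$start[i], info$utr$end[i])
  }
  g <- info$gene
  if (g$strand == "+") {
    add("upstream_gene", g$start - windows$upstream, g$start - 1L)
    add("downstream_gene", g$end + 1L, g$end + windows$downstream)
  } else {
    add("upstream_gene", g$end + 1L, g$end + windows$upstream)
    add("downstream_gene", g$start - windows$downstream, g$start - 1L)
  }
  do.call(rbind, z)
}

variant_type <- function(ref, alt) {
  if (nchar(ref) == nchar(alt)) {
    if (nchar(ref) == 1L) "SNP" else "MNP"
  } else if (nchar(ref) > nchar(alt)) "deletion" else "insertion"
}

# Affected genomic range: deleted bases for deletions; both flanking bases
# for insertions (so junction insertions pick up both sides).
affected_range <- function(pos, ref, alt) {
  type <- variant_type(ref, alt)
  switch(type,
         SNP = c(pos, pos),
         MNP = c(pos, pos + nchar(ref) - 1L),
         deletion = c(pos + 1L, pos + nchar(ref) - 1L),
         insertion = c(pos, pos + 1L))
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Concrete coding effect of a variant whose affected bases lie in the CDS.
coding_effect <- function(info, pos, ref, alt) {
  type <- variant_type(ref, alt)
  strand <- info$strand
  comp <- function(x) chartr("ACGT", "TGCA", x)
  n_codons <- nchar(info$cds_seq) %/% 3L
  if (type %in% c("SNP", "MNP")) {
    offs <- vapply(pos:(pos + nchar(ref) - 1L), info$g2o, 1L)
    if (anyNA(offs)) return("missense")   # partial CDS overlap: treat as coding change
    bases <- strsplit(alt, "")[[1]]
    if (strand == "-") bases <- rev(comp(bases))
    alt_cds <- strsplit(info$cds_seq, "")[[1]]
    alt_cds[sort(offs)] <- bases[order(offs)]
    cods <- unique((sort(offs) - 1L) %/% 3L + 1L)
    changed <- FALSE
    for (ci in cods) {
      from <- translate_codon(substr(info$cds_seq, ci * 3L - 2L, ci * 3L))
      to <- translate_codon(paste(alt_cds[(ci * 3L - 2L):(ci * 3L)], collapse = ""))
      if (from != to) {
        if (ci == 1L && from == "M") return("start_lost")
        if (from == "*") return("stop_lost")
        if (to == "*") return("stop_gained")
        changed <- TRUE
      }
    }
    if (changed) "missense" else "synonymous"
  } else if (type == "insertion") {
    ins_len <- nchar(alt) - 1L
    if (ins_len %% 3L != 0L) return("frameshift")
    o_up <- if (strand == "+") info$g2o(pos) else info$g2o(pos + 1L)
    if (!is.na(o_up) && o_up %% 3L == 0L) "conservative_inframe_insertion"
    else "disruptive_inframe_insertion"
  } else {
    del <- (pos + 1L):(pos + nchar(ref) - 1L)
    offs <- vapply(del, info$g2o, 1L)
    offs <- offs[!is.na(offs)]
    if (length(offs) %% 3L != 0L) return("frameshift")
    if (min(offs) %% 3L == 1L && max(offs) %% 3L == 0L) {
      "conservative_inframe_deletion"
    } else "disruptive_inframe_deletion"
  }
}

# Does an SNP in the 5'UTR create a new upstream ATG?
utr5_start_gain <- function(info, pos, alt) {
  u <- info$utr[info$utr$label == "5_prime_UTR", , drop = FALSE]
  if (!nrow(u)) return(FALSE)
  u <- if (info$strand == "+") u[order(u$start), , drop = FALSE] else
    u[order(-u$start), , drop = FALSE]
  seq_ref <- paste(mapply(info$seg_seq, u$start, u$end), collapse = "")
  # offset of pos within the 5'UTR transcript sequence
  off <- 0L; hit <- NA_integer_
  for (i in seq_len(nrow(u))) {
    if (pos >= u$start[i] && pos <= u$end[i]) {
      hit <- off + if (info$strand == "+") pos - u$start[i] + 1L else u$end[i] - pos + 1L
      break
    }
    off <- off + u$end[i] - u$start[i] + 1L
  }
  if (is.na(hit)) return(FALSE)
  base <- if (info$strand == "-") chartr("ACGT", "TGCA", alt) else alt
  seq_alt <- seq_ref
  substr(seq_alt, hit, hit) <- base
  count_atg <- function(s) length(gregexpr("ATG", s, fixed = TRUE)[[1]][
    gregexpr("ATG", s, fixed = TRUE)[[1]] > 0])
  count_atg(seq_alt) > count_atg(seq_ref)
}

#' Annotate a single variant against gene models
#'
#' Determines every genomic zone the variant's affected bases overlap
#' (coding, splice donor/acceptor/region, UTRs, intron, up/downstream
#' windows, intergenic), refines coding zones to the concrete effect by
#' codon comparison on the strand-corrected CDS (synonymous vs missense;
#' indel length mod 3 deciding frameshift vs inframe, inframe split
#' conservative/disruptive by codon-boundary alignment), detects 5'UTR SNPs
#' that create a premature start codon, and reports the precedence-ordered
#' compound category with its impact tier.
#'
#' @param variant list or one-row data frame with `chrom`, `pos`, `ref`,
#'   `alt` (VCF convention: 1-based, indels left-anchored).
#' @param models a [gene_models()] object.
#' @param ref named character vector of chromosome sequences.
#' @param windows a [variant_windows()] configuration.
#' @param impacts impact mapping (see [impact_map()]).
#' @return list with `gene` (or `NA`), `category` (compound string),
#'   `primary` (highest-precedence component), `impact`, `type`.
#' @export
annotate_variant <- function(variant, models, ref, windows = variant_windows(),
                             impacts = impact_map(), cache = NULL) {
  if (is.null(cache)) cache <- annotation_cache(models, ref, windows)
  chrom <- variant$chrom; pos <- as.integer(variant$pos)
  refa <- toupper(variant$ref); alta <- toupper(variant$alt)
  if (refa == alta) abort("ref and alt alleles are identical")
  if (!chrom %in% names(ref)) abort("unknown chromosome %s", chrom)
  if (pos < 1L || pos + nchar(refa) - 1L > nchar(ref[[chrom]])) {
    abort("variant at %s:%d outside the reference", chrom, pos)
  }
  if (substr(ref[[chrom]], pos, pos + nchar(refa) - 1L) != refa) {
    abort("ref allele mismatch at %s:%d", chrom, pos)
  }
  rng <- affected_range(pos, refa, alta)
  type <- variant_type(refa, alta)

  genes <- models$genes[models$genes$chrom == chrom, , drop = FALSE]
  labels <- character(0)
  hit_gene <- NA_character_
  for (gid in genes$gene_id) {
    info <- cache$infos[[gid]]
    z <- cache$zones[[gid]]
    ov <- z[z$start <= rng[2] & z$end >= rng[1], , drop = FALSE]
    if (!nrow(ov)) next
    labs <- unique(ov$label)
    genic <- setdiff(labs, c("upstream_gene", "downstream_gene"))
    if (length(genic)) {
      if ("CDS" %in% genic) {
        genic[genic == "CDS"] <- coding_effect(info, pos, refa, alta)
      }
      if ("5_prime_UTR" %in% genic && type == "SNP" &&
          utr5_start_gain(info, pos, alta)) {
        genic[genic == "5_prime_UTR"] <- "5_prime_UTR_premature_start_codon_gain"
      }
      labels <- c(labels, genic)
      if (is.na(hit_gene)) hit_gene <- gid
    } else {
      labels <- c(labels, labs)
      if (is.na(hit_gene)) hit_gene <- gid
    }
  }
  genic_labels <- setdiff(labels, c("upstream_gene", "downstream_gene"))
  labels <- if (length(genic_labels)) genic_labels else labels
  if (!length(labels)) labels <- "intergenic"
  labels <- unique(labels)
  labels <- labels[order(match(labels, CATEGORY_PRECEDENCE))]
  primary <- labels[1]
  list(gene = hit_gene, category = paste(labels, collapse = "&"),
       primary = primary, impact = unname(impacts[primary]), type = type)
}

#' Annotate a table of variants
#'
#' @param variants data frame with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `id`.
#' @inheritParams annotate_variant
#' @return data frame with `id`, `chrom`, `pos`, `type`, `gene`, `category`,
#'   `primary`, `impact`.
#' @export
annotate_variants <- function(variants, models, ref,
                              windows = variant_windows(),
                              impacts = impact_map()) {
  if (is.null(variants$id)) variants$id <- sprintf("var%05d", seq_len(nrow(variants)))
  cache <- annotation_cache(models, ref, windows)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    a <- annotate_variant(variants[i, ], models, ref, windows, impacts, cache)
    data.frame(id = variants$id[i], chrom = variants$chrom[i],
               pos = variants$pos[i], type = a$type, gene = a$gene,
               category = a$category, primary = a$primary, impact = a$impact,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a variant annotation table
#'
#' Per-category counts and percentages (over all variants, rounded half-up
#' to `digits` decimals; compound categories are counted by their full
#' label) and per-impact-tier counts.
#'
#' @param annotations output of [annotate_variants()].
#' @param digits decimals for percentages (printed tables use 1 or 2).
#' @return list with `total`, `by_category` (data frame `category, n, pct`),
#'   `by_impact` (named integer vector).
#' @export
distribution_summary <- function(annotations, digits = 2) {
  if (is.null(annotations) || nrow(annotations) == 0) {
    return(list(total = 0L,
                by_category = data.frame(category = character(0), n = integer(0),
                                         pct = numeric(0)),
                by_impact = stats::setNames(integer(4),
                                            c("HIGH", "MODERATE", "LOW", "MODIFIER"))))
  }
  tab <- sort(table(annotations$category), decreasing = TRUE)
  by_cat <- data.frame(category = names(tab), n = as.integer(tab),
                       pct = round_half_up(100 * as.integer(tab) /
                                             nrow(annotations), digits),
                       row.names = NULL, stringsAsFactors = FALSE)
  imp <- table(factor(annotations$impact,
                      levels = c("HIGH", "MODERATE", "LOW", "MODIFIER")))
  list(total = nrow(annotations), by_category = by_cat,
       by_impact = stats::setNames(as.integer(imp), names(imp)))
}

#' Write variants as a minimal VCF-like table
#'
#' @param variants data frame with `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_lite <- function(variants, path) {
  if (is.null(variants$id)) variants$id <- sprintf("var%05d", seq_len(nrow(variants)))
  lines <- c("#CHROM\tPOS\tID\tREF\tALT",
             sprintf("%s\t%d\t%s\t%s\t%s", variants$chrom, variants$pos,
                     variants$id, variants$ref, variants$alt))
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal VCF-like table
#'
#' @param path input path (columns CHROM POS ID REF ALT, `#` header).
#' @return data frame with `chrom`, `pos`, `id`, `ref`, `alt`.
#' @export
read_vcf_lite <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "",
                          col.names = c("chrom", "pos", "id", "ref", "alt"),
                          skip = 1L, stringsAsFactors = FALSE)
  df$pos <- as.integer(df$pos)
  df
}
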