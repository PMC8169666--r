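# RING domain scanning and subtype classification.
#
# A RING domain is recognized as a chain of eight zinc-coordinating residues
# (metal ligands ML1..ML8, Cys/His in the canonical subtypes) whose seven
# inter-ligand gaps fall inside configured ranges. Scanning searches the
# union envelope of all subtype rules; classification then assigns each
# chain to the first subtype (in priority order) it satisfies.

empty_hit_table <- function() {
  cols <- c("start", "end", "span", "n_matched",
            paste0("p", 1:8), paste0("r", 1:8))
  df <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
  names(df) <- cols
  for (i in 1:4) df[[i]] <- integer(0)
  for (i in 5:12) df[[i]] <- integer(0)
  for (i in 13:20) df[[i]] <- character(0)
  df
}

#' Scan a protein sequence for candidate RING domains
#'
#' Enumerates every ligand chain compatible with the union of the rule set's
#' residue sets and gap ranges, then resolves overlaps greedily (leftmost
#' start first, shortest span on ties). Chains matching all eight ligand
#' positions are complete candidates; chains matching at least
#' `min_ligand_matches` positions (with all gaps satisfied) are emitted as
#' incomplete candidates unless `incomplete_policy` is `"drop"`. Complete
#' chains take precedence in overlap resolution, so an incomplete chain never
#' shadows an overlapping complete domain.
#'
#' @param sequence single protein sequence (20-letter alphabet, `X` allowed
#'   but never matching a ligand).
#' @param ruleset a [parse_ruleset()] rule set.
#' @return data frame of unclassified hits with 1-based inclusive `start`,
#'   `end`, `span`, `n_matched`, ligand positions `p1..p8` and ligand
#'   residues `r1..r8`, ordered by start.
#' @export
scan_domains <- function(sequence, ruleset) {
  stopifnot(inherits(ruleset, "ring_ruleset"))
  if (length(sequence) != 1 || is.na(sequence)) abort("sequence must be a single string")
  if (nchar(sequence) == 0) return(empty_hit_table())
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(AA_ALPHABET20, "X"))
  if (length(bad)) abort("sequence contains non amino-acid characters: %s",
                         paste(bad, collapse = ","))

  n <- length(chars)
  u <- ruleset_union(ruleset)
  budget <- if (ruleset$incomplete_policy == "drop") 0L else
    N_LIGANDS - ruleset$min_ligand_matches
  max_span <- ruleset$max_domain_span

  match_mat <- matrix(FALSE, N_LIGANDS, n)
  for (s in seq_len(N_LIGANDS)) match_mat[s, ] <- chars %in% u$residues[[s]]

  # min_tail[s]: minimal residues from the slot-s ligand to the ML8 ligand.
  min_tail <- rev(cumsum(rev(c(u$gap_min + 1L, 0L))))

  hits <- list()
  dfs <- function(slot, positions, mism) {
    if (slot == N_LIGANDS) {
      hits[[length(hits) + 1L]] <<- c(positions, N_LIGANDS - mism)
      return(invisible())
    }
    p <- positions[slot]
    qlo <- p + u$gap_min[slot] + 1L
    qhi <- min(p + u$gap_max[slot] + 1L, n,
               positions[1] + max_span - 1L - min_tail[slot + 1L])
    if (qhi < qlo) return(invisible())
    for (q in qlo:qhi) {
      if (match_mat[slot + 1L, q]) {
        dfs(slot + 1L, c(positions, q), mism)
      } else if (mism < budget) {
        dfs(slot + 1L, c(positions, q), mism + 1L)
      }
    }
  }
  p1_max <- n - min_tail[1]
  if (p1_max >= 1) {
    for (p in 1:p1_max) {
      if (match_mat[1L, p]) dfs(1L, p, 0L)
      else if (budget > 0L) dfs(1L, p, 1L)
    }
  }
  if (!length(hits)) return(empty_hit_table())

  m <- do.call(rbind, hits)
  pos <- m[, 1:8, drop = FALSE]
  df <- data.frame(start = pos[, 1], end = pos[, 8],
                   span = pos[, 8] - pos[, 1] + 1L,
                   n_matched = m[, 9])
  colnames(pos) <- paste0("p", 1:8)
  df <- cbind(df, as.data.frame(pos))
  res <- matrix(chars[t(pos)], ncol = 8, byrow = TRUE,
                dimnames = list(NULL, paste0("r", 1:8)))
  df <- cbind(df, as.data.frame(res, stringsAsFactors = FALSE))
  resolve_overlaps(df)
}

# Greedy overlap resolution: complete chains first (leftmost start, then
# shortest span, then ligand positions for full determinism), then
# incomplete candidates that overlap nothing already selected.
resolve_overlaps <- function(df) {
  pick <- function(cand, occupied) {
    keep <- integer(0)
    for (i in seq_len(nrow(cand))) {
      s <- cand$start[i]; e <- cand$end[i]
      if (!any(s <= occupied$end & e >= occupied$start)) {
        keep <- c(keep, i)
        occupied <- rbind(occupied, data.frame(start = s, end = e))
      }
    }
    list(rows = cand[keep, , drop = FALSE], occupied = occupied)
  }
  ord <- function(x) x[do.call(order, unname(x[c("start", "span", paste0("p", 2:7))])), ,
                       drop = FALSE]
  occupied <- data.frame(start = integer(0), end = integer(0))
  complete <- pick(ord(df[df$n_matched == N_LIGANDS, , drop = FALSE]), occupied)
  incomplete <- pick(ord(df[df$n_matched < N_LIGANDS, , drop = FALSE]),
                     complete$occupied)
  out <- rbind(complete$rows, incomplete$rows)
  out <- out[order(out$start, out$span), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify one candidate chain into a RING subtype
#'
#' Assigns the first subtype (rule-set priority order) whose residue sets and
#' gap ranges are all satisfied. If the only residue mismatch for a subtype is
#' its configured RBX substitution (e.g. Asp in place of Cys at ML8), that
#' subtype is assigned with the `RBX` flag. Otherwise the chain is labelled
#' `INCOMPLETE` and `missing_ligands` lists the ligand slots that fail the
#' best-matching gap-consistent rule.
#'
#' @param residues character vector of the 8 ligand residues.
#' @param gaps integer vector of the 7 inter-ligand gaps (residues between
#'   consecutive ligands).
#' @param ruleset a [parse_ruleset()] rule set.
#' @return list with `subtype` (subtype name or `"INCOMPLETE"`), `rbx`
#'   (logical) and `missing_ligands` (integer vector, empty unless
#'   INCOMPLETE).
#' @export
classify_hit <- function(residues, gaps, ruleset) {
  stopifnot(inherits(ruleset, "ring_ruleset"),
            length(residues) == N_LIGANDS, length(gaps) == N_LIGANDS - 1L)
  residues <- toupper(residues)
  best_missing <- NULL
  best_score <- -1L
  for (rule in ruleset$subtypes) {
    res_ok <- vapply(seq_len(N_LIGANDS),
                     function(i) residues[i] %in% rule$residues[[i]], TRUE)
    gap_ok <- all(gaps >= rule$gaps[, 1] & gaps <= rule$gaps[, 2])
    if (gap_ok && all(res_ok)) {
      return(list(subtype = rule$name, rbx = FALSE, missing_ligands = integer(0)))
    }
    if (gap_ok && !is.null(rule$rbx)) {
      miss <- which(!res_ok)
      if (identical(miss, rule$rbx$position) &&
          residues[miss] == rule$rbx$residue) {
        return(list(subtype = rule$name, rbx = TRUE, missing_ligands = integer(0)))
      }
    }
    score <- sum(res_ok) + if (gap_ok) N_LIGANDS else 0L  # prefer gap-consistent rules
    if (score > best_score) {
      best_score <- score
      best_missing <- which(!res_ok)
    }
  }
  list(subtype = "INCOMPLETE", rbx = FALSE,
       missing_ligands = as.integer(best_missing))
}

#' Classify a table of scanned hits
#'
#' Applies [classify_hit()] to every row of a [scan_domains()] hit table.
#'
#' @param hits hit table from [scan_domains()] (optionally with a
#'   `protein_id` column).
#' @param ruleset a [parse_ruleset()] rule set.
#' @return `hits` with added columns `subtype`, `rbx` and `missing_ligands`
#'   (comma-separated slot indices, `""` for classified hits).
#' @export
classify_hits <- function(hits, ruleset) {
  n <- nrow(hits)
  subtype <- character(n); rbx <- logical(n); missing <- character(n)
  rcols <- paste0("r", 1:8)
  pcols <- paste0("p", 1:8)
  for (i in seq_len(n)) {
    pos <- as.integer(hits[i, pcols])
    cl <- classify_hit(as.character(hits[i, rcols]), diff(pos) - 1L, ruleset)
    subtype[i] <- cl$subtype
    rbx[i] <- cl$rbx
    missing[i] <- paste(cl$missing_ligands, collapse = ",")
  }
  hits$subtype <- subtype
  hits$rbx <- rbx
  hits$missing_ligands <- missing
  hits
}

#' Name domains within multi-domain proteins
#'
#' Proteins with a single domain keep their bare identifier; proteins with
#' several domains get suffixes `a`, `b`, `c`, ... appended in order of
#' domain start position.
#'
#' @param hits classified hit table with `protein_id` and `start` columns.
#' @return `hits` with a `domain_name` column, original row order preserved.
#' @export
assign_domain_names <- function(hits) {
  stopifnot("protein_id" %in% names(hits))
  hits$domain_name <- hits$protein_id
  for (id in unique(hits$protein_id)) {
    idx <- which(hits$protein_id == id)
    if (length(idx) > 1) {
      idx <- idx[order(hits$start[idx])]
      hits$domain_name[idx] <- paste0(id, letters[seq_along(idx)])
    }
  }
  hits
}

#' Scan and classify a whole proteome
#'
#' Convenience wrapper: runs [scan_domains()], [classify_hits()] and
#' [assign_domain_names()] over a set of protein sequences.
#'
#' @param proteins named character vector of protein sequences.
#' @param ruleset a [parse_ruleset()] rule set; default [default_ruleset()].
#' @return classified, named hit table with a `protein_id` column.
#' @export
scan_proteome <- function(proteins, ruleset = default_ruleset()) {
  stopifnot(!is.null(names(proteins)))
  per <- lapply(names(proteins), function(id) {
    h <- scan_domains(proteins[[id]], ruleset)
    if (nrow(h)) cbind(protein_id = id, h, stringsAsFactors = FALSE) else NULL
  })
  per <- per[!vapply(per, is.null, TRUE)]
  if (!length(per)) {
    out <- cbind(protein_id = character(0), empty_hit_table())
    out$subtype <- character(0); out$rbx <- logical(0)
    out$missing_ligands <- character(0); out$domain_name <- character(0)
    return(out)
  }
  hits <- do.call(rbind, per)
  assign_domain_names(classify_hits(hits, ruleset))
}

#' Summarize classified RING domains into subtype groups
#'
#' Computes per-subtype domain counts and percentages (over classified
#' domains, excluding incomplete ones), the distribution of proteins by
#' domain count, and incomplete-domain tallies. Percentages are rounded
#' half-up to 2 decimals.
#'
#' @param x either a classified hit table (from [scan_proteome()] /
#'   [classify_hits()]) or a named numeric vector of per-subtype domain
#'   counts (an `INCOMPLETE` entry, if present, is tallied separately).
#' @param total_proteins total number of proteins scanned (defaults to the
#'   number of distinct `protein_id`s when `x` is a hit table).
#' @return list of class `ring_group_summary` with `counts`, `percentages`,
#'   `total_domains` (classified), `incomplete_domains`,
#'   `incomplete_proteins`, `proteins_by_domain_count`, `total_proteins`.
#' @export
summarize_groups <- function(x, total_proteins = NULL) {
  if (is.data.frame(x)) {
    stopifnot("subtype" %in% names(x))
    classified <- x[x$subtype != "INCOMPLETE", , drop = FALSE]
    counts <- table(factor(classified$subtype,
                           levels = unique(classified$subtype)))
    counts <- stats::setNames(as.integer(counts), names(counts))
    incomplete_domains <- sum(x$subtype == "INCOMPLETE")
    incomplete_proteins <- length(unique(x$protein_id[x$subtype == "INCOMPLETE"]))
    by_protein <- table(table(classified$protein_id))
    if (is.null(total_proteins) && "protein_id" %in% names(x)) {
      total_proteins <- length(unique(classified$protein_id))
    }
  } else {
    counts <- x[names(x) != "INCOMPLETE"]
    counts <- stats::setNames(as.integer(counts), names(counts))
    incomplete_domains <- if ("INCOMPLETE" %in% names(x)) as.integer(x[["INCOMPLETE"]]) else 0L
    incomplete_proteins <- NA_integer_
    by_protein <- NULL
  }
  total <- sum(counts)
  if (total == 0) {
    warning("no classified domains; percentages reported as 0")
    pct <- stats::setNames(rep(0, length(counts)), names(counts))
  } else {
    pct <- round_half_up(100 * counts / total, 2)
  }
  structure(list(counts = counts, percentages = pct,
                 total_domains = total,
                 incomplete_domains = incomplete_domains,
                 incomplete_proteins = incomplete_proteins,
                 proteins_by_domain_count = by_protein,
                 total_proteins = total_proteins),
            class = "ring_group_summary")
}

#' @export
print.ring_group_summary <- function(x, ...) {
  cat(sprintf("%d classified RING domains", x$total_domains))
  if (!is.null(x$total_proteins)) cat(sprintf(" in %d proteins", x$total_proteins))
  cat("\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-10s %5d (%.2f%%)\n", nm, x$counts[[nm]], x$percentages[[nm]]))
  }
  if (x$incomplete_domains > 0) {
    cat(sprintf("  incomplete %4d domains\n", x$incomplete_domains))
  }
  invisible(x)
}
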