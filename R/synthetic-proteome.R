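# Synthetic proteome generator with planted RING domains.
#
# Background residues are drawn from the 20-letter alphabet with Cys and His
# down-weighted (x0.3); residues between planted ligands avoid ligand letters
# entirely, and a post-hoc rescan redraws any window that would create a
# spurious complete chain, so the planted truth is exact by construction.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

bg_sample <- function(n, exclude = character(0), c_h_weight = 0.3) {
  letters20 <- setdiff(AA_ALPHABET20, exclude)
  w <- ifelse(letters20 %in% c("C", "H"), c_h_weight, 1)
  sample(letters20, n, replace = TRUE, prob = w / sum(w))
}

# Draw one domain realization for a subtype rule: ligand residues, gaps
# (rejection-sampled until the span fits max_span) and the interior sequence.
sample_range <- function(lo, hi) if (lo == hi) lo else sample(lo:hi, 1L)

sample_domain <- function(rule, max_span) {
  repeat {
    gaps <- vapply(seq_len(N_LIGANDS - 1L),
                   function(i) sample_range(rule$gaps[i, 1], rule$gaps[i, 2]), 1L)
    if (N_LIGANDS + sum(gaps) <= max_span) break
  }
  residues <- vapply(rule$residues, function(set) sample(set, 1L), "")
  chars <- character(0)
  for (i in seq_len(N_LIGANDS)) {
    chars <- c(chars, residues[i])
    if (i < N_LIGANDS) chars <- c(chars, bg_sample(gaps[i], exclude = c("C", "H")))
  }
  rel <- cumsum(c(1L, gaps + 1L))
  list(chars = chars, residues = residues, gaps = gaps, rel_positions = rel,
       span = length(chars))
}

normalize_domain_plan <- function(domain_plan, n_proteins, ruleset) {
  if (is.null(domain_plan)) {
    plan <- rep(list(character(0)), n_proteins)
  } else if (is.numeric(domain_plan) && !is.null(names(domain_plan))) {
    plan <- rep(list(character(0)), n_proteins)
    ids <- unlist(mapply(rep, names(domain_plan), domain_plan, SIMPLIFY = FALSE))
    if (length(ids) > n_proteins) {
      abort("domain plan requests %d single-domain proteins but n_proteins is %d",
            length(ids), n_proteins)
    }
    for (i in seq_along(ids)) plan[[i]] <- ids[[i]]
  } else if (is.list(domain_plan)) {
    if (length(domain_plan) > n_proteins) {
      abort("domain plan longer than n_proteins")
    }
    plan <- c(domain_plan, rep(list(character(0)), n_proteins - length(domain_plan)))
  } else {
    abort("domain_plan must be NULL, a named count vector, or a list")
  }
  unknown <- setdiff(unlist(plan), names(ruleset$subtypes))
  if (length(unknown)) {
    abort("unknown subtype(s) in domain plan: %s", paste(unique(unknown), collapse = ","))
  }
  plan
}

#' Generate a synthetic proteome with planted RING domains
#'
#' Builds protein sequences carrying RING domains of requested subtypes at
#' known positions, together with the planted-truth record. At
#' `decoy_rate = 0` the scanner finds exactly the planted complete domains:
#' spurious complete chains are detected by rescanning and the offending
#' background residues redrawn. A fraction `decoy_rate` of proteins receives
#' one near-miss motif (a planted chain with one ligand substituted by Ala)
#' that can only surface as an incomplete candidate.
#'
#' @param ruleset a [parse_ruleset()] rule set.
#' @param n_proteins number of proteins.
#' @param domain_plan per-protein subtype plan: a list of character vectors
#'   (one per protein, possibly empty or multi-domain), or a named count
#'   vector (one single-domain protein per count unit), or `NULL` for no
#'   planted domains.
#' @param decoy_rate fraction of proteins receiving a near-miss decoy motif.
#' @param seed integer seed; the output is deterministic given the seed.
#' @return list with `proteins` (named character vector) and `truth` (list
#'   with `planted_domains`: data frame of protein_id, subtype, start, end,
#'   ligand positions `p1..p8` and residues `r1..r8`).
#' @export
gen_proteome <- function(ruleset, n_proteins, domain_plan = NULL,
                         decoy_rate = 0, seed = 1L) {
  stopifnot(inherits(ruleset, "ring_ruleset"), is_count(n_proteins, 1),
            decoy_rate >= 0, decoy_rate <= 1)
  plan <- normalize_domain_plan(domain_plan, n_proteins, ruleset)
  scan_rules <- ruleset
  scan_rules$incomplete_policy <- "drop"   # cleanup only targets complete chains
  union_letters <- unique(unlist(ruleset_union(ruleset)$residues))

  with_seed(seed, {
    ids <- sprintf("P%04d", seq_len(n_proteins))
    proteins <- character(n_proteins)
    truth_rows <- list()
    inter_gap <- ruleset$max_domain_span + 10L  # no chain can straddle two domains

    for (i in seq_len(n_proteins)) {
      subtypes <- plan[[i]]
      chars <- bg_sample(sample(25:60, 1L))
      planted <- list()
      for (st in subtypes) {
        dom <- sample_domain(ruleset$subtypes[[st]], ruleset$max_domain_span)
        start <- length(chars) + 1L
        chars <- c(chars, dom$chars)
        planted[[length(planted) + 1L]] <- data.frame(
          protein_id = ids[i], subtype = st,
          start = start, end = start + dom$span - 1L,
          t(stats::setNames(start + dom$rel_positions - 1L, paste0("p", 1:8))),
          t(stats::setNames(dom$residues, paste0("r", 1:8))),
          stringsAsFactors = FALSE)
        chars <- c(chars, bg_sample(sample(inter_gap:(inter_gap + 40L), 1L)))
      }
      if (stats::runif(1) < decoy_rate) {
        decoy <- sample_domain(ruleset$subtypes[[1L]], ruleset$max_domain_span)
        decoy$chars[decoy$rel_positions[5L]] <- "A"
        chars <- c(chars, decoy$chars, bg_sample(sample(25:60, 1L)))
      } else if (length(subtypes)) {
        chars <- chars[seq_len(length(chars) - inter_gap + sample(25:60, 1L))]
      }
      planted_df <- if (length(planted)) do.call(rbind, planted) else NULL
      planted_pos <- if (is.null(planted_df)) character(0) else
        apply(planted_df[, paste0("p", 1:8)], 1, paste, collapse = "-")

      # Redraw background residues that create spurious complete chains.
      for (iter in 1:100) {
        hits <- scan_domains(paste(chars, collapse = ""), scan_rules)
        if (!nrow(hits)) spurious <- hits else {
          key <- apply(hits[, paste0("p", 1:8)], 1, paste, collapse = "-")
          spurious <- hits[!key %in% planted_pos, , drop = FALSE]
        }
        if (!nrow(spurious)) break
        fix <- setdiff(unlist(spurious[, paste0("p", 1:8)]),
                       if (is.null(planted_df)) integer(0) else
                         unlist(planted_df[, paste0("p", 1:8)]))
        chars[fix] <- bg_sample(length(fix), exclude = union_letters)
      }
      proteins[i] <- paste(chars, collapse = "")
      if (!is.null(planted_df)) truth_rows[[length(truth_rows) + 1L]] <- planted_df
    }
    names(proteins) <- ids
    planted_domains <- if (length(truth_rows)) do.call(rbind, truth_rows) else {
      out <- cbind(protein_id = character(0), subtype = character(0),
                   empty_hit_table()[, c("start", "end", paste0("p", 1:8), paste0("r", 1:8))])
      out
    }
    rownames(planted_domains) <- NULL
    list(proteins = proteins,
         truth = list(planted_domains = planted_domains))
  })
}
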