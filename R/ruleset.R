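# RING subtype rule sets: parsing, validation, defaults.

N_LIGANDS <- 8L

#' Parse a RING subtype rule set
#'
#' Reads and validates a rule-set configuration describing how RING domains
#' are detected and classified. A rule set carries an ordered list of subtype
#' rules, each with the residues accepted at the eight metal-ligand positions
#' (ML1..ML8) and seven inclusive inter-ligand gap ranges, plus global
#' settings (maximum domain span, incomplete-domain policy, the minimum
#' number of matched ligands for a candidate chain to be reported).
#'
#' @param config path to a YAML file, or an already-parsed list with the same
#'   structure (see the shipped `extdata/ring_rules.yaml`).
#' @return object of class `ring_ruleset`: list with elements `subtypes`
#'   (named list of rules, in priority order), `max_domain_span`,
#'   `incomplete_policy` (`"flag"` or `"drop"`) and `min_ligand_matches`.
#' @export
parse_ruleset <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg) || is.null(cfg$subtypes)) {
    abort("rule set must be a list with a 'subtypes' entry")
  }
  problems <- character(0)

  max_span <- cfg$max_domain_span %||% 102L
  if (!is_count(max_span, min = N_LIGANDS)) {
    problems <- c(problems, "max_domain_span must be an integer >= 8")
  }
  policy <- cfg$incomplete_policy %||% "flag"
  if (!policy %in% c("flag", "drop")) {
    problems <- c(problems, "incomplete_policy must be 'flag' or 'drop'")
  }
  min_match <- cfg$min_ligand_matches %||% 6L
  if (!is_count(min_match, min = 1) || min_match > N_LIGANDS) {
    problems <- c(problems, "min_ligand_matches must be an integer in 1..8")
  }

  subtypes <- lapply(seq_along(cfg$subtypes), function(i) {
    s <- cfg$subtypes[[i]]
    tag <- s$name %||% sprintf("subtype #%d", i)
    if (is.null(s$name) || !nzchar(s$name)) {
      problems <<- c(problems, sprintf("%s: missing name", tag))
    }
    res <- lapply(s$residues, function(r) {
      unique(strsplit(toupper(paste(r, collapse = "")), "")[[1]])
    })
    if (length(res) != N_LIGANDS) {
      problems <<- c(problems, sprintf("%s: needs %d residue slots", tag, N_LIGANDS))
    }
    bad <- setdiff(unlist(res), AA_ALPHABET20)
    if (length(bad)) {
      problems <<- c(problems, sprintf("%s: unknown residue letters %s", tag,
                                       paste(bad, collapse = ",")))
    }
    if (any(vapply(res, length, 1L) == 0)) {
      problems <<- c(problems, sprintf("%s: empty residue set", tag))
    }
    gaps <- do.call(rbind, lapply(s$gaps, function(g) as.integer(g[1:2])))
    if (is.null(gaps) || nrow(gaps) != N_LIGANDS - 1L || anyNA(gaps)) {
      problems <<- c(problems, sprintf("%s: needs %d gap ranges", tag, N_LIGANDS - 1L))
      gaps <- matrix(0L, N_LIGANDS - 1L, 2L)
    }
    if (any(gaps < 0L)) {
      problems <<- c(problems, sprintf("%s: negative gap bound", tag))
    }
    if (any(gaps[, 1] > gaps[, 2])) {
      problems <<- c(problems, sprintf("%s: gap range with min > max", tag))
    }
    rbx <- NULL
    if (!is.null(s$rbx_substitution)) {
      rbx <- list(position = as.integer(s$rbx_substitution$position),
                  residue = toupper(s$rbx_substitution$residue))
      if (is.na(rbx$position) || rbx$position < 1 || rbx$position > N_LIGANDS ||
          !rbx$residue %in% AA_ALPHABET20) {
        problems <<- c(problems, sprintf("%s: invalid rbx_substitution", tag))
      }
    }
    colnames(gaps) <- c("min", "max")
    list(name = s$name, residues = res, gaps = gaps, rbx = rbx)
  })
  names(subtypes) <- vapply(subtypes, function(s) s$name %||% "", "")
  if (anyDuplicated(names(subtypes))) {
    problems <- c(problems, sprintf("duplicate subtype names: %s",
                                    paste(unique(names(subtypes)[duplicated(names(subtypes))]),
                                          collapse = ",")))
  }
  if (length(problems)) {
    abort("invalid rule set:\n  - %s", paste(problems, collapse = "\n  - "))
  }
  structure(list(subtypes = subtypes,
                 max_domain_span = as.integer(max_span),
                 incomplete_policy = policy,
                 min_ligand_matches = as.integer(min_match)),
            class = "ring_ruleset")
}

#' Default RING rule set
#'
#' Parses the rule set shipped with the package: RING-H2 (C3H2C3) and RING-HC
#' (C3HC4) with the canonical consensus spacing C-x2-C-x(9-39)-C-x(1-3)-
#' H-x(2-3)-[H/C]-x2-C-x(4-48)-C-x2-C (minimum feasible span 30 residues),
#' an RBX variant of RING-H2 (Asp replacing Cys at ML8), and editable
#' placeholder rules for RING-v and RING-G.
#'
#' @return a `ring_ruleset`.
#' @export
default_ruleset <- function() {
  parse_ruleset(system.file("extdata", "ring_rules.yaml", package = "ringminer",
                            mustWork = TRUE))
}

#' @export
print.ring_ruleset <- function(x, ...) {
  cat(sprintf("RING rule set: %d subtypes (%s), max span %d, policy %s, min ligands %d\n",
              length(x$subtypes), paste(names(x$subtypes), collapse = ", "),
              x$max_domain_span, x$incomplete_policy, x$min_ligand_matches))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: union residue sets and gap envelopes across subtypes (what the
# scanner searches for before classification).
ruleset_union <- function(ruleset) {
  res <- lapply(seq_len(N_LIGANDS), function(i) {
    u <- unique(unlist(lapply(ruleset$subtypes, function(s) s$residues[[i]])))
    for (s in ruleset$subtypes) {
      if (!is.null(s$rbx) && s$rbx$position == i) u <- unique(c(u, s$rbx$residue))
    }
    u
  })
  lo <- apply(vapply(ruleset$subtypes, function(s) s$gaps[, 1], integer(N_LIGANDS - 1L)), 1, min)
  hi <- apply(vapply(ruleset$subtypes, function(s) s$gaps[, 2], integer(N_LIGANDS - 1L)), 1, max)
  list(residues = res, gap_min = as.integer(lo), gap_max = as.integer(hi))
}
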