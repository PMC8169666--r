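# Shared helpers.

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (half-up for
#' positive values), the convention used for all reported percentages. Base
#' [round()] rounds half to even, which does not reproduce printed tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage split of a count over a total
#'
#' Returns the percentage of `k` out of `n` and its complement, each rounded
#' half-up to `digits` decimals (e.g. 885 of 1255 proteins carrying an
#' additional domain gives 70.52 / 29.48).
#'
#' @param k count of interest.
#' @param n total count.
#' @param digits decimals to round to.
#' @return named numeric vector `c(pct, complement_pct)`.
#' @export
pct_split <- function(k, n, digits = 2) {
  stopifnot(n > 0, k >= 0, k <= n)
  c(pct = round_half_up(100 * k / n, digits),
    complement_pct = round_half_up(100 * (n - k) / n, digits))
}

# Internal: stop with a formatted message.
abort <- function(...) stop(sprintf(...), call. = FALSE)

# Internal: integer-ish check.
is_count <- function(x, min = 0) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= min && x == floor(x)
}

#' Write a TSV file with a header row
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV file with a header row
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write protein or nucleotide sequences as wrapped FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  xs <- if (type == "AA") Biostrings::AAStringSet(seqs) else
    Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(xs, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path input path.
#' @param type `"AA"` or `"DNA"`.
#' @return named character vector.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  xs <- if (type == "AA") Biostrings::readAAStringSet(path) else
    Biostrings::readDNAStringSet(path)
  out <- as.character(xs)
  names(out) <- sub("\\s.*$", "", names(xs))
  out
}
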