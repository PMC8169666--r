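# Small construction helpers for scanner tests.

# Assemble a protein string carrying one ligand chain with the given
# residues and inter-ligand gaps, padded with a background letter that never
# matches a ligand.
mk_chain <- function(residues, gaps, bg = "A", lead = 10, trail = 10) {
  stopifnot(length(residues) == 8, length(gaps) == 7)
  s <- character(0)
  for (i in 1:8) {
    s <- c(s, residues[i])
    if (i < 8) s <- c(s, rep(bg, gaps[i]))
  }
  paste(c(rep(bg, lead), s, rep(bg, trail)), collapse = "")
}

H2_RES <- c("C", "C", "C", "H", "H", "C", "C", "C")
HC_RES <- c("C", "C", "C", "H", "C", "C", "C", "C")
VALID_GAPS <- c(2, 12, 2, 3, 2, 10, 2)
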