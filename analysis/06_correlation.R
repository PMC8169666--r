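# Correlation screen of the 36-gene panel against GBSSI and SBEIIa.
#
# Stage means (4 developmental stages) are generated with a planted
# correlation geometry: 7 genes pass the screen against GBSSI, 8 against
# SBEIIa, 5 against both, giving the 10-gene candidate union.

source("analysis/00_common.R")

pan <- gen_correlation_panel(n_genes = 36L, n_a = 7L, n_b = 8L, n_overlap = 5L,
                             seed = SEED + 9L)
write_tsv_file(data.frame(gene = rownames(pan$expr), pan$expr,
                          check.names = FALSE),
               out_path("stage_means.tsv"))

res <- suppressWarnings(correlation_screen(pan$expr))
write_tsv_file(res, out_path("correlation_results.tsv"))

sel <- select_correlated_candidates(res, p_max = 0.05, min_r2 = 0.60)
message(sprintf("GBSSI set: %d, SBEIIa set: %d, overlap: %d, union: %d",
                sel$n_a, sel$n_b, sel$n_overlap, sel$n_union))
message("candidates: ", paste(sel$candidates, collapse = ", "))
jsonlite::write_json(sel[c("n_a", "n_b", "n_overlap", "n_union", "candidates")],
                     out_path("correlation_candidates.json"),
                     auto_unbox = TRUE, pretty = TRUE)
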