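# qRT-PCR validation: delta-delta-Ct fold changes and candidate screening.
#
# A 36-gene panel is measured at 7/14/21/28 DAA in the high-amylose mutant
# versus the parent (ARF as internal control, 3 biological replicates). The
# planted design carries 8 consistently down- and 3 consistently
# up-regulated genes with |log2FC| >= 2 at two or more stages.

source("analysis/00_common.R")

plan <- ringminer:::gen_qpcr_plan(36L, n_down = 8L, n_up = 3L, seed = SEED + 4L)
q <- gen_qpcr(plan, ref_gene_ct = 20, noise_sd = 0, replicates = 3L,
              seed = SEED + 5L)
utils::write.csv(q$table, out_path("ct_table.csv"), row.names = FALSE)

prof <- fc_profiles(q$table, mutant = "TAC75", control = "C306")
write_tsv_file(prof, out_path("qpcr_fc_profiles.tsv"))

cand <- count_candidates(prof, magnitude_min = 2, min_strong_stages = 2)
message(sprintf("candidates: %d down, %d up (total %d)",
                cand$n_down, cand$n_up, cand$n_down + cand$n_up))
message("down: ", paste(cand$down_ids, collapse = ", "))
message("up:   ", paste(cand$up_ids, collapse = ", "))
jsonlite::write_json(cand[c("n_down", "n_up", "down_ids", "up_ids")],
                     out_path("qpcr_candidates.json"), auto_unbox = TRUE,
                     pretty = TRUE)
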