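# Chromosomal distribution and duplication-class analysis.
#
# Lays out a 1238-gene family (plus filler genes) over 21 chromosomes with
# the planted class plan 4 singleton / 49 dispersed / 15 proximal /
# 90 tandem / 1080 WGD-segmental, writes the GFF3 + homolog pairs, then
# re-derives the classes from gene order and collinear block chaining.

source("analysis/00_common.R")

plan <- c(singleton = 4L, dispersed = 49L, proximal = 15L, tandem = 90L,
          WGD_segmental = 1080L)
map <- gen_gene_map(plan, n_chroms = 21, seed = SEED + 1L)
write_gene_map_gff3(map$loci, out_path("gene_map.gff3"))
write_tsv_file(map$pairs, out_path("homolog_pairs.tsv"))

loci <- load_gene_loci(out_path("gene_map.gff3"))
fam <- loci[loci$gene_id %in% map$family_genes, ]

dist <- chrom_distribution(fam)
print(dist)
mb <- mean_adjacent_distance(fam)
message(sprintf("mean adjacent family-gene distance: %.1f-%.1f Mb",
                min(mb$mean_mb, na.rm = TRUE), max(mb$mean_mb, na.rm = TRUE)))

blocks <- chain_collinear_blocks(map$pairs, loci)
message(sprintf("collinear blocks: %d (%d anchor pairs)",
                length(unique(blocks$block_id)), nrow(blocks)))
calls <- classify_duplications(fam, map$pairs, blocks, all_loci = loci)
counts <- duplication_class_counts(calls)
print(counts)
stopifnot(sum(counts) == nrow(fam))

write_tsv_file(calls, out_path("duplication_calls.tsv"))
jsonlite::write_json(as.list(counts), out_path("duplication_counts.json"),
                     auto_unbox = TRUE, pretty = TRUE)
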