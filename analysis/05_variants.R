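# Variant-effect categorization for the two mutant lines.
#
# Variants are planted on toy multi-exon gene models so that each line
# realizes its published category table (457 variants for the high-amylose
# line, 667 for the low-amylose line), then re-annotated from scratch and
# summarized by category and impact tier.

source("analysis/00_common.R")

toy <- toy_gene_models(seed = SEED + 6L)
plans <- ringminer:::variant_plans()

for (line in names(plans)) {
  gv <- gen_variants(toy, plans[[line]], seed = SEED + 7L + match(line, names(plans)))
  write_vcf_lite(gv$variants, out_path(sprintf("variants_%s.vcf", line)))
  ann <- annotate_variants(gv$variants, toy$models, toy$ref)
  write_tsv_file(ann, out_path(sprintf("variant_annotations_%s.tsv", line)))
  ds <- distribution_summary(ann, digits = 2)
  message(sprintf("%s: %d variants", line, ds$total))
  print(ds$by_category)
  print(ds$by_impact)
  stopifnot(identical(ann$category[match(gv$truth$id, ann$id)],
                      gv$truth$category))
  jsonlite::write_json(list(total = ds$total, by_impact = as.list(ds$by_impact),
                            by_category = ds$by_category),
                       out_path(sprintf("variant_summary_%s.json", line)),
                       auto_unbox = TRUE, pretty = TRUE)
}
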