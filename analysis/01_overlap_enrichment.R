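#!/usr/bin/env Rscript

# Overlap enrichment: gene lists and genomic risk intervals.
#
# The gene-list stage evaluates hypergeometric over-representation at the
# published list sizes (23 query genes; monogenic 54 / polygenic 127 /
# union 176 subject networks; 19,303-gene interactome background), with
# the observed overlap counts implied by each reported row. The interval
# stage demonstrates the locus pipeline end to end on synthetic loci with
# a known overlap against the 6598-block genome background.

suppressPackageStartupMessages(library(mrshare))

out_dir <- "results/overlap"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("Gene-list enrichment at the published parameters")
# (label, subject size K, observed overlap k); k for each row is the
# integer consistent with the reported fold x expected overlap. The
# published narrative count (19 of 23 against the 131-gene polygenic
# list) is shown alongside, since the two parameterizations differ and
# neither is privileged here.
rows <- list(
  list(label = "monogenic_subject", n = 23, K = 54, k = 3),
  list(label = "polygenic_subject", n = 23, K = 127, k = 20),
  list(label = "polygenic_subject_narrative", n = 23, K = 131, k = 19),
  list(label = "all_subject", n = 23, K = 176, k = 20)
)
gene_tab <- do.call(rbind, lapply(rows, function(r) {
  res <- hypergeom_enrichment(r$k, r$n, r$K, 19303)
  cbind(format_enrichment(res, r$label),
        k = r$k, n = r$n, K = r$K, fold_exact = res$fold)
}))
print(gene_tab)
readr::write_tsv(gene_tab, file.path(out_dir, "gene_enrichment.tsv"))

message("\nGenome block background: ",
        genome_block_count(3298912062, 500000), " blocks of 500 kb")

message("\nSynthetic locus-overlap analysis (known truth: 12 of 40 query loci overlap)")
sim <- simulate_overlap_loci(n_query = 40, n_subject = 55, k_true = 12,
                             seed = 20260925)
rep <- run_locus_overlap_report(sim$query, sim$subject, out_dir = out_dir)
print(rep$table)
message(sprintf("query loci: %d, subject loci: %d, overlapping query windows: %d",
                nrow(rep$query_loci), nrow(rep$subject_loci), rep$overlap$k))

message("\nWrote tables under ", out_dir)
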