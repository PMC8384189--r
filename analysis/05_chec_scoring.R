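#!/usr/bin/env Rscript
# Stage 5: ChEC-style coverage tracks and upstream/TESR enrichment.
#
# Per-million normalized tracks for the bound factor and free MNase;
# per-gene log2(upstream 500 bp / TESR 500 bp) enrichment scores; Wilcoxon
# rank-sum comparison of the two factors over the same genes, overall and
# within the concordant down/up gene groups (pairwise with Holm).

suppressMessages(library(medtail))
outdir <- "results/run"

ann <- read_annotation(file.path(outdir, "annotation.bed"),
                       file.path(outdir, "gene_labels.tsv"))
exp_ann <- ann[ann$organism == "experimental", ]
chrom_sizes <- c(chrI = 900000L, chrII = 900000L, spike_I = 200000L)

scores <- list()
for (f in c("bound_factor", "free_mnase")) {
  fr <- read_fragments_bed(file.path(outdir, paste0("fragments_", f,
                                                    ".bed")),
                           sample_id = f)
  tr <- fragment_coverage(fr, chrom_sizes, bin_size = 10L,
                          normalization = "per-million")
  write_bedgraph(tr, file.path(outdir, paste0("track_", f, ".bedgraph")))
  sc <- upstream_tesr_scores(tr, exp_ann, upstream_len = 500L,
                             tesr_len = 500L, pseudocount = 1)
  write.table(sc, file.path(outdir, paste0("scores_", f, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  scores[[f]] <- sc
  message(sprintf("%-12s: mean log2 upstream/TESR = %+.2f", f,
                  mean(sc$log2_ratio)))
}

cmp <- compare_groups(scores$bound_factor$log2_ratio,
                      scores$free_mnase$log2_ratio)
message(sprintf("bound factor vs free MNase: rank-sum p = %.3g",
                cmp$p_value))

# factor enrichment by regulated gene group (three groups -> Holm)
down <- readLines(file.path(outdir, "concordant_down.txt"))
up <- readLines(file.path(outdir, "concordant_up.txt"))
grp <- ifelse(exp_ann$gene_id %in% down, "down",
              ifelse(exp_ann$gene_id %in% up, "up", "unchanged"))
pw <- compare_groups_pairwise(scores$bound_factor$log2_ratio, grp)
out <- rbind(data.frame(group_1 = "bound_factor", group_2 = "free_mnase",
                        p_value = cmp$p_value, p_holm = NA),
             pw)
write.table(out, file.path(outdir, "group_comparison.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("stage 5 complete")
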