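#!/usr/bin/env Rscript
# Stage 4: cross-strain concordant gene sets.
#
# Union of genes significant in either strain, filtered to those changing
# in the same direction in both; Venn overlaps of the per-strain
# significant sets; coactivator-class composition (CR vs TFIID-dependent)
# of the concordant down- and up-sets; fraction of upregulated genes
# changing by less than 2-fold.

suppressMessages(library(medtail))
outdir <- "results/run"

de1 <- read_de_result(file.path(outdir, "de_deletion.tsv"))
de2 <- read_de_result(file.path(outdir, "de_depletion.tsv"))
labels_df <- read.delim(file.path(outdir, "gene_labels.tsv"))
labels <- setNames(labels_df$class, labels_df$gene_id)

rs <- concordant_union(de1, de2, alpha = 0.05)
message(sprintf(
  "union %d significant; concordant %d (%d down, %d up); %d discordant dropped",
  rs$counts["union_significant"], rs$counts["concordant_total"],
  rs$counts["concordant_down"], rs$counts["concordant_up"],
  rs$counts["discordant_dropped"]))

s1 <- significant_sets(de1, 0.05)
s2 <- significant_sets(de2, 0.05)
v_up <- venn_overlap(s2$up, s1$up)
v_dn <- venn_overlap(s2$down, s1$down)
cf_dn <- class_fractions(rs$concordant_down, labels)
cf_up <- class_fractions(rs$concordant_up, labels)
lfc1 <- setNames(de1$log2fc, de1$gene_id)
mf_up <- magnitude_fraction(rs$concordant_up, lfc1, fold_threshold = 2)

summary <- data.frame(
  metric = c("union_significant", "concordant_down", "concordant_up",
             "discordant_dropped", "single_result_dropped",
             "venn_up_shared_of_depletion_pct",
             "venn_down_shared_of_depletion_pct",
             "down_CR_pct", "up_TFIID_pct", "up_below_2fold_pct"),
  value = c(rs$counts["union_significant"], rs$counts["concordant_down"],
            rs$counts["concordant_up"], rs$counts["discordant_dropped"],
            rs$counts["single_result_dropped"],
            v_up$pct_of_A, v_dn$pct_of_A,
            cf_dn$pct_CR, cf_up$pct_TFIID, mf_up$pct_below))
write.table(summary, file.path(outdir, "gene_sets_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(rs$concordant_down, file.path(outdir, "concordant_down.txt"))
writeLines(rs$concordant_up, file.path(outdir, "concordant_up.txt"))

message(sprintf("down set: %.1f%% CR of %d annotated; up set: %.1f%% TFIID of %d annotated; %.1f%% of up genes < 2-fold",
                cf_dn$pct_CR, cf_dn$n_annotated, cf_up$pct_TFIID,
                cf_up$n_annotated, mf_up$pct_below))
message("stage 4 complete")
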