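#!/usr/bin/env Rscript
# Stage 6: short-fragment (<= 80 bp) TSS-centred TBP footprint profile.
#
# Fragments of at most 80 bp from the TBP-like library, deduplicated and
# CPM-normalized, averaged over a 2 kb strand-oriented window centred on
# the TSSs of all experimental genes and of the concordant down/up groups.

suppressMessages(library(medtail))
outdir <- "results/run"

ann <- read_annotation(file.path(outdir, "annotation.bed"),
                       file.path(outdir, "gene_labels.tsv"))
exp_ann <- ann[ann$organism == "experimental", ]
chrom_sizes <- c(chrI = 900000L, chrII = 900000L, spike_I = 200000L)
fr <- read_fragments_bed(file.path(outdir, "fragments_tbp_like.bed"),
                         sample_id = "tbp_like")

groups <- list(all = exp_ann,
               down = exp_ann[exp_ann$gene_id %in%
                                readLines(file.path(outdir,
                                                    "concordant_down.txt")), ],
               up = exp_ann[exp_ann$gene_id %in%
                              readLines(file.path(outdir,
                                                  "concordant_up.txt")), ])
profiles <- NULL
for (g in names(groups)) {
  if (nrow(groups[[g]]) == 0) next
  p <- size_filtered_profile(fr, groups[[g]], chrom_sizes, max_len = 80L,
                             flank = 1000L, bin = 10L)
  message(sprintf("group %-5s (%3d genes): profile peak at %+d bp from TSS",
                  g, nrow(groups[[g]]),
                  as.integer(p$position[which.max(p$signal)])))
  profiles <- if (is.null(profiles))
    data.frame(position = p$position, signal = p$signal,
               check.names = FALSE)
  else cbind(profiles, p$signal)
  names(profiles)[ncol(profiles)] <- g
}
write.table(profiles, file.path(outdir, "tbp_profiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("stage 6 complete")
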