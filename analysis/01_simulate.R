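#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data with known ground truth.
#
# One gene annotation (experimental + spike-in genomes) is shared by two
# simulated strains: a "deletion" with full true effects and a "depletion"
# with the same effects attenuated to 60%, mirroring a chronic knockout
# versus an acute degron. Cleavage-fragment libraries are generated for a
# UAS-bound factor, free MNase, and a TBP-like short-footprint factor.
# Everything is written as plain text under results/run/ together with the
# ground truth (true fold changes, depth factors, UAS windows).

suppressMessages(library(medtail))

outdir <- "results/run"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260929L, n_genes_exp = 400L,
                  n_genes_spike = 50L,
                  chrom_sizes = c(chrI = 900000L, chrII = 900000L),
                  n_fragments = 50000L)
ann <- simulate_annotation(cfg)
params <- sim_params(ann, cfg)
write_annotation(ann, file.path(outdir, "annotation.bed"),
                 file.path(outdir, "gene_labels.tsv"))
write_ground_truth(ann, params, cfg, outdir)

strains <- c(deletion = 1.0, depletion = 0.6)
for (s in names(strains)) {
  p <- params
  p$true_log2fc <- p$true_log2fc * strains[[s]]
  scfg <- cfg
  scfg$seed <- child_seed(cfg$seed, paste0("strain/", s))
  cm <- simulate_counts(ann, scfg, params = p)
  write_count_matrix(cm, file.path(outdir, paste0("counts_", s, ".tsv")),
                     file.path(outdir, paste0("samples_", s, ".tsv")))
  message(sprintf("strain %-10s: %d genes x %d samples, %d true effects",
                  s, nrow(cm$counts), ncol(cm$counts),
                  sum(p$true_log2fc != 0)))
}

for (f in c("bound_factor", "free_mnase", "tbp_like")) {
  fr <- simulate_fragments(ann, cfg, factor = f, sample_id = f)
  write_fragments_bed(fr, file.path(outdir, paste0("fragments_", f,
                                                   ".bed")))
  message(sprintf("fragments %-12s: %d total, %.1f%% spike-in", f,
                  nrow(fr), 100 * mean(fr$organism == "spikein")))
}

message("stage 1 complete: ", outdir)
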