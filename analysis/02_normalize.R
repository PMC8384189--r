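#!/usr/bin/env Rscript
# Stage 2: spike-in size factors.
#
# Library size factors for each strain are estimated by median-of-ratios
# on the spike-in genes only, then compared with the true depth factors
# recorded by the simulator. ChEC spike-in scale factors are derived from
# spike-in fragment counts of the three fragment libraries.

suppressMessages(library(medtail))
outdir <- "results/run"

truth <- read.delim(file.path(outdir, "true_depth_factors.tsv"))
for (s in c("deletion", "depletion")) {
  cm <- read_count_matrix(file.path(outdir, paste0("counts_", s, ".tsv")),
                          file.path(outdir, paste0("samples_", s, ".tsv")))
  sf <- size_factors_median_of_ratios(cm)
  write_size_factors(sf, file.path(outdir,
                                   paste0("size_factors_", s, ".tsv")))
  est <- sf$sf / exp(mean(log(sf$sf)))
  tru <- setNames(truth$depth_factor, truth$sample_id)[names(sf$sf)]
  tru <- tru / exp(mean(log(tru)))
  message(sprintf(
    "strain %-10s: %d spike-in genes used, Spearman rho vs truth = %.3f, mean rel err = %.1f%%",
    s, sf$n_genes_used, cor(est, tru, method = "spearman"),
    100 * mean(abs(est - tru) / tru)))
}

frs <- lapply(c(bound_factor = "bound_factor", free_mnase = "free_mnase",
                tbp_like = "tbp_like"), function(f)
  read_fragments_bed(file.path(outdir, paste0("fragments_", f, ".bed")),
                     sample_id = f))
scales <- chec_scale_factors(frs)
write.table(data.frame(sample_id = names(scales), scale = unname(scales)),
            file.path(outdir, "chec_scale_factors.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("ChEC scale factors: ",
        paste(sprintf("%s=%.3f", names(scales), scales), collapse = ", "))
message("stage 2 complete")
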