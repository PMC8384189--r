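test_that("zero spike-in fraction places no fragments on spike chroms", {
  cfg <- tiny_config(seed = 21L, spikein_fraction = 0)
  ann <- simulate_annotation(cfg)
  fr <- simulate_fragments(ann, cfg, "bound_factor")
  expect_identical(nrow(fr), cfg$n_fragments)
  expect_false(any(fr$organism == "spikein"))
})

test_that("with background weight 0 every midpoint lies inside a UAS window", {
  cfg <- tiny_config(seed = 22L, spikein_fraction = 0,
                     uas_signal_weight = 1)
  ann <- simulate_annotation(cfg)
  fr <- simulate_fragments(ann, cfg, "bound_factor")
  mid <- fr$start + fr$length %/% 2L
  win <- uas_window(ann[ann$organism == "experimental", ], cfg)
  # brute-force membership scan over every fragment x window pair
  inside <- vapply(seq_len(nrow(fr)), function(i)
    any(win$chrom == fr$chrom[i] & win$start <= mid[i] &
          mid[i] < win$end), logical(1))
  expect_true(all(inside))
})

test_that("fragment output is byte-identical under a fixed seed", {
  cfg <- tiny_config(seed = 23L)
  ann <- simulate_annotation(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_fragments_bedpe(simulate_fragments(ann, cfg, "free_mnase"), f1)
  write_fragments_bedpe(simulate_fragments(ann, cfg, "free_mnase"), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("fragment counts are exact and spike share is binomial", {
  cfg <- tiny_config(seed = 24L, spikein_fraction = 0.2,
                     n_fragments = 5000L)
  ann <- simulate_annotation(cfg)
  fr <- simulate_fragments(ann, cfg, "free_mnase")
  expect_identical(nrow(fr), 5000L)
  share <- mean(fr$organism == "spikein")
  se <- sqrt(0.2 * 0.8 / 5000)
  expect_lt(abs(share - 0.2), 4 * se)
})

test_that("fragment lengths respect the mixture bounds; tbp signal is short", {
  cfg <- tiny_config(seed = 25L, spikein_fraction = 0,
                     uas_signal_weight = 1)
  ann <- simulate_annotation(cfg)
  fr <- simulate_fragments(ann, cfg, "tbp_like")
  expect_true(all(fr$length <= 80))
  fr2 <- simulate_fragments(ann, tiny_config(seed = 25L), "free_mnase")
  mix <- cfg$fraglen_mix
  expect_true(all(fr2$length >= min(mix$min) & fr2$length <= max(mix$max)))
})

test_that("free MNase background is enriched at TES regions", {
  cfg <- tiny_config(seed = 26L, spikein_fraction = 0,
                     tes_background_boost = 3, n_fragments = 20000L)
  ann <- simulate_annotation(cfg)
  fr <- simulate_fragments(ann, cfg, "free_mnase")
  mid <- fr$start + fr$length %/% 2L
  tes <- tesr_window(ann[ann$organism == "experimental", ], 500L)
  in_tes <- vapply(seq_len(nrow(fr)), function(i)
    any(tes$chrom == fr$chrom[i] & tes$start <= mid[i] &
          mid[i] < tes$end), logical(1))
  tes_len <- sum(tes$end - tes$start)
  genome_len <- sum(cfg$chrom_sizes)
  expected_flat <- tes_len / genome_len
  # boosted density: observed share must clearly exceed the flat share
  expect_gt(mean(in_tes), 2 * expected_flat)
})

test_that("ground truth round-trips through the plain-text writers", {
  cfg <- tiny_config(seed = 27L)
  ann <- simulate_annotation(cfg)
  params <- sim_params(ann, cfg)
  dir <- tempfile()
  paths <- write_ground_truth(ann, params, cfg, dir)
  gp <- utils::read.delim(paths[1])
  expect_equal(stats::setNames(gp$true_log2fc, gp$gene_id),
               params$true_log2fc[gp$gene_id])
  dp <- utils::read.delim(paths[2])
  expect_equal(stats::setNames(dp$depth_factor, dp$sample_id),
               params$depth_factors)
  uw <- utils::read.delim(paths[3])
  expect_equal(nrow(uw), sum(ann$organism == "experimental"))
})
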