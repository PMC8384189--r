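# brute-force median-of-ratios oracle: explicit loops, no shared code with
# the implementation
brute_force_mor <- function(k) {
  m <- ncol(k)
  usable <- which(apply(k, 1, function(r) all(r > 0)))
  ratios <- matrix(NA_real_, length(usable), m)
  for (ii in seq_along(usable)) {
    g <- prod(k[usable[ii], ])^(1 / m)
    for (j in seq_len(m)) ratios[ii, j] <- k[usable[ii], j] / g
  }
  list(sf = apply(ratios, 2, function(x) {
    s <- sort(x)
    n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }), n = length(usable))
}

test_that("identical samples give unit size factors", {
  k <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  sf <- size_factors_median_of_ratios(k)
  expect_equal(unname(sf$sf), c(1, 1))
  expect_identical(sf$n_genes_used, 3L)
})

test_that("an exact 2x sample yields sf (1/sqrt(2), sqrt(2))", {
  k <- matrix(c(10L, 50L, 200L, 20L, 100L, 400L), ncol = 2,
              dimnames = list(paste0("s", 1:3), c("A", "B")))
  sf <- size_factors_median_of_ratios(k)
  # hand oracle: g_i = sqrt(k_iA * 2 k_iA) = k_iA sqrt(2); every ratio is
  # 1/sqrt(2) in A and sqrt(2) in B
  expect_equal(unname(sf$sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
})

test_that("genes containing zeros are excluded from the estimator", {
  k <- matrix(c(10L, 0L, 30L, 40L,
                20L, 5L, 60L, 80L), ncol = 2,
              dimnames = list(paste0("s", 1:4), c("A", "B")))
  k[2, 1] <- 0L
  sf <- size_factors_median_of_ratios(k)
  expect_identical(sf$n_genes_used, 3L)
  expect_error(size_factors_median_of_ratios(matrix(0L, 2, 2)),
               "positive geometric mean")
})

test_that("estimator matches the brute-force oracle on random matrices", {
  set.seed(31)
  for (trial in 1:20) {
    k <- matrix(rpois(15, 50) + 1L, nrow = 5, ncol = 3,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
    ours <- size_factors_median_of_ratios(k)
    ref <- brute_force_mor(k)
    expect_equal(unname(ours$sf), ref$sf, tolerance = 1e-12)
    expect_identical(ours$n_genes_used, ref$n)
  }
})

test_that("scaling one sample's counts is tracked by the oracle", {
  set.seed(32)
  k <- matrix(rpois(15, 100) + 1L, nrow = 5, ncol = 3,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  k2 <- k
  k2[, 2] <- k2[, 2] * 3L
  ours <- size_factors_median_of_ratios(k2)
  ref <- brute_force_mor(k2)
  expect_equal(unname(ours$sf), ref$sf, tolerance = 1e-12)
  # the scaled sample's ratio column grows by c^(1 - 1/m)
  r1 <- size_factors_median_of_ratios(k)$sf[2]
  expect_equal(unname(ours$sf[2] / r1), 3^(1 - 1 / 3), tolerance = 1e-12)
})

test_that("size factors agree with the reference median-of-ratios code", {
  set.seed(33)
  # odd gene count: with an even count the reference takes the midpoint on
  # the log scale while this package midpoints the raw ratios
  k <- matrix(rpois(306, 200) + 1L, nrow = 51, ncol = 6,
              dimnames = list(paste0("g", 1:51), paste0("s", 1:6)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(k)
  ours <- size_factors_median_of_ratios(k)
  expect_equal(unname(ours$sf), unname(ref), tolerance = 1e-10)
})

test_that("apply_size_factors divides columns and validates sample ids", {
  k <- matrix(c(10L, 20L), nrow = 1, dimnames = list("g", c("A", "B")))
  expect_equal(unname(apply_size_factors(k, c(A = 1, B = 1))), unname(k))
  expect_equal(unname(apply_size_factors(k, c(A = 1, B = 2))[1, ]),
               c(10, 10))
  expect_error(apply_size_factors(k, c(A = 1)), "B")
})

test_that("estimated factors recover true depth on simulated spike-ins", {
  cfg <- sim_config(seed = 41L, n_genes_exp = 5L, n_genes_spike = 80L,
                    spike_chrom_sizes = c(spike_I = 500000L),
                    replicates_per_condition = 3L,
                    depth_factors = c(0.6, 1.8, 0.9, 1.4, 0.75, 1.1),
                    dispersion = 0.05)
  ann <- simulate_annotation(cfg)
  cm <- simulate_counts(ann, cfg)
  sf <- size_factors_median_of_ratios(cm)
  d <- cm$params$depth_factors
  expect_equal(cor(sf$sf, d, method = "spearman"), 1)
  norm <- apply_size_factors(cm, sf)
  spike <- cm$organism[rownames(norm)] == "spikein"
  col_means <- colMeans(norm[spike, ])
  # normalized spike-in means equal across samples within sampling error
  expect_lt(max(col_means) / min(col_means), 1.1)
})

test_that("ChEC scale factors satisfy the reciprocal and mean-1 rules", {
  expect_equal(unname(chec_scale_factors(c(a = 100, b = 100))), c(1, 1))
  expect_equal(unname(chec_scale_factors(c(a = 100, b = 200))),
               c(4 / 3, 2 / 3))
  expect_equal(unname(chec_scale_factors(c(only = 123))), 1)
  expect_error(chec_scale_factors(c(a = 10, bad = 0)), "bad")
  frs <- list(s1 = data.frame(organism = rep(c("spikein", "experimental"),
                                             c(10, 90)), sample_id = "s1"),
              s2 = data.frame(organism = rep(c("spikein", "experimental"),
                                             c(20, 80)), sample_id = "s2"))
  expect_equal(unname(chec_scale_factors(frs)), c(4 / 3, 2 / 3))
})
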