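gene_row <- function(chrom, start, end, strand, id = "g1") {
  ann <- data.frame(gene_id = id, chrom = chrom, start = as.integer(start),
                    end = as.integer(end), strand = strand,
                    stringsAsFactors = FALSE)
  ann$tss <- ifelse(strand == "+", ann$start, ann$end - 1L)
  ann$tes <- ifelse(strand == "+", ann$end - 1L, ann$start)
  ann$organism <- "experimental"
  ann$class <- "unannotated"
  ann$tata <- FALSE
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

uniform_track <- function(v, L = 100000L, bin = 10L) {
  tr <- list(bins = list(c1 = rep(v, ceiling(L / bin))), bin_size = bin,
             chrom_sizes = c(c1 = L), normalization = "raw")
  class(tr) <- "signal_track"
  tr
}

test_that("uniform signal gives a log2 ratio of exactly zero", {
  ann <- rbind(gene_row("c1", 20000, 22000, "+", "gp"),
               gene_row("c1", 50000, 52000, "-", "gm"))
  sc <- upstream_tesr_scores(uniform_track(2.5), ann)
  expect_equal(sc$log2_ratio, c(0, 0))
  expect_false(any(sc$clipped))
})

test_that("constructed window counts give the hand-computed ratio", {
  ann <- gene_row("c1", 20000, 22000, "+")
  # upstream window [19500, 20000); TESR [21749, 22249)
  up_frags <- data.frame(chrom = "c1",
                         start = as.integer(seq(19500, 19940, length.out = 400)),
                         stringsAsFactors = FALSE)
  up_frags$end <- up_frags$start + 50L
  te_frags <- data.frame(chrom = "c1",
                         start = as.integer(seq(21749, 22150, length.out = 100)),
                         stringsAsFactors = FALSE)
  te_frags$end <- te_frags$start + 50L
  fr <- rbind(up_frags, te_frags)
  fr$length <- 50L
  tr <- fragment_coverage(fr, c(c1 = 100000L), bin_size = 1L,
                          normalization = "raw")
  sc <- upstream_tesr_scores(tr, ann, pseudocount = 1e-9)
  # counting oracle: 400 vs 100 fragments of equal length, all inside
  expect_equal(sc$log2_ratio, 2, tolerance = 1e-6)
})

test_that("mirrored minus-strand genes score identically", {
  L <- 50000L
  ann_p <- gene_row("c1", 20000, 22000, "+")
  ann_m <- gene_row("c1", L - 22000, L - 20000, "-")
  set.seed(81)
  s <- as.integer(sample(18000:23000, 300, replace = TRUE))
  e <- s + 60L
  fr_p <- data.frame(chrom = "c1", start = s, end = e, length = 60L)
  fr_m <- data.frame(chrom = "c1", start = L - e, end = L - s, length = 60L)
  tr_p <- fragment_coverage(fr_p, c(c1 = L), bin_size = 1L,
                            normalization = "raw")
  tr_m <- fragment_coverage(fr_m, c(c1 = L), bin_size = 1L,
                            normalization = "raw")
  sp <- upstream_tesr_scores(tr_p, ann_p)
  sm <- upstream_tesr_scores(tr_m, ann_m)
  expect_equal(sm$upstream_signal, sp$upstream_signal, tolerance = 1e-9)
  expect_equal(sm$log2_ratio, sp$log2_ratio, tolerance = 1e-9)
})

test_that("scores ignore global track rescaling when pseudocount is zero", {
  ann <- gene_row("c1", 20000, 22000, "+")
  set.seed(82)
  s <- as.integer(sample(19000:23000, 500, replace = TRUE))
  fr <- data.frame(chrom = "c1", start = s, end = s + 80L, length = 80L)
  t_raw <- fragment_coverage(fr, c(c1 = 100000L), normalization = "raw")
  t_pm <- fragment_coverage(fr, c(c1 = 100000L),
                            normalization = "per-million")
  s_raw <- upstream_tesr_scores(t_raw, ann, pseudocount = 0)
  s_pm <- upstream_tesr_scores(t_pm, ann, pseudocount = 0)
  expect_equal(s_raw$log2_ratio, s_pm$log2_ratio, tolerance = 1e-9)
})

test_that("windows truncated at a chromosome edge are flagged", {
  ann <- gene_row("c1", 200, 1200, "+") # upstream window starts at -300
  sc <- upstream_tesr_scores(uniform_track(1, L = 5000L), ann)
  expect_true(sc$clipped)
})

test_that("rank-sum comparison matches exact enumeration and invariances", {
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  # exact oracle: 20 equally likely rank splits, the observed one and its
  # mirror are the most extreme -> two-sided p = 2/20
  expect_equal(compare_groups(a, b)$p_value, 0.1)
  expect_equal(compare_groups(a + 100, b + 100)$p_value, 0.1)
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("pairwise comparisons apply Holm correction across pairs", {
  set.seed(83)
  vals <- c(rnorm(10), rnorm(10) + 3, rnorm(10) + 3.2)
  grp <- rep(c("a", "b", "c"), each = 10)
  pw <- compare_groups_pairwise(vals, grp)
  expect_identical(nrow(pw), 3L)
  expect_equal(pw$p_holm, p.adjust(pw$p_value, method = "holm"))
  expect_true(all(pw$p_holm >= pw$p_value))
})
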