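test_that("significant sets split by adjusted p and fold-change sign", {
  de <- toy_de(paste0("g", 1:5), c(1, 0.5, -2, -0.1, 0.3),
               c(0.01, 0.2, 0.04, 0.9, 0.03))
  s <- significant_sets(de, 0.05)
  expect_setequal(s$up, c("g1", "g5"))
  expect_setequal(s$down, "g3")
  empty <- significant_sets(toy_de("g1", 1, 1), 0.05)
  expect_length(empty$up, 0)
  all_in <- significant_sets(de, 1.0)
  expect_setequal(c(all_in$up, all_in$down), paste0("g", 1:5))
})

test_that("identical contrasts make concordant sets equal significant sets", {
  de <- toy_de(paste0("g", 1:6), c(1, -1, 2, -2, 0.5, -0.5),
               c(0.01, 0.01, 0.2, 0.04, 0.9, 0.03))
  rs <- concordant_union(de, de, 0.05)
  s <- significant_sets(de, 0.05)
  expect_setequal(rs$concordant_up, s$up)
  expect_setequal(rs$concordant_down, s$down)
  expect_length(rs$discordant_dropped, 0)
})

test_that("the six-gene worked example partitions as enumerated by hand", {
  # 1: significant both, same sign; 2: significant only in 1, same sign;
  # 3: significant only in 1, opposite sign; 4: significant only in 2,
  # same sign; 5: significant nowhere; 6: significant both, opposite sign
  de1 <- toy_de(paste0("g", 1:6),
                log2fc = c(1, 1, 1, -1, 1, 1),
                padj = c(0.01, 0.01, 0.01, 0.5, 0.5, 0.01))
  de2 <- toy_de(paste0("g", 1:6),
                log2fc = c(2, 0.5, -1, -2, 0.8, -1),
                padj = c(0.01, 0.5, 0.5, 0.01, 0.5, 0.01))
  rs <- concordant_union(de1, de2, 0.05)
  expect_setequal(rs$union_significant, paste0("g", c(1, 2, 3, 4, 6)))
  expect_setequal(rs$concordant_up, c("g1", "g2"))
  expect_setequal(rs$concordant_down, "g4")
  expect_setequal(rs$discordant_dropped, c("g3", "g6"))
  expect_length(rs$single_result_dropped, 0)
})

test_that("no significant genes yields empty regulated sets", {
  de <- toy_de(paste0("g", 1:4), c(1, -1, 2, -2), rep(0.9, 4))
  rs <- concordant_union(de, de, 0.05)
  expect_length(rs$union_significant, 0)
  expect_identical(unname(rs$counts["concordant_total"]), 0L)
})

test_that("genes absent from one result are dropped and counted", {
  de1 <- toy_de(paste0("g", 1:3), c(1, 1, 1), c(0.01, 0.01, 0.5))
  de2 <- toy_de(paste0("g", 2:3), c(1, 1), c(0.5, 0.01))
  rs <- concordant_union(de1, de2, 0.05)
  expect_setequal(rs$single_result_dropped, "g1")
  expect_setequal(rs$concordant_up, c("g2", "g3"))
})

test_that("bookkeeping categories always sum to the union size", {
  set.seed(61)
  for (trial in 1:200) {
    n <- sample(5:40, 1)
    ids <- paste0("g", seq_len(n))
    de1 <- toy_de(ids, rnorm(n), runif(n))
    ids2 <- sample(ids, sample(seq_len(n), 1))
    de2 <- toy_de(ids2, rnorm(length(ids2)), runif(length(ids2)))
    rs <- concordant_union(de1, de2, 0.2)
    expect_identical(
      unname(rs$counts["concordant_down"] + rs$counts["concordant_up"] +
               rs$counts["discordant_dropped"] +
               rs$counts["single_result_dropped"]),
      unname(rs$counts["union_significant"]))
  }
})

test_that("venn overlap reports counts and one-decimal shared fractions", {
  A <- paste0("a", 1:340)
  B <- c(A[1:100], paste0("b", 1:478))
  v <- venn_overlap(A, B)
  expect_identical(v$n_shared, 100L)
  expect_equal(v$pct_of_A, 29.4)
  v2 <- venn_overlap(paste0("x", 1:44), c(paste0("x", 1:34), "y1"))
  expect_equal(v2$pct_of_A, 77.3)
  expect_equal(venn_overlap("a", "b")$pct_of_A, 0)
  expect_true(is.na(venn_overlap(character(0), "b")$pct_of_A))
  # symmetry of the intersection count
  expect_identical(venn_overlap(A, B)$n_shared, venn_overlap(B, A)$n_shared)
})

test_that("class fractions use annotated genes as denominator", {
  labels <- c(setNames(rep("CR", 139), paste0("c", 1:139)),
              setNames(rep("TFIID", 29), paste0("t", 1:29)),
              setNames(rep("unannotated", 19), paste0("u", 1:19)))
  cf <- class_fractions(names(labels), labels)
  expect_identical(cf$n_annotated, 168L)
  expect_equal(cf$pct_CR, 82.7)
  labels2 <- c(setNames(rep("TFIID", 496), paste0("t", 1:496)),
               setNames(rep("CR", 175), paste0("c", 1:175)))
  cf2 <- class_fractions(names(labels2), labels2)
  expect_equal(cf2$pct_TFIID, 73.9)
  one <- class_fractions("g1", c(g1 = "CR"))
  expect_equal(one$pct_CR, 100)
  expect_true(is.na(class_fractions("u1", c(u1 = "unannotated"))$pct_CR))
})

test_that("magnitude fractions count genes below the fold threshold", {
  lfc <- setNames(c(rep(0.5, 628), rep(1.5, 116)), paste0("g", 1:744))
  mf <- magnitude_fraction(names(lfc), lfc, fold_threshold = 2)
  expect_identical(mf$n_below, 628L)
  expect_equal(mf$pct_below, 84.4)
  z <- setNames(rep(0, 5), paste0("g", 1:5))
  expect_equal(magnitude_fraction(names(z), z)$pct_below, 100)
  # threshold 1: 2^|lfc| >= 1 always, strict inequality never satisfied
  v <- setNames(c(0.1, -0.2, 0, 1, -3), paste0("g", 1:5))
  expect_equal(magnitude_fraction(names(v), v, 1)$pct_below, 0)
  expect_true(is.na(magnitude_fraction(character(0), lfc)$pct_below))
})

test_that("percentages are rounded half-up to one decimal", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(29.44, 1), 29.4)
  expect_equal(round_half_up(82.75, 1), 82.8)
})
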