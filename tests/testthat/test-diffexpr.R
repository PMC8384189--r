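sim_counts_matrix <- function(seed, ng, n_per_group, mu, alpha, lfc = 0) {
  set.seed(seed)
  lfc <- rep_len(lfc, ng)
  cond <- rep(c("A", "B"), each = n_per_group)
  k <- sapply(seq_along(cond), function(j) {
    m <- mu * 2^(lfc * (cond[j] == "B"))
    if (alpha == 0) rpois(ng, m) else rnbinom(ng, mu = m, size = 1 / alpha)
  })
  dimnames(k) <- list(sprintf("g%04d", seq_len(ng)),
                      paste0(cond, seq_along(cond)))
  list(k = k, cond = cond, sf = setNames(rep(1, length(cond)),
                                         colnames(k)))
}

test_that("dispersion estimates vanish for Poisson data", {
  d <- sim_counts_matrix(51, 2000, 6, mu = 100, alpha = 0)
  a <- estimate_dispersion(d$k, d$sf, d$cond, pool_floor = FALSE)
  expect_lte(median(a), 0.01)
})

test_that("zero within-condition variance returns the dispersion floor", {
  k <- matrix(rep(c(50L, 80L), each = 4), nrow = 1,
              dimnames = list("g1", paste0("s", 1:8)))
  cond <- rep(c("A", "B"), each = 4)
  a <- estimate_dispersion(k, setNames(rep(1, 8), colnames(k)), cond,
                           pool_floor = FALSE)
  expect_equal(unname(a), 1e-8)
})

test_that("dispersion estimates recover the simulated value", {
  d <- sim_counts_matrix(52, 2000, 20, mu = 200, alpha = 0.2)
  a <- estimate_dispersion(d$k, d$sf, d$cond, pool_floor = FALSE)
  expect_lt(abs(mean(a) - 0.2), 0.05)
})

test_that("all-zero genes are flagged low_count and excluded from BH", {
  d <- sim_counts_matrix(53, 50, 3, mu = 100, alpha = 0.05)
  d$k[1, ] <- 0L
  res <- wald_test_two_group(d$k, d$sf, d$cond, c("A", "B"))
  expect_identical(res$status[1], "low_count")
  expect_true(is.na(res$pvalue[1]) && is.na(res$padj[1]))
  tested <- res$status == "tested"
  expect_equal(res$padj[tested],
               p.adjust(res$pvalue[tested], method = "BH"))
})

test_that("identical groups give zero fold change and p = 1", {
  k <- matrix(rep(c(10L, 20L, 30L), 2), nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  cond <- rep(c("A", "B"), each = 3)
  res <- wald_test_two_group(k, setNames(rep(1, 6), colnames(k)), cond,
                             c("A", "B"))
  expect_equal(res$log2fc, 0)
  expect_equal(res$pvalue, 1)
})

test_that("swapping the contrast negates log2fc and preserves p", {
  d <- sim_counts_matrix(54, 200, 3, mu = 100, alpha = 0.05,
                         lfc = rep(c(0, 1), each = 100))
  r1 <- wald_test_two_group(d$k, d$sf, d$cond, c("A", "B"))
  r2 <- wald_test_two_group(d$k, d$sf, d$cond, c("B", "A"))
  expect_equal(r2$log2fc, -r1$log2fc)
  expect_equal(r2$pvalue, r1$pvalue)
})

test_that("results are invariant to a common rescaling of size factors", {
  d <- sim_counts_matrix(55, 200, 3, mu = 100, alpha = 0.05,
                         lfc = rep(c(0, 1), each = 100))
  r1 <- wald_test_two_group(d$k, d$sf, d$cond, c("A", "B"))
  r2 <- wald_test_two_group(d$k, d$sf * 7.3, d$cond, c("A", "B"))
  expect_equal(r2$log2fc, r1$log2fc, tolerance = 1e-12)
  expect_equal(r2$pvalue, r1$pvalue, tolerance = 1e-12)
})

test_that("BH adjustment agrees with the brute-force step-up procedure", {
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    for (i in seq(m - 1, 1)) adj[i] <- min(adj[i], adj[i + 1])
    pmin(adj, 1)[order(o)]
  }
  set.seed(56)
  for (trial in 1:10) {
    p <- runif(sample(2:50, 1))
    expect_equal(p.adjust(p, method = "BH"), step_up(p))
  }
})

test_that("power is monotone non-decreasing in the true effect size", {
  power_at <- function(lfc) {
    hits <- 0; tot <- 0
    for (s in 1:5) {
      d <- sim_counts_matrix(600 + s, 1000, 3, mu = 100, alpha = 0.05,
                             lfc = rep(c(0, lfc), each = 500))
      res <- wald_test_two_group(d$k, d$sf, d$cond, c("A", "B"))
      hits <- hits + sum(res$padj[501:1000] < 0.05, na.rm = TRUE)
      tot <- tot + 500
    }
    hits / tot
  }
  p <- vapply(c(0.5, 1, 2), power_at, numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_gt(p[3], p[1])
})

test_that("absent contrast labels raise an error", {
  d <- sim_counts_matrix(57, 10, 2, mu = 50, alpha = 0.05)
  expect_error(wald_test_two_group(d$k, d$sf, d$cond, c("A", "Z")), "Z")
})
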