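# Reconstructs the published worked example as explicit gene tables: two
# strains' differential-transcription calls with the reported set sizes,
# overlaps and concordance structure (824 significant in the deletion
# strain, 578 up; 384 in the depletion strain, 340 up; 100 shared up, 34
# shared down; 932 concordant = 187 down + 745 up out of the 1,068-gene
# union, implying 136 direction-discordant union genes of which 6 are
# significant in both strains with opposite signs). Percentages, Venn
# counts and bookkeeping must all be recomputed from these tables by the
# package.
printed_example_de <- function() {
  ids <- sprintf("y%04d", 1:6000)
  take <- local({
    i <- 0L
    function(n) {
      out <- ids[(i + 1L):(i + n)]
      i <<- i + n
      out
    }
  })
  # category: (sign in strain 1, sign in strain 2, significant in 1, in 2)
  cats <- list(
    shared_up = list(take(100), +1, +1, TRUE, TRUE),
    up1_conc  = list(take(450), +1, +1, TRUE, FALSE),
    up1_disc  = list(take(25),  +1, -1, TRUE, FALSE),
    cross_12  = list(take(3),   +1, -1, TRUE, TRUE),
    up2_conc  = list(take(195), +1, +1, FALSE, TRUE),
    up2_disc  = list(take(42),  -1, +1, FALSE, TRUE),
    cross_21  = list(take(3),   -1, +1, TRUE, TRUE),
    shared_dn = list(take(34),  -1, -1, TRUE, TRUE),
    dn1_conc  = list(take(146), -1, -1, TRUE, FALSE),
    dn1_disc  = list(take(63),  -1, +1, TRUE, FALSE),
    dn2_conc  = list(take(7),   -1, -1, FALSE, TRUE)
  )
  lfc1 <- setNames(rep(0.1, 6000), ids)
  lfc2 <- setNames(rep(0.1, 6000), ids)
  padj1 <- setNames(rep(0.9, 6000), ids)
  padj2 <- setNames(rep(0.9, 6000), ids)
  for (cat in cats) {
    lfc1[cat[[1]]] <- cat[[2]]
    lfc2[cat[[1]]] <- cat[[3]]
    if (cat[[4]]) padj1[cat[[1]]] <- 0.01
    if (cat[[5]]) padj2[cat[[1]]] <- 0.01
  }
  list(de1 = toy_de(ids, unname(lfc1), unname(padj1)),
       de2 = toy_de(ids, unname(lfc2), unname(padj2)))
}
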