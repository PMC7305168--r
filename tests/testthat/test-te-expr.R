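# TE quantification: fractional family counts, unique copy counts,
# upregulated-copy summaries, ERV-proximal genes, LTR strand metaplots.

test_that("fractional family counting splits multi-mappers and conserves mass", {
  tes <- rbind(te_df("chr1", 1000, 2000, "famA"),
               te_df("chr1", 5000, 6000, "famA"),
               te_df("chr2", 1000, 2000, "famB"),
               te_df("chr2", 5000, 6000, "famB"))
  # read r1: 4 hits, two alignments in famA, two in famB -> 0.5 each
  aln <- rbind(
    aln_df(rep("r1", 4), c("chr1", "chr1", "chr2", "chr2"),
           c(1100, 5100, 1100, 5100), c(1200, 5200, 1200, 5200),
           n_hits = 4L),
    aln_df("r2", "chr1", 1500, 1600, n_hits = 1L),     # unique in famA
    aln_df("r3", "chr1", 9000, 9100, n_hits = 1L))     # outside any TE
  fc <- count_te_families(aln, tes)
  get <- function(f) fc[fc$family == f, 3]
  expect_equal(get("famA"), 0.5 + 1)
  expect_equal(get("famB"), 0.5)
  expect_equal(get("unassigned"), 1)
  # total mass equals the number of distinct reads
  expect_equal(sum(fc[, 3]), 3, tolerance = 1e-6)
})

test_that("an alignment overlapping two families splits its weight equally", {
  tes <- rbind(te_df("chr1", 1000, 2000, "famA"),
               te_df("chr1", 1900, 3000, "famB"))
  aln <- aln_df("r1", "chr1", 1850, 1950, n_hits = 1L)
  fc <- count_te_families(aln, tes)
  expect_equal(fc[fc$family == "famA", 3], 0.5)
  expect_equal(fc[fc$family == "famB", 3], 0.5)
})

test_that("fractional mass is conserved on fuzzed alignment tables", {
  set.seed(31)
  tes <- do.call(rbind, lapply(1:20, function(i)
    te_df("chr1", i * 5000, i * 5000 + sample(200:3000, 1),
          sample(c("A", "B", "C"), 1))))
  for (rep in 1:5) {
    reads <- lapply(1:50, function(r) {
      nh <- sample(1:5, 1)
      pos <- sample(0:110000, nh)
      aln_df(rep(paste0("r", r), nh), "chr1", pos, pos + 100,
             n_hits = nh)
    })
    aln <- do.call(rbind, reads)
    fc <- count_te_families(aln, tes)
    expect_equal(sum(fc[, 3]), 50, tolerance = 1e-6)
    # any copy with unique counts implies nonzero family mass
    cc <- count_te_copies(aln, tes)
    with_unique <- tes$family[rowSums(cc) > 0]
    expect_true(all(fc[fc$family %in% with_unique, 3] > 0))
  }
})

test_that("copy counting uses unique reads only and counts spanned copies", {
  tes <- rbind(te_df("chr1", 1000, 2000, "famA"),
               te_df("chr1", 2000, 3000, "famA"))
  aln <- rbind(aln_df("r1", "chr1", 1500, 1600, n_hits = 2L),
               aln_df("r1", "chr1", 2500, 2600, n_hits = 2L),
               aln_df("r2", "chr1", 1950, 2050, n_hits = 1L))
  cc <- count_te_copies(aln, tes)
  expect_equal(unname(cc[, 1]), c(1L, 1L))   # r1 multi-maps: excluded;
                                             # r2 spans both copies
  empty <- count_te_copies(aln, tes[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("per-sample columns are kept separate", {
  tes <- te_df("chr1", 1000, 2000, "famA")
  aln <- aln_df(c("r1", "r2"), "chr1", c(1100, 1100), c(1200, 1200),
                n_hits = 1L, sample = c("s1", "s2"))
  fc <- count_te_families(aln, tes)
  expect_equal(fc[fc$family == "famA", "s1"], 1)
  expect_equal(fc[fc$family == "famA", "s2"], 1)
})

test_that("copy-up summaries compute percentages and the size contrast", {
  set.seed(32)
  tes <- do.call(rbind, lapply(1:10, function(i)
    te_df("chr1", i * 10000, i * 10000 + ifelse(i <= 3, 6000, 500),
          "famA")))
  de <- data.frame(feature_id = tes$copy_id,
                   log2fc = c(rep(3, 3), rep(0, 7)),
                   p = c(rep(1e-9, 3), rep(0.9, 7)),
                   p_adj = c(rep(1e-6, 3), rep(0.95, 7)))
  de <- call_de(de, "te_copies")
  su <- copy_up_summary(de, tes)
  expect_equal(su$families$n_copies, 10)
  expect_equal(su$families$n_up, 3)
  expect_equal(su$families$pct_up, 30)
  # only long copies are up -> significant size difference, direction up
  expect_lt(su$size_test$p, 0.01)
  expect_gt(su$size_test$median_up, su$size_test$median_not_up)
  # identical length sets give p = 1
  tes2 <- do.call(rbind, lapply(1:6, function(i)
    te_df("chr1", i * 10000, i * 10000 + 1000, "famB")))
  de2 <- data.frame(feature_id = tes2$copy_id,
                    log2fc = rep(c(3, 0), each = 3),
                    p = rep(c(1e-9, 0.9), each = 3),
                    p_adj = rep(c(1e-6, 0.9), each = 3))
  su2 <- copy_up_summary(call_de(de2, "te_copies"), tes2)
  expect_equal(su2$size_test$p, 1)
  # no up copies: size test skipped
  de3 <- de2; de3$p_adj <- 1; de3 <- call_de(de3, "te_copies")
  expect_null(copy_up_summary(de3, tes2)$size_test)
})

test_that("ERV-proximal genes use a strict 20 kb TSS distance", {
  tx <- rbind(tx_df("near", "near.t1", "chr1", "+", 115000, 118000),
              tx_df("far", "far.t1", "chr1", "+", 125001, 128000),
              tx_df("other", "other.t1", "chr2", "+", 1000, 4000))
  up_erv <- te_df("chr1", 95000, 100000, "IAPEz-int")
  de <- data.frame(feature_id = c("near", "far", "other"),
                   log2fc = c(2, 0, 0), p = 1, p_adj = 1,
                   up = c(TRUE, FALSE, FALSE))
  res <- erv_proximal_genes(up_erv, tx, de, seed = 9)
  expect_equal(res$proximal, "near")   # 15 kb away; 25 kb excluded
  # empty when no ERV is up
  res0 <- erv_proximal_genes(up_erv[0, ], tx, de)
  expect_equal(res0$n_proximal, 0)
  # seeded control is reproducible
  res2 <- erv_proximal_genes(up_erv, tx, de, seed = 9)
  expect_identical(res$sets$random_ctrl, res2$sets$random_ctrl)
})

test_that("LTR metaplot merges close elements and bins both strands", {
  tes <- rbind(te_df("chr1", 100000, 100400, "IAPLTR1_Mm"),
               te_df("chr1", 107000, 107400, "IAPLTR1_Mm"),  # 6.6 kb gap
               te_df("chr1", 200000, 200400, "IAPLTR1_Mm"))  # far away
  cov_fwd <- data.frame(chrom = "chr1", start = 99000, end = 101000,
                        score = 2)
  cov_rev <- data.frame(chrom = "chr1", start = 99000, end = 101000,
                        score = 1)
  mp <- ltr_strand_metaplot(cov_fwd, cov_rev, tes, "IAPLTR1_Mm")
  expect_equal(nrow(mp$elements), 2)          # <8 kb merged
  expect_equal(length(mp$sense), 200)         # 10,000 / 50
  expect_error(ltr_strand_metaplot(cov_fwd, cov_rev, tes, "absent"),
               "not in annotation")
  # 9 kb apart stays separate
  tes2 <- rbind(te_df("chr1", 100000, 100400, "IAPLTR1_Mm"),
                te_df("chr1", 109400, 109800, "IAPLTR1_Mm"))
  mp2 <- ltr_strand_metaplot(cov_fwd, cov_rev, tes2, "IAPLTR1_Mm")
  expect_equal(nrow(mp2$elements), 2)
  # plus-strand element: sense = forward coverage around the start
  el1 <- mp$sense_matrix[1, ]
  expect_equal(max(el1, na.rm = TRUE), 2)
  expect_equal(max(mp$antisense_matrix[1, ], na.rm = TRUE), 1)
})

test_that("a minus-strand element flips orientation", {
  tes <- te_df("chr1", 100000, 100400, "ltr", strand = "-")
  # forward-strand signal upstream in genome = downstream of the element
  cov_fwd <- data.frame(chrom = "chr1", start = 95000, end = 96000,
                        score = 5)
  cov_rev <- data.frame(chrom = "chr1", start = 104000, end = 105000,
                        score = 3)
  mp <- ltr_strand_metaplot(cov_fwd, cov_rev, tes, "ltr")
  # anchor is the 5' start (the genomic end of a minus element).
  # Reverse-strand signal genomically above the anchor is sense signal
  # upstream of the start -> negative offsets (low bins); forward-strand
  # signal genomically below is antisense downstream -> positive offsets
  expect_true(all(which(mp$sense > 0) <= 100))
  expect_true(all(which(mp$antisense > 0) > 100))
})
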