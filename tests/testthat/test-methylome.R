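# Methylation summarisation: pooling, feature/window means, classes,
# de novo selection, metaplots, correlation, DMRs.

test_that("replicate pooling sums counts and recomputes percentages", {
  a <- calls_df("chr1", c(10, 20), c(10, 10), c(5, 2))
  b <- calls_df("chr1", c(10, 30), c(10, 4), c(0, 4))
  p <- pool_replicates(list(a, b))
  expect_equal(p$pct_meth[p$start == 10], 25)           # (5+0)/(10+10)
  expect_equal(sort(p$start), c(10, 20, 30))            # union of CpGs
  expect_equal(pool_replicates(list(a)), a)             # identity

  # pooled value is count-weighted, not the mean of percentages: oracle
  # by brute-force recomputation from concatenated raw counts
  set.seed(1)
  tabs <- lapply(1:3, function(i)
    calls_df("chr1", c(5, 6, 7), sample(1:30, 3), 0))
  for (i in seq_along(tabs))
    tabs[[i]]$n_meth <- rbinom(3, tabs[[i]]$depth, 0.4)
  tabs <- lapply(tabs, function(t) {
    t$pct_meth <- 100 * t$n_meth / t$depth; t
  })
  p <- pool_replicates(tabs)
  raw <- do.call(rbind, tabs)
  oracle <- sapply(split(raw, raw$start), function(d)
    100 * sum(d$n_meth) / sum(d$depth))
  expect_equal(p$pct_meth, unname(oracle[as.character(p$start)]))
  naive <- sapply(split(raw, raw$start), function(d) mean(d$pct_meth))
  expect_false(isTRUE(all.equal(unname(naive), p$pct_meth)))
})

test_that("feature means are CpG-weighted and respect the half-open end", {
  calls <- calls_df("chr1", c(100, 200, 300), 10, c(4, 6, 9))
  feats <- data.frame(chrom = "chr1", start = c(50, 0), end = c(300, 10))
  fm <- feature_methylation(calls, feats)
  expect_equal(fm$mean_pct[1], 50)     # 40% and 60%; CpG at 300 excluded
  expect_equal(fm$n_cpgs[1], 2)
  expect_true(is.na(fm$mean_pct[2]))   # no CpGs -> undefined, not 0
})

test_that("family methylation drops families under the CpG coverage floor", {
  tes <- rbind(te_df("chr1", 0, 5000, "famA"),
               te_df("chr1", 6000, 11000, "famB"))
  calls <- calls_df("chr1", c(seq(10, 4900, length.out = 120),
                              seq(6010, 10900, length.out = 99)),
                    10, 5)
  fam <- family_methylation(calls, tes, min_cpgs = 100)
  expect_equal(fam$family, "famA")     # famB has 99 CpGs: dropped
  expect_equal(fam$mean_pct, 50)
})

test_that("window methylation tiles from zero and needs a minimum CpG count", {
  calls <- calls_df("chr1", c(100, 200, 1500, 1600, 1700), 10,
                    c(0, 0, 0, 0, 10))
  w <- window_methylation(calls, chrom_lengths = c(chr1 = 3500),
                          window_size = 1000, min_cpgs = 3)
  expect_equal(nrow(w), ceiling(3500 / 1000))
  expect_true(is.na(w$mean_pct[1]))              # 2 CpGs only
  expect_equal(w$mean_pct[2], 100 * 10 / 10 / 3) # 0, 0, 100 -> 33.33
  expect_equal(w$end[4], 3500)                   # truncated last window
})

test_that("window classes use >50 / [10,50] / <10 and partition to 1", {
  w <- data.frame(chrom = "chr1", start = 0:5 * 1000, end = 1:6 * 1000,
                  n_cpgs = 5,
                  mean_pct = c(55, 10.0, 50.0, 9.99, NA, 80))
  cl <- classify_windows(w)
  expect_equal(as.character(cl$class), c("high", "medium", "medium",
                                         "low", "high"))
  expect_equal(sum(cl$proportions), 1, tolerance = 1e-12)
  empty <- w; empty$mean_pct <- NA
  expect_warning(cl0 <- classify_windows(empty), "no windows")
  expect_equal(length(cl0$class), 0)
})

test_that("de novo window selection equals the brute-force filter and is strict", {
  set.seed(2)
  n <- 200
  early <- data.frame(chrom = "chr1", start = 0:(n - 1) * 1000,
                      end = 1:n * 1000, n_cpgs = 5,
                      mean_pct = runif(n, 0, 100))
  late <- early
  late$mean_pct <- runif(n, 0, 100)
  early$mean_pct[c(5, 6)] <- c(3, 3)
  late$mean_pct[c(5, 6)] <- c(60, 50)   # row 6: exactly 50 -> rejected
  sel <- select_de_novo_windows(early, late)
  brute <- which(!is.na(early$mean_pct) & !is.na(late$mean_pct) &
                   early$mean_pct < 5 & late$mean_pct > 50)
  expect_equal(sel$start, early$start[brute])
  expect_true(early$start[5] %in% sel$start)
  expect_false(early$start[6] %in% sel$start)
  # idempotent under re-filtering
  sel2 <- sel[sel$mean_early < 5 & sel$mean_late > 50, ]
  expect_equal(nrow(sel2), nrow(sel))
  bad <- late[-1, ]
  expect_error(select_de_novo_windows(early, bad), "tilings differ")
})

test_that("gene metaplot is flat on a constant methylome and strand-aware", {
  tx <- tx_df("g1", "g1.t1", "chr1", "+", 20000, 24000)
  calls <- constant_calls(seq(5000, 40000, by = 97), pct = 80)
  mp <- gene_metaplot(calls, tx)
  expect_equal(nrow(mp), 40)
  expect_true(all(abs(mp$mean_pct - 80) < 1e-9, na.rm = TRUE))

  # upstream flank of a minus-strand gene maps to bins -10..-1
  tx_m <- tx_df("g2", "g2.t1", "chr1", "-", 20000, 24000)
  # methylation high only downstream of the gene end (upstream of TSS)
  calls2 <- rbind(constant_calls(seq(24100, 34000, by = 50), pct = 100),
                  constant_calls(seq(10000, 23950, by = 50), pct = 0))
  mp2 <- gene_metaplot(calls2, tx_m)
  up <- mp2$mean_pct[grepl("^-", as.character(mp2$bin))]
  down <- mp2$mean_pct[grepl("^\\+", as.character(mp2$bin))]
  expect_true(all(up > 99))
  expect_true(all(down < 1))
})

test_that("gene metaplot matches a brute-force per-bin oracle and translates", {
  set.seed(3)
  g0 <- 50000; g1 <- 54000
  tx <- tx_df("g1", "g1.t1", "chr1", "+", g0, g1)
  pos <- sort(sample(seq(g0 - 10000, g1 + 10000), 400))
  calls <- calls_df("chr1", pos, 20, rbinom(400, 20, 0.5))
  mp <- gene_metaplot(calls, tx)
  # brute force: assign each CpG to its bin, average
  breaks <- c(seq(g0 - 10000, g0, by = 1000)[1:10],
              seq(g0, g1, length.out = 21),
              seq(g1 + 1000, g1 + 10000, by = 1000))
  oracle <- sapply(seq_len(40), function(b) {
    lo <- breaks[b]; hi <- breaks[b + 1]
    sel <- pos >= lo & pos < hi
    if (!any(sel)) NA_real_ else mean(calls$pct_meth[sel])
  })
  expect_equal(mp$mean_pct, oracle)
  # invariance under uniform coordinate translation
  sh <- calls; sh$start <- sh$start + 12345L; sh$end <- sh$end + 12345L
  tx_sh <- tx_df("g1", "g1.t1", "chr1", "+", g0 + 12345, g1 + 12345)
  expect_equal(gene_metaplot(sh, tx_sh)$mean_pct, mp$mean_pct)
})

test_that("site metaplot geometry and constant-field flatness hold", {
  sites <- data.frame(chrom = "chr1", pos = 50000, strand = "+")
  calls <- constant_calls(seq(40000, 60000, by = 83), pct = 40)
  mp <- site_metaplot(calls, sites, "methylation")
  expect_equal(nrow(mp), 40)
  expect_true(all(abs(mp$value - 40) < 1e-9))
  # strand flip reverses an asymmetric profile
  asym <- rbind(constant_calls(seq(45000, 49999, by = 40), pct = 100),
                constant_calls(seq(50000, 55000, by = 40), pct = 0))
  plus <- site_metaplot(asym, sites, "methylation")
  minus <- site_metaplot(asym, transform(sites, strand = "-"),
                         "methylation")
  expect_equal(minus$value, rev(plus$value))
})

test_that("CpG density mode counts dinucleotides per kb around sites", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGT", 5000), collapse = "")))  # CG density: one per 4 bp
  sites <- data.frame(chrom = "chr1", pos = 10000, strand = "+")
  mp <- site_metaplot(NULL, sites, "cpg_density", genome = genome)
  expect_equal(nrow(mp), 40)
  # 250 bp bins catch 62 or 63 of the 4-periodic CpGs: 248-252 per kb
  expect_true(all(abs(mp$value - 250) <= 2))
  expect_equal(mean(mp$value), 250)
  # near-edge site flags partial bins
  edge <- data.frame(chrom = "chr1", pos = 1000, strand = "+")
  mp2 <- site_metaplot(NULL, edge, "cpg_density", genome = genome)
  expect_gt(attr(mp2, "n_partial"), 0)
  expect_true(anyNA(mp2$value))
})

test_that("window correlation handles identity, anticorrelation and errors", {
  w <- data.frame(chrom = "chr1", start = 0:9 * 1000, end = 1:10 * 1000,
                  n_cpgs = 5, mean_pct = seq(5, 95, length.out = 10))
  expect_equal(methylation_correlation(w, w), 1)
  anti <- w; anti$mean_pct <- 100 - w$mean_pct
  expect_equal(methylation_correlation(w, anti), -1)
  few <- w; few$mean_pct[3:10] <- NA
  expect_error(methylation_correlation(w, few), "fewer than 3")
})

test_that("gDMR scoring produces one column per genotype", {
  gdmrs <- data.frame(chrom = "chr1", start = c(0, 5000),
                      end = c(2000, 7000), name = c("d1", "d2"))
  by_gt <- list(WT = calls_df("chr1", 100, 100, 47),
                KO = calls_df("chr1", 100, 10, 1))
  sc <- score_gdmrs(by_gt, gdmrs)
  expect_equal(sc$mean_pct.WT, c(47, NA))
  expect_equal(sc$mean_pct.KO, c(10, NA))
  empty <- score_gdmrs(by_gt, gdmrs[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("DMR caller enforces the three published criteria", {
  # identical conditions: no DMRs
  a <- calls_df("chr1", seq(100, 2000, by = 50), 30, 15)
  expect_equal(nrow(call_dmrs(a, a)), 0)

  # planted 5-CpG region at 80% vs 10%, depth 30: recovered
  set.seed(4)
  pos <- seq(100, 5000, by = 100)
  base_a <- calls_df("chr1", pos, 30, rbinom(length(pos), 30, 0.5))
  base_b <- calls_df("chr1", pos, 30, rbinom(length(pos), 30, 0.5))
  reg <- pos >= 2000 & pos < 2500
  base_a$n_meth[reg] <- rbinom(sum(reg), 30, 0.8)
  base_b$n_meth[reg] <- rbinom(sum(reg), 30, 0.1)
  base_a$pct_meth <- 100 * base_a$n_meth / base_a$depth
  base_b$pct_meth <- 100 * base_b$n_meth / base_b$depth
  dmrs <- call_dmrs(base_a, base_b)
  expect_equal(nrow(dmrs), 1)
  expect_true(dmrs$start >= 2000 && dmrs$end <= 2500)
  expect_true(dmrs$n_dmcs >= 3)
  expect_lt(dmrs$mean_diff, -20)

  # a 2-DMC region otherwise passing is rejected
  two_a <- calls_df("chr1", c(100, 200), 60, c(55, 56))
  two_b <- calls_df("chr1", c(100, 200), 60, c(5, 6))
  expect_equal(nrow(call_dmrs(two_a, two_b)), 0)

  zero <- calls_df("chr1", 100, 0, 0)
  expect_error(call_dmrs(zero, zero), "zero total depth")
})

test_that("per-CpG Fisher p matches fisher.test", {
  set.seed(5)
  for (i in 1:20) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c <- sample(0:15, 1); d <- sample(0:15, 1)
    if (a + b == 0 || c + d == 0) next
    got <- methtx:::fisher_p2(a, b, c, d)
    want <- stats::fisher.test(matrix(c(a, b, c, d), 2))$p.value
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("label-permuted null yields no DMRs in nearly all seeded runs", {
  # two conditions drawn from one distribution; any DMR is a false call
  n_clean <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    pos <- seq(50, 10000, by = 50)
    a <- calls_df("chr1", pos, 25, rbinom(length(pos), 25, 0.4))
    b <- calls_df("chr1", pos, 25, rbinom(length(pos), 25, 0.4))
    if (nrow(call_dmrs(a, b)) == 0) n_clean <- n_clean + 1L
  }
  expect_gte(n_clean, 95)
})
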