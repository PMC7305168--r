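# Normalisation, FPKM and the NB Wald test with its calling policies.

make_counts <- function(n, mu, groups, disp = 0.05, sf = NULL,
                        fc = rep(1, n), seed = 1) {
  set.seed(seed)
  if (is.null(sf)) sf <- rep(1, length(groups))
  m <- sapply(seq_along(groups), function(j) {
    mm <- mu * sf[j]
    if (groups[j] == "B") mm <- mm * fc
    rnbinom(n, mu = mm, size = 1 / disp)
  })
  rownames(m) <- paste0("f", seq_len(n))
  colnames(m) <- paste0(groups, seq_along(groups))
  m
}

test_that("size factors satisfy the closed-form cases", {
  m <- matrix(rpois(400, 50), 200, 2)
  m2 <- cbind(m[, 1], m[, 1])
  expect_equal(unname(size_factors(m2)), c(1, 1))
  doubled <- cbind(m[, 1], 2 * m[, 1])
  sf <- size_factors(doubled)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_error(size_factors(matrix(0, 200, 2)), "all-zero")
  small <- matrix(rpois(20, 50), 10, 2)
  expect_warning(size_factors(small), "library-size")
})

test_that("size factors recover simulated depth multipliers within 5%", {
  set.seed(21)
  true_sf <- c(0.6, 1, 1.4, 2.2)
  mu <- rlnorm(2000, log(100), 1)
  m <- sapply(true_sf, function(s) rnbinom(2000, mu = mu * s, size = 20))
  sf <- size_factors(m)
  target <- true_sf / exp(mean(log(true_sf)))
  expect_true(all(abs(sf / target - 1) < 0.05))
})

test_that("FPKM has the defining scale and conservation properties", {
  counts <- matrix(c(100, 900), 2, 1,
                   dimnames = list(c("a", "b"), "s1"))
  # library of 10^6 with count 100 on a 1 kb feature -> FPKM 100
  counts[2, 1] <- 1e6 - 100
  fp <- fpkm(counts, lengths = c(a = 1000, b = 500),
             sf = c(s1 = 1))
  expect_equal(unname(fp["a", 1]), 100)
  # doubling length halves FPKM
  fp2 <- fpkm(counts, lengths = c(a = 2000, b = 500), sf = c(s1 = 1))
  expect_equal(unname(fp2["a", 1]), 50)
  # sum over features of FPKM*length/1e9 = 1 per sample under
  # library-size normalisation
  set.seed(22)
  m <- matrix(rpois(300, 80), 100, 3,
              dimnames = list(paste0("f", 1:100), paste0("s", 1:3)))
  len <- sample(200:5000, 100)
  sf_lib <- colSums(m) / exp(mean(log(colSums(m))))
  fp3 <- fpkm(m, len, sf = sf_lib)
  expect_equal(unname(colSums(fp3 * len) / 1e9), rep(1, 3))
  expect_error(fpkm(m, rep(0, 100)), "positive")
})

test_that("identical groups give zero fold change and p near 1", {
  m <- make_counts(500, rep(100, 500), rep("A", 6), seed = 23)
  de <- nb_wald_test(m, rep(c("A", "B"), each = 3), "A", "B")
  expect_lt(median(abs(de$log2fc)), 0.35)
  expect_gt(median(de$p), 0.3)
  expect_true(all(de$p_adj >= de$p))
  # BH is monotone: ordering by p implies ordering by p_adj
  o <- order(de$p)
  expect_true(all(diff(de$p_adj[o]) >= -1e-12))
})

test_that("swapping group labels negates fold changes and keeps p", {
  m <- make_counts(300, rlnorm(300, log(150), 1),
                   rep(c("A", "B"), each = 3), fc = ifelse(1:300 <= 30, 6, 1),
                   seed = 24)
  ab <- nb_wald_test(m, rep(c("A", "B"), each = 3), "A", "B")
  ba <- nb_wald_test(m, rep(c("A", "B"), each = 3), "B", "A")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p, ba$p)
})

test_that("rescaling one sample is absorbed by its size factor", {
  set.seed(25)
  mu <- rlnorm(400, log(200), 0.8)
  # plant clear effects so up/down calls are comparable across runs
  m <- make_counts(400, mu, rep(c("A", "B"), each = 3),
                   fc = ifelse(1:400 <= 40, 8, 1), seed = 25)
  de1 <- call_de(nb_wald_test(m, rep(c("A", "B"), each = 3), "A", "B"),
                 "genes")
  m2 <- m
  m2[, 1] <- m[, 1] * 4   # exact scaling, no resampling
  de2 <- call_de(nb_wald_test(m2, rep(c("A", "B"), each = 3), "A", "B"),
                 "genes")
  # fold changes are invariant (up to the 0.5 pseudocount against the
  # moved geometric-mean anchor) and so are the calls; p-values keep
  # their ordering
  expect_equal(de1$log2fc, de2$log2fc, tolerance = 5e-3)
  expect_identical(de1$up, de2$up)
  expect_identical(de1$down, de2$down)
  expect_gt(cor(log(de1$p + 1e-300), log(de2$p + 1e-300)), 0.999)
})

test_that("single-replicate groups report fold changes but no p", {
  m <- make_counts(50, rep(100, 50), c("A", "B", "B"), seed = 26)
  de <- suppressWarnings(nb_wald_test(m, c("A", "B", "B"), "A", "B"))
  expect_true(all(is.na(de$p)))
  expect_true(all(is.finite(de$log2fc)))
  expect_error(nb_wald_test(m, c("A", "B", "B"), "A", "C"), "empty group")
})

test_that("calling policies apply the published thresholds", {
  de <- data.frame(feature_id = c("a", "b", "c", "d"),
                   base_mean = 100,
                   log2fc = log2(c(3.5, 3.5, 4, 2.9)),
                   p = c(1e-5, 1e-4, 8e-4, 1e-9),
                   p_adj = c(5e-4, 5e-3, 1e-2, 1e-8))
  g <- call_de(de, "genes")
  expect_true(g$up[g$feature_id == "a"])    # fc 3.5, p_adj 5e-4
  expect_false(g$up[g$feature_id == "b"])   # p_adj 5e-3 too large
  expect_false(g$up[g$feature_id == "d"])   # fold change below 3
  e <- call_de(de, "exons")                 # exons use raw p
  expect_true(e$up[e$feature_id == "c"])    # fc 4, p 8e-4, p_adj 0.01
  f <- call_de(de, "te_families")           # fold change > 2
  expect_true(f$up[f$feature_id == "d"])
  expect_error(call_de(de, "nope"), "unknown policy")
  # down direction is symmetric
  dn <- de; dn$log2fc <- -dn$log2fc
  expect_true(call_de(dn, "genes")$down[1])
})

test_that("the Wald engine agrees with an established NB engine on effect calls", {
  skip_if_not_installed("DESeq2")
  set.seed(27)
  n <- 400
  mu <- rlnorm(n, log(200), 0.8)
  fc <- rep(1, n); fc[1:40] <- 8
  m <- make_counts(n, mu, rep(c("A", "B"), each = 3), fc = fc, seed = 27)
  de <- call_de(nb_wald_test(m, rep(c("A", "B"), each = 3), "A", "B"),
                "genes")
  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, S4Vectors::DataFrame(condition = factor(rep(c("A", "B"), each = 3))),
    ~condition)
  res <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
  # fold-change estimates track each other
  expect_gt(cor(de$log2fc, res$log2FoldChange, use = "complete.obs"), 0.95)
  ds_up <- which(!is.na(res$padj) & res$padj < 0.001 &
                   res$log2FoldChange > log2(3))
  # planted features found by the reference engine are found here too
  expect_gt(mean(which(de$up) %in% ds_up), 0.8)
  expect_gte(mean(de$up[1:40]), 0.9)
})
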