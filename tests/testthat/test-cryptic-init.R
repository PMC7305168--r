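# The cryptic intragenic initiation caller and the exon-ratio diagnostic.

# transcript with ne exons on chr1, 200 bp exons, 800 bp introns
simple_tx <- function(gene = "g1", tx_id = "g1.t1", ne = 6,
                      strand = "+", origin = 10000) {
  starts <- origin + (0:(ne - 1)) * 1000
  tx_df(gene, tx_id, "chr1", strand, starts, starts + 200)
}

test_that("a downstream block of upregulated exons yields a call at its first exon", {
  tx <- simple_tx(ne = 6)
  de <- exon_de_from_flags("g1.t1", c(FALSE, FALSE, FALSE, TRUE, TRUE,
                                      TRUE))
  calls <- call_cryptic_initiation(de, tx, tes = NULL)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$init_exon_index, 4)
  expect_equal(calls$init_position, 13000)   # genomic start of exon 4
  expect_equal(calls$pct_up_exons, 50)
  expect_true(all(unlist(calls[, grep("^crit_", names(calls))])))
})

test_that("minus-strand initiation positions are the exon 5' end", {
  tx <- simple_tx(ne = 6, strand = "-")
  de <- exon_de_from_flags("g1.t1", c(FALSE, FALSE, TRUE, TRUE, TRUE,
                                      TRUE))
  calls <- call_cryptic_initiation(de, tx, tes = NULL)
  # exon 3 in transcription order is the 4th genomic exon from the left;
  # its 5' end on the minus strand is its genomic end - 1
  expect_equal(calls$init_exon_index, 3)
  expect_equal(calls$init_position, 13000 + 200 - 1)
})

test_that("an upregulated first exon or full upregulation blocks the call", {
  tx <- simple_tx(ne = 6)
  de1 <- exon_de_from_flags("g1.t1", c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                       FALSE))
  expect_equal(nrow(call_cryptic_initiation(de1, tx, NULL)), 0)
  de2 <- exon_de_from_flags("g1.t1", rep(TRUE, 6))
  expect_equal(nrow(call_cryptic_initiation(de2, tx, NULL)), 0)
})

test_that("gap tolerance differs between small and large up sets", {
  tx <- simple_tx(ne = 8)
  # five up exons with a single internal gap pass (criterion v)
  ok <- exon_de_from_flags("g1.t1", seq_len(8) %in% c(3, 4, 6, 7, 8))
  expect_equal(nrow(call_cryptic_initiation(ok, tx, NULL)), 1)
  # three up exons with a gap fail (criterion iv)
  bad <- exon_de_from_flags("g1.t1", seq_len(8) %in% c(3, 4, 6))
  expect_equal(nrow(call_cryptic_initiation(bad, tx, NULL)), 0)
  # five up exons with two gaps fail
  bad2 <- exon_de_from_flags("g1.t1", seq_len(8) %in% c(2, 4, 6, 7, 8))
  expect_equal(nrow(call_cryptic_initiation(bad2, tx, NULL)), 0)
})

test_that("fold-change and FPKM contrasts (vi, vii) are enforced", {
  tx <- simple_tx(ne = 6)
  flags <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  # up fold only 2.5x the background fold: fails (vi)
  weak_fc <- exon_de_from_flags("g1.t1", flags, fc_up = 5, fc_bg = 2)
  expect_equal(nrow(call_cryptic_initiation(weak_fc, tx, NULL)), 0)
  # up FPKM below background FPKM: fails (vii)
  weak_fp <- exon_de_from_flags("g1.t1", flags, fpkm_up_val = 1,
                                fpkm_bg = 5)
  expect_equal(nrow(call_cryptic_initiation(weak_fp, tx, NULL)), 0)
})

test_that("a sibling isoform with 100% up exons vetoes the gene", {
  tx <- rbind(simple_tx(ne = 6),
              simple_tx(gene = "g1", tx_id = "g1.t2", ne = 3))
  de <- rbind(
    exon_de_from_flags("g1.t1", c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)),
    exon_de_from_flags("g1.t2", rep(TRUE, 3)))
  expect_equal(nrow(call_cryptic_initiation(de, tx, NULL)), 0)
})

test_that("TE overlap and alternative promoters exclude calls", {
  tx <- simple_tx(ne = 6)
  de <- exon_de_from_flags("g1.t1", c(FALSE, FALSE, FALSE, TRUE, TRUE,
                                      TRUE))
  te_on_site <- te_df("chr1", 12990, 13100, "IAPLTR1_Mm")
  calls <- call_cryptic_initiation(de, tx, te_on_site)
  expect_equal(nrow(calls), 0)
  expect_equal(nrow(attr(calls, "excluded")), 1)
  expect_true(attr(calls, "excluded")$te_overlap_excluded)
  # simple repeats do not exclude
  sr <- te_df("chr1", 12990, 13100, "Simple_repeat", te_class = "other")
  expect_equal(nrow(call_cryptic_initiation(de, tx, sr)), 1)
  # an annotated alternative promoter excludes
  alt <- data.frame(chrom = "chr1", start = 12980, end = 13020)
  expect_equal(nrow(call_cryptic_initiation(de, tx, NULL,
                                            alt_promoters = alt)), 0)
})

test_that("isoform tie-breaking makes output order-independent", {
  tx <- rbind(simple_tx(ne = 6),
              simple_tx(gene = "g1", tx_id = "g1.t0", ne = 6))
  de <- rbind(
    exon_de_from_flags("g1.t1", c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)),
    exon_de_from_flags("g1.t0", c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)))
  c1 <- call_cryptic_initiation(de, tx, NULL)
  c2 <- call_cryptic_initiation(de[rev(seq_len(nrow(de))), ], tx, NULL)
  expect_equal(c1, c2)
  # equal up counts and lengths: lexicographically first transcript wins
  expect_equal(c1$transcript_id, "g1.t0")
})

test_that("missing FPKM is an error and single-exon transcripts are skipped", {
  tx <- simple_tx(ne = 6)
  de <- exon_de_from_flags("g1.t1", c(FALSE, TRUE, TRUE, TRUE, FALSE,
                                      FALSE))
  de$fpkm_b <- NULL
  expect_error(call_cryptic_initiation(de, tx, NULL), "FPKM")
  one <- tx_df("s", "s.t1", "chr1", "+", 1000, 1200)
  de1 <- exon_de_from_flags("s.t1", TRUE)
  expect_equal(nrow(call_cryptic_initiation(de1, one, NULL)), 0)
})

test_that("exon ratio profiles have the documented inclusion rules", {
  tx <- rbind(simple_tx(gene = "gA", tx_id = "gA.t1", ne = 6),
              simple_tx(gene = "gB", tx_id = "gB.t1", ne = 4,
                        origin = 40000),
              simple_tx(gene = "gC", tx_id = "gC.t1", ne = 6,
                        origin = 70000))
  mk_fpkm <- function(vals) {
    ids <- unlist(lapply(names(vals), function(t)
      paste(t, seq_along(vals[[t]]), sep = ":")))
    m <- cbind(WT = unlist(vals), DKO = unlist(vals))
    rownames(m) <- ids
    m
  }
  fp <- mk_fpkm(list(gA.t1 = rep(4, 6), gB.t1 = rep(4, 4),
                     gC.t1 = c(0, 5, 5, 5, 5, 5)))
  pr <- exon_ratio_profile(fp, tx)
  # gB has 4 exons (excluded); gC has zero first-exon FPKM (excluded)
  expect_equal(unique(pr$ratios$gene_id), "gA")
  expect_true(all(pr$ratios$ratio == 1))        # uniform FPKM
  expect_equal(sort(unique(pr$ratios$position)),
               sort(c("exon2", "exon3", "exon4", "exon5", "exon_n")))
  # low-FPKM genes are excluded
  fp2 <- mk_fpkm(list(gA.t1 = rep(0.1, 6)))
  expect_equal(exon_ratio_profile(fp2, tx)$n_genes, 0)
})

test_that("site report produces the four 40-bin profiles and handles no calls", {
  cfg <- small_config(seed = 8)
  ann <- simulate_annotation(cfg)
  empty <- call_cryptic_initiation(
    exon_de_from_flags("none.t1", FALSE)[0, ], ann$transcripts, ann$tes)
  expect_equal(length(cryptic_site_report(empty, NULL, ann$genome,
                                          ann$transcripts)), 0)
  calls <- data.frame(gene_id = "g1", transcript_id = "g1.t1",
                      init_chrom = "chr1", init_position = 50000L,
                      init_strand = "+")
  meth <- constant_calls(seq(40000, 60000, by = 101), pct = 70)
  rep <- cryptic_site_report(calls, meth, ann$genome, ann$transcripts)
  expect_setequal(names(rep), c("cryptic_density", "cryptic_meth",
                                "tss_density", "tss_meth"))
  expect_true(all(vapply(rep, nrow, 1L) == 40))
})
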