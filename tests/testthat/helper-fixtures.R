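# Builders for small in-code fixtures shared across test files.

# CpG call table from parallel vectors
calls_df <- function(chrom, start, depth, n_meth) {
  n <- length(start)
  depth <- rep_len(depth, n); n_meth <- rep_len(n_meth, n)
  pct <- 100 * n_meth / depth
  pct[depth == 0] <- NA_real_
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start) + 1L, depth = depth, n_meth = n_meth,
             pct_meth = pct, stringsAsFactors = FALSE)
}

# a constant-methylation call table covering positions `pos`
constant_calls <- function(pos, pct = 80, depth = 10, chrom = "chr1") {
  calls_df(chrom, pos, depth, round(depth * pct / 100))
}

# minimal transcript model table
tx_df <- function(gene_id, transcript_id, chrom, strand, starts, ends) {
  transcript_models(data.frame(
    gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
    strand = strand, start = as.integer(starts), end = as.integer(ends),
    stringsAsFactors = FALSE))
}

# TE annotation rows
te_df <- function(chrom, start, end, family, te_class = "ERVK",
                  strand = "+") {
  d <- data.frame(chrom = chrom, start = as.integer(start),
                  end = as.integer(end), strand = strand, family = family,
                  te_class = te_class, stringsAsFactors = FALSE)
  d$copy_id <- paste0(d$chrom, ":", d$start, "-", d$end, ":", d$family)
  d$length <- d$end - d$start
  d
}

# alignment table rows
aln_df <- function(read_id, chrom, start, end, strand = "+", n_hits = 1L,
                   sample = NULL) {
  d <- data.frame(read_id = read_id, chrom = chrom,
                  start = as.integer(start), end = as.integer(end),
                  strand = strand, n_hits = as.integer(n_hits),
                  stringsAsFactors = FALSE)
  if (!is.null(sample)) d$sample <- sample
  d
}

# small simulation config for fast end-to-end tests
small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_chroms = 1L, chrom_length = 2.5e6,
             n_genes = 75L, n_derepressed = 8L, n_cryptic = 8L,
             n_te_decoys = 1L, n_de_novo_windows = 8L, n_gdmrs = 6L,
             n_reactivated = 6L, n_te_reads = 1500L,
             te_families = {
               f <- default_te_families()
               f$copies <- pmax(4L, f$copies %/% 3L)
               f
             }, ...)
}

# an exon DE table consistent with a vector of up flags, for caller tests
exon_de_from_flags <- function(transcript_id, up, fc_up = 10, fc_bg = 1,
                               fpkm_up_val = 8, fpkm_bg = 2) {
  n <- length(up)
  fc <- ifelse(up, fc_up, fc_bg)
  data.frame(feature_id = paste(transcript_id, seq_len(n), sep = ":"),
             base_mean = 100, log2fc = log2(fc),
             p = ifelse(up, 1e-6, 0.5),
             p_adj = ifelse(up, 1e-4, 0.9),
             fpkm_a = 2, fpkm_b = ifelse(up, fpkm_up_val, fpkm_bg),
             up = up, down = FALSE, stringsAsFactors = FALSE)
}
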