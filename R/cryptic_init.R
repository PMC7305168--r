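# Detection of cryptic intragenic transcription initiation from exon-level
# differential expression, plus the genome-wide downstream/first-exon
# ratio diagnostic.

#' Exon/first-exon FPKM ratio profiles
#'
#' For every gene with at least `min_exons` exons and gene FPKM above
#' `min_fpkm`, computes the ratio of each downstream exon's FPKM to the
#' first exon's FPKM at positions 2..5 and at the last exon ("exon n"),
#' per condition, with two-sided Wilcoxon rank-sum comparisons between
#' the two conditions at each position. Genes whose first exon has zero
#' FPKM are excluded.
#'
#' @param exon_fpkm Matrix of per-exon FPKM, rownames
#'   `transcript_id:exon_rank`; one column per condition (e.g. group-mean
#'   FPKM).
#' @param tx `transcript_models` table (one profiled transcript per gene:
#'   the one with most exons, ties to the longest).
#' @param min_exons Minimum exon count (default 5).
#' @param min_fpkm Minimum gene-level FPKM (mean over exons; default 1).
#' @return List with `ratios` (long data.frame gene_id, position, ratio,
#'   condition), `tests` (per position, Wilcoxon p between the two
#'   conditions) and `n_genes`.
#' @export
exon_ratio_profile <- function(exon_fpkm, tx, min_exons = 5L,
                               min_fpkm = 1) {
  stopifnot(ncol(exon_fpkm) >= 1)
  ids <- do.call(rbind, strsplit(rownames(exon_fpkm), ":", fixed = TRUE))
  tx_id <- ids[, 1]; rank <- as.integer(ids[, 2])
  spans <- transcript_spans(tx)
  n_ex <- table(tx$transcript_id)
  spans$n_exons <- as.integer(n_ex[spans$transcript_id])
  spans <- spans[order(spans$gene_id, -spans$n_exons, -spans$length), ]
  spans <- spans[!duplicated(spans$gene_id), ]
  spans <- spans[spans$n_exons >= min_exons, , drop = FALSE]
  conds <- colnames(exon_fpkm)
  rows <- list()
  for (i in seq_len(nrow(spans))) {
    t_id <- spans$transcript_id[i]
    sel <- which(tx_id == t_id)
    if (!length(sel)) next
    sel <- sel[order(rank[sel])]
    fp <- exon_fpkm[sel, , drop = FALSE]
    if (mean(fp) <= min_fpkm) next
    n <- nrow(fp)
    pos_idx <- c(2:5, n)
    pos_lab <- c("exon2", "exon3", "exon4", "exon5", "exon_n")
    for (cj in seq_along(conds)) {
      if (fp[1, cj] == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = spans$gene_id[i], position = pos_lab,
        ratio = fp[pos_idx, cj] / fp[1, cj], condition = conds[cj],
        stringsAsFactors = FALSE)
    }
  }
  ratios <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), position = character(),
               ratio = numeric(), condition = character())
  tests <- NULL
  if (length(conds) == 2 && nrow(ratios)) {
    tests <- do.call(rbind, lapply(split(ratios, ratios$position),
                                   function(d) {
      x <- d$ratio[d$condition == conds[1]]
      y <- d$ratio[d$condition == conds[2]]
      p <- if (length(x) >= 2 && length(y) >= 2)
        stats::wilcox.test(x, y, exact = FALSE)$p.value else NA_real_
      data.frame(position = d$position[1], p = p,
                 median_a = stats::median(x), median_b = stats::median(y))
    }))
    rownames(tests) <- NULL
  }
  list(ratios = ratios, tests = tests,
       n_genes = length(unique(ratios$gene_id)))
}

# The seven criteria applied to one isoform's exon-level flags/statistics.
# up: logical per exon in transcription order; fc: linear fold change per
# exon; fpkm_up: per-exon FPKM in the upregulated condition.
# agg: aggregation for criteria (vi)/(vii) (mean by default).
evaluate_criteria <- function(up, fc, fpkm_up, isoform_100pct_in_gene,
                              agg = mean) {
  n <- length(up)
  trace <- c(i = FALSE, ii = FALSE, iii = FALSE, iv = TRUE, v = TRUE,
             vi = FALSE, vii = FALSE)
  up_idx <- which(up)
  trace["i"] <- length(up_idx) < n
  trace["ii"] <- !up[1]
  trace["iii"] <- !isoform_100pct_in_gene
  if (length(up_idx) < 5) {
    # (iv) fewer than 5 upregulated exons: they must be consecutive
    trace["iv"] <- length(up_idx) >= 1 &&
      all(diff(up_idx) == 1)
  } else {
    # (v) 5 or more: at most one non-up exon inside the up span
    span <- seq(min(up_idx), max(up_idx))
    trace["v"] <- sum(!up[span]) <= 1
  }
  if (length(up_idx) >= 1 && length(up_idx) < n) {
    trace["vi"] <- agg(fc[up_idx]) > 3 * agg(fc[-up_idx])
    trace["vii"] <- agg(fpkm_up[up_idx]) > agg(fpkm_up[-up_idx])
  }
  trace
}

#' Call cryptic intragenic transcription initiation
#'
#' Applies seven criteria to each isoform with at least one upregulated
#' exon (exon policy: fold change > 3, raw p < 0.001): (i) fewer than
#' 100% of exons upregulated; (ii) the first exon is not upregulated;
#' (iii) no isoform of the same gene has 100% upregulated exons; (iv)
#' with fewer than 5 upregulated exons they must be consecutive; (v) with
#' 5 or more, a single-exon gap inside the upregulated block is
#' tolerated; (vi) the aggregated linear fold change of upregulated exons
#' exceeds 3 times that of the other exons; (vii) the aggregated FPKM of
#' upregulated exons (in the upregulated condition) exceeds that of the
#' other exons. One isoform per gene is kept (most upregulated exons,
#' ties broken by transcript length then transcript id), and calls whose
#' inferred initiation position +/- `te_flank` bp overlaps a TE copy
#' (other than simple repeats / low complexity, which the annotation
#' maps to class "other" family names "Simple_repeat"/"Low_complexity")
#' or an annotated alternative promoter are excluded. The initiation
#' position is the genomic 5' start of the 5'-most upregulated exon in
#' transcription orientation — an automated surrogate for manual
#' curation, flagged as inferred.
#'
#' @param exon_de Exon-level results from [call_de()] with policy
#'   "exons"; feature ids `transcript_id:exon_rank`, and `fpkm_b` the
#'   FPKM in the upregulated (test) condition.
#' @param tx `transcript_models` table.
#' @param tes TE annotation or NULL to skip the TE exclusion.
#' @param alt_promoters Optional interval data.frame of alternative
#'   promoters.
#' @param te_flank Half-width of the TE exclusion window (default 50 bp).
#' @param agg Aggregation function for criteria (vi)/(vii): mean
#'   (default) or median.
#' @return data.frame of calls: gene_id, transcript_id, n_exons, n_up,
#'   pct_up_exons, init_exon_index, init_chrom, init_position,
#'   init_strand, te_overlap_excluded, plus criterion columns
#'   `crit_i`..`crit_vii`; excluded candidates are returned with
#'   `te_overlap_excluded = TRUE` in attribute `excluded`.
#' @export
call_cryptic_initiation <- function(exon_de, tx, tes = NULL,
                                    alt_promoters = NULL, te_flank = 50L,
                                    agg = mean) {
  if (is.null(exon_de$fpkm_b) || anyNA(exon_de$fpkm_b))
    stop("exon_de must carry FPKM of the upregulated condition (fpkm_b)",
         call. = FALSE)
  empty <- data.frame(gene_id = character(), transcript_id = character(),
                      n_exons = integer(), n_up = integer(),
                      pct_up_exons = numeric(), init_exon_index = integer(),
                      init_chrom = character(), init_position = integer(),
                      init_strand = character(),
                      te_overlap_excluded = logical())
  attr(empty, "excluded") <- empty
  if (nrow(exon_de) == 0) return(empty)
  ids <- do.call(rbind, strsplit(exon_de$feature_id, ":", fixed = TRUE))
  de_tx <- ids[, 1]; de_rank <- as.integer(ids[, 2])
  ord <- order(de_tx, de_rank)
  exon_de <- exon_de[ord, ]; de_tx <- de_tx[ord]; de_rank <- de_rank[ord]
  gene_of <- tx$gene_id[match(de_tx, tx$transcript_id)]
  # isoforms with 100% up exons, per gene (criterion iii)
  pct_by_tx <- tapply(exon_de$up, de_tx, mean)
  genes_with_full <- unique(gene_of[match(names(pct_by_tx)[pct_by_tx == 1],
                                          de_tx)])
  spans <- transcript_spans(tx)
  cand <- list()
  for (t_id in unique(de_tx[exon_de$up])) {
    sel <- which(de_tx == t_id)
    if (length(sel) < 2) next  # single-exon isoform cannot qualify
    up <- exon_de$up[sel]
    fc <- 2^exon_de$log2fc[sel]
    fpkm_up <- exon_de$fpkm_b[sel]
    g <- gene_of[sel[1]]
    trace <- evaluate_criteria(up, fc, fpkm_up, g %in% genes_with_full,
                               agg = agg)
    if (!all(trace)) next
    up_idx <- which(up)
    init_rank <- min(up_idx)
    ex <- tx[tx$transcript_id == t_id & tx$exon_rank == init_rank, ]
    init_pos <- if (ex$strand == "+") ex$start else ex$end - 1L
    sp <- spans[spans$transcript_id == t_id, ]
    cand[[length(cand) + 1]] <- data.frame(
      gene_id = g, transcript_id = t_id, n_exons = length(sel),
      n_up = length(up_idx), pct_up_exons = 100 * mean(up),
      init_exon_index = init_rank, init_chrom = ex$chrom,
      init_position = init_pos, init_strand = ex$strand,
      tx_length = sp$length,
      crit_i = trace[["i"]], crit_ii = trace[["ii"]],
      crit_iii = trace[["iii"]], crit_iv = trace[["iv"]],
      crit_v = trace[["v"]], crit_vi = trace[["vi"]],
      crit_vii = trace[["vii"]], stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(empty)
  calls <- do.call(rbind, cand)
  # one isoform per gene: most up exons, then longest, then transcript id
  calls <- calls[order(calls$gene_id, -calls$n_up, -calls$tx_length,
                       calls$transcript_id), ]
  calls <- calls[!duplicated(calls$gene_id), ]
  calls$tx_length <- NULL
  # TE / alternative-promoter exclusion at the inferred site
  excl <- rep(FALSE, nrow(calls))
  site_iv <- data.frame(chrom = calls$init_chrom,
                        start = pmax(calls$init_position - te_flank, 0L),
                        end = calls$init_position + te_flank + 1L)
  if (!is.null(tes) && nrow(tes)) {
    te_use <- tes[!tes$family %in% c("Simple_repeat", "Low_complexity"), ,
                  drop = FALSE]
    if (nrow(te_use)) {
      hits <- GenomicRanges::findOverlaps(as_gr(site_iv), as_gr(te_use),
                                          ignore.strand = TRUE)
      excl[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
  }
  if (!is.null(alt_promoters) && nrow(alt_promoters)) {
    hits <- GenomicRanges::findOverlaps(as_gr(site_iv),
                                        as_gr(alt_promoters),
                                        ignore.strand = TRUE)
    excl[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  calls$te_overlap_excluded <- excl
  out <- calls[!excl, , drop = FALSE]
  rownames(out) <- NULL
  excluded <- calls[excl, , drop = FALSE]
  rownames(excluded) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Methylation and CpG-density metaplots around cryptic initiation sites
#'
#' Profiles CpG density and CpG methylation in the flanking sequence of
#' the inferred cryptic initiation sites, with the canonical TSS of the
#' same annotation as contrast, using [site_metaplot()] (250 bp bins over
#' +/- 5 kb).
#'
#' @param calls Output of [call_cryptic_initiation()].
#' @param calls_meth CpG call table (e.g. pooled wild-type).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param tx `transcript_models` table (for canonical TSS).
#' @param half_width,bin Profile geometry in bp.
#' @return Named list of profiles: `cryptic_density`, `cryptic_meth`,
#'   `tss_density`, `tss_meth`; empty list when there are no calls.
#' @export
cryptic_site_report <- function(calls, calls_meth, genome, tx,
                                half_width = 5000L, bin = 250L) {
  if (nrow(calls) == 0) return(list())
  sites <- data.frame(chrom = calls$init_chrom, pos = calls$init_position,
                      strand = calls$init_strand, stringsAsFactors = FALSE)
  spans <- transcript_spans(tx)
  spans <- spans[order(spans$gene_id, -spans$length), ]
  spans <- spans[!duplicated(spans$gene_id), ]
  tss <- data.frame(chrom = spans$chrom, pos = spans$tss,
                    strand = spans$strand, stringsAsFactors = FALSE)
  list(
    cryptic_density = site_metaplot(NULL, sites, "cpg_density",
                                    genome = genome,
                                    half_width = half_width, bin = bin),
    cryptic_meth = site_metaplot(calls_meth, sites, "methylation",
                                 half_width = half_width, bin = bin),
    tss_density = site_metaplot(NULL, tss, "cpg_density", genome = genome,
                                half_width = half_width, bin = bin),
    tss_meth = site_metaplot(calls_meth, tss, "methylation",
                             half_width = half_width, bin = bin))
}
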