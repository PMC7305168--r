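# Transposable-element expression: fractional family counting of
# multi-mapping reads, unique-read copy counting, upregulated-copy and
# copy-size summaries, ERV-proximal gene effects, and strand-resolved LTR
# metaplots.

te_overlap_weights <- function(alignments, tes) {
  # per alignment row: list of TE rows hit (>= 1 bp overlap)
  GenomicRanges::findOverlaps(as_gr(alignments), as_gr(tes),
                              ignore.strand = TRUE, minoverlap = 1L)
}

#' Fractional TE family counts from an alignment table
#'
#' Every alignment of a read carries weight 1/n_hits. An alignment
#' overlapping at least 1 bp of a TE copy contributes its weight to that
#' copy's family; when one alignment overlaps copies of k different
#' families its weight is split equally among them. Alignments touching
#' no TE contribute their weight to the `unassigned` row, so the total
#' mass per sample equals the number of distinct reads.
#'
#' @param alignments Alignment table (see [read_alignment_table()]); an
#'   optional `sample` column yields one count column per sample.
#' @param tes TE annotation.
#' @return data.frame `family`, `te_class`, one numeric column per
#'   sample (fractional counts); last row is `unassigned`.
#' @export
count_te_families <- function(alignments, tes) {
  validate_alignments(alignments)
  samples <- if ("sample" %in% names(alignments))
    sort(unique(alignments$sample)) else "sample1"
  smp <- if ("sample" %in% names(alignments)) alignments$sample
  else rep("sample1", nrow(alignments))
  fams <- unique(tes$family)
  out <- matrix(0, nrow = length(fams) + 1L, ncol = length(samples),
                dimnames = list(c(fams, "unassigned"), samples))
  if (nrow(alignments)) {
    w <- 1 / alignments$n_hits
    hits <- if (nrow(tes)) te_overlap_weights(alignments, tes) else NULL
    if (!is.null(hits) && length(hits)) {
      q <- S4Vectors::queryHits(hits)
      fam_hit <- tes$family[S4Vectors::subjectHits(hits)]
      # families hit per alignment (dedupe alignment x family pairs)
      pair_key <- paste(q, fam_hit, sep = "\r")
      keep <- !duplicated(pair_key)
      q <- q[keep]; fam_hit <- fam_hit[keep]
      nfam_per_aln <- tabulate(q, nbins = nrow(alignments))
      contrib <- w[q] / nfam_per_aln[q]
      agg <- rowsum(contrib, paste(fam_hit, smp[q], sep = "\r"))
      parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
      out[cbind(parts[, 1], parts[, 2])] <- agg[, 1]
      assigned <- nfam_per_aln > 0
    } else assigned <- rep(FALSE, nrow(alignments))
    if (any(!assigned)) {
      agg <- rowsum(w[!assigned], smp[!assigned])
      out["unassigned", rownames(agg)] <- agg[, 1]
    }
  }
  df <- data.frame(family = rownames(out),
                   te_class = c(tes$te_class[match(fams, tes$family)],
                                NA_character_),
                   out, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Unique-read counts per TE copy
#'
#' Only alignments of uniquely mapping reads (n_hits = 1) are counted; a
#' unique read overlapping k copies increments all k.
#'
#' @param alignments Alignment table.
#' @param tes TE annotation.
#' @return Integer matrix copy_id x sample.
#' @export
count_te_copies <- function(alignments, tes) {
  validate_alignments(alignments)
  samples <- if ("sample" %in% names(alignments))
    sort(unique(alignments$sample)) else "sample1"
  out <- matrix(0L, nrow = nrow(tes), ncol = max(length(samples), 1L),
                dimnames = list(tes$copy_id, samples))
  uniq <- alignments[alignments$n_hits == 1L, , drop = FALSE]
  if (nrow(uniq) == 0 || nrow(tes) == 0) return(out)
  smp <- if ("sample" %in% names(uniq)) uniq$sample
  else rep("sample1", nrow(uniq))
  hits <- te_overlap_weights(uniq, tes)
  if (length(hits)) {
    s <- S4Vectors::subjectHits(hits)
    q <- S4Vectors::queryHits(hits)
    agg <- rowsum(rep(1L, length(s)), paste(s, smp[q], sep = "\r"))
    parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
    out[cbind(as.integer(parts[, 1]), match(parts[, 2], samples))] <-
      as.integer(agg[, 1])
  }
  out
}

#' Percentage of upregulated copies per TE family, with size comparison
#'
#' Given copy-level differential expression called at the copy policy
#' (fold change > 3, adjusted p < 0.001), reports per family the number
#' of annotated copies, the number upregulated and the percentage, plus
#' an overall two-sided Wilcoxon rank-sum test comparing the lengths of
#' upregulated versus non-upregulated copies.
#'
#' @param copy_de Output of [call_de()] on copy counts, feature ids being
#'   copy_ids.
#' @param tes TE annotation.
#' @return List with `families` (family, te_class, n_copies, n_up,
#'   pct_up), `size_test` (Wilcoxon p, median lengths; NULL when no copy
#'   is up) and `up_copy_ids`.
#' @export
copy_up_summary <- function(copy_de, tes) {
  up_ids <- copy_de$feature_id[copy_de$up]
  is_up <- tes$copy_id %in% up_ids
  n_copies <- table(tes$family)
  n_up <- table(factor(tes$family[is_up], levels = names(n_copies)))
  fam <- data.frame(family = names(n_copies),
                    te_class = tes$te_class[match(names(n_copies),
                                                  tes$family)],
                    n_copies = as.integer(n_copies),
                    n_up = as.integer(n_up),
                    stringsAsFactors = FALSE)
  fam$pct_up <- 100 * fam$n_up / fam$n_copies
  size_test <- NULL
  if (any(is_up) && any(!is_up)) {
    up_len <- tes$length[is_up]; not_len <- tes$length[!is_up]
    wt <- stats::wilcox.test(up_len, not_len, exact = FALSE)
    # fully tied samples degenerate to an undefined statistic: no
    # evidence against equality
    if (is.nan(wt$p.value)) wt$p.value <- 1
    size_test <- list(p = wt$p.value,
                      median_up = stats::median(up_len),
                      median_not_up = stats::median(not_len))
  }
  list(families = fam[order(-fam$pct_up), ], size_test = size_test,
       up_copy_ids = up_ids)
}

tss_to_interval_dist <- function(tss_chrom, tss_pos, ivs) {
  # distance from a TSS point to the nearest edge of each interval set;
  # 0 when inside. Returns min distance per TSS.
  vapply(seq_along(tss_pos), function(i) {
    sel <- ivs$chrom == tss_chrom[i]
    if (!any(sel)) return(Inf)
    s <- ivs$start[sel]; e <- ivs$end[sel]
    d <- pmax(s - tss_pos[i], tss_pos[i] - (e - 1L), 0L)
    min(d)
  }, numeric(1))
}

#' Effect of activated ERVs on proximal genes
#'
#' The proximal set contains genes whose TSS lies within `max_dist` bp of
#' any upregulated ERV copy (TSS-to-interval nearest-edge distance,
#' strand-ignored). Its log2 fold-change distribution is compared with
#' (a) all genes, (b) all ERV-proximal genes regardless of ERV activity,
#' and (c) a seeded random sample of the latter of the same size as the
#' proximal set, using two-sided Wilcoxon rank-sum tests; the fraction of
#' each set flagged up at the gene policy is also reported.
#'
#' @param up_erv_copies TE annotation rows of upregulated ERV copies.
#' @param tx `transcript_models` table.
#' @param gene_de Output of [call_de()] on genes (feature ids = gene
#'   ids).
#' @param all_erv_copies TE annotation rows of all ERV copies (for the
#'   control set); defaults to `up_erv_copies`.
#' @param max_dist Maximum TSS distance in bp (default 20000, strict <).
#' @param seed Seed for the random control sample.
#' @return List with per-set gene ids, log2fc summaries, `frac_up` per
#'   set, and Wilcoxon p-values (`p_vs_all`, `p_vs_random`); sets other
#'   than `proximal` are NULL when the proximal set is empty.
#' @export
erv_proximal_genes <- function(up_erv_copies, tx, gene_de,
                               all_erv_copies = up_erv_copies,
                               max_dist = 20000L, seed = 1L) {
  spans <- transcript_spans(tx)
  spans <- spans[order(spans$gene_id, -spans$length), ]
  spans <- spans[!duplicated(spans$gene_id), ]
  lfc <- gene_de$log2fc[match(spans$gene_id, gene_de$feature_id)]
  up_flag <- gene_de$up[match(spans$gene_id, gene_de$feature_id)]
  proximal <- if (nrow(up_erv_copies)) {
    d <- tss_to_interval_dist(spans$chrom, spans$tss, up_erv_copies)
    spans$gene_id[d < max_dist]
  } else character()
  result <- list(proximal = proximal,
                 n_proximal = length(proximal))
  if (!length(proximal)) return(result)
  erv_any <- {
    d <- tss_to_interval_dist(spans$chrom, spans$tss, all_erv_copies)
    spans$gene_id[d < max_dist]
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  random_ctrl <- sample(erv_any, min(length(proximal), length(erv_any)))
  sets <- list(proximal = proximal, all_genes = spans$gene_id,
               erv_any = erv_any, random_ctrl = random_ctrl)
  lfc_by <- lapply(sets, function(ids)
    lfc[match(ids, spans$gene_id)])
  frac_up <- vapply(sets, function(ids)
    mean(up_flag[match(ids, spans$gene_id)], na.rm = TRUE), numeric(1))
  p_vs_all <- stats::wilcox.test(lfc_by$proximal, lfc_by$all_genes,
                                 exact = FALSE)$p.value
  p_vs_random <- stats::wilcox.test(lfc_by$proximal, lfc_by$random_ctrl,
                                    exact = FALSE)$p.value
  c(result, list(sets = sets, log2fc = lfc_by, frac_up = frac_up,
                 p_vs_all = p_vs_all, p_vs_random = p_vs_random))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

merge_close <- function(iv, gap) {
  # merge intervals of one chromosome-sorted data.frame when distance < gap
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  if (nrow(iv) < 2) return(iv)
  new_grp <- c(TRUE, iv$chrom[-1] != iv$chrom[-nrow(iv)] |
                 iv$start[-1] - iv$end[-nrow(iv)] >= gap)
  grp <- cumsum(new_grp)
  do.call(rbind, lapply(split(iv, grp), function(d)
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
               strand = d$strand[1], stringsAsFactors = FALSE)))
}

coverage_profile <- function(track, chrom, lo, hi, bin) {
  # mean bedGraph signal in fixed bins over [lo, hi)
  nb <- as.integer((hi - lo) / bin)
  out <- rep(0, nb)
  t <- track[track$chrom == chrom & track$end > lo & track$start < hi, ,
             drop = FALSE]
  if (nrow(t) == 0) return(out)
  for (j in seq_len(nb)) {
    b0 <- lo + (j - 1) * bin; b1 <- b0 + bin
    ov <- pmin(t$end, b1) - pmax(t$start, b0)
    sel <- ov > 0
    out[j] <- sum(t$score[sel] * ov[sel]) / bin
  }
  out
}

#' Strand-resolved metaplot around LTR elements
#'
#' Copies of the named family are merged when separated by less than
#' `merge_gap` bp; for each merged element, per-strand RNA signal is
#' extracted over +/- `half_width` bp from the element start (in element
#' orientation) and averaged in `bin` bp windows. Sense and antisense are
#' defined relative to the element's annotated strand; minus-strand
#' elements are flipped so profiles read 5' to 3' of the element.
#'
#' @param cov_fwd,cov_rev bedGraph coverage data.frames (chrom, start,
#'   end, score) for the genome forward and reverse strands.
#' @param tes TE annotation.
#' @param family Family name to profile (error when absent).
#' @param merge_gap,half_width,bin Merging distance, flank and bin width
#'   in bp.
#' @return List with `offset` (bin centres), `sense`/`antisense` mean
#'   profiles, per-element matrices `sense_matrix`/`antisense_matrix` and
#'   the merged `elements`.
#' @export
ltr_strand_metaplot <- function(cov_fwd, cov_rev, tes, family,
                                merge_gap = 8000L, half_width = 5000L,
                                bin = 50L) {
  copies <- tes[tes$family == family, , drop = FALSE]
  if (nrow(copies) == 0)
    stop("family not in annotation: ", family, call. = FALSE)
  el <- merge_close(copies[, c("chrom", "start", "end", "strand")],
                    merge_gap)
  nb <- as.integer(2 * half_width / bin)
  sense <- matrix(NA_real_, nrow(el), nb)
  anti <- matrix(NA_real_, nrow(el), nb)
  for (i in seq_len(nrow(el))) {
    plus_strand_el <- el$strand[i] != "-"
    anchor <- if (plus_strand_el) el$start[i] else el$end[i]
    lo <- anchor - half_width; hi <- anchor + half_width
    pf <- coverage_profile(cov_fwd, el$chrom[i], lo, hi, bin)
    pr <- coverage_profile(cov_rev, el$chrom[i], lo, hi, bin)
    if (plus_strand_el) {
      sense[i, ] <- pf; anti[i, ] <- pr
    } else {
      sense[i, ] <- rev(pr); anti[i, ] <- rev(pf)
    }
  }
  list(offset = -half_width + bin * (seq_len(nb) - 1) + bin / 2,
       sense = colMeans(sense), antisense = colMeans(anti),
       sense_matrix = sense, antisense_matrix = anti, elements = el)
}
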