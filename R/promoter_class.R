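# Promoter CpG-content classification (LCP/ICP/HCP) from sequence, and
# the three-group assignment of upregulated genes by promoter class and
# wild-type promoter methylation.

# Sliding-window statistics over one promoter sequence. The CpG ratio is
# the standard observed/expected: (#CpG * L) / (#C * #G), 0 when either
# count is 0; N bases are excluded from all counts and from the window
# length.
promoter_window_stats <- function(seq, window = 500L, step = 20L) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  L <- length(chars)
  if (L < window)
    return(data.frame(offset = integer(), cpg_ratio = numeric(),
                      gc_content = numeric()))
  is_c <- chars == "C"; is_g <- chars == "G"; is_n <- chars == "N"
  is_cpg <- c(is_c[-L] & is_g[-1], FALSE)  # CpG attributed to its C
  cum <- function(x) c(0, cumsum(x))
  cc <- cum(is_c); cg <- cum(is_g); cn <- cum(is_n); ccpg <- cum(is_cpg)
  offsets <- seq.int(0L, L - window, by = step)
  n_c <- cc[offsets + window + 1] - cc[offsets + 1]
  n_g <- cg[offsets + window + 1] - cg[offsets + 1]
  n_n <- cn[offsets + window + 1] - cn[offsets + 1]
  n_cpg <- ccpg[offsets + window + 1] - ccpg[offsets + 1]
  eff_len <- window - n_n
  ratio <- ifelse(n_c > 0 & n_g > 0, n_cpg * eff_len / (n_c * n_g), 0)
  gc <- ifelse(eff_len > 0, 100 * (n_c + n_g) / eff_len, 0)
  data.frame(offset = offsets, cpg_ratio = ratio, gc_content = gc)
}

#' Classify one promoter sequence as LCP, ICP or HCP
#'
#' The CpG ratio (observed/expected CpG) and GC content are computed in
#' 500 bp sliding windows advanced in 20 bp increments across the
#' promoter sequence (TSS +/- 1 kb; 76 windows when the full 2 kb is
#' available, a final partial window is not evaluated). A promoter is a
#' high-CpG promoter (HCP) if at least one window has CpG ratio > 0.65
#' and GC content > 55%, a low-CpG promoter (LCP) if no window has CpG
#' ratio > 0.45, and an intermediate-CpG promoter (ICP) otherwise.
#'
#' @param seq Promoter sequence (character or [Biostrings::DNAString]),
#'   given 5' to 3' on the gene strand. N bases are excluded from counts
#'   and window lengths.
#' @param window,step Sliding window width and increment in bp.
#' @return List with `class` ("LCP", "ICP" or "HCP") and `windows`
#'   (per-window offset, cpg_ratio, gc_content).
#' @export
classify_promoter <- function(seq, window = 500L, step = 20L) {
  s <- toupper(as.character(seq))
  if (nchar(s) == 0 || gsub("N", "", s) == "")
    stop("promoter sequence is empty or all N", call. = FALSE)
  w <- promoter_window_stats(s, window = window, step = step)
  cls <- if (nrow(w) == 0) {
    "LCP"  # shorter than one window: no window can qualify
  } else if (any(w$cpg_ratio > 0.65 & w$gc_content > 55)) {
    "HCP"
  } else if (!any(w$cpg_ratio > 0.45)) {
    "LCP"
  } else "ICP"
  list(class = cls, windows = w)
}

#' Classify all promoters of an annotation
#'
#' Extracts TSS +/- `flank` from the genome for every gene (one
#' representative transcript per gene: most exons, then longest, then
#' lexicographically first transcript id), orients it on the gene strand
#' and applies [classify_promoter()].
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param tx `transcript_models` table.
#' @param flank Half-width of the promoter window around the TSS
#'   (default 1000 bp).
#' @return data.frame gene_id, transcript_id, cls, max_cpg_ratio,
#'   n_windows, truncated (TRUE when the contig edge shortened the
#'   sequence).
#' @export
classify_promoters <- function(genome, tx, flank = 1000L) {
  spans <- transcript_spans(tx)
  n_ex <- table(tx$transcript_id)
  spans$n_exons <- as.integer(n_ex[spans$transcript_id])
  spans <- spans[order(spans$gene_id, -spans$n_exons, -spans$length,
                       spans$transcript_id), ]
  spans <- spans[!duplicated(spans$gene_id), ]
  out <- lapply(seq_len(nrow(spans)), function(i) {
    g <- spans[i, ]
    chrom_len <- length(genome[[g$chrom]])
    lo <- max(0L, g$tss - flank); hi <- min(chrom_len, g$tss + flank)
    s <- Biostrings::subseq(genome[[g$chrom]], lo + 1L, hi)
    if (g$strand == "-") s <- Biostrings::reverseComplement(s)
    cl <- classify_promoter(s)
    data.frame(gene_id = g$gene_id, transcript_id = g$transcript_id,
               cls = cl$class,
               max_cpg_ratio = if (nrow(cl$windows)) max(cl$windows$cpg_ratio) else 0,
               n_windows = nrow(cl$windows),
               truncated = (hi - lo) < 2L * flank,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Promoter methylation around the TSS
#'
#' Mean wild-type CpG methylation in the interval used for gene grouping:
#' `upstream` bp before to `downstream` bp after the TSS in transcription
#' orientation (defaults -1000 to +500).
#'
#' @param calls CpG call table (typically pooled wild-type).
#' @param tx `transcript_models` table.
#' @param upstream,downstream Extent of the promoter interval in bp.
#' @return data.frame gene_id, n_cpgs, mean_pct (NA when no CpG covered).
#' @export
promoter_methylation <- function(calls, tx, upstream = 1000L,
                                 downstream = 500L) {
  spans <- transcript_spans(tx)
  spans <- spans[order(spans$gene_id, -spans$length), ]
  spans <- spans[!duplicated(spans$gene_id), ]
  iv <- data.frame(chrom = spans$chrom,
                   start = ifelse(spans$strand == "+",
                                  spans$tss - upstream,
                                  spans$tss - downstream + 1L),
                   end = ifelse(spans$strand == "+",
                                spans$tss + downstream,
                                spans$tss + upstream + 1L),
                   stringsAsFactors = FALSE)
  iv$start <- pmax(iv$start, 0L)
  fm <- feature_methylation(calls, iv)
  data.frame(gene_id = spans$gene_id, n_cpgs = fm$n_cpgs,
             mean_pct = fm$mean_pct, stringsAsFactors = FALSE)
}

#' Assign upregulated genes to promoter-methylation groups
#'
#' Group 1: low-CpG promoter (LCP), any methylation. Group 2:
#' intermediate or high CpG promoter (ICP/HCP) with wild-type promoter
#' methylation < 30%. Group 3: ICP/HCP with promoter methylation >= 30%
#' (boundary inclusive). Genes without a defined promoter methylation are
#' returned separately.
#'
#' @param gene_ids Upregulated gene ids.
#' @param promoter_classes data.frame gene_id, cls (from
#'   [classify_promoters()]).
#' @param promoter_meth data.frame gene_id, mean_pct (from
#'   [promoter_methylation()] on the wild-type methylome).
#' @param meth_cutoff Group 2/3 boundary in percent (default 30,
#'   inclusive on the group-3 side).
#' @return List with `groups` (gene_id, cls, promoter_meth_wt, group) and
#'   `undefined` (gene ids lacking covered promoter CpGs).
#' @export
assign_groups <- function(gene_ids, promoter_classes, promoter_meth,
                          meth_cutoff = 30) {
  cls <- promoter_classes$cls[match(gene_ids, promoter_classes$gene_id)]
  if (anyNA(cls))
    stop("genes without promoter class: ",
         paste(utils::head(gene_ids[is.na(cls)], 3), collapse = ", "),
         call. = FALSE)
  meth <- promoter_meth$mean_pct[match(gene_ids, promoter_meth$gene_id)]
  undef <- is.na(meth) & cls != "LCP"   # LCP grouping ignores methylation
  grp <- ifelse(cls == "LCP", 1L,
                ifelse(meth < meth_cutoff, 2L, 3L))
  groups <- data.frame(gene_id = gene_ids[!undef], cls = cls[!undef],
                       promoter_meth_wt = meth[!undef],
                       group = grp[!undef], stringsAsFactors = FALSE)
  list(groups = groups, undefined = gene_ids[undef])
}
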