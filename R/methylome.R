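# Methylation summarisation. All means over CpGs are CpG-weighted (every
# covered CpG counts once, regardless of depth); undefined means are NA,
# never 0.

#' Pool replicate methylation call tables
#'
#' Replicates are combined by adding the methylated and total read counts
#' at each CpG position; the percent methylation is recomputed from the
#' pooled counts (so it is count-weighted, not an average of per-replicate
#' percentages). CpGs present in any input appear in the output.
#'
#' @param tables List of CpG call tables (see
#'   [read_methylation_calls()]), same coordinate convention.
#' @return A pooled CpG call table.
#' @export
pool_replicates <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  if (length(tables) == 1) return(tables[[1]])
  df <- do.call(rbind, lapply(tables, function(t)
    t[, c("chrom", "start", "depth", "n_meth")]))
  key <- paste(df$chrom, df$start, sep = "\r")
  depth <- rowsum(df$depth, key, reorder = FALSE)
  n_meth <- rowsum(df$n_meth, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(chrom = df$chrom[first], start = df$start[first],
                    end = df$start[first] + 1L,
                    depth = as.numeric(depth[, 1]),
                    n_meth = as.numeric(n_meth[, 1]),
                    stringsAsFactors = FALSE)
  out$pct_meth <- ifelse(out$depth > 0, 100 * out$n_meth / out$depth,
                         NA_real_)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Mean methylation per feature
#'
#' Unweighted mean of per-CpG percent methylation over the CpGs whose C
#' position falls inside each feature (0-based half-open; a CpG at the
#' exclusive end is outside). Features with no covered CpG get NA.
#'
#' @param calls CpG call table.
#' @param features Interval data.frame (chrom, start, end, optional name).
#' @param min_cpgs Minimum number of covered CpGs for the mean to be
#'   defined (default 1).
#' @return `features` with added columns `n_cpgs` and `mean_pct`.
#' @export
feature_methylation <- function(calls, features, min_cpgs = 1L) {
  validate_intervals(features, "features")
  features <- as.data.frame(features)
  if (nrow(features) == 0) {
    features$n_cpgs <- integer(0); features$mean_pct <- numeric(0)
    return(features)
  }
  if (nrow(calls) == 0) {
    features$n_cpgs <- 0L; features$mean_pct <- NA_real_
    return(features)
  }
  hits <- GenomicRanges::findOverlaps(as_gr(calls), as_gr(features),
                                      ignore.strand = TRUE)
  f <- S4Vectors::subjectHits(hits)
  pct <- calls$pct_meth[S4Vectors::queryHits(hits)]
  n <- tabulate(f, nbins = nrow(features))
  s <- rep(0, nrow(features))
  if (length(f)) {
    agg <- rowsum(pct, f)
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  features$n_cpgs <- n
  features$mean_pct <- ifelse(n >= min_cpgs & n > 0, s / pmax(n, 1),
                              NA_real_)
  features
}

#' Mean methylation per TE family
#'
#' Averages per-CpG methylation over all CpGs falling in any copy of each
#' family (one pooled mean per family, CpG-weighted across copies). For
#' cross-dataset comparisons only families covered by at least `min_cpgs`
#' CpGs are kept (use 100, restricted upstream to LTR/LINE families, for
#' such comparisons).
#'
#' @param calls CpG call table.
#' @param tes TE annotation (see [read_repeatmasker()]).
#' @param min_cpgs Minimum CpG coverage per family.
#' @param min_length Keep only elements longer than this (bp); the
#'   genomic-feature panel uses 400.
#' @return data.frame family, te_class, n_cpgs, mean_pct.
#' @export
family_methylation <- function(calls, tes, min_cpgs = 1L, min_length = 0L) {
  tes <- tes[tes$length > min_length, , drop = FALSE]
  if (nrow(tes) == 0)
    return(data.frame(family = character(), te_class = character(),
                      n_cpgs = integer(), mean_pct = numeric()))
  hits <- GenomicRanges::findOverlaps(as_gr(calls), as_gr(tes),
                                      ignore.strand = TRUE)
  fam <- tes$family[S4Vectors::subjectHits(hits)]
  pct <- calls$pct_meth[S4Vectors::queryHits(hits)]
  # a CpG inside two copies of the same family counts once per overlap;
  # copies rarely overlap within a family so this is immaterial
  n <- tapply(pct, fam, length)
  m <- tapply(pct, fam, mean)
  cls <- tes$te_class[match(names(n), tes$family)]
  out <- data.frame(family = names(n), te_class = cls,
                    n_cpgs = as.integer(n), mean_pct = as.numeric(m),
                    stringsAsFactors = FALSE)
  out <- out[out$n_cpgs >= min_cpgs, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tile chromosomes into fixed windows
#'
#' Non-overlapping tiling anchored at coordinate 0 of each chromosome; the
#' last window is truncated at the chromosome end.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param window_size Window width in bp.
#' @return Interval data.frame chrom, start, end.
#' @export
tile_windows <- function(chrom_lengths, window_size) {
  stopifnot(window_size > 0, length(chrom_lengths) > 0,
            !is.null(names(chrom_lengths)))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(0L, len - 1L, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean methylation in fixed genomic windows
#'
#' Methylation averaged in non-overlapping windows tiled from each
#' chromosome start; windows containing fewer than `min_cpgs` covered CpGs
#' have an undefined (NA) mean. The residual-methylation analyses use 1 kb
#' windows with at least 3 CpGs; cross-platform correlations use 500 bp.
#'
#' @param calls CpG call table.
#' @param chrom_lengths Named vector of chromosome lengths; when NULL,
#'   each chromosome extends to its last covered CpG.
#' @param window_size Window width in bp (default 1000).
#' @param min_cpgs Minimum covered CpGs per window (default 3).
#' @return data.frame chrom, start, end, n_cpgs, mean_pct.
#' @export
window_methylation <- function(calls, chrom_lengths = NULL,
                               window_size = 1000L, min_cpgs = 3L) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(calls$end, calls$chrom, max)
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                     names(chrom_lengths))
  }
  windows <- tile_windows(chrom_lengths, window_size)
  feature_methylation(calls, windows, min_cpgs = min_cpgs)
}

#' Classify windows by methylation level
#'
#' Windows with a defined mean are classified as high (> 50%), medium
#' (10-50%, both boundaries included) or low (< 10%).
#'
#' @param windows Output of [window_methylation()].
#' @return List with `class` (factor per defined window, aligned to
#'   `windows[defined, ]`) and `proportions` (named numeric summing to 1).
#' @export
classify_windows <- function(windows) {
  defined <- !is.na(windows$mean_pct)
  if (!any(defined)) {
    warning("no windows with defined methylation", call. = FALSE)
    return(list(class = factor(character(),
                               levels = c("low", "medium", "high")),
                proportions = c(low = NA_real_, medium = NA_real_,
                                high = NA_real_)))
  }
  m <- windows$mean_pct[defined]
  cls <- factor(ifelse(m > 50, "high", ifelse(m < 10, "low", "medium")),
                levels = c("low", "medium", "high"))
  list(class = cls,
       proportions = prop.table(table(cls)))
}

#' Select windows methylated de novo between two states
#'
#' Returns the windows with mean methylation below `early_max` percent in
#' the early state and strictly above `late_min` percent in the late
#' state (defaults select windows < 5% in the pre-implantation methylome
#' and > 50% in the post-implantation one). Both inputs must share the
#' same tiling.
#'
#' @param meth_early,meth_late Window methylation tables from
#'   [window_methylation()] on the same tiling.
#' @param early_max,late_min Thresholds in percent.
#' @return Subset of windows (chrom, start, end, plus both means).
#' @export
select_de_novo_windows <- function(meth_early, meth_late,
                                   early_max = 5, late_min = 50) {
  if (nrow(meth_early) != nrow(meth_late) ||
      any(meth_early$chrom != meth_late$chrom) ||
      any(meth_early$start != meth_late$start))
    stop("window tilings differ between inputs", call. = FALSE)
  ok <- !is.na(meth_early$mean_pct) & !is.na(meth_late$mean_pct) &
    meth_early$mean_pct < early_max & meth_late$mean_pct > late_min
  out <- meth_early[ok, c("chrom", "start", "end"), drop = FALSE]
  out$mean_early <- meth_early$mean_pct[ok]
  out$mean_late <- meth_late$mean_pct[ok]
  rownames(out) <- NULL
  out
}

bin_means <- function(pos, val, breaks) {
  # mean of val per interval [breaks[i], breaks[i+1]) ; NA when empty
  idx <- findInterval(pos, breaks, rightmost.closed = FALSE)
  nb <- length(breaks) - 1
  keep <- idx >= 1 & idx <= nb
  n <- tabulate(idx[keep], nbins = nb)
  s <- rep(0, nb)
  if (any(keep)) {
    agg <- rowsum(val[keep], idx[keep])
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  ifelse(n > 0, s / pmax(n, 1), NA_real_)
}

#' Gene-body methylation metaplot
#'
#' Each gene body (transcript span) is split into 20 equal-sized bins
#' oriented 5' to 3'; the flanks are tiled in ten 1 kb bins on each side.
#' The profile is the unweighted mean over genes of the per-gene per-bin
#' means. Genes on excluded chromosomes (e.g. the sex chromosomes) are
#' dropped; genes shorter than 20 bp are skipped and counted.
#'
#' @param calls CpG call table.
#' @param tx `transcript_models` table; one span per gene (the longest
#'   transcript) is used.
#' @param flank_bp Total flank width (default 10000, i.e. ten 1 kb bins).
#' @param n_body_bins Number of gene-body bins (default 20).
#' @param exclude_chroms Chromosome names to drop.
#' @return data.frame `bin` (-10..-1, body1..body20, +1..+10), `mean_pct`,
#'   `n_genes` contributing per bin; attribute `n_skipped` counts too-short
#'   genes.
#' @export
gene_metaplot <- function(calls, tx, flank_bp = 10000L, n_body_bins = 20L,
                          exclude_chroms = character()) {
  spans <- transcript_spans(tx)
  # one representative (longest) transcript per gene
  spans <- spans[order(spans$gene_id, -spans$length), ]
  spans <- spans[!duplicated(spans$gene_id), ]
  spans <- spans[!spans$chrom %in% exclude_chroms, , drop = FALSE]
  if (nrow(spans) == 0) stop("no genes to plot", call. = FALSE)
  n_flank <- as.integer(round(flank_bp / 1000))
  flank_bin <- flank_bp / n_flank
  nb <- n_flank + n_body_bins + n_flank
  skipped <- 0L
  acc_sum <- rep(0, nb); acc_n <- rep(0L, nb)
  calls_by_chrom <- split(calls, calls$chrom)
  for (i in seq_len(nrow(spans))) {
    g <- spans[i, ]
    if (g$end - g$start < n_body_bins) { skipped <- skipped + 1L; next }
    cc <- calls_by_chrom[[g$chrom]]
    if (is.null(cc)) next
    lo <- g$start - flank_bp; hi <- g$end + flank_bp
    sel <- cc$start >= lo & cc$start < hi
    if (!any(sel)) next
    pos <- cc$start[sel]; val <- cc$pct_meth[sel]
    body_breaks <- g$start + (g$end - g$start) * (0:n_body_bins) / n_body_bins
    breaks <- c(g$start - flank_bp + flank_bin * (0:(n_flank - 1)),
                body_breaks,
                g$end + flank_bin * (1:n_flank))
    prof <- bin_means(pos, val, breaks)
    if (g$strand == "-") prof <- rev(prof)
    ok <- !is.na(prof)
    acc_sum[ok] <- acc_sum[ok] + prof[ok]
    acc_n[ok] <- acc_n[ok] + 1L
  }
  labels <- c(paste0("-", n_flank:1), paste0("body", seq_len(n_body_bins)),
              paste0("+", 1:n_flank))
  out <- data.frame(bin = factor(labels, levels = labels),
                    mean_pct = ifelse(acc_n > 0, acc_sum / pmax(acc_n, 1),
                                      NA_real_),
                    n_genes = acc_n)
  attr(out, "n_skipped") <- skipped
  out
}

#' Site-centred metaplot of methylation or CpG density
#'
#' Profiles around single-base sites (TSS or inferred cryptic initiation
#' sites): fixed-width bins over +/- `half_width`, oriented by the site
#' strand. In `"methylation"` mode bins average per-CpG percent
#' methylation; in `"cpg_density"` mode they count CpG dinucleotides per
#' kb in the genome sequence.
#'
#' @param calls CpG call table (methylation mode) or NULL.
#' @param sites data.frame chrom, pos (0-based), strand.
#' @param mode "methylation" or "cpg_density".
#' @param genome Named [Biostrings::DNAStringSet] (required for density
#'   mode).
#' @param half_width Half window (default 5000 bp).
#' @param bin Bin width (default 250 bp).
#' @return data.frame `offset` (bin centre relative to site, oriented),
#'   `value`, `n_sites`; sites truncated by a contig edge contribute only
#'   their covered bins and are flagged in attribute `n_partial`.
#' @export
site_metaplot <- function(calls, sites,
                          mode = c("methylation", "cpg_density"),
                          genome = NULL, half_width = 5000L, bin = 250L) {
  mode <- match.arg(mode)
  stopifnot(nrow(sites) > 0, 2 * half_width %% bin == 0)
  nb <- as.integer(2 * half_width / bin)
  acc_sum <- rep(0, nb); acc_n <- rep(0L, nb); n_partial <- 0L
  if (mode == "cpg_density") {
    if (is.null(genome)) stop("genome required for cpg_density mode",
                              call. = FALSE)
    cpg_pos <- lapply(as.list(genome), function(s)
      Biostrings::start(Biostrings::matchPattern("CG", s)) - 1L)
  } else {
    calls_by_chrom <- split(calls, calls$chrom)
  }
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]; p <- sites$pos[i]
    st <- if ("strand" %in% names(sites)) sites$strand[i] else "+"
    lo <- p - half_width; hi <- p + half_width
    lim <- if (mode == "cpg_density") {
      if (!ch %in% names(genome)) next
      length(genome[[ch]])
    } else Inf
    if (lo < 0 || hi > lim) n_partial <- n_partial + 1L
    if (mode == "cpg_density") {
      pos <- cpg_pos[[ch]]
      pos <- pos[pos >= max(lo, 0) & pos < min(hi, lim)]
      idx <- findInterval(pos, lo + bin * (0:nb))
      counts <- tabulate(idx[idx >= 1 & idx <= nb], nbins = nb)
      prof <- counts / (bin / 1000)  # CpGs per kb
      covered <- (lo + bin * (0:(nb - 1))) >= 0 &
        (lo + bin * (1:nb)) <= lim
      prof[!covered] <- NA_real_
    } else {
      cc <- calls_by_chrom[[ch]]
      if (is.null(cc)) next
      sel <- cc$start >= lo & cc$start < hi
      prof <- bin_means(cc$start[sel], cc$pct_meth[sel],
                        lo + bin * (0:nb))
    }
    if (st == "-") prof <- rev(prof)
    ok <- !is.na(prof)
    acc_sum[ok] <- acc_sum[ok] + prof[ok]
    acc_n[ok] <- acc_n[ok] + 1L
  }
  offset <- -half_width + bin * (seq_len(nb) - 1) + bin / 2
  out <- data.frame(offset = offset,
                    value = ifelse(acc_n > 0, acc_sum / pmax(acc_n, 1),
                                   NA_real_),
                    n_sites = acc_n)
  attr(out, "n_partial") <- n_partial
  out
}

#' Pearson correlation of two window methylation tables
#'
#' @param a,b Window methylation tables on the same tiling.
#' @return Pearson r over windows with a defined mean in both.
#' @export
methylation_correlation <- function(a, b) {
  if (nrow(a) != nrow(b) || any(a$start != b$start) ||
      any(a$chrom != b$chrom))
    stop("window tilings differ", call. = FALSE)
  ok <- !is.na(a$mean_pct) & !is.na(b$mean_pct)
  if (sum(ok) < 3)
    stop("fewer than 3 windows defined in both inputs", call. = FALSE)
  stats::cor(a$mean_pct[ok], b$mean_pct[ok])
}

#' Score germline DMR methylation per genotype
#'
#' Mean CpG methylation of each germline differentially methylated region
#' (imprinted gDMR) in each genotype's pooled call table.
#'
#' @param calls_by_genotype Named list of CpG call tables.
#' @param gdmrs Interval data.frame of gDMRs (e.g. from [read_bed()]),
#'   with optional `name`.
#' @return data.frame with one row per gDMR and one `mean_pct.<genotype>`
#'   column per genotype; regions without covered CpGs get NA.
#' @export
score_gdmrs <- function(calls_by_genotype, gdmrs) {
  stopifnot(is.list(calls_by_genotype), !is.null(names(calls_by_genotype)))
  if (nrow(gdmrs) == 0) {
    out <- gdmrs
    for (g in names(calls_by_genotype)) out[[paste0("mean_pct.", g)]] <- numeric(0)
    return(out)
  }
  out <- gdmrs
  for (g in names(calls_by_genotype)) {
    fm <- feature_methylation(calls_by_genotype[[g]], gdmrs)
    out[[paste0("mean_pct.", g)]] <- fm$mean_pct
  }
  out
}

# Vectorised two-sided Fisher exact p for 2x2 tables
# (a = meth in cond A, b = unmeth in A, c = meth in B, d = unmeth in B).
fisher_p2 <- function(a, b, c, d) {
  n <- length(a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m <- a[i] + b[i]; nn <- c[i] + d[i]; k <- a[i] + c[i]
    lo <- max(0, k - nn); hi <- min(k, m)
    dens <- stats::dhyper(lo:hi, m, nn, k)
    p[i] <- sum(dens[dens <= dens[a[i] - lo + 1] * (1 + 1e-7)])
  }
  pmin(p, 1)
}

#' Call differentially methylated regions between two conditions
#'
#' Per-CpG two-sided Fisher exact test on methylated/unmethylated read
#' counts over CpGs covered in both conditions; a differentially
#' methylated CpG (DMC) is a CpG with p < `dmc_p` and an absolute
#' methylation difference > `min_diff` percentage points. Candidate
#' regions are maximal runs of DMCs in which consecutive DMCs lie at most
#' `max_gap` bp apart; the region p-value is the signed Stouffer
#' combination of its DMC p-values, adjusted by Benjamini-Hochberg across
#' candidates. Reported DMRs satisfy all three published criteria: at
#' least `min_dmcs` DMCs, |mean difference| > `min_diff`, adjusted
#' p < `alpha`.
#'
#' @param calls_a,calls_b Pooled CpG call tables for the two conditions.
#' @param min_dmcs Minimum DMCs per region (default 3).
#' @param min_diff Methylation difference threshold in percentage points
#'   (default 20; strict inequality).
#' @param alpha Adjusted region p-value threshold (default 0.001).
#' @param dmc_p Per-CpG p threshold defining a DMC (default 0.01).
#' @param max_gap Maximum distance between consecutive DMCs in a region
#'   (default 250 bp).
#' @return data.frame chrom, start, end, n_dmcs, mean_diff (B minus A,
#'   percentage points), region_p, region_p_adj.
#' @export
call_dmrs <- function(calls_a, calls_b, min_dmcs = 3L, min_diff = 20,
                      alpha = 0.001, dmc_p = 0.01, max_gap = 250L) {
  if (sum(calls_a$depth) == 0 || sum(calls_b$depth) == 0)
    stop("a condition has zero total depth", call. = FALSE)
  key_a <- paste(calls_a$chrom, calls_a$start, sep = "\r")
  key_b <- paste(calls_b$chrom, calls_b$start, sep = "\r")
  ib <- match(key_a, key_b)
  keep <- !is.na(ib)
  a <- calls_a[keep, ]; b <- calls_b[ib[keep], ]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_dmcs = integer(),
                      mean_diff = numeric(), region_p = numeric(),
                      region_p_adj = numeric())
  if (nrow(a) == 0) return(empty)
  diff <- b$pct_meth - a$pct_meth
  # only CpGs passing the difference filter can be DMCs; test only those
  cand <- which(abs(diff) > min_diff)
  if (!length(cand)) return(empty)
  p <- rep(1, nrow(a))
  p[cand] <- fisher_p2(a$n_meth[cand], a$depth[cand] - a$n_meth[cand],
                       b$n_meth[cand], b$depth[cand] - b$n_meth[cand])
  is_dmc <- p < dmc_p & abs(diff) > min_diff
  if (!any(is_dmc)) return(empty)
  dmc <- data.frame(chrom = a$chrom[is_dmc], start = a$start[is_dmc],
                    p = p[is_dmc], diff = diff[is_dmc],
                    stringsAsFactors = FALSE)
  dmc <- dmc[order(dmc$chrom, dmc$start), ]
  new_region <- c(TRUE, dmc$chrom[-1] != dmc$chrom[-nrow(dmc)] |
                    diff(dmc$start) > max_gap)
  region_id <- cumsum(new_region)
  regions <- do.call(rbind, lapply(split(dmc, region_id), function(d) {
    z <- sign(d$diff) * stats::qnorm(1 - pmax(d$p, 1e-300) / 2)
    Z <- sum(z) / sqrt(nrow(d))
    data.frame(chrom = d$chrom[1], start = min(d$start),
               end = max(d$start) + 1L, n_dmcs = nrow(d),
               mean_diff = mean(d$diff),
               region_p = 2 * stats::pnorm(-abs(Z)),
               stringsAsFactors = FALSE)
  }))
  regions$region_p_adj <- stats::p.adjust(regions$region_p, method = "BH")
  out <- regions[regions$n_dmcs >= min_dmcs &
                   abs(regions$mean_diff) > min_diff &
                   regions$region_p_adj < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}
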