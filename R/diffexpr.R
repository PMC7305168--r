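# Count normalisation, FPKM and a negative-binomial Wald test with
# threshold-based calling policies. This engine is deliberately minimal:
# median-of-ratios size factors, per-feature method-of-moments dispersion
# with a floor, delta-method Wald statistic. It implements the published
# thresholds, not any particular DE package's internals (no dispersion
# shrinkage, no fold-change shrinkage, no independent filtering, no
# outlier handling).

#' Median-of-ratios size factors
#'
#' The per-sample normalisation factor is the median across features of
#' the ratio of the sample's count to the feature's geometric mean across
#' samples, computed over features with nonzero counts in every sample,
#' then rescaled to geometric mean 1. With fewer than `min_features`
#' usable features, falls back to library-size scaling with a warning.
#'
#' @param counts Feature-by-sample count matrix.
#' @param min_features Minimum all-nonzero features for median-of-ratios
#'   (default 100).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, min_features = 100L) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) stop("all-zero count matrix", call. = FALSE)
  usable <- rowSums(counts > 0) == ncol(counts)
  if (sum(usable) < min_features) {
    warning("fewer than ", min_features,
            " features nonzero in all samples; using library-size factors",
            call. = FALSE)
    sf <- colSums(counts)
  } else {
    lgm <- rowMeans(log(counts[usable, , drop = FALSE]))
    sf <- apply(counts[usable, , drop = FALSE], 2,
                function(cnt) stats::median(exp(log(cnt) - lgm)))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Fragments per kilobase per million (FPKM)
#'
#' FPKM_ij = 1e9 * count_ij / (length_i * N_j), with N_j the normalised
#' library size: size factor times the mean across samples of
#' (library size / size factor). Under pure library-size factors N_j is
#' the column total, so FPKM * length / 1e9 sums to 1 per sample.
#'
#' @param counts Feature-by-sample count matrix.
#' @param lengths Feature lengths in bp (named or in row order).
#' @param sf Size factors; computed by [size_factors()] when NULL.
#' @param groups Optional factor of group labels per sample; when given,
#'   per-group mean FPKM columns are attached as attribute
#'   `group_means`.
#' @return FPKM matrix, same shape as `counts`.
#' @export
fpkm <- function(counts, lengths, sf = NULL, groups = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  lengths <- as.vector(lengths)
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("feature lengths must be positive", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("sample with zero library size", call. = FALSE)
  N <- sf * mean(libsize / sf)
  out <- 1e9 * sweep(counts, 2, N, "/") / lengths
  if (!is.null(groups)) {
    gm <- vapply(levels(factor(groups)), function(g)
      rowMeans(out[, groups == g, drop = FALSE]), numeric(nrow(out)))
    attr(out, "group_means") <- gm
  }
  out
}

#' Negative-binomial Wald test between two groups
#'
#' Counts are normalised by median-of-ratios size factors. Per feature,
#' the log2 fold change is log2((m_B + 0.5)/(m_A + 0.5)) on normalised
#' group means (the 0.5 pseudocount bounds fold changes of sparse
#' features). The dispersion is estimated per feature by method of
#' moments on normalised counts, pooling the within-group variances
#' across the two groups, and floored at `min_dispersion`. The Wald
#' statistic uses the delta-method standard error of the log2 fold change
#' under NB variance m + alpha m^2; p-values are two-sided normal and BH
#' adjustment is applied across the tested features.
#'
#' @param counts Feature-by-sample count matrix.
#' @param groups Vector of group labels per sample (length ncol(counts)).
#' @param group_a,group_b Labels of the reference and test group; fold
#'   changes are B over A.
#' @param sf Optional size factors for all samples of `counts`.
#' @param lengths Optional feature lengths; when given, per-group mean
#'   FPKM columns `fpkm_a`/`fpkm_b` are included.
#' @param min_dispersion Dispersion floor (default 0.01).
#' @param min_features_sf Passed to [size_factors()] when `sf` is NULL.
#' @return data.frame feature_id, base_mean, log2fc, p, p_adj, and FPKM
#'   columns when lengths are given. With a single replicate in either
#'   group, fold changes are reported and p is NA.
#' @export
nb_wald_test <- function(counts, groups, group_a, group_b, sf = NULL,
                         lengths = NULL, min_dispersion = 0.01,
                         min_features_sf = 100L) {
  counts <- as.matrix(counts)
  stopifnot(length(groups) == ncol(counts))
  ia <- which(groups == group_a); ib <- which(groups == group_b)
  if (!length(ia) || !length(ib))
    stop("empty group: ", if (!length(ia)) group_a else group_b,
         call. = FALSE)
  if (is.null(sf)) {
    sf_sub <- size_factors(counts[, c(ia, ib), drop = FALSE],
                           min_features = min_features_sf)
    sf_all <- rep(NA_real_, ncol(counts))
    sf_all[c(ia, ib)] <- sf_sub
  } else {
    if (length(sf) != ncol(counts))
      stop("sf must have one factor per column of counts", call. = FALSE)
    sf_all <- sf
  }
  norm <- sweep(counts, 2, sf_all, "/")
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(norm[, ia, drop = FALSE])
  mb <- rowMeans(norm[, ib, drop = FALSE])
  log2fc <- log2((mb + 0.5) / (ma + 0.5))
  base_mean <- rowMeans(norm[, c(ia, ib), drop = FALSE])
  if (na >= 2 && nb >= 2) {
    va <- apply(norm[, ia, drop = FALSE], 1, stats::var)
    vb <- apply(norm[, ib, drop = FALSE], 1, stats::var)
    # pooled within-group excess variance -> method-of-moments dispersion
    pooled_var <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    pooled_mean <- (na * ma + nb * mb) / (na + nb)
    mom <- (pooled_var - pooled_mean) / pooled_mean^2
    mom[!is.finite(mom)] <- NA_real_
    # with few replicates the per-feature estimate is extremely noisy and
    # underestimates half the time, inflating Wald statistics; bound it
    # below by a common-dispersion estimate (trimmed mean of the MoM
    # values over adequately expressed features, where MoM is
    # informative). Features with genuinely high dispersion keep their
    # own larger estimate.
    informative <- mom[pooled_mean >= 5 & !is.na(mom)]
    common <- if (length(informative) >= 10)
      mean(informative, trim = 0.1) else mean(mom, na.rm = TRUE)
    if (!is.finite(common)) common <- min_dispersion
    alpha <- pmax(mom, common, min_dispersion)
    alpha[is.na(alpha)] <- max(common, min_dispersion)
    var_ma <- (ma + alpha * ma^2) / na
    var_mb <- (mb + alpha * mb^2) / nb
    se <- sqrt(var_ma / (ma + 0.5)^2 + var_mb / (mb + 0.5)^2) / log(2)
    z <- ifelse(se > 0, log2fc / se, 0)
    p <- 2 * stats::pnorm(-abs(z))
    p[ma == 0 & mb == 0] <- 1
    p_adj <- stats::p.adjust(p, method = "BH")
  } else {
    p <- rep(NA_real_, nrow(counts))
    p_adj <- p
  }
  out <- data.frame(feature_id = if (is.null(rownames(counts)))
    as.character(seq_len(nrow(counts))) else rownames(counts),
    base_mean = base_mean, log2fc = log2fc, p = p, p_adj = p_adj,
    stringsAsFactors = FALSE)
  if (!is.null(lengths)) {
    fp <- fpkm(counts[, c(ia, ib), drop = FALSE], lengths,
               sf = sf_all[c(ia, ib)])
    out$fpkm_a <- rowMeans(fp[, seq_len(na), drop = FALSE])
    out$fpkm_b <- rowMeans(fp[, na + seq_len(nb), drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Differential-expression calling policies
#'
#' The thresholds used per feature type: genes and TE copies are called at
#' fold change > 3 with BH-adjusted p < 0.001; TE families at fold
#' change > 2 with adjusted p < 0.001; exons at fold change > 3 with raw
#' p < 0.001 (unadjusted).
#'
#' @return Named list of policies (fc, alpha, adjusted).
#' @export
de_policies <- function() {
  list(genes = list(fc = 3, alpha = 0.001, adjusted = TRUE),
       te_copies = list(fc = 3, alpha = 0.001, adjusted = TRUE),
       te_families = list(fc = 2, alpha = 0.001, adjusted = TRUE),
       exons = list(fc = 3, alpha = 0.001, adjusted = FALSE))
}

#' Call up/down features at a threshold policy
#'
#' @param de Result of [nb_wald_test()].
#' @param policy Policy name (see [de_policies()]) or a list with
#'   elements fc, alpha, adjusted.
#' @return `de` with logical columns `up` and `down`.
#' @export
call_de <- function(de, policy = "genes") {
  if (is.character(policy)) {
    pols <- de_policies()
    if (!policy %in% names(pols))
      stop("unknown policy: ", policy, call. = FALSE)
    policy <- pols[[policy]]
  }
  pval <- if (isTRUE(policy$adjusted)) de$p_adj else de$p
  sig <- !is.na(pval) & pval < policy$alpha
  de$up <- sig & de$log2fc > log2(policy$fc)
  de$down <- sig & de$log2fc < -log2(policy$fc)
  de
}
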