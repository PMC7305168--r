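# End-to-end orchestration: methylome summaries -> promoter classes ->
# gene/exon/TE differential expression -> gene groups -> cryptic
# initiation -> TE reports, with a JSON manifest of inputs and
# parameters. All thresholds live in the config, never in stage logic.

#' Default pipeline thresholds
#'
#' The published defaults: 1 kb methylation windows with >= 3 CpGs,
#' window classes at 10/50%, de novo selection at <5%/>50%, DMRs with
#' >= 3 DMCs, difference > 20 points, adjusted p < 0.001; DE policies per
#' feature type (see [de_policies()]); promoter grouping at 30%
#' methylation; ERV proximity at 20 kb.
#' @return Named list of thresholds.
#' @export
pipeline_defaults <- function() {
  list(window_size = 1000L, min_cpgs = 3L, min_depth_wgbs = 5L,
       class_low = 10, class_high = 50,
       de_novo_early_max = 5, de_novo_late_min = 50,
       dmr_min_dmcs = 3L, dmr_min_diff = 20, dmr_alpha = 0.001,
       group_meth_cutoff = 30, erv_max_dist = 20000L,
       exon_min_exons = 5L, exon_min_fpkm = 1)
}

stage_msg <- function(stage, t0) {
  message(sprintf("[methtx] %-22s %6.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline on simulated or loaded data
#'
#' Composes the package stages in order on an in-memory bundle as
#' produced by [simulate_all()] (or assembled from files with the
#' genome_io readers): pooled methylomes, global/window/feature
#' methylation, window classes, de novo windows, methylome correlation,
#' gDMR scores, DMR calls, promoter classification and grouping of
#' upregulated genes, gene/exon/TE-copy/TE-family differential
#' expression, cryptic initiation calls and site report, TE family
#' counts, copy summaries, ERV-proximal gene effects and the LTR strand
#' metaplot.
#'
#' @param bundle List with `annotation`, `methylome`, `counts` (see
#'   [simulate_all()]).
#' @param mutant Genotype tested against WT for expression stages
#'   (default "DKO").
#' @param thresholds See [pipeline_defaults()].
#' @param out_dir When non-NULL, writes result TSVs and a JSON manifest.
#' @param ltr_family Family profiled by the strand metaplot.
#' @param seed Seed for the seeded random control of the ERV-proximal
#'   comparison.
#' @return Named list of stage results.
#' @export
run_pipeline <- function(bundle, mutant = "DKO",
                         thresholds = pipeline_defaults(),
                         out_dir = NULL, ltr_family = "IAPLTR1_Mm",
                         seed = 1L) {
  t0 <- as.numeric(Sys.time())
  ann <- bundle$annotation; meth <- bundle$methylome
  cnt <- bundle$counts
  # fail before any compute on an incomplete bundle
  if (is.null(ann) || is.null(meth) || is.null(cnt))
    stop("bundle must contain annotation, methylome and counts",
         call. = FALSE)
  if (is.null(cnt$samples) || !all(c("sample", "genotype") %in%
                                     names(cnt$samples)))
    stop("missing or malformed sample sheet", call. = FALSE)
  if (!mutant %in% cnt$samples$genotype)
    stop("genotype not in sample sheet: ", mutant, call. = FALSE)
  th <- utils::modifyList(pipeline_defaults(), thresholds)
  res <- list(thresholds = th)

  # --- methylome stage
  pooled <- lapply(meth$calls, pool_replicates)
  res$global_meth <- vapply(pooled, function(p) mean(p$pct_meth),
                            numeric(1))
  win <- lapply(pooled, window_methylation,
                chrom_lengths = ann$chrom_lengths,
                window_size = th$window_size, min_cpgs = th$min_cpgs)
  res$windows <- win
  res$window_classes <- lapply(win, classify_windows)
  res$de_novo <- select_de_novo_windows(win$ICM, win$WT,
                                        early_max = th$de_novo_early_max,
                                        late_min = th$de_novo_late_min)
  res$cor_dko_icm <- methylation_correlation(win$DKO, win$ICM)
  res$gdmr_scores <- score_gdmrs(pooled, ann$gdmrs)
  res$dmrs <- call_dmrs(pooled$Dnmt1KO, pooled$DKO,
                        min_dmcs = th$dmr_min_dmcs,
                        min_diff = th$dmr_min_diff,
                        alpha = th$dmr_alpha)
  stage_msg("methylome", t0)

  # --- promoter classes
  res$promoter_classes <- classify_promoters(ann$genome, ann$transcripts)
  res$promoter_meth_wt <- promoter_methylation(pooled$WT, ann$transcripts)
  stage_msg("promoter classes", t0)

  # --- differential expression
  grp <- cnt$samples$genotype
  res$gene_de <- call_de(nb_wald_test(cnt$gene_counts, grp, "WT", mutant,
                                      lengths = cnt$gene_lengths),
                         "genes")
  res$exon_de <- call_de(nb_wald_test(cnt$exon_counts, grp, "WT", mutant,
                                      lengths = cnt$exon_lengths),
                         "exons")
  up_genes <- res$gene_de$feature_id[res$gene_de$up]
  res$groups <- assign_groups(up_genes, res$promoter_classes,
                              res$promoter_meth_wt,
                              meth_cutoff = th$group_meth_cutoff)
  stage_msg("gene/exon DE", t0)

  # --- TE stage
  if (!is.null(cnt$te_copy_counts)) {
    res$copy_de <- call_de(nb_wald_test(cnt$te_copy_counts, grp, "WT",
                                        mutant),
                           "te_copies")
    res$copy_summary <- copy_up_summary(res$copy_de, ann$tes)
    fam_counts <- count_te_families(cnt$alignments, ann$tes)
    fam_mat <- as.matrix(fam_counts[, cnt$samples$sample, drop = FALSE])
    rownames(fam_mat) <- fam_counts$family
    res$family_counts <- fam_counts
    # family counts are a composition within a fixed read total, so
    # normalise by total read mass (assigned + unassigned), not by
    # median-of-ratios on the handful of family rows
    fam_sf <- colSums(fam_mat)
    fam_sf <- fam_sf / exp(mean(log(fam_sf)))
    res$family_de <- call_de(nb_wald_test(round(fam_mat), grp, "WT",
                                          mutant, sf = fam_sf),
                             "te_families")
    up_erv <- ann$tes[ann$tes$copy_id %in% res$copy_summary$up_copy_ids &
                        ann$tes$te_class %in% c("ERV1", "ERVK", "ERVL"), ]
    all_erv <- ann$tes[ann$tes$te_class %in% c("ERV1", "ERVK", "ERVL"), ]
    res$erv_proximal <- erv_proximal_genes(up_erv, ann$transcripts,
                                           res$gene_de,
                                           all_erv_copies = all_erv,
                                           max_dist = th$erv_max_dist,
                                           seed = seed)
    mut_samples <- cnt$samples$sample[cnt$samples$genotype == mutant]
    aln_mut <- cnt$alignments[cnt$alignments$sample %in% mut_samples, ]
    if (ltr_family %in% ann$tes$family) {
      res$ltr_metaplot <- ltr_strand_metaplot(
        alignment_coverage(aln_mut, "+", ann$chrom_lengths),
        alignment_coverage(aln_mut, "-", ann$chrom_lengths),
        ann$tes, ltr_family)
    }
    stage_msg("TE analysis", t0)
  }

  # --- cryptic initiation
  fp <- fpkm(cnt$exon_counts, cnt$exon_lengths,
             groups = cnt$samples$genotype)
  gm <- attr(fp, "group_means")[, c("WT", mutant)]
  res$exon_ratio <- exon_ratio_profile(gm, ann$transcripts,
                                       min_exons = th$exon_min_exons,
                                       min_fpkm = th$exon_min_fpkm)
  res$cryptic_calls <- call_cryptic_initiation(res$exon_de,
                                               ann$transcripts, ann$tes)
  res$cryptic_report <- cryptic_site_report(res$cryptic_calls, pooled$WT,
                                            ann$genome, ann$transcripts)
  stage_msg("cryptic initiation", t0)

  if (!is.null(out_dir)) write_pipeline_results(res, bundle, out_dir)
  res
}

write_pipeline_results <- function(res, bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (g in names(res$windows))
    wt(res$windows[[g]], sprintf("windows_%s.tsv", g))
  wt(res$de_novo, "de_novo_windows.tsv")
  wt(res$gdmr_scores, "gdmr_scores.tsv")
  wt(res$dmrs, "dmrs.tsv")
  wt(res$promoter_classes, "promoter_classes.tsv")
  wt(res$gene_de, "gene_de.tsv")
  wt(res$exon_de, "exon_de.tsv")
  wt(res$groups$groups, "gene_groups.tsv")
  wt(res$cryptic_calls, "cryptic_calls.tsv")
  if (nrow(res$cryptic_calls))
    write_bed(data.frame(chrom = res$cryptic_calls$init_chrom,
                         start = res$cryptic_calls$init_position,
                         end = res$cryptic_calls$init_position + 1L,
                         name = res$cryptic_calls$gene_id),
              file.path(out_dir, "cryptic_sites.bed"))
  if (!is.null(res$copy_de)) {
    wt(res$copy_de, "te_copy_de.tsv")
    wt(res$copy_summary$families, "te_copy_summary.tsv")
    wt(res$family_counts, "te_family_counts.tsv")
    wt(res$family_de, "te_family_de.tsv")
  }
  manifest <- list(
    package = "methtx",
    version = as.character(utils::packageVersion("methtx")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    thresholds = res$thresholds,
    global_meth = as.list(res$global_meth),
    n_samples = nrow(bundle$counts$samples),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Simulate a dataset and run the full pipeline
#'
#' @param seed Simulation seed.
#' @param out_dir Optional output directory for result TSVs and the
#'   manifest.
#' @param config Optional [sim_config()] overriding the default (its
#'   seed is replaced by `seed`).
#' @param ... Passed to [run_pipeline()].
#' @return List with `bundle` (the simulated data) and `results`.
#' @export
run_demo <- function(seed = 1L, out_dir = NULL, config = NULL, ...) {
  if (is.null(config)) config <- sim_config(seed = seed)
  else config$seed <- seed
  bundle <- simulate_all(config)
  results <- run_pipeline(bundle, out_dir = out_dir, seed = seed, ...)
  list(bundle = bundle, results = results)
}
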