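# Seeded synthetic data: a toy genome with constructed promoter classes,
# CpG islands, TE copies and germline DMRs; per-genotype beta-binomial
# methylomes; and negative-binomial count matrices with planted
# derepressed genes, reactivated TE copies and cryptic intragenic
# initiation events. Every quantity the downstream analyses estimate is
# planted by construction and recorded in a ground-truth sidecar.

#' Simulation configuration
#'
#' Defaults describe a desk-scale embryo-methylome-like study: two 5 Mb
#' chromosomes, 300 genes, four methylome states (wild type, Dnmt1-null,
#' Dnmt3a/b double-null, and an inner-cell-mass-like hypomethylated
#' reference whose landscape the double-null copies), two bisulfite
#' replicates and three RNA replicates per genotype, 12x mean depth.
#' Methylation means are per-region-class: CpG islands are hypomethylated
#' in every state; the hypomethylated states share a per-window latent
#' landscape (which is what makes their window-level methylation
#' correlate); selected young ERV families retain high methylation in the
#' double-null but not in the Dnmt1-null, which is scaled down uniformly,
#' germline DMRs included.
#'
#' @param seed Integer seed fixing every downstream draw.
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes Total gene count.
#' @param isoforms_per_gene,exons_per_transcript Ranges (min, max).
#' @param te_families data.frame name, te_class, copies, len_min,
#'   len_max.
#' @param genotype_meth_means Named list genotype -> c(non_cgi, cgi)
#'   means in \[0,1\]. The CGI entries are used directly; the ratio of
#'   the Dnmt1-null to wild-type non-CGI entries sets the uniform
#'   Dnmt1-null scaling; the other non-CGI entries document the centres
#'   of the latent landscapes below.
#' @param hypo_range,hyper_range Uniform ranges of the per-window latent
#'   methylation landscape of the hypomethylated states (ICM-like and
#'   double-null) and the wild type. The hypomethylated floor (0.18) is
#'   chosen so that, at the default depth, precision and CpG density, no
#'   non-planted window drops below the 5% de novo selection bound.
#' @param retained_te_families Families kept highly methylated in the
#'   double-null.
#' @param beta_binomial_precision Precision of per-CpG beta-binomial
#'   draws.
#' @param nb_dispersion NB dispersion of counts.
#' @param n_replicates RNA replicates per genotype.
#' @param n_meth_replicates Bisulfite replicates per state.
#' @param depth_mean,depth_size Truncated-NB read depth parameters.
#' @param n_derepressed,derepressed_fc Planted upregulated genes and
#'   their fold change.
#' @param n_reactivated,reactivated_fc Planted upregulated TE copies.
#' @param n_cryptic,cryptic_fc,n_te_decoys Planted cryptic-initiation
#'   genes, their exon fold change, and decoy genes whose cryptic-like
#'   site overlaps a TE copy (the caller must exclude these).
#' @param n_de_novo_windows Windows planted low in the hypomethylated
#'   reference and high in the wild type.
#' @param n_gdmrs Germline DMR intervals.
#' @param n_te_reads TE-derived alignment rows target per sample.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 5e6,
                       n_genes = 300L,
                       isoforms_per_gene = c(1L, 2L),
                       exons_per_transcript = c(4L, 10L),
                       te_families = default_te_families(),
                       genotype_meth_means = list(
                         WT = c(non_cgi = 0.80, cgi = 0.03),
                         Dnmt1KO = c(non_cgi = 0.20, cgi = 0.0075),
                         DKO = c(non_cgi = 0.38, cgi = 0.02),
                         ICM = c(non_cgi = 0.38, cgi = 0.02)),
                       hypo_range = c(0.18, 0.58),
                       hyper_range = c(0.65, 0.95),
                       retained_te_families = c("IAPEz-int", "IAPLTR1_Mm"),
                       beta_binomial_precision = 100,
                       nb_dispersion = 0.05,
                       n_replicates = 3L,
                       n_meth_replicates = 2L,
                       depth_mean = 12, depth_size = 4,
                       n_derepressed = 20L, derepressed_fc = 8,
                       n_reactivated = 12L, reactivated_fc = 10,
                       n_cryptic = 20L, cryptic_fc = 10,
                       n_te_decoys = 2L,
                       n_de_novo_windows = 30L,
                       n_gdmrs = 20L,
                       n_te_reads = 4000L) {
  cfg <- as.list(environment())
  stopifnot(cfg$seed == as.integer(cfg$seed),
            all(unlist(genotype_meth_means) >= 0),
            all(unlist(genotype_meth_means) <= 1),
            derepressed_fc > 1, reactivated_fc > 1, cryptic_fc > 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Default TE family catalogue for the simulator
#' @return data.frame name, te_class, copies, len_min, len_max,
#'   multimapper (whether reads from the family multi-map) and
#'   expression weight.
#' @export
default_te_families <- function() {
  data.frame(
    name = c("IAPEz-int", "IAPLTR1_Mm", "MERVL-int", "MT2_Mm", "L1MdA",
             "B1_Mus", "RLTR10", "Simple_repeat"),
    te_class = c("ERVK", "ERVK", "ERVL", "ERVL", "LINE", "SINE", "ERV1",
                 "other"),
    copies = c(24L, 16L, 16L, 10L, 30L, 40L, 10L, 10L),
    len_min = c(4000, 300, 4000, 400, 1000, 130, 400, 100),
    len_max = c(6500, 400, 5500, 500, 6000, 160, 600, 300),
    multimapper = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    weight = c(2, 1, 2, 1, 2, 3, 1, 0.5),
    stringsAsFactors = FALSE)
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

# iid DNA with given GC content, then CpG dinucleotides thinned to
# `cpg_keep` of their iid expectation (the G of a removed CpG becomes
# A/T). Returns a character vector of single bases.
random_dna <- function(n, gc = 0.42, cpg_keep = 0.30) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  x <- sample(names(p), n, replace = TRUE, prob = p)
  if (cpg_keep < 1 && n > 1) {
    is_cpg_c <- which(x[-n] == "C" & x[-1] == "G")
    kill <- is_cpg_c[stats::runif(length(is_cpg_c)) > cpg_keep]
    if (length(kill))
      x[kill + 1L] <- sample(c("A", "T"), length(kill), replace = TRUE)
  }
  x
}

# Sequence recipes per promoter class; each returns a base vector.
promoter_sequence <- function(cls, n) {
  switch(cls,
         HCP = random_dna(n, gc = 0.65, cpg_keep = 1),
         ICP = random_dna(n, gc = 0.48, cpg_keep = 0.55),
         LCP = random_dna(n, gc = 0.42, cpg_keep = 0.05))
}

#' Simulate genome, gene models and annotations
#'
#' Lays out genes on a regular grid of slots, synthesises promoter
#' sequence so that target LCP/ICP/HCP proportions are realised by
#' construction (high-CpG promoters get a CpG-island block that is also
#' emitted in the CGI BED), places TE copies in inter-genic slot tails,
#' reserves tails for germline DMRs and de novo methylated windows, and
#' implants a CpG-dense block at each planted cryptic initiation exon.
#'
#' @param config A [sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]),
#'   `transcripts` (`transcript_models`), `cgis`, `tes`, `gdmrs`
#'   (interval data.frames) and `truth` (planted ground truth).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_annotation_impl(config))
}

simulate_annotation_impl <- function(cfg) {
  genes_per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  slot_w <- floor(cfg$chrom_length / genes_per_chrom)
  min_head <- 6000L
  if (slot_w < min_head + 16000L)
    stop("requested features exceed genome capacity: ", cfg$n_genes,
         " genes do not fit in ", cfg$n_chroms, " x ", cfg$chrom_length,
         " bp", call. = FALSE)
  chrom_names <- paste0("chr", seq_len(cfg$n_chroms))

  # --- gene-level design drawn first (global, chromosome-independent)
  n <- cfg$n_genes
  cls_target <- sample(c("HCP", "ICP", "LCP"), n, replace = TRUE,
                       prob = c(0.5, 0.25, 0.25))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_exons <- sample(seq(cfg$exons_per_transcript[1],
                        cfg$exons_per_transcript[2]), n, replace = TRUE)
  # the last slot of each chromosome is reserved as a TE-free zone that
  # hosts the simulated non-TE alignment reads
  reserved <- pmin(seq_len(cfg$n_chroms) * genes_per_chrom, n)
  # planted cryptic genes need headroom for a downstream init exon
  elig <- setdiff(which(n_exons >= 6), reserved)
  n_special <- cfg$n_cryptic + cfg$n_te_decoys + cfg$n_derepressed
  if (length(elig) < cfg$n_cryptic + cfg$n_te_decoys ||
      n < n_special + length(reserved))
    stop("too few genes for the requested planted effects", call. = FALSE)
  cryptic_idx <- sort(sample(elig, cfg$n_cryptic))
  decoy_idx <- sort(sample(setdiff(elig, cryptic_idx), cfg$n_te_decoys))
  rest <- setdiff(seq_len(n), c(cryptic_idx, decoy_idx, reserved))
  derep_idx <- sort(sample(rest, cfg$n_derepressed))
  # derepressed genes span the three promoter groups: germline-like
  # (HCP, promoter methylated in WT), 2C-like (HCP unmethylated), LCP
  n_d <- cfg$n_derepressed
  derep_kind <- rep(c("germline", "twoC", "lcp"), length.out = n_d)
  cls_target[derep_idx[derep_kind == "germline"]] <- "HCP"
  cls_target[derep_idx[derep_kind == "twoC"]] <- "HCP"
  cls_target[derep_idx[derep_kind == "lcp"]] <- "LCP"
  meth_cgi_promoter <- rep(FALSE, n)
  meth_cgi_promoter[derep_idx[derep_kind == "germline"]] <- TRUE

  # tail roles: gDMR and de novo window slots, spread across the genome
  tail_role <- rep("te", n)
  tail_role[reserved] <- "reserved"
  role_pool <- setdiff(seq_len(n), reserved)
  gdmr_slots <- sort(sample(role_pool, cfg$n_gdmrs))
  dn_slots <- sort(sample(setdiff(role_pool, gdmr_slots),
                          cfg$n_de_novo_windows))
  tail_role[gdmr_slots] <- "gdmr"
  tail_role[dn_slots] <- "de_novo"

  # TE copy catalogue to place
  fams <- cfg$te_families
  copies <- if (nrow(fams)) do.call(rbind, lapply(seq_len(nrow(fams)),
    function(i)
      data.frame(family = fams$name[i], te_class = fams$te_class[i],
                 length = round(stats::runif(fams$copies[i],
                                             fams$len_min[i],
                                             fams$len_max[i])),
                 stringsAsFactors = FALSE)))
  else data.frame(family = character(), te_class = character(),
                  length = integer())
  copies <- copies[sample(nrow(copies)), , drop = FALSE]
  # reactivated copies come from the young ERV families; a subset is
  # forced next to a derepressed gene so ERV-proximal effects exist
  erv_pool <- which(copies$family %in% c("IAPEz-int", "MERVL-int"))
  react_rows <- sort(sample(erv_pool, cfg$n_reactivated))
  n_prox <- min(8L, cfg$n_reactivated, cfg$n_derepressed)
  prox_react_rows <- react_rows[seq_len(n_prox)]
  # the slot head of each of the first n_prox derepressed genes hosts
  # one of these copies, i.e. just upstream of the gene, so derepressed
  # genes near activated ERVs exist by construction
  prox_target_slot <- derep_idx[seq_len(n_prox)]

  seqs <- list()
  exon_rows <- list(); cgi_rows <- list(); te_rows <- list()
  gdmr_rows <- list(); dn_rows <- list(); outside_regions <- list()
  cryptic_truth <- list()
  placed_te <- 0L
  gene_meta <- data.frame(gene_id = paste0("g", seq_len(n)),
                          cls_target = cls_target, strand = strand,
                          n_exons = n_exons, chrom = NA_character_,
                          tss = NA_integer_, stringsAsFactors = FALSE)

  gi <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    chars <- random_dna(cfg$chrom_length, gc = 0.42, cpg_keep = 0.30)
    n_here <- min(genes_per_chrom, n - gi)
    for (si in seq_len(n_here)) {
      gi <- gi + 1L
      S <- (si - 1L) * slot_w
      gene_id <- paste0("g", gi)
      st <- strand[gi]
      ne <- n_exons[gi]
      ex_len <- round(stats::runif(ne, 150, 400))
      in_len <- round(stats::runif(max(ne - 1, 0), 700, 1500))
      gene_start <- S + min_head
      starts <- gene_start + c(0, cumsum(ex_len[-ne] + in_len))
      ends <- starts + ex_len
      gene_end <- ends[ne]
      if (gene_end > S + slot_w - 9000L)
        stop("gene span exceeds slot; reduce exons_per_transcript",
             call. = FALSE)
      tss <- if (st == "+") gene_start else gene_end - 1L
      gene_meta$chrom[gi] <- chrom_names[ci]
      gene_meta$tss[gi] <- tss

      # promoter sequence implant
      cls <- cls_target[gi]
      half <- if (cls == "LCP") 1000L else 800L
      p0 <- max(tss - half, 0L); p1 <- min(tss + half, cfg$chrom_length)
      chars[(p0 + 1):p1] <- promoter_sequence(cls, p1 - p0)
      if (cls == "HCP")
        cgi_rows[[length(cgi_rows) + 1]] <- data.frame(
          chrom = chrom_names[ci], start = p0, end = p1,
          name = paste0("CGI_", gene_id),
          methylated = meth_cgi_promoter[gi], stringsAsFactors = FALSE)

      # exons (two isoforms when allowed: the second skips one internal
      # exon of the primary)
      tx1 <- paste0(gene_id, ".t1")
      exon_rows[[length(exon_rows) + 1]] <- data.frame(
        gene_id = gene_id, transcript_id = tx1, chrom = chrom_names[ci],
        strand = st, start = starts, end = ends, stringsAsFactors = FALSE)
      iso_max <- sample(seq(cfg$isoforms_per_gene[1],
                            cfg$isoforms_per_gene[2]), 1)
      if (iso_max >= 2 && ne >= 4) {
        skip <- sample(2:(ne - 1), 1)
        exon_rows[[length(exon_rows) + 1]] <- data.frame(
          gene_id = gene_id, transcript_id = paste0(gene_id, ".t2"),
          chrom = chrom_names[ci], strand = st, start = starts[-skip],
          end = ends[-skip], stringsAsFactors = FALSE)
      }

      # cryptic initiation implant: CpG-dense block at the 5' edge of the
      # first upregulated exon (transcription order)
      if (gi %in% c(cryptic_idx, decoy_idx)) {
        first_up <- sample(3:(ne - 1), 1)
        # transcription-order exon index -> genomic exon
        genomic_idx <- if (st == "+") first_up else ne - first_up + 1L
        init_pos <- if (st == "+") starts[genomic_idx]
        else ends[genomic_idx] - 1L
        b0 <- if (st == "+") starts[genomic_idx]
        else ends[genomic_idx] - 300L
        chars[(b0 + 1):(b0 + 300)] <- random_dna(300, gc = 0.55,
                                                 cpg_keep = 0.9)
        if (gi %in% decoy_idx) {
          # decoy: a TE copy sits on the would-be initiation site
          te_rows[[length(te_rows) + 1]] <- data.frame(
            chrom = chrom_names[ci], start = init_pos - 100L,
            end = init_pos + 200L, strand = st, family = "IAPLTR1_Mm",
            te_class = "ERVK", stringsAsFactors = FALSE)
        }
        cryptic_truth[[length(cryptic_truth) + 1]] <- data.frame(
          gene_id = gene_id, transcript_id = tx1,
          first_up_exon_index = first_up, init_chrom = chrom_names[ci],
          init_position = init_pos, strand = st,
          decoy = gi %in% decoy_idx, stringsAsFactors = FALSE)
      }

      # forced ERV-proximal reactivated copies sit in the slot head,
      # just upstream of the gene
      force_rows <- which(prox_target_slot == gi)
      for (fr in force_rows) {
        cp <- copies[prox_react_rows[fr], ]
        h_end <- S + 5500L
        h_start <- max(S + 400L, h_end - cp$length)
        te_rows[[length(te_rows) + 1]] <- data.frame(
          chrom = chrom_names[ci], start = h_start, end = h_end,
          strand = sample(c("+", "-"), 1), family = cp$family,
          te_class = cp$te_class, planted_row = prox_react_rows[fr],
          stringsAsFactors = FALSE)
      }

      # slot tail
      t0 <- gene_end + 2000L; t1 <- S + slot_w - 1000L
      role <- tail_role[gi]
      if (role == "reserved") {
        dn_out <- data.frame(chrom = chrom_names[ci],
                             start = S + slot_w - 6000L,
                             end = S + slot_w - 1500L,
                             stringsAsFactors = FALSE)
        outside_regions[[length(outside_regions) + 1]] <- dn_out
      } else if (role == "gdmr" && t1 - t0 >= 2500L) {
        gdmr_rows[[length(gdmr_rows) + 1]] <- data.frame(
          chrom = chrom_names[ci], start = t0 + 200L, end = t0 + 2200L,
          name = paste0("gDMR_", length(gdmr_rows) + 1L),
          stringsAsFactors = FALSE)
      } else if (role == "de_novo" && t1 - t0 >= 2500L) {
        w0 <- 1000L * ceiling((t0 + 100L) / 1000L)
        # guarantee the window carries CpGs (well above the 3-CpG window
        # minimum) so its methylation mean is always defined: a dozen
        # CpG dinucleotides are spaced through the planted window
        for (k in 1:12) {
          p <- w0 + k * 77L
          chars[p + 1L] <- "C"; chars[p + 2L] <- "G"
        }
        dn_rows[[length(dn_rows) + 1]] <- data.frame(
          chrom = chrom_names[ci], start = w0, end = w0 + 1000L,
          stringsAsFactors = FALSE)
      } else {
        # sequential TE placement in the tail
        cursor <- t0
        while (nrow(copies) > 0 && placed_te < nrow(copies) &&
                 cursor < t1) {
          repeat {
            placed_te <- placed_te + 1L
            if (placed_te > nrow(copies) ||
                !placed_te %in% prox_react_rows) break
          }
          if (placed_te > nrow(copies)) break
          cp <- copies[placed_te, ]
          gap <- round(stats::runif(1, 300, 1200))
          if (cursor + gap + cp$length > t1) { placed_te <- placed_te - 1L; break }
          te_rows[[length(te_rows) + 1]] <- data.frame(
            chrom = chrom_names[ci], start = cursor + gap,
            end = cursor + gap + cp$length,
            strand = sample(c("+", "-"), 1), family = cp$family,
            te_class = cp$te_class, planted_row = placed_te,
            stringsAsFactors = FALSE)
          cursor <- cursor + gap + cp$length
        }
      }
    }
    seqs[[chrom_names[ci]]] <- paste(chars, collapse = "")
  }
  if (placed_te < nrow(copies))
    warning(nrow(copies) - placed_te, " TE copies did not fit and were ",
            "dropped", call. = FALSE)

  genome <- Biostrings::DNAStringSet(unlist(seqs))
  tx <- transcript_models(do.call(rbind, exon_rows))
  te <- if (length(te_rows)) {
    d <- do.call(rbind, lapply(te_rows, function(r) {
      if (!"planted_row" %in% names(r)) r$planted_row <- NA_integer_
      r
    }))
    d$copy_id <- paste0(d$chrom, ":", d$start, "-", d$end, ":", d$family)
    d$length <- d$end - d$start
    d
  } else data.frame(chrom = character(), start = integer(),
                    end = integer(), strand = character(),
                    family = character(), te_class = character(),
                    copy_id = character(), length = integer())
  cgis <- if (length(cgi_rows)) do.call(rbind, cgi_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), methylated = logical())
  gdmrs <- if (length(gdmr_rows)) do.call(rbind, gdmr_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character())
  dn <- if (length(dn_rows)) do.call(rbind, dn_rows) else
    data.frame(chrom = character(), start = integer(), end = integer())
  react_ids <- te$copy_id[match(react_rows, te$planted_row)]
  react_ids <- react_ids[!is.na(react_ids)]
  cr <- if (length(cryptic_truth)) do.call(rbind, cryptic_truth) else NULL
  truth <- list(
    derepressed = data.frame(
      gene_id = gene_meta$gene_id[derep_idx], kind = derep_kind,
      fold_change = cfg$derepressed_fc, stringsAsFactors = FALSE),
    reactivated_copy_ids = react_ids,
    cryptic = cr[!cr$decoy, , drop = FALSE],
    te_decoys = cr[cr$decoy, , drop = FALSE],
    de_novo_windows = dn,
    promoter_class = gene_meta[, c("gene_id", "cls_target")],
    methylated_cgi_genes =
      gene_meta$gene_id[meth_cgi_promoter])
  te$planted_row <- NULL
  list(genome = genome, transcripts = tx, cgis = cgis, tes = te,
       gdmrs = gdmrs, truth = truth,
       outside_regions = do.call(rbind, outside_regions),
       chrom_lengths = stats::setNames(rep(as.integer(cfg$chrom_length),
                                           cfg$n_chroms), chrom_names))
}

# region class per CpG: precedence gdmr > retained TE > CGI > de novo >
# background window landscape
assign_cpg_class <- function(cpgs, ann, cfg) {
  cls <- rep("background", nrow(cpgs))
  mark <- function(cls, ivs, label) {
    if (is.null(ivs) || nrow(ivs) == 0) return(cls)
    hits <- GenomicRanges::findOverlaps(as_gr(cpgs), as_gr(ivs),
                                        ignore.strand = TRUE)
    cls[unique(S4Vectors::queryHits(hits))] <- label
    cls
  }
  cls <- mark(cls, ann$truth$de_novo_windows, "de_novo")
  cgi_un <- ann$cgis[!ann$cgis$methylated, , drop = FALSE]
  cgi_me <- ann$cgis[ann$cgis$methylated, , drop = FALSE]
  cls <- mark(cls, cgi_un, "cgi")
  cls <- mark(cls, cgi_me, "cgi_methylated")
  ret <- ann$tes[ann$tes$family %in% cfg$retained_te_families, ,
                 drop = FALSE]
  cls <- mark(cls, ret, "retained_te")
  cls <- mark(cls, ann$gdmrs, "gdmr")
  cls
}

#' Simulate per-genotype methylomes
#'
#' CpG positions come from the simulated genome sequence. Each CpG gets a
#' genotype-specific mean: a shared per-1kb-window latent landscape for
#' the hypomethylated states (the ICM-like reference and the
#' Dnmt3a/b-null, which copies it except at retained TE families and
#' germline DMRs), an independent high landscape for the wild type, a
#' uniform scaling of the wild-type means for the Dnmt1-null (germline
#' DMRs included), and fixed class means for CpG islands, germline DMRs,
#' retained TE families and planted de novo windows. Depth is truncated
#' negative binomial (minimum 1) and methylated counts are
#' beta-binomial.
#'
#' @param config A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return List with `calls` (genotype -> list of replicate CpG call
#'   tables), `cpg_means` (per-CpG true means per genotype) and `cpgs`
#'   (positions).
#' @export
simulate_methylome <- function(config, ann) {
  with_seed(config$seed + 1L, simulate_methylome_impl(config, ann))
}

simulate_methylome_impl <- function(cfg, ann) {
  cpgs <- do.call(rbind, lapply(names(ann$genome), function(ch) {
    pos <- Biostrings::start(Biostrings::matchPattern("CG",
                                                      ann$genome[[ch]])) - 1L
    data.frame(chrom = ch, start = pos, end = pos + 1L,
               stringsAsFactors = FALSE)
  }))
  cls <- assign_cpg_class(cpgs, ann, cfg)
  win_id <- paste(cpgs$chrom, cpgs$start %/% 1000L)
  uw <- unique(win_id)
  # shared latent landscapes; the hypomethylated floor keeps non-planted
  # windows clear of the 5% de novo selection bound, the wild-type floor
  # keeps them clear of the 50% bound
  hypo <- stats::setNames(stats::runif(length(uw), cfg$hypo_range[1],
                                       cfg$hypo_range[2]), uw)
  hyper <- stats::setNames(stats::runif(length(uw), cfg$hyper_range[1],
                                        cfg$hyper_range[2]), uw)
  mm <- cfg$genotype_meth_means
  mu <- list()
  mu$WT <- ifelse(cls == "cgi", mm$WT[["cgi"]],
           ifelse(cls == "cgi_methylated", 0.80,
           ifelse(cls == "gdmr", 0.50,
           ifelse(cls == "retained_te", 0.85,
           ifelse(cls == "de_novo", 0.75, hyper[win_id])))))
  # young ERVs stay comparatively methylated in the hypomethylated
  # pre-implantation state too, so the landscape stays largely shared
  mu$ICM <- ifelse(cls == "cgi", mm$ICM[["cgi"]],
            ifelse(cls == "cgi_methylated", 0.50,
            ifelse(cls == "gdmr", 0.50,
            ifelse(cls == "retained_te", 0.75,
            ifelse(cls == "de_novo", 0.01, hypo[win_id])))))
  mu$DKO <- ifelse(cls == "gdmr", 0.50,
            ifelse(cls == "retained_te", 0.85, mu$ICM))
  d1_scale <- mm$Dnmt1KO[["non_cgi"]] / mm$WT[["non_cgi"]]
  mu$Dnmt1KO <- mu$WT * d1_scale
  s <- cfg$beta_binomial_precision
  calls <- lapply(mu, function(m) {
    lapply(seq_len(cfg$n_meth_replicates), function(r) {
      depth <- stats::rnbinom(nrow(cpgs), mu = cfg$depth_mean,
                              size = cfg$depth_size)
      depth[depth < 1L] <- 1L
      pm <- stats::rbeta(nrow(cpgs), pmax(m * s, 1e-3),
                         pmax((1 - m) * s, 1e-3))
      n_meth <- stats::rbinom(nrow(cpgs), depth, pm)
      data.frame(chrom = cpgs$chrom, start = cpgs$start, end = cpgs$end,
                 depth = depth, n_meth = n_meth,
                 pct_meth = 100 * n_meth / depth,
                 stringsAsFactors = FALSE)
    })
  })
  list(calls = calls, cpg_means = mu, cpgs = cpgs, cpg_class = cls)
}

#' Simulate count matrices and a TE alignment table
#'
#' Baseline transcript expression is log-normal; per-sample counts are
#' negative binomial around mean x size factor with the configured
#' dispersion. Exon counts split transcript means proportionally to exon
#' length; planted cryptic-initiation genes multiply the means of exons
#' at or downstream of the planted initiation exon by the cryptic fold
#' change in the mutant genotypes. Planted derepressed genes are
#' multiplied in the mutants at the gene level. TE copy counts are NB
#' with planted reactivated copies; a simplified alignment table carries
#' TE-derived reads, multi-mapping (n_hits > 1) for young families, each
#' read appearing in exactly n_hits rows. Gene counts emulate
#' repeat-masked counting: they contain no TE-derived reads by
#' construction.
#'
#' @param config A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return List with `gene_counts`, `exon_counts` (rownames
#'   `transcript:rank`), `exon_lengths`, `gene_lengths`,
#'   `te_copy_counts`, `alignments`, `samples` (sample sheet) and
#'   `truth` (per-feature expected means).
#' @export
simulate_counts <- function(config, ann) {
  with_seed(config$seed + 2L, simulate_counts_impl(config, ann))
}

simulate_counts_impl <- function(cfg, ann) {
  genotypes <- c("WT", "Dnmt1KO", "DKO")
  samples <- data.frame(
    sample = paste(rep(genotypes, each = cfg$n_replicates),
                   seq_len(cfg$n_replicates), sep = "_"),
    genotype = rep(genotypes, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), length(genotypes)),
    stringsAsFactors = FALSE)
  ns <- nrow(samples)
  sf <- exp(stats::rnorm(ns, 0, 0.1))
  disp <- cfg$nb_dispersion

  tx <- ann$transcripts
  spans <- transcript_spans(tx)
  gene_ids <- unique(spans$gene_id)
  base_gene <- stats::setNames(stats::rlnorm(length(gene_ids),
                                             log(300), 0.7), gene_ids)
  derep <- ann$truth$derepressed
  gene_mult <- matrix(1, length(gene_ids), ns,
                      dimnames = list(gene_ids, samples$sample))
  mut <- samples$genotype != "WT"
  gene_mult[derep$gene_id, mut] <- cfg$derepressed_fc

  rnb <- function(mu) stats::rnbinom(length(mu), mu = mu, size = 1 / disp)
  gene_mu <- outer(base_gene, sf) * gene_mult
  gene_counts <- matrix(rnb(gene_mu), nrow(gene_mu),
                        dimnames = list(gene_ids, samples$sample))

  # exon counts per isoform
  cr <- rbind(ann$truth$cryptic, ann$truth$te_decoys)
  ex_meta <- tx[, c("gene_id", "transcript_id", "exon_rank", "start",
                    "end")]
  ex_meta$length <- ex_meta$end - ex_meta$start
  tot_len <- tapply(ex_meta$length, ex_meta$transcript_id, sum)
  ex_meta$share <- ex_meta$length / tot_len[ex_meta$transcript_id]
  ex_meta$feature_id <- paste(ex_meta$transcript_id, ex_meta$exon_rank,
                              sep = ":")
  base_ex <- base_gene[ex_meta$gene_id] * ex_meta$share
  cr_mult <- rep(1, nrow(ex_meta))
  if (!is.null(cr) && nrow(cr)) {
    first_up <- cr$first_up_exon_index[match(ex_meta$transcript_id,
                                             cr$transcript_id)]
    if (any(!is.na(first_up) &
              first_up > tapply(ex_meta$exon_rank, ex_meta$transcript_id,
                                max)[ex_meta$transcript_id]))
      stop("planted initiation exon beyond transcript length",
           call. = FALSE)
    cr_mult <- ifelse(!is.na(first_up) & ex_meta$exon_rank >= first_up,
                      cfg$cryptic_fc, 1)
  }
  ex_mu <- outer(base_ex, sf)
  ex_mu[, mut] <- ex_mu[, mut] * cr_mult
  # derepressed genes also rise at exon level
  dmask <- ex_meta$gene_id %in% derep$gene_id
  ex_mu[dmask, mut] <- ex_mu[dmask, mut] * cfg$derepressed_fc
  exon_counts <- matrix(rnb(ex_mu), nrow(ex_mu),
                        dimnames = list(ex_meta$feature_id,
                                        samples$sample))

  # TE copy counts
  tes <- ann$tes
  te_counts <- NULL
  if (nrow(tes)) {
    base_te <- stats::rlnorm(nrow(tes), log(15), 0.6)
    te_mult <- matrix(1, nrow(tes), ns,
                      dimnames = list(tes$copy_id, samples$sample))
    te_mult[tes$copy_id %in% ann$truth$reactivated_copy_ids, mut] <-
      cfg$reactivated_fc
    te_mu <- outer(base_te, sf) * te_mult
    te_counts <- matrix(rnb(te_mu), nrow(te_mu),
                        dimnames = list(tes$copy_id, samples$sample))
  }

  alignments <- simulate_te_alignments(cfg, ann, samples)

  list(gene_counts = gene_counts, exon_counts = exon_counts,
       exon_lengths = stats::setNames(ex_meta$length, ex_meta$feature_id),
       gene_lengths = stats::setNames(
         tapply(spans$length, spans$gene_id, max)[gene_ids], gene_ids),
       te_copy_counts = te_counts, alignments = alignments,
       samples = samples,
       truth = c(ann$truth, list(samples = samples)))
}

simulate_te_alignments <- function(cfg, ann, samples) {
  tes <- ann$tes
  fams <- cfg$te_families
  if (nrow(tes) == 0 || cfg$n_te_reads == 0)
    return(data.frame(read_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), n_hits = integer(),
                      sample = character()))
  react_fams <- unique(tes$family[tes$copy_id %in%
                                    ann$truth$reactivated_copy_ids])
  fam_copy_rows <- split(seq_len(nrow(tes)), tes$family)
  read_len <- 100L
  per_sample <- lapply(seq_len(nrow(samples)), function(si) {
    mutant <- samples$genotype[si] != "WT"
    w <- fams$weight
    if (mutant) w[fams$name %in% react_fams] <-
      w[fams$name %in% react_fams] * 6
    n_reads <- stats::rpois(1, cfg$n_te_reads)
    fam_of_read <- sample(fams$name, n_reads, replace = TRUE,
                          prob = w / sum(w))
    # ~15% of reads fall outside TEs, in the reserved TE-free zones
    outside <- stats::runif(n_reads) < 0.15
    nh <- ifelse(fams$multimapper[match(fam_of_read, fams$name)],
                 sample(2:4, n_reads, replace = TRUE), 1L)
    nh[outside] <- 1L
    row_read <- rep(seq_len(n_reads), nh)
    n_rows <- length(row_read)
    is_out <- outside[row_read]
    copy_row <- integer(n_rows)
    fam_row <- fam_of_read[row_read]
    for (f in unique(fam_row[!is_out])) {
      sel <- which(fam_row == f & !is_out)
      copy_row[sel] <- sample(fam_copy_rows[[f]], length(sel),
                              replace = TRUE)
    }
    chrom <- character(n_rows); start <- integer(n_rows)
    end <- integer(n_rows); strand <- character(n_rows)
    if (any(is_out)) {
      zone <- ann$outside_regions[
        sample(nrow(ann$outside_regions), sum(is_out), replace = TRUE), ,
        drop = FALSE]
      p0 <- zone$start + floor(stats::runif(nrow(zone)) *
                                 (zone$end - zone$start - read_len))
      chrom[is_out] <- zone$chrom
      start[is_out] <- p0; end[is_out] <- p0 + read_len
      strand[is_out] <- sample(c("+", "-"), sum(is_out), replace = TRUE)
    }
    if (any(!is_out)) {
      cp <- tes[copy_row[!is_out], ]
      off <- floor(stats::runif(nrow(cp)) * pmax(cp$length - read_len, 1))
      chrom[!is_out] <- cp$chrom
      start[!is_out] <- cp$start + off
      end[!is_out] <- pmin(cp$start + off + read_len, cp$end)
      anti_p <- if (mutant) 0.25 else 0.08  # antisense leakage
      flip <- stats::runif(nrow(cp)) < anti_p
      strand[!is_out] <- ifelse(flip,
                                ifelse(cp$strand == "+", "-", "+"),
                                cp$strand)
    }
    data.frame(read_id = paste0(samples$sample[si], "_r", row_read),
               chrom = chrom, start = start, end = end, strand = strand,
               n_hits = nh[row_read], sample = samples$sample[si],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_sample)
  rownames(out) <- NULL
  out
}

#' Strand-resolved read coverage from an alignment table
#'
#' Each alignment contributes 1/n_hits coverage over its interval on its
#' strand, per sample or summed over samples.
#'
#' @param alignments Alignment table.
#' @param strand "+" or "-".
#' @param chrom_lengths Named chromosome lengths.
#' @return bedGraph-style data.frame chrom, start, end, score.
#' @export
alignment_coverage <- function(alignments, strand, chrom_lengths) {
  a <- alignments[alignments$strand == strand, , drop = FALSE]
  out <- list()
  for (ch in names(chrom_lengths)) {
    s <- a[a$chrom == ch, , drop = FALSE]
    if (!nrow(s)) next
    cov <- IRanges::coverage(IRanges::IRanges(s$start + 1L, s$end),
                             weight = 1 / s$n_hits,
                             width = chrom_lengths[[ch]])
    rl <- S4Vectors::runLength(cov); rv <- S4Vectors::runValue(cov)
    ends <- cumsum(rl)
    keep <- rv != 0
    if (!any(keep)) next
    out[[ch]] <- data.frame(chrom = ch, start = (ends - rl)[keep],
                            end = ends[keep], score = rv[keep],
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full simulation and optionally write all files
#'
#' @param config A [sim_config()].
#' @param dir When non-NULL, writes genome FASTA, transcripts GTF, CGI
#'   and gDMR BEDs, TE TSV, per-genotype methylation call tables, count
#'   matrices, the alignment table and a ground-truth JSON sidecar.
#' @return List with `annotation`, `methylome`, `counts` and, when
#'   written, `files`.
#' @export
simulate_all <- function(config, dir = NULL) {
  ann <- simulate_annotation(config)
  meth <- simulate_methylome(config, ann)
  cnt <- simulate_counts(config, ann)
  out <- list(annotation = ann, methylome = meth, counts = cnt)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    files$genome <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(ann$genome, files$genome)
    files$gtf <- file.path(dir, "transcripts.gtf")
    write_gtf(ann$transcripts, files$gtf)
    files$cgis <- file.path(dir, "cgis.bed")
    write_bed(ann$cgis[, c("chrom", "start", "end", "name")], files$cgis)
    files$gdmrs <- file.path(dir, "gdmrs.bed")
    write_bed(ann$gdmrs, files$gdmrs)
    files$tes <- file.path(dir, "repeats.tsv")
    write_repeatmasker(ann$tes, files$tes)
    for (g in names(meth$calls))
      for (r in seq_along(meth$calls[[g]])) {
        f <- file.path(dir, sprintf("meth_%s_rep%d.cov", g, r))
        write_methylation_calls(meth$calls[[g]][[r]], f)
        files[[sprintf("meth_%s_%d", g, r)]] <- f
      }
    files$gene_counts <- file.path(dir, "gene_counts.tsv")
    write_count_matrix(cnt$gene_counts, files$gene_counts)
    files$exon_counts <- file.path(dir, "exon_counts.tsv")
    write_count_matrix(cnt$exon_counts, files$exon_counts)
    if (!is.null(cnt$te_copy_counts)) {
      files$te_copy_counts <- file.path(dir, "te_copy_counts.tsv")
      write_count_matrix(cnt$te_copy_counts, files$te_copy_counts)
    }
    files$alignments <- file.path(dir, "te_alignments.tsv")
    write_alignment_table(cnt$alignments, files$alignments)
    files$samples <- file.path(dir, "samples.tsv")
    utils::write.table(cnt$samples, files$samples, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files$truth <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(ann$truth, files$truth, dataframe = "columns",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$files <- files
  }
  out
}

#' Write transcript models as GTF
#' @param tx `transcript_models` table.
#' @param path Output path.
#' @export
write_gtf <- function(tx, path) {
  lines <- sprintf(
    '%s\tmethtx\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    tx$chrom, tx$start + 1L, tx$end, tx$strand, tx$gene_id,
    tx$transcript_id)
  writeLines(lines, path)
  invisible(path)
}
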