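#' @keywords internal
"_PACKAGE"

# All internal tables use 0-based half-open coordinates (BED convention):
# `start` is the first base, `end` one past the last. GTF (1-based closed)
# and methylation-caller dialects are converted on read. A CpG is keyed by
# the 0-based position of its C on the plus strand.

#' Convert an internal interval table to a GRanges
#'
#' Internal intervals are 0-based half-open; GRanges are 1-based closed.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `strand`.
#' @return A [GenomicRanges::GRanges] object.
#' @keywords internal
as_gr <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    s <- as.character(x$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

validate_intervals <- function(x, what = "interval table") {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x)))
    stop(what, " must have columns chrom, start, end", call. = FALSE)
  if (nrow(x) > 0) {
    if (any(is.na(x$start)) || any(is.na(x$end)))
      stop(what, ": NA coordinates", call. = FALSE)
    if (any(x$start < 0))
      stop(what, ": negative start coordinate", call. = FALSE)
    if (any(x$start >= x$end))
      stop(what, ": start must be < end (0-based half-open)", call. = FALSE)
    if (any(!nzchar(as.character(x$chrom))))
      stop(what, ": empty chromosome name", call. = FALSE)
  }
  invisible(x)
}

strip_chr <- function(chrom, strip_chr_prefix) {
  if (strip_chr_prefix) sub("^chr", "", chrom) else chrom
}

#' Read per-CpG methylation calls
#'
#' Parses a per-cytosine methylation call table in either the BSMAP
#' `methratio` dialect (columns chrom, pos, strand, context, ratio, eff_CT,
#' C_count, CT_count; 1-based cytosine positions) or the Bismark coverage
#' dialect (chrom, start, end, percent methylation, methylated count,
#' unmethylated count; 1-based positions). Cytosines reported separately on
#' the two strands are merged into one CpG keyed by the plus-strand C
#' (0-based) by summing depths and methylated counts; the depth filter is
#' applied after merging.
#'
#' @param path Path to the call table (TSV; a header line is detected for
#'   the methratio dialect).
#' @param dialect `"methratio"` or `"bismark_cov"`.
#' @param min_depth Minimum read depth per (merged) CpG; CpGs below it are
#'   dropped. Use 8 for MspI-based reduced-representation data and 5 per
#'   replicate for whole-genome bisulfite data.
#' @param merge_strands Merge opposite-strand calls at one CpG (default
#'   TRUE). With FALSE every input row is kept as its own record.
#' @param strip_chr_prefix Remove a leading "chr" from chromosome names.
#'   No silent normalisation is ever attempted.
#' @return data.frame with columns `chrom`, `start` (0-based plus-strand C
#'   position), `end` (= start + 1), `depth`, `n_meth`, `pct_meth`
#'   (in \[0,100\]), sorted by (chrom, start).
#' @export
read_methylation_calls <- function(path,
                                   dialect = c("methratio", "bismark_cov"),
                                   min_depth = 1L,
                                   merge_strands = TRUE,
                                   strip_chr_prefix = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  skip <- 0L
  if (length(lines) > 0 && grepl("^(chr\\t|chrom)", lines[1], ignore.case = TRUE))
    skip <- 1L
  body <- lines[seq_len(length(lines) - skip) + skip]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      depth = integer(), n_meth = integer(),
                      pct_meth = numeric())
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (dialect == "methratio") 8L else 6L
  bad <- which(nf < need)
  if (length(bad))
    stop("malformed row at line ", bad[1] + skip, " of ", path,
         " (expected >= ", need, " tab-separated fields)", call. = FALSE)
  m <- do.call(rbind, fields)

  if (dialect == "methratio") {
    pos <- suppressWarnings(as.integer(m[, 2]))
    strand <- m[, 3]
    n_meth <- suppressWarnings(as.numeric(m[, 7]))
    depth <- suppressWarnings(as.numeric(m[, 8]))
    bad <- which(is.na(pos) | is.na(n_meth) | is.na(depth) |
                   !strand %in% c("+", "-"))
    if (length(bad))
      stop("malformed row at line ", bad[1] + skip, " of ", path,
           call. = FALSE)
    # plus-strand C at 1-based p -> CpG start p-1; minus-strand C sits on
    # the G of the plus-strand CpG, so its CpG start is p-2
    start <- ifelse(strand == "+", pos - 1L, pos - 2L)
  } else {
    pos <- suppressWarnings(as.integer(m[, 2]))
    n_meth <- suppressWarnings(as.numeric(m[, 5]))
    n_unmeth <- suppressWarnings(as.numeric(m[, 6]))
    bad <- which(is.na(pos) | is.na(n_meth) | is.na(n_unmeth))
    if (length(bad))
      stop("malformed row at line ", bad[1] + skip, " of ", path,
           call. = FALSE)
    depth <- n_meth + n_unmeth
    start <- pos - 1L
  }
  bad <- which(n_meth > depth)
  if (length(bad))
    stop("methylated count exceeds depth at line ", bad[1] + skip, " of ",
         path, call. = FALSE)
  chrom <- strip_chr(m[, 1], strip_chr_prefix)

  df <- data.frame(chrom = chrom, start = start,
                   depth = as.numeric(depth), n_meth = as.numeric(n_meth),
                   stringsAsFactors = FALSE)
  if (merge_strands) {
    key <- paste(df$chrom, df$start, sep = "\r")
    agg_depth <- rowsum(df$depth, key, reorder = FALSE)
    agg_meth <- rowsum(df$n_meth, key, reorder = FALSE)
    first <- !duplicated(key)
    df <- data.frame(chrom = df$chrom[first], start = df$start[first],
                     depth = as.numeric(agg_depth[, 1]),
                     n_meth = as.numeric(agg_meth[, 1]),
                     stringsAsFactors = FALSE)
  }
  df <- df[df$depth >= min_depth, , drop = FALSE]
  df$end <- df$start + 1L
  df$pct_meth <- ifelse(df$depth > 0, 100 * df$n_meth / df$depth, NA_real_)
  df <- df[order(df$chrom, df$start), c("chrom", "start", "end", "depth",
                                        "n_meth", "pct_meth")]
  rownames(df) <- NULL
  validate_intervals(df, "CpG call table")
  df
}

#' Write per-CpG methylation calls in the Bismark coverage dialect
#'
#' Inverse of [read_methylation_calls()] with `dialect = "bismark_cov"`:
#' positions are written 1-based so a read/write round trip is the
#' identity.
#'
#' @param calls CpG call table as returned by [read_methylation_calls()].
#' @param path Output path (TSV, no header).
#' @export
write_methylation_calls <- function(calls, path) {
  out <- data.frame(chrom = calls$chrom,
                    start = calls$start + 1L,
                    end = calls$start + 1L,
                    pct = ifelse(calls$depth > 0,
                                 100 * calls$n_meth / calls$depth, 0),
                    n_meth = calls$n_meth,
                    n_unmeth = calls$depth - calls$n_meth)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Exon features are grouped per transcript and ordered in transcription
#' orientation (exon 1 is the 5'-most exon of the transcript, i.e. the
#' ascending-coordinate first exon on the plus strand and the
#' descending-coordinate first on the minus strand). 1-based closed GTF
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path Path to a GTF2.2 file with exon features carrying `gene_id`
#'   and `transcript_id` attributes.
#' @param strip_chr_prefix Remove a leading "chr" from chromosome names.
#' @return A `transcript_models` data.frame with columns `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `start`, `end`, `exon_rank`
#'   (1-based in transcription order).
#' @export
read_gtf <- function(path, strip_chr_prefix = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0)
    stop("no exon features in ", path, call. = FALSE)
  tid <- gr$transcript_id
  if (is.null(tid) || anyNA(tid) || any(!nzchar(tid)))
    stop("exon feature without transcript_id in ", path, call. = FALSE)
  gid <- gr$gene_id
  if (is.null(gid)) gid <- tid
  df <- data.frame(gene_id = gid, transcript_id = tid,
                   chrom = strip_chr(as.character(GenomicRanges::seqnames(gr)),
                                     strip_chr_prefix),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  transcript_models(df)
}

#' Construct a transcript_models table
#'
#' Validates per-transcript invariants (single strand, non-overlapping
#' exons) and assigns `exon_rank` in transcription order.
#'
#' @param df data.frame with columns gene_id, transcript_id, chrom, strand,
#'   start, end (0-based half-open).
#' @return The validated, ordered data.frame with class
#'   `transcript_models`.
#' @export
transcript_models <- function(df) {
  validate_intervals(df, "transcript model")
  mixed <- tapply(df$strand, df$transcript_id,
                  function(s) length(unique(s)) > 1)
  if (any(mixed))
    stop("mixed strands within transcript: ",
         paste(names(mixed)[mixed], collapse = ", "), call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("transcript strand must be '+' or '-'", call. = FALSE)
  ord <- order(df$transcript_id, ifelse(df$strand == "+", 1, -1) * df$start)
  df <- df[ord, , drop = FALSE]
  df$exon_rank <- stats::ave(seq_len(nrow(df)), df$transcript_id,
                             FUN = seq_along)
  # non-overlap check within transcript (exons are coordinate-sorted per
  # strand direction, so compare neighbours)
  by_tx <- split(seq_len(nrow(df)), df$transcript_id)
  for (idx in by_tx) {
    s <- sort(df$start[idx]); e <- df$end[idx][order(df$start[idx])]
    if (length(idx) > 1 && any(s[-1] < e[-length(e)]))
      stop("overlapping exons in transcript ",
           df$transcript_id[idx[1]], call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("transcript_models", "data.frame")
  df
}

#' Transcript spans and TSS
#'
#' @param tx A `transcript_models` table.
#' @return data.frame with one row per transcript: gene_id, transcript_id,
#'   chrom, strand, start, end (span), `tss` (0-based position of the
#'   transcription start site base) and `length` (summed exon length).
#' @export
transcript_spans <- function(tx) {
  sp <- do.call(rbind, lapply(split(tx, tx$transcript_id), function(d) {
    data.frame(gene_id = d$gene_id[1], transcript_id = d$transcript_id[1],
               chrom = d$chrom[1], strand = d$strand[1],
               start = min(d$start), end = max(d$end),
               length = sum(d$end - d$start),
               stringsAsFactors = FALSE)
  }))
  sp$tss <- ifelse(sp$strand == "+", sp$start, sp$end - 1L)
  rownames(sp) <- NULL
  sp
}

RMSK_CLASSES <- c("SINE", "LINE", "ERV1", "ERVK", "ERVL", "other")

te_class_from_string <- function(cls) {
  out <- rep("other", length(cls))
  for (k in c("SINE", "LINE", "ERV1", "ERVK", "ERVL"))
    out[grepl(k, cls, fixed = TRUE)] <- k
  unknown <- !grepl("SINE|LINE|ERV1|ERVK|ERVL|Simple_repeat|Low_complexity|DNA|LTR|[Oo]ther",
                    cls)
  if (any(unknown))
    warning("unrecognised repeat class mapped to 'other': ",
            paste(unique(cls[unknown]), collapse = ", "), call. = FALSE)
  out
}

#' Read a RepeatMasker-style TE annotation
#'
#' Expects a TSV with columns chrom, start, end, strand, repeat family
#' name, repeat class (e.g. "LTR/ERVK"). Coordinates are 0-based half-open
#' (UCSC rmsk table convention). Every row becomes one TE copy with a
#' stable `copy_id` of the form chrom:start-end:family. Class strings are
#' mapped to \{SINE, LINE, ERV1, ERVK, ERVL, other\}; the size filter some
#' analyses apply (elements > 400 bp) is left to consumers.
#'
#' @param path Path to the annotation TSV (header optional).
#' @param strip_chr_prefix Remove a leading "chr" from chromosome names.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `family`, `te_class`, `copy_id`, `length`.
#' @export
read_repeatmasker <- function(path, strip_chr_prefix = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (is.character(df[1, 2]) && is.na(suppressWarnings(as.integer(df[1, 2])))) {
    df <- df[-1, , drop = FALSE]  # header line
  }
  if (ncol(df) < 6)
    stop("RepeatMasker table needs >= 6 columns", call. = FALSE)
  out <- data.frame(chrom = strip_chr(as.character(df[[1]]), strip_chr_prefix),
                    start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                    strand = as.character(df[[4]]),
                    family = as.character(df[[5]]),
                    te_class = te_class_from_string(as.character(df[[6]])),
                    stringsAsFactors = FALSE)
  validate_intervals(out, "TE annotation")
  out$copy_id <- paste0(out$chrom, ":", out$start, "-", out$end, ":",
                        out$family)
  out$length <- out$end - out$start
  rownames(out) <- NULL
  out
}

#' Write a TE annotation table
#' @param tes TE annotation as returned by [read_repeatmasker()].
#' @param path Output TSV path.
#' @export
write_repeatmasker <- function(tes, path) {
  cls <- tes$te_class
  cls[cls %in% c("ERV1", "ERVK", "ERVL")] <-
    paste0("LTR/", cls[cls %in% c("ERV1", "ERVK", "ERVL")])
  cls[cls == "SINE"] <- "SINE/Alu"
  cls[cls == "LINE"] <- "LINE/L1"
  out <- data.frame(tes$chrom, tes$start, tes$end, tes$strand, tes$family,
                    cls)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path Path to a 3- or 6-column BED file.
#' @param strip_chr_prefix Remove a leading "chr" from chromosome names.
#' @return data.frame with columns chrom, start, end and, when present,
#'   name, score, strand; coordinates stay 0-based half-open.
#' @export
read_bed <- function(path, strip_chr_prefix = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  info <- file.info(path)
  if (info$size == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  gr <- rtracklayer::import(path, format = "bed")
  df <- data.frame(chrom = strip_chr(as.character(GenomicRanges::seqnames(gr)),
                                     strip_chr_prefix),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- gr$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- st
  validate_intervals(df, "BED")
  df
}

#' Write intervals as BED
#' @param x Interval data.frame (internal 0-based half-open coordinates).
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- list(x$chrom, x$start, x$end)
  if (!is.null(x$name) || !is.null(x$score) || !is.null(x$strand)) {
    cols <- c(cols, list(
      if (is.null(x$name)) "." else x$name,
      if (is.null(x$score)) 0 else x$score,
      if (is.null(x$strand)) "." else x$strand))
  }
  utils::write.table(do.call(data.frame, cols), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a bedGraph track
#'
#' @param x data.frame with chrom, start, end and a value column.
#' @param path Output path.
#' @param value Name of the value column (default "score").
#' @export
write_bedgraph <- function(x, path, value = "score") {
  validate_intervals(x)
  out <- data.frame(x$chrom, x$start, x$end, x[[value]])
  out <- out[!is.na(out[[4]]), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#' @param path Path to a 4-column bedGraph file.
#' @return data.frame chrom, start, end, score (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "score"))
  validate_intervals(df, "bedGraph")
  df
}

#' Read a feature-by-sample count matrix from TSV
#'
#' @param path TSV with a header of sample names and feature ids in the
#'   first column.
#' @return Numeric matrix with feature rownames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          row.names = 1)
  as.matrix(df)
}

#' Write a count matrix as TSV
#' @param m Matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a simplified alignment table for TE counting
#'
#' One row per genomic alignment: `read_id`, `chrom`, `start`, `end`
#' (0-based half-open), `strand`, `n_hits` (total number of genomic
#' alignments of the read) and optionally `sample`. All rows of one read
#' must agree on `n_hits`, which must equal the read's row multiplicity
#' per sample.
#'
#' @param path TSV path with header.
#' @return Validated data.frame.
#' @export
read_alignment_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_alignments(df)
}

validate_alignments <- function(df) {
  req <- c("read_id", "chrom", "start", "end", "strand", "n_hits")
  if (!all(req %in% names(df)))
    stop("alignment table must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  validate_intervals(df, "alignment table")
  if (nrow(df)) {
    key <- if ("sample" %in% names(df))
      paste(df$sample, df$read_id) else df$read_id
    nh <- tapply(df$n_hits, key, function(v) length(unique(v)))
    if (any(nh > 1))
      stop("inconsistent n_hits for read(s): ",
           paste(utils::head(names(nh)[nh > 1], 3), collapse = ", "),
           call. = FALSE)
  }
  df
}

#' Write an alignment table
#' @param df Alignment table (see [read_alignment_table()]).
#' @param path Output path.
#' @export
write_alignment_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
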