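#' Construct a validated count matrix
#'
#' The raw quantitative substrate for both assays: a transcript-by-sample
#' matrix of non-negative integer tag or read counts plus a sample sheet
#' describing each column. For a CLIP sample the column sum is that
#' replicate's uniquely-mapped-tag (UMT) count.
#'
#' @param counts Integer matrix, rows named by transcript id, columns by
#'   sample label.
#' @param samples Data frame with columns `sample`, `assay` (one of `CLIP`,
#'   `RiboTag-IP`, `RiboTag-Input`), `condition` (`Control` or `Opto`) and
#'   `replicate` (integer), one row per count column.
#' @return A list of class `"count_matrix"` with elements `counts` and
#'   `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no transcripts")
  if (is.null(rownames(counts))) stop("counts must have transcript rownames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated transcript_id rows: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double"  # large CLIP libraries overflow int sums
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample", "assay", "condition", "replicate")
  if (!all(need %in% names(samples)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  if (!setequal(samples$sample, colnames(counts)) ||
      anyDuplicated(samples$sample))
    stop("sample sheet does not match count columns one-to-one")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  ok_assay <- c("CLIP", "RiboTag-IP", "RiboTag-Input")
  if (!all(samples$assay %in% ok_assay))
    stop("assay must be one of: ", paste(ok_assay, collapse = ", "))
  if (!all(samples$condition %in% c("Control", "Opto")))
    stop("condition must be Control or Opto")
  structure(list(counts = counts, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " transcripts x ",
      ncol(x$counts), " samples\n", sep = "")
  print(x$samples)
  invisible(x)
}

#' Subset a count matrix by samples
#'
#' @param x A `"count_matrix"`.
#' @param assay,condition Optional filters on the sample sheet.
#' @return A `"count_matrix"` restricted to the matching samples.
#' @export
subset_samples <- function(x, assay = NULL, condition = NULL) {
  keep <- rep(TRUE, nrow(x$samples))
  if (!is.null(assay)) keep <- keep & x$samples$assay %in% assay
  if (!is.null(condition)) keep <- keep & x$samples$condition %in% condition
  if (!any(keep)) stop("no samples match the requested assay/condition")
  count_matrix(x$counts[, x$samples$sample[keep], drop = FALSE],
               x$samples[keep, , drop = FALSE])
}

#' Read a transcript-by-sample count table
#'
#' @param path TSV with a header row; first column holds transcript ids.
#' @param sample_sheet Data frame mapping every data column to
#'   (assay, condition, replicate); see [count_matrix()].
#' @return A `"count_matrix"`.
#' @export
read_count_table <- function(path, sample_sheet) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no transcripts")
  ids <- as.character(df[[1]])
  dat <- df[, -1, drop = FALSE]
  missing <- setdiff(names(dat), sample_sheet$sample)
  if (length(missing))
    stop("columns absent from sample sheet: ", paste(missing, collapse = ", "))
  m <- as.matrix(dat)
  if (!is.numeric(m)) stop("non-numeric count value in ", path)
  rownames(m) <- ids
  count_matrix(m, sample_sheet[sample_sheet$sample %in% colnames(m), ,
                               drop = FALSE])
}

#' Construct a TPM quantification table
#'
#' @param tpm Numeric matrix (transcripts x samples).
#' @param lengths Named vector of transcript lengths (nt).
#' @param scale `"linear"` (columns sum to 1e6) or `"log2"`.
#' @param pseudocount Pseudocount used if `scale == "log2"`.
#' @return A list of class `"quant_table"`.
#' @export
quant_table <- function(tpm, lengths, scale = c("linear", "log2"),
                        pseudocount = 0) {
  scale <- match.arg(scale)
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm))) stop("tpm must have transcript rownames")
  lengths <- lengths[rownames(tpm)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("every transcript needs a positive length")
  if (scale == "linear") {
    if (any(tpm < 0)) stop("linear-scale TPM must be non-negative")
    cs <- colSums(tpm)
    bad <- cs > 0 & abs(cs - 1e6) > 1e-9 * 1e6
    if (any(bad))
      stop("linear TPM columns must sum to 1e6: ",
           paste(colnames(tpm)[bad], collapse = ", "))
  }
  structure(list(tpm = tpm, lengths = lengths, scale = scale,
                 pseudocount = pseudocount),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat("quant_table (", x$scale, "): ", nrow(x$tpm), " transcripts x ",
      ncol(x$tpm), " samples\n", sep = "")
  invisible(x)
}

# Row-subset a quant table without re-validating the column-sum invariant
# (a subset of a valid TPM table no longer sums to 1e6 by construction).
quant_subset <- function(x, ids) {
  stopifnot(inherits(x, "quant_table"))
  missing <- setdiff(ids, rownames(x$tpm))
  if (length(missing))
    stop("transcripts absent from quant table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  structure(list(tpm = x$tpm[ids, , drop = FALSE],
                 lengths = x$lengths[ids], scale = x$scale,
                 pseudocount = x$pseudocount),
            class = "quant_table")
}

#' Log2-transform a linear quant table
#'
#' @param x A linear-scale `"quant_table"`.
#' @param pseudocount TPM pseudocount added before log2.
#' @return A log2-scale `"quant_table"`.
#' @export
log2_quant <- function(x, pseudocount = 0.01) {
  stopifnot(inherits(x, "quant_table"))
  if (x$scale != "linear") stop("input must be on the linear scale")
  quant_table(log2(x$tpm + pseudocount), x$lengths, scale = "log2",
              pseudocount = pseudocount)
}

#' Read per-sample quantification files
#'
#' Ingests either salmon-style per-sample tables (columns `Name`, `Length`,
#' `TPM`, in any capitalisation, one file per sample) or a single shared
#' matrix whose first two columns are transcript id and length.
#'
#' @param paths Character vector of file paths (one per sample for
#'   `salmon_like`; a single path for `matrix`).
#' @param dialect `"salmon_like"` or `"matrix"`.
#' @param sample_names Column labels; defaults to file base names for
#'   `salmon_like` and to the file's own header for `matrix`.
#' @return A linear-scale `"quant_table"`.
#' @export
read_quant_files <- function(paths, dialect = c("salmon_like", "matrix"),
                             sample_names = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix") {
    df <- utils::read.delim(paths[1], header = TRUE, sep = "\t",
                            check.names = FALSE, comment.char = "#")
    ids <- as.character(df[[1]])
    lens <- as.numeric(df[[2]])
    m <- as.matrix(df[, -(1:2), drop = FALSE])
    rownames(m) <- ids
    return(quant_table(m, stats::setNames(lens, ids), scale = "linear"))
  }
  if (is.null(sample_names))
    sample_names <- sub("\\.[^.]*$", "", basename(paths))
  tabs <- lapply(paths, function(p) {
    df <- utils::read.delim(p, header = TRUE, sep = "\t",
                            check.names = FALSE, comment.char = "#")
    names(df) <- tolower(names(df))
    need <- c("name", "length", "tpm")
    if (!all(need %in% names(df)))
      stop("quant file ", p, " lacks columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    df[, need]
  })
  ids <- tabs[[1]]$name
  lens <- stats::setNames(as.numeric(tabs[[1]]$length), ids)
  m <- matrix(NA_real_, length(ids), length(tabs),
              dimnames = list(ids, sample_names))
  for (i in seq_along(tabs)) {
    t2 <- tabs[[i]]
    if (!setequal(t2$name, ids))
      stop("quant files cover different transcript sets")
    idx <- match(ids, t2$name)
    if (any(abs(t2$length[idx] - lens) > 0.5))
      stop("conflicting lengths for transcript(s): ",
           paste(utils::head(ids[abs(t2$length[idx] - lens) > 0.5], 5),
                 collapse = ", "))
    m[, i] <- t2$tpm[idx]
  }
  quant_table(m, lens, scale = "linear")
}

#' Read stranded CLIP tags from a BED6 file
#'
#' Coordinates are BED convention (0-based half-open) and are preserved
#' bit-exactly in the returned `GRanges` (which is 1-based inclusive:
#' `start = BED start + 1`, `end = BED end`).
#'
#' @param path BED6 file.
#' @param replicate Replicate label attached to every tag.
#' @param allow_strandless Accept records with strand `"."`; rejected by
#'   default because CLIP tags are stranded.
#' @return A `GRanges` with metadata columns `name`, `score`, `replicate`.
#' @export
read_tags_bed <- function(path, replicate = NA, allow_strandless = FALSE) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("BED6 required (6 columns), got ", ncol(df))
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (any(df$start >= df$end))
    stop("malformed BED record: start >= end at line(s) ",
         paste(utils::head(which(df$start >= df$end), 5), collapse = ", "))
  if (!allow_strandless && any(df$strand == "."))
    stop("strandless BED records present; set allow_strandless = TRUE to keep")
  if (!all(df$strand %in% c("+", "-", ".")))
    stop("invalid strand value(s)")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = sub("^\\.$", "*", df$strand),
    name = df$name, score = df$score, replicate = replicate)
  gr
}

#' Write a pipeline result table
#'
#' Writes a TSV with a stable column order and a comment header recording
#' the configuration hash and seed, so identical runs produce byte-identical
#' files apart from the timestamp line.
#'
#' @param x Data frame (or object with an `as.data.frame` method).
#' @param path Output file.
#' @param config Optional `"clipribo_config"`; its hash and seed are recorded.
#' @param timestamp Include a timestamp comment line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, config = NULL, timestamp = TRUE) {
  df <- as.data.frame(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# clipribo v", as.character(utils::packageVersion("clipribo"))), con)
  if (!is.null(config))
    writeLines(sprintf("# config=%s seed=%d", config_hash(config),
                       config$rng_seed), con)
  if (timestamp)
    writeLines(paste0("# written=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Parses gene models (GTF 2.2, 1-based inclusive coordinates) into the
#' internal representation used for tag annotation: a feature-level
#' `GRanges` and a per-transcript summary with exonic length.
#'
#' @param path GTF file with `exon` features and, for coding transcripts,
#'   `CDS` (UTRs are taken from `five_prime_utr`/`three_prime_utr` features
#'   when present, otherwise derived from exons minus CDS).
#' @return A list of class `"transcript_models"` with elements `features`
#'   (`GRanges`, metadata `type`, `gene_id`, `transcript_id`) and
#'   `transcripts` (data frame `transcript_id`, `gene_id`, `length`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- S4Vectors::mcols(gr)$type %in%
    c("exon", "CDS", "five_prime_utr", "three_prime_utr", "5UTR", "3UTR")
  gr <- gr[keep]
  ty <- as.character(S4Vectors::mcols(gr)$type)
  ty[ty == "5UTR"] <- "five_prime_utr"
  ty[ty == "3UTR"] <- "three_prime_utr"
  feats <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr),
    type = ty,
    gene_id = as.character(S4Vectors::mcols(gr)$gene_id),
    transcript_id = as.character(S4Vectors::mcols(gr)$transcript_id))
  transcript_models(feats)
}

#' Assemble transcript models from a feature-level GRanges
#'
#' @param features `GRanges` with metadata columns `type` (exon, CDS,
#'   five_prime_utr, three_prime_utr), `gene_id`, `transcript_id`.
#' @return A `"transcript_models"` object; transcript length is the sum of
#'   exon widths. Every transcript must carry at least one exon and map to
#'   exactly one gene.
#' @export
transcript_models <- function(features) {
  stopifnot(methods::is(features, "GRanges"))
  ex <- features[S4Vectors::mcols(features)$type == "exon"]
  if (length(ex) == 0L) stop("no exon features")
  tid <- S4Vectors::mcols(ex)$transcript_id
  lens <- tapply(GenomicRanges::width(ex), tid, sum)
  gid <- tapply(S4Vectors::mcols(ex)$gene_id, tid, function(g) {
    u <- unique(g)
    if (length(u) != 1L) stop("transcript maps to multiple genes")
    u
  })
  tx <- data.frame(transcript_id = names(lens),
                   gene_id = as.character(gid[names(lens)]),
                   length = as.integer(lens),
                   stringsAsFactors = FALSE)
  rownames(tx) <- NULL
  structure(list(features = features, transcripts = tx),
            class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models: ", nrow(x$transcripts), " transcripts, ",
      length(unique(x$transcripts$gene_id)), " genes, ",
      length(x$features), " features\n", sep = "")
  invisible(x)
}

#' Transcript lengths from a model set
#'
#' @param models A `"transcript_models"` object.
#' @return Named integer vector of exonic lengths.
#' @export
transcript_lengths <- function(models) {
  stats::setNames(models$transcripts$length, models$transcripts$transcript_id)
}
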