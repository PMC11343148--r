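#' Transcripts per million from counts and lengths
#'
#' `TPM_i = (c_i / L_i) / sum_j (c_j / L_j) * 1e6` per sample, so every
#' non-degenerate column sums to exactly one million. An all-zero sample
#' yields an all-zero column with a warning rather than a division error.
#'
#' @param counts A `"count_matrix"`.
#' @param lengths Named vector of transcript lengths covering every counted
#'   transcript (see [transcript_lengths()]).
#' @return A linear-scale `"quant_table"`.
#' @export
compute_tpm <- function(counts, lengths) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  lens <- lengths[rownames(m)]
  if (any(is.na(lens)))
    stop("missing length for transcript(s): ",
         paste(utils::head(rownames(m)[is.na(lens)], 5), collapse = ", "))
  rate <- m / as.numeric(lens)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero sample column(s): ",
            paste(colnames(m)[zero], collapse = ", "))
    tot[zero] <- 1  # leaves the column all-zero
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  quant_table(tpm, lens, scale = "linear")
}

#' Select one representative transcript per gene
#'
#' The transcript with the highest mean TPM across all RiboTag replicates of
#' both conditions represents its gene in every downstream analysis. Ties
#' break to the lexicographically smallest transcript id; genes whose best
#' transcript does not exceed the expression floor are dropped.
#'
#' @param ribo_quant Linear-scale `"quant_table"` over all RiboTag samples
#'   (both conditions).
#' @param models A `"transcript_models"` object.
#' @param expression_floor Mean TPM the selected transcript must exceed
#'   (default 0, i.e. any expression).
#' @return Data frame `gene_id`, `transcript_id`, `mean_tpm`, sorted by
#'   `gene_id`; attribute `"dropped_genes"` lists genes with no expressed
#'   transcript.
#' @export
select_representative_transcripts <- function(ribo_quant, models,
                                              expression_floor = 0) {
  stopifnot(inherits(ribo_quant, "quant_table"),
            inherits(models, "transcript_models"))
  if (ribo_quant$scale != "linear") stop("ribo_quant must be linear scale")
  tx <- models$transcripts
  tx <- tx[tx$transcript_id %in% rownames(ribo_quant$tpm), , drop = FALSE]
  mean_tpm <- rowMeans(ribo_quant$tpm)[tx$transcript_id]
  # order by gene, then descending mean TPM, then transcript id: the first
  # row per gene is the representative regardless of input row order
  ord <- order(tx$gene_id, -mean_tpm, tx$transcript_id)
  tx <- tx[ord, , drop = FALSE]
  mean_tpm <- mean_tpm[ord]
  first <- !duplicated(tx$gene_id)
  out <- data.frame(gene_id = tx$gene_id[first],
                    transcript_id = tx$transcript_id[first],
                    mean_tpm = unname(mean_tpm[first]),
                    stringsAsFactors = FALSE)
  dropped <- out$gene_id[out$mean_tpm <= expression_floor]
  if (length(dropped))
    message(length(dropped), " gene(s) dropped below the expression floor")
  out <- out[out$mean_tpm > expression_floor, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_genes") <- dropped
  out
}

#' Restrict CLIP counts to RiboTag-expressed transcripts
#'
#' Only CLIP tags on transcripts in the representative expressed set are
#' retained, mirroring the rule that tags must map to transcripts expressed
#' by RiboTag.
#'
#' @param clip_counts A `"count_matrix"` of CLIP tags.
#' @param selected Character vector of retained transcript ids (typically
#'   `select_representative_transcripts(...)$transcript_id`).
#' @return A `"count_matrix"` restricted to `selected`; the number of tags
#'   removed per sample is reported via `message()`.
#' @export
restrict_clip_to_expressed <- function(clip_counts, selected) {
  stopifnot(inherits(clip_counts, "count_matrix"))
  keep <- intersect(rownames(clip_counts$counts), selected)
  if (length(keep) == 0L)
    stop("no CLIP transcripts intersect the expressed set")
  removed <- colSums(clip_counts$counts) -
    colSums(clip_counts$counts[keep, , drop = FALSE])
  if (any(removed > 0))
    message("removed ", sum(removed), " tag(s) on unexpressed transcripts")
  count_matrix(clip_counts$counts[keep, , drop = FALSE], clip_counts$samples)
}

#' Biological complexity of CLIP signal
#'
#' For each gene (or transcript) counts the number of biological replicates
#' carrying at least `bc_min_tags` CLIP tags. The published filter keeps
#' genes with at least 5 tags in all four replicates of a condition (BC = 4).
#'
#' @param clip_counts A `"count_matrix"` of CLIP samples (one condition, or
#'   pass `condition` to subset).
#' @param bc_min_tags Minimum tag count for a replicate to support an entity
#'   (default 5).
#' @param level `"transcript"` keeps count-table rows as-is; `"gene"` sums
#'   transcript counts within genes first (requires `gene_map`).
#' @param gene_map Named vector transcript_id -> gene_id, required for
#'   `level = "gene"`.
#' @param condition Optional condition filter.
#' @return A list of class `"bc_profile"`: `support` (named integer vector),
#'   `tag_counts` (entity x replicate matrix), `bc_min_tags`.
#' @export
biological_complexity <- function(clip_counts, bc_min_tags = 5,
                                  level = c("transcript", "gene"),
                                  gene_map = NULL, condition = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(clip_counts, "count_matrix"))
  x <- if (is.null(condition)) clip_counts else
    subset_samples(clip_counts, condition = condition)
  m <- x$counts
  if (level == "gene") {
    if (is.null(gene_map)) stop("gene_map required at gene level")
    g <- gene_map[rownames(m)]
    if (any(is.na(g))) stop("gene_map does not cover all transcripts")
    m <- rowsum(m, group = as.character(g))
  }
  support <- rowSums(m >= bc_min_tags)
  structure(list(support = support, tag_counts = m,
                 bc_min_tags = bc_min_tags,
                 n_replicates = ncol(m)),
            class = "bc_profile")
}

#' Entities passing the biological-complexity filter
#'
#' @param bc A `"bc_profile"`.
#' @param bc_required Number of supporting replicates required (default: all
#'   replicates present in the profile).
#' @return Character vector of gene/transcript ids with support >=
#'   `bc_required`.
#' @export
bc_filter <- function(bc, bc_required = bc$n_replicates) {
  stopifnot(inherits(bc, "bc_profile"))
  if (bc_required > bc$n_replicates)
    stop("bc_required exceeds the number of replicates (",
         bc$n_replicates, ")")
  names(bc$support)[bc$support >= bc_required]
}

#' RiboTag enrichment score
#'
#' Per-gene `log2((IP TPM + pseudocount) / (Input TPM + pseudocount))` using
#' mean TPM across replicates, optionally joined with IP-vs-Input
#' differential significance. The score is exactly antisymmetric under
#' swapping IP and Input.
#'
#' @param ip_quant,input_quant Linear-scale `"quant_table"`s for RiboTag IP
#'   and Input samples on a matched transcript set.
#' @param diff Optional `"diff_result"` from [nb_wald_test()] of IP vs
#'   Input; its `p`/`padj` are joined by id.
#' @param pseudocount TPM pseudocount (default 0.01).
#' @return Data frame `id`, `ip_tpm`, `input_tpm`, `enrichment`, and if
#'   `diff` is supplied `p`, `padj`.
#' @export
ribotag_enrichment <- function(ip_quant, input_quant, diff = NULL,
                               pseudocount = 0.01) {
  stopifnot(inherits(ip_quant, "quant_table"),
            inherits(input_quant, "quant_table"))
  common <- intersect(rownames(ip_quant$tpm), rownames(input_quant$tpm))
  lost <- setdiff(union(rownames(ip_quant$tpm), rownames(input_quant$tpm)),
                  common)
  if (length(lost))
    warning(length(lost), " id(s) present in only one table were dropped")
  ip <- rowMeans(ip_quant$tpm[common, , drop = FALSE])
  inp <- rowMeans(input_quant$tpm[common, , drop = FALSE])
  out <- data.frame(id = common,
                    ip_tpm = unname(ip),
                    input_tpm = unname(inp),
                    enrichment = unname(log2((ip + pseudocount) /
                                             (inp + pseudocount))),
                    stringsAsFactors = FALSE)
  if (!is.null(diff)) {
    idx <- match(out$id, diff$table$id)
    out$p <- diff$table$p[idx]
    out$padj <- diff$table$padj[idx]
  }
  out
}

#' Default cell-type marker panel
#'
#' Marker genes used to verify that the RiboTag immunoprecipitation captured
#' CA1 excitatory neurons: excitatory markers are expected enriched
#' (IP > Input), markers of other cell classes depleted.
#'
#' @return Named list with elements `genes` (list of character vectors) and
#'   `direction` (named +1/-1 vector; +1 = expected enriched).
#' @export
default_marker_panel <- function() {
  genes <- list(
    ca1_excitatory = c("Neurod6", "Camk2a", "Rbfox3", "Snap25", "Nrgn",
                       "Hpca", "Crym", "Chn1"),
    inhibitory = c("Gad1", "Gad2", "Slc32a1", "Pvalb", "Sst"),
    opc = c("Pdgfra", "Cspg4", "Olig1"),
    oligodendrocyte = c("Mbp", "Mog", "Plp1", "Mal"),
    astrocyte = c("Aqp4", "Gfap", "Slc1a3", "Aldoc")
  )
  direction <- c(ca1_excitatory = 1, inhibitory = -1, opc = -1,
                 oligodendrocyte = -1, astrocyte = -1)
  list(genes = genes, direction = direction)
}

#' Check marker-panel concordance of RiboTag enrichment
#'
#' For every marker set, reports the mean enrichment, the fraction of
#' present genes whose enrichment sign agrees with the expected direction
#' (strict inequality against zero), and a pass flag at the requested
#' concordance fraction. Sets with no present genes are flagged
#' not-evaluable.
#'
#' @param enr Enrichment table from [ribotag_enrichment()].
#' @param panel Marker panel as from [default_marker_panel()].
#' @param min_concordance Fraction of genes that must agree (default 0.8).
#' @return Data frame with one row per marker set: `set`, `n_expected`,
#'   `n_present`, `mean_enrichment`, `concordance`, `pass`, `evaluable`.
#' @export
marker_panel_check <- function(enr, panel = default_marker_panel(),
                               min_concordance = 0.8) {
  sets <- names(panel$genes)
  rows <- lapply(sets, function(s) {
    g <- panel$genes[[s]]
    present <- intersect(g, enr$id)
    e <- enr$enrichment[match(present, enr$id)]
    dir <- panel$direction[[s]]
    evaluable <- length(present) > 0
    conc <- if (evaluable) mean(sign(e) == dir & e != 0) else NA_real_
    data.frame(set = s, n_expected = length(g), n_present = length(present),
               mean_enrichment = if (evaluable) mean(e) else NA_real_,
               concordance = conc,
               pass = evaluable && conc >= min_concordance,
               evaluable = evaluable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
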