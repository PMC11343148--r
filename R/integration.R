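#' Quadrant classification of FMRP binding vs ribosome association
#'
#' Overlays differential FMRP binding (CLIP-score moderated t, direction at
#' raw p < `clip_diff_alpha`) with differential ribosome association
#' (NB Wald, direction at BH-adjusted p < `ribo_diff_alpha`, optional
#' |log2FC| floor). Transcripts less bound by FMRP after activation
#' (FMRP-Down) split by whether their ribosome-associated abundance went up
#' (candidate ribosome re-association), down (candidate ribosome runoff) or
#' stayed unchanged.
#'
#' @param clip_diff `"diff_result"` from [moderated_t()] (Opto vs Control
#'   CLIP scores).
#' @param ribo_diff `"diff_result"` from [nb_wald_test()] (Opto vs Control
#'   RiboTag counts).
#' @param config A `"clipribo_config"` supplying the two alpha levels and
#'   the RiboTag fold-change floor.
#' @param id_map Optional data frame with columns `transcript_id`,
#'   `gene_id` used to join transcript-level CLIP results to gene-level
#'   RiboTag results; by default ids are joined directly.
#' @return A list of class `"quadrant_table"`: `table` (id,
#'   fmrp_direction, ribo_direction, quadrant, clip_effect, clip_p,
#'   ribo_log2fc, ribo_padj) and `counts` (named integer vector over the
#'   seven quadrant labels).
#' @export
quadrant_classify <- function(clip_diff, ribo_diff,
                              config = pipeline_config(), id_map = NULL) {
  stopifnot(inherits(clip_diff, "diff_result"),
            inherits(ribo_diff, "diff_result"))
  ct <- clip_diff$table
  rt <- ribo_diff$table
  if (anyDuplicated(ct$id) || anyDuplicated(rt$id))
    stop("duplicated ids in differential results")
  rid <- rt$id
  cid <- ct$id
  if (!is.null(id_map)) {
    # translate RiboTag gene ids into the CLIP transcript-id space
    idx <- match(rid, id_map$gene_id)
    rid <- id_map$transcript_id[idx]
  }
  common <- intersect(cid, rid)
  total <- length(union(cid, rid))
  if (length(common) < 0.5 * total)
    warning("quadrant join lost more than half of the ids (",
            length(common), "/", total, ")")
  ci <- match(common, cid)
  ri <- match(common, rid)
  fmrp <- ifelse(ct$p[ci] < config$clip_diff_alpha,
                 ifelse(ct$effect[ci] > 0, "up", "down"), "unchanged")
  ribo_sig <- !is.na(rt$padj[ri]) & rt$padj[ri] < config$ribo_diff_alpha &
    abs(rt$effect[ri]) > config$ribo_lfc_floor
  ribo <- ifelse(ribo_sig, ifelse(rt$effect[ri] > 0, "up", "down"),
                 "unchanged")
  quad <- ifelse(fmrp == "unchanged" & ribo == "unchanged", "unchanged",
          ifelse(fmrp == "unchanged", paste0("fmrp_unchanged_ribo_", ribo),
                 paste0("fmrp_", fmrp, "_ribo_", ribo)))
  levels_quad <- c("fmrp_down_ribo_up", "fmrp_down_ribo_down",
                   "fmrp_down_ribo_unchanged", "fmrp_up_ribo_up",
                   "fmrp_up_ribo_down", "fmrp_up_ribo_unchanged",
                   "fmrp_unchanged_ribo_up", "fmrp_unchanged_ribo_down",
                   "unchanged")
  tab <- data.frame(id = common,
                    fmrp_direction = fmrp,
                    ribo_direction = ribo,
                    quadrant = factor(quad, levels = levels_quad),
                    clip_effect = ct$effect[ci], clip_p = ct$p[ci],
                    ribo_log2fc = rt$effect[ri], ribo_padj = rt$padj[ri],
                    stringsAsFactors = FALSE)
  counts <- table(tab$quadrant)
  structure(list(table = tab, counts = counts), class = "quadrant_table")
}

#' @export
print.quadrant_table <- function(x, ...) {
  cat("quadrant_table:", nrow(x$table), "transcripts\n")
  print(x$counts)
  invisible(x)
}

#' JSON summary of quadrant counts
#'
#' @param quad A `"quadrant_table"`.
#' @param path Optional output file; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
quadrant_summary_json <- function(quad, path = NULL) {
  stopifnot(inherits(quad, "quadrant_table"))
  j <- jsonlite::toJSON(as.list(stats::setNames(as.integer(quad$counts),
                                                names(quad$counts))),
                        auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(j)
}
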