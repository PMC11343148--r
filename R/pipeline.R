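#' Run the integrated CLIP x RiboTag analysis
#'
#' Chains the full analysis: TPM quantification of RiboTag samples,
#' representative-transcript selection, restriction of CLIP counts to the
#' expressed set, CLIP TPM, per-replicate abundance regressions and CLIP
#' scores for both conditions, tier and cross-condition classification,
#' moderated-t differential CLIP binding (Opto vs Control), NB Wald
#' differential ribosome association (IP vs Input and Opto vs Control IP),
#' RiboTag enrichment with the marker-panel check, and the quadrant
#' integration.
#'
#' @param clip_counts,ribo_counts `"count_matrix"` objects (e.g. from
#'   [read_count_table()] or [generate_dataset()]).
#' @param models A `"transcript_models"` object.
#' @param config A `"clipribo_config"`.
#' @param outdir Optional directory; when given, stage outputs are written
#'   as TSV (plus a JSON quadrant summary and run manifest).
#' @return A list of class `"clipribo_run"` with elements `rep_map`,
#'   `ribo_tpm`, `clip_tpm`, `fits`, `scores`, `classification`
#'   (per condition), `cross_classes`, `clip_diff`, `ip_vs_input`,
#'   `ribo_diff`, `enrichment`, `marker_report`, `bc`, `quadrants`,
#'   `config`.
#' @export
run_pipeline <- function(clip_counts, ribo_counts, models,
                         config = pipeline_config(), outdir = NULL) {
  lens <- transcript_lengths(models)
  set.seed(config$rng_seed)

  ribo_ip <- subset_samples(ribo_counts, assay = "RiboTag-IP")
  ribo_input <- subset_samples(ribo_counts, assay = "RiboTag-Input")
  ribo_tpm_all <- compute_tpm(ribo_ip, lens)
  rep_map <- select_representative_transcripts(ribo_tpm_all, models,
                                               config$expression_floor)
  sel <- rep_map$transcript_id

  clip_sel <- restrict_clip_to_expressed(clip_counts, sel)
  clip_tpm <- compute_tpm(clip_sel, lens)
  # scores are computed on the representative set; RiboTag TPM is
  # deliberately NOT renormalized after selection so that abundances stay
  # on the original library scale
  ribo_tpm <- quant_subset(ribo_tpm_all, sel)

  fits <- list(); scores <- list(); classification <- list()
  for (cond in c("Control", "Opto")) {
    fits[[cond]] <- fit_condition_regressions(
      clip_tpm, ribo_tpm, clip_sel$samples, ribo_ip$samples, cond,
      config$pseudocount)
    scores[[cond]] <- score_table(clip_tpm, ribo_tpm, clip_sel$samples,
                                  ribo_ip$samples, fits[[cond]], cond,
                                  config)
    classification[[cond]] <- classify_targets(scores[[cond]], config)
  }
  cross <- cross_condition_classes(classification$Control,
                                   classification$Opto)

  clip_diff <- moderated_t(scores$Control$scores, scores$Opto$scores,
                           alpha = config$clip_diff_alpha)

  # IP vs Input (Control condition) for the enrichment check
  ribo_ctrl <- subset_samples(ribo_counts, condition = "Control")
  sel_in_ribo <- intersect(sel, rownames(ribo_ctrl$counts))
  ip_vs_input <- nb_wald_test(
    count_matrix(ribo_ctrl$counts[sel_in_ribo, , drop = FALSE],
                 ribo_ctrl$samples),
    design = factor(ribo_ctrl$samples$assay,
                    levels = c("RiboTag-Input", "RiboTag-IP")),
    alpha = config$ribo_diff_alpha)

  # Opto vs Control on IP samples: differential ribosome association
  ribo_ip_sel <- count_matrix(ribo_ip$counts[sel, , drop = FALSE],
                              ribo_ip$samples)
  ribo_diff <- nb_wald_test(
    ribo_ip_sel,
    design = factor(ribo_ip$samples$condition,
                    levels = c("Control", "Opto")),
    alpha = config$ribo_diff_alpha)

  input_tpm <- compute_tpm(subset_samples(ribo_input,
                                          condition = "Control"), lens)
  ip_tpm_ctrl <- compute_tpm(subset_samples(ribo_ip,
                                            condition = "Control"), lens)
  enr <- ribotag_enrichment(
    quant_subset(ip_tpm_ctrl, sel),
    quant_subset(input_tpm, sel),
    diff = ip_vs_input, pseudocount = config$pseudocount)
  # marker panels are defined on gene symbols: report at gene level
  enr_gene <- enr
  enr_gene$id <- rep_map$gene_id[match(enr$id, rep_map$transcript_id)]
  marker_report <- marker_panel_check(enr_gene)

  gene_map <- stats::setNames(models$transcripts$gene_id,
                              models$transcripts$transcript_id)
  bc <- biological_complexity(clip_sel, config$bc_min_tags, level = "gene",
                              gene_map = gene_map)

  quad <- quadrant_classify(clip_diff, ribo_diff, config)

  res <- structure(list(rep_map = rep_map, ribo_tpm = ribo_tpm,
                        clip_tpm = clip_tpm, fits = fits, scores = scores,
                        classification = classification,
                        cross_classes = cross, clip_diff = clip_diff,
                        ip_vs_input = ip_vs_input, ribo_diff = ribo_diff,
                        enrichment = enr, marker_report = marker_report,
                        bc = bc, quadrants = quad, config = config),
                   class = "clipribo_run")
  if (!is.null(outdir)) write_run(res, outdir)
  res
}

#' @export
print.clipribo_run <- function(x, ...) {
  cat("clipribo_run over", nrow(x$rep_map), "representative transcripts\n")
  for (cond in names(x$classification))
    cat(sprintf("  %s stringent targets: %d\n", cond,
                sum(x$classification[[cond]]$tier == "stringent")))
  cat("  cross-condition classes:\n")
  print(attr(x$cross_classes, "counts"))
  cat("  quadrants:\n")
  print(x$quadrants$counts)
  invisible(x)
}

# Write every stage output of a pipeline run as deterministic TSV/JSON.
write_run <- function(res, outdir, timestamp = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  w <- function(df, name)
    write_results(df, file.path(outdir, name), cfg, timestamp = timestamp)
  w(res$rep_map, "representative_transcripts.tsv")
  fit_df <- do.call(rbind, lapply(unlist(res$fits, recursive = FALSE),
    function(f) data.frame(condition = f$condition, replicate = f$replicate,
                           slope = f$slope, intercept = f$intercept,
                           n_points = f$n_points,
                           residual_sd = f$residual_sd)))
  w(fit_df, "regression_fits.tsv")
  for (cond in names(res$scores)) {
    sc <- res$scores[[cond]]
    df <- data.frame(transcript_id = rownames(sc$scores), sc$scores,
                     mean_score = sc$mean_score, check.names = FALSE)
    names(df)[2:(1 + ncol(sc$scores))] <-
      paste0("score_rep", colnames(sc$scores))
    w(df, paste0("clip_scores_", tolower(cond), ".tsv"))
  }
  w(res$cross_classes, "target_classes.tsv")
  w(res$clip_diff$table, "clip_differential.tsv")
  w(res$ip_vs_input$table, "ribotag_ip_vs_input.tsv")
  w(res$ribo_diff$table, "ribotag_differential.tsv")
  w(res$enrichment, "ribotag_enrichment.tsv")
  w(res$marker_report, "marker_panel_report.tsv")
  w(data.frame(gene_id = names(res$bc$support),
               support = unname(res$bc$support)), "biological_complexity.tsv")
  w(res$quadrants$table, "quadrants.tsv")
  quadrant_summary_json(res$quadrants, file.path(outdir, "quadrant_counts.json"))
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$rng_seed,
                   n_transcripts = nrow(res$rep_map),
                   outputs = list.files(outdir))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(outdir, "run_manifest.json"))
  invisible(outdir)
}
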