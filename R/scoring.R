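#' Fit the CLIP-vs-RiboTag abundance regression for one replicate
#'
#' CLIP tag density scales with transcript abundance, so FMRP binding is
#' quantified relative to similarly abundant transcripts: each CLIP
#' replicate's log2 TPM is regressed (ordinary least squares) on the mean
#' log2 RiboTag TPM of the matching condition. Transcripts with zero CLIP
#' TPM are excluded from the fit because their log is undefined.
#'
#' @param clip_log2 Named vector: log2(CLIP TPM + pseudocount) for one
#'   replicate; entries that are `NA` (zero CLIP TPM) are dropped.
#' @param ribo_mean_log2 Named vector: condition-matched mean log2 RiboTag
#'   TPM, on the same transcript set.
#' @param condition,replicate Labels recorded in the fit.
#' @return A list of class `"regression_fit"`: `slope`, `intercept`,
#'   `n_points`, `residual_sd`, `condition`, `replicate`.
#' @examples
#' f <- fit_abundance_regression(c(a = 1, b = 3, c = 5), c(a = 0, b = 1, c = 2))
#' c(f$slope, f$intercept)  # 2, 1
#' @export
fit_abundance_regression <- function(clip_log2, ribo_mean_log2,
                                     condition = NA, replicate = NA) {
  common <- intersect(names(clip_log2), names(ribo_mean_log2))
  y <- clip_log2[common]
  x <- ribo_mean_log2[common]
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3L) stop("need at least 3 finite points to fit")
  if (stats::var(x) == 0) stop("degenerate fit: zero variance in RiboTag TPM")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 n_points = length(y),
                 residual_sd = stats::sd(stats::residuals(fit)),
                 condition = condition, replicate = replicate),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit [%s rep %s]: slope %.4f, intercept %.4f (n=%d)\n",
              x$condition, x$replicate, x$slope, x$intercept, x$n_points))
  invisible(x)
}

#' CLIP score of a transcript
#'
#' The published convention (`"as_printed"`) follows the formula
#' `score = log2 CLIP TPM - slope * log2 RiboTag TPM + intercept`
#' literally; `"residual"` is the ordinary regression residual
#' `y - (slope * x + intercept)`. For any point the two differ by the
#' constant `2 * intercept`.
#'
#' @param y log2 CLIP TPM (vector).
#' @param x log2 RiboTag TPM (vector, same length).
#' @param fit A `"regression_fit"`.
#' @param convention `"as_printed"` or `"residual"`.
#' @return Numeric vector of scores.
#' @export
clip_score <- function(y, x, fit, convention = c("as_printed", "residual")) {
  convention <- match.arg(convention)
  if (convention == "as_printed") y - fit$slope * x + fit$intercept
  else y - (fit$slope * x + fit$intercept)
}

#' Fit regressions for every CLIP replicate of a condition
#'
#' @param clip_quant Linear `"quant_table"` of CLIP samples.
#' @param ribo_quant Linear `"quant_table"` of RiboTag samples used for
#'   normalization (typically the IP samples).
#' @param clip_samples,ribo_samples Sample sheets for the two tables.
#' @param condition Condition to fit (`"Control"` or `"Opto"`).
#' @param pseudocount TPM pseudocount before log2.
#' @return List of `"regression_fit"`, one per CLIP replicate, named by
#'   replicate.
#' @export
fit_condition_regressions <- function(clip_quant, ribo_quant, clip_samples,
                                      ribo_samples, condition,
                                      pseudocount = 0.01) {
  xr <- condition_ribo_log2(ribo_quant, ribo_samples, condition, pseudocount)
  cs <- clip_samples[clip_samples$condition == condition &
                       clip_samples$assay == "CLIP", , drop = FALSE]
  if (nrow(cs) == 0L) stop("no CLIP samples for condition ", condition)
  fits <- lapply(seq_len(nrow(cs)), function(i) {
    smp <- cs$sample[i]
    tpm <- clip_quant$tpm[, smp]
    y <- log2(tpm + pseudocount)
    y[tpm == 0] <- NA  # zero CLIP TPM excluded from the fit
    names(y) <- rownames(clip_quant$tpm)
    fit_abundance_regression(y, xr, condition = condition,
                             replicate = cs$replicate[i])
  })
  names(fits) <- as.character(cs$replicate)
  fits
}

# Mean log2(RiboTag TPM + pseudocount) over the condition's replicates,
# averaged on the log2 scale.
condition_ribo_log2 <- function(ribo_quant, ribo_samples, condition,
                                pseudocount = 0.01) {
  rs <- ribo_samples[ribo_samples$condition == condition, , drop = FALSE]
  if (nrow(rs) == 0L) stop("no RiboTag samples for condition ", condition)
  m <- log2(ribo_quant$tpm[, rs$sample, drop = FALSE] + pseudocount)
  rowMeans(m)
}

#' Per-replicate and mean CLIP scores for one condition
#'
#' Computes the CLIP score of every transcript in every CLIP replicate of a
#' condition, plus the per-transcript mean across replicates (the final CLIP
#' score). Transcripts with zero CLIP TPM in a replicate receive a missing
#' score in that replicate; the mean is taken over finite scores.
#'
#' @param clip_quant,ribo_quant Linear `"quant_table"`s.
#' @param clip_samples,ribo_samples Sample sheets.
#' @param fits Fits from [fit_condition_regressions()] for this condition.
#' @param condition Condition label.
#' @param config A `"clipribo_config"` (score convention, pseudocount).
#' @return A list of class `"clip_scores"`: `condition`, `scores`
#'   (transcript x replicate matrix, NA where CLIP TPM was zero),
#'   `mean_score` (named vector), `convention`, `fits`.
#' @export
score_table <- function(clip_quant, ribo_quant, clip_samples, ribo_samples,
                        fits, condition, config = pipeline_config()) {
  xr <- condition_ribo_log2(ribo_quant, ribo_samples, condition,
                            config$pseudocount)
  cs <- clip_samples[clip_samples$condition == condition &
                       clip_samples$assay == "CLIP", , drop = FALSE]
  if (!setequal(as.character(cs$replicate), names(fits)))
    stop("missing regression fit for replicate(s): ",
         paste(setdiff(as.character(cs$replicate), names(fits)),
               collapse = ", "))
  ids <- rownames(clip_quant$tpm)
  x <- xr[ids]
  sc <- matrix(NA_real_, length(ids), nrow(cs),
               dimnames = list(ids, as.character(cs$replicate)))
  for (i in seq_len(nrow(cs))) {
    rep_id <- as.character(cs$replicate[i])
    tpm <- clip_quant$tpm[, cs$sample[i]]
    y <- log2(tpm + config$pseudocount)
    s <- clip_score(y, x, fits[[rep_id]], config$score_convention)
    s[tpm == 0] <- NA_real_
    sc[, rep_id] <- s
  }
  structure(list(condition = condition, scores = sc,
                 mean_score = rowMeans(sc, na.rm = TRUE),
                 convention = config$score_convention, fits = fits),
            class = "clip_scores")
}

#' @export
print.clip_scores <- function(x, ...) {
  cat("clip_scores [", x$condition, "]: ", nrow(x$scores), " transcripts x ",
      ncol(x$scores), " replicates (", x$convention, ")\n", sep = "")
  invisible(x)
}

#' Classify transcripts into binding tiers
#'
#' Stringent targets exceed the stringent threshold (default 2) — in every
#' replicate under `per_replicate` mode, or on the mean score under `mean`
#' mode. Tiers below stringent are always evaluated on the mean: high
#' binding above 1, low binding above 0, otherwise non-target. All
#' inequalities are strict, so a mean score of exactly 2 is high, not
#' stringent. A transcript with any missing replicate score cannot be
#' stringent in `per_replicate` mode.
#'
#' @param scores A `"clip_scores"` object.
#' @param config A `"clipribo_config"`.
#' @return Data frame `transcript_id`, `mean_score`, `tier` (factor with
#'   levels stringent, high, low, nontarget); attribute `"condition"`.
#' @export
classify_targets <- function(scores, config = pipeline_config()) {
  stopifnot(inherits(scores, "clip_scores"))
  sc <- scores$scores
  ms <- scores$mean_score
  stringent <- switch(config$stringency_mode,
    per_replicate = apply(sc, 1, function(v)
      all(!is.na(v)) && all(v > config$stringent_threshold)),
    mean = !is.na(ms) & ms > config$stringent_threshold,
    stop("unknown stringency mode: ", config$stringency_mode))
  tier <- rep("nontarget", nrow(sc))
  tier[!is.na(ms) & ms > config$low_threshold] <- "low"
  tier[!is.na(ms) & ms > config$high_threshold] <- "high"
  tier[stringent] <- "stringent"
  out <- data.frame(transcript_id = rownames(sc),
                    mean_score = unname(ms),
                    tier = factor(tier, levels = c("stringent", "high",
                                                   "low", "nontarget")),
                    stringsAsFactors = FALSE)
  attr(out, "condition") <- scores$condition
  out
}

#' Cross-condition target classes
#'
#' Combines the per-condition stringency calls: transcripts stringent in
#' both conditions, in control only, in activated (Opto) only, or in
#' neither.
#'
#' @param control,opto Classification tables from [classify_targets()] on
#'   the same transcript set.
#' @return Data frame `transcript_id`, `control_tier`, `opto_tier`, `class`
#'   (factor stringent_both / control_only / opto_only / neither);
#'   attribute `"counts"` is the per-class table.
#' @export
cross_condition_classes <- function(control, opto) {
  if (!setequal(control$transcript_id, opto$transcript_id))
    stop("conditions classified on different transcript sets")
  opto <- opto[match(control$transcript_id, opto$transcript_id), ,
               drop = FALSE]
  sc <- control$tier == "stringent"
  so <- opto$tier == "stringent"
  cls <- ifelse(sc & so, "stringent_both",
         ifelse(sc & !so, "control_only",
         ifelse(!sc & so, "opto_only", "neither")))
  out <- data.frame(transcript_id = control$transcript_id,
                    control_tier = control$tier,
                    opto_tier = opto$tier,
                    class = factor(cls, levels = c("stringent_both",
                                                   "control_only",
                                                   "opto_only", "neither")),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(out$class)
  out
}
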