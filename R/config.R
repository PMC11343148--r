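#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one validated object.
#' Defaults follow the published analysis conventions: stringent targets need
#' a CLIP score above 2 in every biological replicate, high-binding targets a
#' mean score above 1, low-binding targets a mean score above 0; differential
#' CLIP binding is called at raw p < 0.05 while differential ribosome
#' association is called at BH-adjusted p < 0.05.
#'
#' @param stringent_threshold CLIP score above which a transcript is a
#'   stringent target (default 2).
#' @param high_threshold Mean CLIP score above which a non-stringent
#'   transcript is a high-binding target (default 1).
#' @param low_threshold Mean CLIP score above which a transcript is at least
#'   a low-binding target (default 0).
#' @param stringency_mode `"per_replicate"` requires the stringent threshold
#'   to be exceeded in every replicate; `"mean"` applies it to the mean score.
#' @param score_convention `"as_printed"` computes
#'   `score = y - slope * x + intercept`; `"residual"` computes the ordinary
#'   regression residual `y - (slope * x + intercept)`. The two differ by the
#'   constant `2 * intercept` within a replicate.
#' @param pseudocount TPM pseudocount added before taking log2 (default 0.01).
#' @param clip_diff_alpha Significance level for differential CLIP binding,
#'   applied to the raw moderated-t p-value (default 0.05).
#' @param ribo_diff_alpha Significance level for differential ribosome
#'   association, applied to the BH-adjusted p-value (default 0.05).
#' @param ribo_lfc_floor Minimum |log2 fold change| additionally required to
#'   call a RiboTag change (default 0, i.e. no floor).
#' @param bc_min_tags Minimum tag count for a replicate to support a gene in
#'   the biological-complexity filter (default 5).
#' @param bc_required Number of supporting replicates required to pass the
#'   biological-complexity filter (default 4).
#' @param expression_floor Mean RiboTag TPM a representative transcript must
#'   exceed to count as expressed (default 0).
#' @param allow_strandless Accept BED records with strand "." (default FALSE).
#' @param rng_seed Integer seed from which all randomness flows.
#' @return A list of class `"clipribo_config"`.
#' @examples
#' cfg <- pipeline_config(rng_seed = 1)
#' cfg$stringent_threshold
#' @export
pipeline_config <- function(stringent_threshold = 2,
                            high_threshold = 1,
                            low_threshold = 0,
                            stringency_mode = c("per_replicate", "mean"),
                            score_convention = c("as_printed", "residual"),
                            pseudocount = 0.01,
                            clip_diff_alpha = 0.05,
                            ribo_diff_alpha = 0.05,
                            ribo_lfc_floor = 0,
                            bc_min_tags = 5,
                            bc_required = 4,
                            expression_floor = 0,
                            allow_strandless = FALSE,
                            rng_seed = 1L) {
  stringency_mode <- match.arg(stringency_mode)
  score_convention <- match.arg(score_convention)
  stopifnot(is.numeric(stringent_threshold), is.numeric(high_threshold),
            is.numeric(low_threshold))
  if (!(stringent_threshold > high_threshold && high_threshold > low_threshold))
    stop("thresholds must satisfy stringent > high > low")
  for (a in c(clip_diff_alpha, ribo_diff_alpha))
    if (!is.numeric(a) || a <= 0 || a >= 1)
      stop("alpha levels must lie in (0, 1)")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (bc_min_tags < 0 || bc_required < 0)
    stop("biological-complexity parameters must be non-negative")
  cfg <- list(
    stringent_threshold = stringent_threshold,
    high_threshold = high_threshold,
    low_threshold = low_threshold,
    stringency_mode = stringency_mode,
    score_convention = score_convention,
    pseudocount = pseudocount,
    clip_diff_alpha = clip_diff_alpha,
    ribo_diff_alpha = ribo_diff_alpha,
    ribo_lfc_floor = ribo_lfc_floor,
    bc_min_tags = as.integer(bc_min_tags),
    bc_required = as.integer(bc_required),
    expression_floor = expression_floor,
    allow_strandless = isTRUE(allow_strandless),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "clipribo_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected so that typos in a config file fail loudly.
#'
#' @param path Path to a YAML file whose keys match [pipeline_config()]
#'   arguments.
#' @return A `"clipribo_config"` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Stable hash of a configuration
#'
#' A short deterministic digest (FNV-1a over the deparsed object) recorded in
#' every output header so results can be traced to the configuration that
#' produced them.
#'
#' @param cfg A `"clipribo_config"` object.
#' @return An 8-hex-digit character scalar.
#' @export
config_hash <- function(cfg) {
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)   # keep in integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' @export
print.clipribo_config <- function(x, ...) {
  cat("clipribo pipeline configuration (hash ", config_hash(x), ")\n", sep = "")
  for (nm in names(x)) cat("  ", nm, ": ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}
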