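#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort ascending, multiply `p_(i)` by `m/i`,
#' enforce monotonicity from the largest rank down, cap at 1, and return in
#' input order. Delegates to `stats::p.adjust(method = "BH")` after input
#' validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs propagated).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

new_diff_result <- function(table, assay, details = list()) {
  table <- table[order(table$p), , drop = FALSE]
  rownames(table) <- NULL
  structure(c(list(table = table, assay = assay), details),
            class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat("diff_result [", x$assay, "]: ", nrow(x$table), " features, ",
      sum(x$table$padj < 0.05, na.rm = TRUE), " at padj < 0.05\n", sep = "")
  invisible(x)
}

#' Empirical-Bayes moderated t-test of CLIP scores
#'
#' Two-sample comparison of per-replicate CLIP scores between conditions
#' with the classic empirical-Bayes variance moderation: per-transcript
#' pooled residual variances `s_g^2` (df `d_g = n1 + n2 - 2`) are shrunk
#' toward a prior `s0^2` with prior df `d0`, both estimated by closed-form
#' moments of `log s_g^2`; the moderated statistic is
#' `t = effect / (s_tilde * sqrt(1/n1 + 1/n2))` on `d0 + d_g` df. The
#' effect is mean(group2) - mean(group1), i.e. Opto minus Control when
#' called with (control, opto). Direction labels follow the raw-p
#' convention for differential binding: `up`/`down` at `p < alpha`.
#'
#' @param control_scores,opto_scores Matrices (transcripts x replicates) of
#'   per-replicate scores; rows are matched by rownames. Transcripts with
#'   fewer than 2 finite replicates in either group are dropped.
#' @param alpha Significance level applied to the raw p-value for the
#'   direction label (default 0.05).
#' @param d0_override Force the prior df (0 recovers the ordinary pooled t;
#'   `Inf` fully pools variances). Default NULL: estimate from the data.
#' @return A `"diff_result"`; `$table` has columns `id`, `effect`,
#'   `statistic`, `p`, `padj`, `direction`, `n1`, `n2`, `s2`, `df`;
#'   `$prior_df`, `$prior_var` hold the empirical-Bayes hyperparameters.
#' @export
moderated_t <- function(control_scores, opto_scores, alpha = 0.05,
                        d0_override = NULL) {
  control_scores <- as.matrix(control_scores)
  opto_scores <- as.matrix(opto_scores)
  common <- intersect(rownames(control_scores), rownames(opto_scores))
  if (length(common) == 0L) stop("no shared transcripts")
  a <- control_scores[common, , drop = FALSE]
  b <- opto_scores[common, , drop = FALSE]
  n1 <- rowSums(is.finite(a))
  n2 <- rowSums(is.finite(b))
  keep <- n1 >= 2 & n2 >= 2
  dropped <- sum(!keep)
  if (dropped)
    message(dropped, " transcript(s) dropped with < 2 finite replicates")
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  n1 <- n1[keep]; n2 <- n2[keep]
  m1 <- rowMeans(a, na.rm = TRUE)
  m2 <- rowMeans(b, na.rm = TRUE)
  ss <- function(m, mu) rowSums((m - mu)^2, na.rm = TRUE)
  dg <- n1 + n2 - 2
  s2 <- (ss(a, m1) + ss(b, m2)) / dg
  effect <- m2 - m1
  if (length(s2) < 2L) {
    warning("fewer than 2 transcripts: falling back to ordinary t")
    d0 <- 0; s02 <- NA_real_
  } else if (!is.null(d0_override)) {
    d0 <- d0_override
    s02 <- if (is.finite(d0) && d0 > 0) fit_f_dist(s2, dg, d0 = d0)$s02
           else mean(s2)
  } else {
    fd <- fit_f_dist(s2, dg)
    d0 <- fd$d0; s02 <- fd$s02
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))   # fully pooled variance
    df <- rep(Inf, length(dg))
  } else {
    d0 <- min(d0, 1e6)                # numerical-stability cap
    s2_post <- if (d0 > 0) (d0 * s02 + dg * s2) / (d0 + dg) else s2
    df <- d0 + dg
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- effect / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  tab <- data.frame(id = names(effect), effect = unname(effect),
                    statistic = unname(tstat), p = unname(p),
                    padj = bh_adjust(unname(p)),
                    direction = ifelse(p < alpha,
                                       ifelse(effect > 0, "up", "down"),
                                       "unchanged"),
                    n1 = unname(n1), n2 = unname(n2),
                    s2 = unname(s2), df = unname(df),
                    stringsAsFactors = FALSE)
  new_diff_result(tab, assay = "CLIP",
                  details = list(prior_df = d0, prior_var = s02,
                                 alpha = alpha))
}

# Method-of-moments fit of the scaled-F model to sample variances s2 with
# residual df dg (Smyth-style, via moments of log s2). Returns prior df d0
# and prior variance s02. When d0 is supplied, only s02 is estimated.
fit_f_dist <- function(s2, dg, d0 = NULL) {
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  d <- dg[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  if (is.null(d0)) {
    n <- length(e)
    ev <- mean((e - ebar)^2) * n / (n - 1) - mean(trigamma(d / 2))
    if (is.finite(ev) && ev > 0) {
      d0 <- 2 * trigamma_inverse(ev)
    } else {
      d0 <- Inf
    }
  }
  s02 <- if (is.finite(d0)) exp(ebar + digamma(d0 / 2) - log(d0 / 2))
         else exp(ebar)
  list(d0 = d0, s02 = s02)
}

# Newton inversion of the trigamma function (monotone decreasing on (0,Inf)).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-nonzero genes of the ratio of its
#' count to the gene's geometric mean across samples; factors are then
#' rescaled to geometric mean 1.
#'
#' @param counts A `"count_matrix"` or plain count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  logs <- log(m)
  ok <- rowSums(is.finite(logs)) == ncol(m)  # genes nonzero in all samples
  if (!any(ok))
    stop("no gene has nonzero counts in every sample; ",
         "consider a pseudo-reference")
  gm <- exp(rowMeans(logs[ok, , drop = FALSE]))
  sf <- apply(m[ok, , drop = FALSE] / gm, 2, stats::median)
  sf / exp(mean(log(sf)))  # geometric mean 1
}

#' Negative-binomial Wald test for differential counts
#'
#' Simplified two-group NB differential test: counts are normalized by
#' median-of-ratios size factors, gene-wise dispersion is estimated by
#' method of moments (floored at 1e-8, no trend or shrinkage), the group
#' mean is the NB maximum-likelihood estimate (Newton-refined from the
#' normalized-count mean), and the Wald statistic is the log2 fold change
#' over its standard error from observed Fisher information. Two-sided
#' normal p-values, BH adjustment. Serves both contrasts of the design
#' (IP vs Input; Opto vs Control).
#'
#' @param counts A `"count_matrix"` containing the samples of both groups.
#' @param design Character/factor vector over the count columns with exactly
#'   two levels; the effect is level 2 vs level 1 (log2 scale).
#' @param sf Size factors (default: computed from `counts`).
#' @param alpha BH-adjusted significance level for the direction label
#'   (default 0.05).
#' @return A `"diff_result"` with table columns `id`, `effect` (log2FC),
#'   `statistic` (Wald z), `p`, `padj`, `direction`, `mu1`, `mu2`,
#'   `dispersion`, `flagged` (TRUE when a zero group mean required the
#'   pseudocount policy).
#' @export
nb_wald_test <- function(counts, design, sf = NULL, alpha = 0.05) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  design <- as.factor(design)
  if (nlevels(design) != 2L) stop("design must have exactly two levels")
  if (length(design) != ncol(m)) stop("design length != number of samples")
  if (any(table(design) < 2L)) stop("need at least 2 samples per group")
  if (is.null(sf)) sf <- size_factors(m)
  g1 <- design == levels(design)[1]
  g2 <- design == levels(design)[2]
  norm <- sweep(m, 2, sf, "/")
  q1 <- rowMeans(norm[, g1, drop = FALSE])
  q2 <- rowMeans(norm[, g2, drop = FALSE])
  n1 <- sum(g1); n2 <- sum(g2)
  # method-of-moments dispersion on normalized counts, pooled within groups
  v1 <- apply(norm[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, stats::var)
  vw <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mu_bar <- (n1 * q1 + n2 * q2) / (n1 + n2)
  disp <- pmax((vw - mu_bar) / mu_bar^2, 1e-8)
  disp[!is.finite(disp)] <- 1e-8
  # NB MLE of the group mean q: Newton from the normalized-count mean
  q1 <- nb_group_mle(m[, g1, drop = FALSE], sf[g1], disp, q1)
  q2 <- nb_group_mle(m[, g2, drop = FALSE], sf[g2], disp, q2)
  flagged <- q1 == 0 | q2 == 0
  pc <- 0.5  # normalized-count pseudocount for all-zero groups
  q1f <- ifelse(q1 == 0, pc, q1)
  q2f <- ifelse(q2 == 0, pc, q2)
  effect <- log2(q2f / q1f)
  # observed Fisher information for q: sum_j sf_j^2 / (mu_j + a mu_j^2)
  info_q <- function(q, sfg, a) {
    sapply(seq_along(q), function(g) {
      mu <- sfg * q[g]
      sum(sfg^2 / (mu + a[g] * mu^2))
    })
  }
  var_log2 <- function(q, sfg, a) 1 / info_q(q, sfg, a) / (q * log(2))^2
  se <- sqrt(var_log2(q1f, sf[g1], disp) + var_log2(q2f, sf[g2], disp))
  z <- effect / se
  p <- 2 * stats::pnorm(-abs(z))
  padj <- bh_adjust(p)
  tab <- data.frame(id = rownames(m), effect = unname(effect),
                    statistic = unname(z), p = unname(p),
                    padj = unname(padj),
                    direction = ifelse(!is.na(padj) & padj < alpha,
                                       ifelse(effect > 0, "up", "down"),
                                       "unchanged"),
                    mu1 = unname(q1), mu2 = unname(q2),
                    dispersion = unname(disp),
                    flagged = unname(flagged),
                    stringsAsFactors = FALSE)
  new_diff_result(tab, assay = "RiboTag",
                  details = list(size_factors = sf, alpha = alpha,
                                 contrast = paste(levels(design)[2], "vs",
                                                  levels(design)[1])))
}

# Vectorised Newton refinement of the NB group-mean MLE. Score in q:
# U(q) = sum_j (k_j - sf_j q) / (q (1 + a sf_j q)).
nb_group_mle <- function(k, sfg, a, q0, iter = 25L) {
  q <- pmax(q0, 0)
  pos <- q > 0
  for (it in seq_len(iter)) {
    if (!any(pos)) break
    U <- rep(0, length(q)); J <- rep(0, length(q))
    for (j in seq_along(sfg)) {
      mu <- sfg[j] * q
      denom <- 1 + a * mu
      U <- U + (k[, j] - mu) / (q * denom)
      # derivative of the score term wrt q
      J <- J + (-sfg[j] * q * denom -
                  (k[, j] - mu) * (denom + a * sfg[j] * q)) / (q * denom)^2
    }
    step <- ifelse(pos & is.finite(U / J), -U / J, 0)
    qn <- q + step
    bad <- qn <= 0 | !is.finite(qn)
    qn[bad] <- q[bad] / 2  # damped fallback keeps q positive
    conv <- abs(qn - q) < 1e-10 * (q + 1e-10)
    q <- ifelse(pos, qn, q)
    pos <- pos & !conv
  }
  q
}
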