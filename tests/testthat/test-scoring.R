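test_that("abundance regression equals the closed-form OLS solution", {
  # collinear points: exact line
  f <- fit_abundance_regression(c(a = 1, b = 3, c = 5), c(a = 0, b = 1, c = 2))
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  # flat response
  f0 <- fit_abundance_regression(c(a = 4, b = 4, c = 4), c(a = 0, b = 1, c = 2))
  expect_equal(f0$slope, 0, tolerance = 1e-12)
  expect_equal(f0$intercept, 4, tolerance = 1e-12)
  # degenerate predictor
  expect_error(fit_abundance_regression(c(a = 1, b = 2, c = 3),
                                        c(a = 1, b = 1, c = 1)),
               "degenerate")

  set.seed(7)
  for (i in 1:1000) {
    n <- sample(5:100, 1)
    x <- rnorm(n); y <- rnorm(n, 2 * x)
    names(x) <- names(y) <- paste0("t", seq_len(n))
    f <- fit_abundance_regression(y, x)
    b <- cov(x, y) / var(x)           # independent closed form
    a <- mean(y) - b * mean(x)
    expect_equal(f$slope, b, tolerance = 1e-10)
    expect_equal(f$intercept, a, tolerance = 1e-10)
  }
})

test_that("clip_score implements both conventions, differing by 2a", {
  fit <- structure(list(slope = 1, intercept = 1), class = "regression_fit")
  expect_equal(clip_score(5, 2, fit, "as_printed"), 4)   # 5 - 1*2 + 1
  # a point on the fitted line
  on_line <- fit$slope * 3 + fit$intercept
  expect_equal(clip_score(on_line, 3, fit, "residual"), 0)
  expect_equal(clip_score(on_line, 3, fit, "as_printed"), 2 * fit$intercept)
  # the offset is constant for any point
  y <- rnorm(50); x <- rnorm(50)
  expect_equal(clip_score(y, x, fit, "as_printed") -
                 clip_score(y, x, fit, "residual"),
               rep(2 * fit$intercept, 50))
})

test_that("residual-convention scores of fitted transcripts sum to zero", {
  set.seed(3)
  x <- rnorm(200); y <- 1.5 * x - 2 + rnorm(200)
  names(x) <- names(y) <- paste0("t", 1:200)
  f <- fit_abundance_regression(y, x)
  expect_lt(abs(sum(clip_score(y, x, f, "residual"))), 1e-8)
})

test_that("pipeline CLIP scores match the committed brute-force oracle", {
  d <- tiny_dir()
  ds <- read_dataset(d)
  oracle <- utils::read.delim(file.path(d, "oracle_clip_scores.tsv"),
                              stringsAsFactors = FALSE)
  res <- suppressMessages(run_pipeline(ds$clip_counts, ds$ribo_counts,
                                       ds$models))
  for (cond in c("Control", "Opto")) {
    ora <- oracle[oracle$condition == cond, ]
    sc <- res$scores[[cond]]
    idx <- match(ora$transcript_id, rownames(sc$scores))
    expect_false(anyNA(idx))
    for (r in 1:4)
      expect_equal(unname(sc$scores[idx, as.character(r)]),
                   ora[[paste0("score_rep", r)]], tolerance = 1e-9)
    expect_equal(unname(sc$mean_score[idx]), ora$mean_score,
                 tolerance = 1e-9)
  }
})

test_that("switching score convention shifts each replicate by exactly 2a", {
  d <- tiny_dir()
  ds <- read_dataset(d)
  r1 <- suppressMessages(run_pipeline(ds$clip_counts, ds$ribo_counts,
    ds$models, pipeline_config(score_convention = "as_printed")))
  r2 <- suppressMessages(run_pipeline(ds$clip_counts, ds$ribo_counts,
    ds$models, pipeline_config(score_convention = "residual")))
  for (cond in c("Control", "Opto")) {
    for (r in colnames(r1$scores[[cond]]$scores)) {
      a <- r1$fits[[cond]][[r]]$intercept
      delta <- r1$scores[[cond]]$scores[, r] - r2$scores[[cond]]$scores[, r]
      expect_equal(unname(delta[!is.na(delta)]),
                   rep(2 * a, sum(!is.na(delta))), tolerance = 1e-10)
      # and the transcript ordering within a replicate is unchanged
      s1 <- r1$scores[[cond]]$scores[, r]
      s2 <- r2$scores[[cond]]$scores[, r]
      ok <- !is.na(s1)
      expect_identical(order(s1[ok]), order(s2[ok]))
    }
  }
})

fake_scores <- function(mat, convention = "as_printed") {
  structure(list(condition = "Control", scores = mat,
                 mean_score = rowMeans(mat, na.rm = TRUE),
                 convention = convention, fits = list()),
            class = "clip_scores")
}

test_that("tier classification follows the published thresholds", {
  mat <- rbind(
    strict = c(2.5, 2.2, 3.0, 2.1),   # > 2 in every replicate
    high = c(1.5, 1.5, 1.5, 1.5),     # mean 1.5
    border = c(2.0, 2.0, 2.0, 2.0),   # mean exactly 2: high, not stringent
    low = c(0.4, 0.6, 0.5, 0.5),
    none = c(-1, -0.5, 0, -2),
    gap = c(4, 4, 4, NA))             # missing replicate blocks stringency
  cls <- classify_targets(fake_scores(mat),
                          pipeline_config(stringency_mode = "per_replicate"))
  expect_equal(as.character(cls$tier[match(
    c("strict", "high", "border", "low", "none", "gap"),
    cls$transcript_id)]),
    c("stringent", "high", "high", "low", "nontarget", "high"))

  cls_m <- classify_targets(fake_scores(mat),
                            pipeline_config(stringency_mode = "mean"))
  expect_equal(as.character(
    cls_m$tier[cls_m$transcript_id == "gap"]), "stringent")
  expect_equal(as.character(
    cls_m$tier[cls_m$transcript_id == "border"]), "high")

  # tiers partition the scored set
  expect_equal(sum(table(cls$tier)), nrow(mat))
})

test_that("cross-condition classes partition the transcript set", {
  ctrl <- data.frame(transcript_id = c("t1", "t2", "t3", "t4"),
                     mean_score = c(3, 3, 1, 0),
                     tier = c("stringent", "stringent", "high", "nontarget"))
  opto <- data.frame(transcript_id = c("t1", "t2", "t3", "t4"),
                     mean_score = c(3, 1, 3, 0),
                     tier = c("stringent", "high", "stringent", "nontarget"))
  cc <- cross_condition_classes(ctrl, opto)
  expect_equal(as.character(cc$class),
               c("stringent_both", "control_only", "opto_only", "neither"))
  expect_equal(sum(attr(cc, "counts")), 4)
  expect_error(cross_condition_classes(ctrl, opto[1:3, ]), "different")
})
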