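test_that("BH adjustment matches the brute-force step-up procedure", {
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])  # step-up monotonicity
    pmin(q, 1)[order(o)]
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (i in 1:1000) {
    p <- runif(sample(2:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
  }
})

sim_scores <- function(n, reps, effect = 0, sd = 1, seed = 1) {
  set.seed(seed)
  list(a = matrix(rnorm(n * reps, 0, sd), n,
                  dimnames = list(paste0("t", 1:n), NULL)),
       b = matrix(rnorm(n * reps, effect, sd), n,
                  dimnames = list(paste0("t", 1:n), NULL)))
}

test_that("moderated t reduces to the pooled t when the prior df is zero", {
  s <- sim_scores(200, 4, seed = 2)
  res <- moderated_t(s$a, s$b, d0_override = 0)
  tab <- res$table[match(rownames(s$a), res$table$id), ]
  ord_t <- sapply(seq_len(200), function(i)
    stats::t.test(s$b[i, ], s$a[i, ], var.equal = TRUE)$statistic)
  expect_lt(max(abs(tab$statistic - ord_t)), 1e-8)
})

test_that("infinite prior df pools every variance to s0^2", {
  s <- sim_scores(200, 4, seed = 3)
  res <- moderated_t(s$a, s$b, d0_override = Inf)
  tab <- res$table[match(rownames(s$a), res$table$id), ]
  eff <- rowMeans(s$b) - rowMeans(s$a)
  # statistic must be effect / (s0 * sqrt(1/2)) with one shared s0
  implied_s0 <- (eff / tab$statistic)^2 / (1 / 4 + 1 / 4)
  expect_lt(diff(range(implied_s0)), 1e-8)
})

test_that("moderated t agrees with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  # heteroskedastic truth: per-transcript variances from a scaled inv-chisq
  # so the prior df is finite and genuinely estimated
  set.seed(4)
  n <- 500; reps <- 4
  sd_g <- sqrt(4 * 0.36 / rchisq(n, df = 4))
  s <- list(a = matrix(rnorm(n * reps, 0, sd_g), n,
                       dimnames = list(paste0("t", 1:n), NULL)),
            b = matrix(rnorm(n * reps, 0.3, sd_g), n,
                       dimnames = list(paste0("t", 1:n), NULL)))
  res <- moderated_t(s$a, s$b)
  tab <- res$table[match(rownames(s$a), res$table$id), ]
  m <- cbind(s$a, s$b)
  design <- cbind(1, rep(0:1, each = 4))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(res$prior_df, fit$df.prior, tolerance = 1e-6)
  expect_equal(res$prior_var, fit$s2.prior, tolerance = 1e-6)
  expect_equal(tab$statistic, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(tab$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("size factors follow median-of-ratios with unit geometric mean", {
  m <- matrix(c(10, 20, 30, 40,
                10, 20, 30, 40,
                10, 20, 30, 40), 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(unname(size_factors(m)), rep(1, 3))

  m2 <- m; m2[, 2] <- 2 * m2[, 2]
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)

  # hand-computed median-of-ratios oracle on an asymmetric toy matrix
  toy <- matrix(c(4, 10, 20, 100,
                  8, 10, 10, 200,
                  2, 40, 20, 100), 4,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  gm <- apply(toy, 1, function(r) exp(mean(log(r))))
  raw <- apply(toy, 2, function(col) median(col / gm))
  expect_equal(unname(size_factors(toy)), unname(raw / exp(mean(log(raw)))),
               tolerance = 1e-12)

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
               "pseudo-reference")
})

test_that("NB dispersion estimates vanish on Poisson data", {
  set.seed(9)
  m <- matrix(rpois(1000 * 6, 200), 1000,
              dimnames = list(paste0("g", 1:1000), paste0("s", 1:6)))
  res <- nb_wald_test(m, design = rep(c("A", "B"), each = 3))
  expect_gte(mean(res$table$dispersion <= 0.01), 0.95)
  # equal group means at scale: effects center on zero
  expect_lt(abs(mean(res$table$effect)), 0.02)
})

test_that("NB Wald test recovers a planted fold change and flags zeros", {
  set.seed(15)
  n <- 400
  fc <- rep(c(1, 0), c(80, 320))
  k1 <- matrix(rnbinom(n * 3, mu = 100, size = 10), n)
  k2 <- matrix(rnbinom(n * 3, mu = rep(100 * 2^fc, 3), size = 10), n)
  m <- cbind(k1, k2)
  dimnames(m) <- list(paste0("g", 1:n), paste0("s", 1:6))
  # unit size factors isolate the estimator from normalization effects
  # (20% one-directional DE would bias median-of-ratios)
  sf1 <- setNames(rep(1, 6), colnames(m))
  res <- nb_wald_test(m, design = rep(c("A", "B"), each = 3), sf = sf1)
  tab <- res$table[match(rownames(m), res$table$id), ]
  expect_equal(mean(tab$effect[fc == 1]), 1, tolerance = 0.1)
  expect_equal(sum(table(tab$direction)), n)   # direction labels partition

  # a group with all zeros gets the pseudocount policy and a flag
  m[1, 1:3] <- 0
  res0 <- nb_wald_test(m, design = rep(c("A", "B"), each = 3), sf = sf1)
  row0 <- res0$table[res0$table$id == "g1", ]
  expect_true(row0$flagged)
  expect_true(is.finite(row0$effect) && row0$effect > 0)
})

test_that("NB Wald effects track a reference NB GLM implementation", {
  skip_if_not_installed("DESeq2")
  skip_if_not_installed("SummarizedExperiment")
  set.seed(21)
  n <- 300
  fc <- rep(c(1.5, 0), c(30, 270))
  m <- cbind(matrix(rnbinom(n * 3, mu = 150, size = 8), n),
             matrix(rnbinom(n * 3, mu = rep(150 * 2^fc, 3), size = 8), n))
  dimnames(m) <- list(paste0("g", 1:n), paste0("s", 1:6))
  res <- nb_wald_test(m, design = rep(c("A", "B"), each = 3))
  tab <- res$table[match(rownames(m), res$table$id), ]
  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, data.frame(condition = factor(rep(c("A", "B"), each = 3))),
    ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  # same estimand, different dispersion machinery: agreement is approximate
  keep <- is.finite(ref$log2FoldChange)
  expect_gt(cor(tab$effect[keep], ref$log2FoldChange[keep]), 0.95)
  expect_lt(abs(mean(tab$effect[keep] - ref$log2FoldChange[keep])), 0.05)
})
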