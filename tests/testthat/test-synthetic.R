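test_that("generation is deterministic given the seed", {
  p <- generator_params(n_genes = 60, clip_library_size = 2e4,
                        ribo_library_size = 2e4, seed = 5)
  d1 <- generate_dataset(p)
  d2 <- generate_dataset(p)
  expect_identical(d1$clip_counts$counts, d2$clip_counts$counts)
  expect_identical(d1$ribo_counts$counts, d2$ribo_counts$counts)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(generator_params(n_genes = 60,
                                          clip_library_size = 2e4,
                                          ribo_library_size = 2e4, seed = 6))
  expect_false(identical(d1$clip_counts$counts, d3$clip_counts$counts))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(generator_params(frac_stringent = 0.8, frac_fmrp_down = 0.3),
               "jointly")
  expect_error(generator_params(clip_noise_sd = 0), "positive")
  expect_error(generator_params(nb_dispersion = -1), "non-negative")
})

test_that("truth classes are consistent with the planted offsets", {
  ds <- generate_dataset(generator_params(n_genes = 400,
                                          clip_library_size = 1e5,
                                          ribo_library_size = 1e5, seed = 8))
  tr <- ds$truth
  expect_setequal(unique(tr$truth_class),
                  c("stringent_both", "control_only", "opto_only",
                    "nontarget"))
  expect_true(all((tr$beta_control > 2 & tr$beta_control + tr$delta > 2) ==
                    (tr$truth_class == "stringent_both")))
  expect_true(all((tr$beta_control > 2 & tr$beta_control + tr$delta <= 2) ==
                    (tr$truth_class == "control_only")))
  expect_true(all((tr$beta_control <= 2 & tr$beta_control + tr$delta > 2) ==
                    (tr$truth_class == "opto_only")))
})

test_that("the noise-free limit produces a tight regression line", {
  ds <- generate_dataset(generator_params(
    n_genes = 300, clip_noise_sd = 1e-6, frac_stringent = 0,
    frac_fmrp_down = 0, frac_fmrp_up = 0, include_markers = FALSE,
    clip_library_size = 2e6, ribo_library_size = 1e6, seed = 12))
  lens <- transcript_lengths(ds$models)
  ribo_ip <- subset_samples(ds$ribo_counts, assay = "RiboTag-IP")
  ribo_tpm <- compute_tpm(ribo_ip, lens)
  clip_tpm <- compute_tpm(ds$clip_counts, lens)
  fits <- fit_condition_regressions(clip_tpm, ribo_tpm,
                                    ds$clip_counts$samples, ribo_ip$samples,
                                    "Control")
  # only counting noise remains: residual sd far below the default sigma
  for (f in fits) expect_lt(f$residual_sd, 0.1)
})

test_that("RiboTag Input counts are NB-overdispersed when dispersion > 0", {
  ds <- generate_dataset(generator_params(n_genes = 500,
                                          nb_dispersion = 0.2,
                                          ribo_library_size = 5e5,
                                          clip_library_size = 1e4,
                                          seed = 13))
  inp <- subset_samples(ds$ribo_counts, assay = "RiboTag-Input")
  m <- inp$counts
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  keep <- mu > 50
  # pooled variance-to-mean ratio well above the Poisson value of 1
  expect_gt(median(v[keep] / mu[keep]), 2)
})

test_that("the empirical regression among nontargets recovers the line", {
  ds <- generate_dataset(generator_params(
    n_genes = 1500, frac_stringent = 0, frac_fmrp_down = 0, frac_fmrp_up = 0,
    include_markers = FALSE, seed = 14))
  lens <- transcript_lengths(ds$models)
  ribo_ip <- subset_samples(ds$ribo_counts, assay = "RiboTag-IP")
  ribo_tpm <- compute_tpm(ribo_ip, lens)
  clip_tpm <- compute_tpm(ds$clip_counts, lens)
  fits <- fit_condition_regressions(clip_tpm, ribo_tpm,
                                    ds$clip_counts$samples, ribo_ip$samples,
                                    "Control")
  exp_fit <- ds$expected_fits[ds$expected_fits$condition == "Control", ]
  for (r in seq_along(fits)) {
    expect_equal(fits[[r]]$slope, exp_fit$slope[r], tolerance = 0.05)
    expect_equal(fits[[r]]$intercept, exp_fit$intercept_realized[r],
                 tolerance = 0.15)
  }
})

test_that("the committed tiny fixture regenerates byte-identically", {
  d <- tiny_dir()
  tmp <- tempfile()
  make_fixture("tiny", dir = tmp)
  for (f in list.files(tmp)) {
    expect_identical(readLines(file.path(tmp, f)),
                     readLines(file.path(d, f)),
                     label = paste("regenerated", f))
  }
})

test_that("the tiny fixture covers every truth class", {
  d <- tiny_dir()
  tr <- utils::read.delim(file.path(d, "truth.tsv"),
                          stringsAsFactors = FALSE)
  expect_setequal(unique(tr$truth_class),
                  c("stringent_both", "control_only", "opto_only",
                    "nontarget"))
  expect_true(any(tr$ribo_log2fc > 0) && any(tr$ribo_log2fc < 0))
})

test_that("multi-isoform mode exercises representative selection", {
  ds <- generate_dataset(generator_params(n_genes = 40,
                                          isoforms_per_gene = 3,
                                          clip_library_size = 5e4,
                                          ribo_library_size = 5e4,
                                          include_markers = FALSE,
                                          seed = 16))
  expect_equal(nrow(ds$truth), 120)
  lens <- transcript_lengths(ds$models)
  ribo_tpm <- compute_tpm(subset_samples(ds$ribo_counts,
                                         assay = "RiboTag-IP"), lens)
  sel <- suppressMessages(
    select_representative_transcripts(ribo_tpm, ds$models))
  expect_lte(nrow(sel), 40)
  expect_false(anyDuplicated(sel$gene_id) > 0)
  # primary isoforms carry ~3x the abundance of the next one: they win
  picked_primary <- ds$truth$is_primary[match(sel$transcript_id,
                                              ds$truth$transcript_id)]
  expect_gt(mean(picked_primary), 0.9)
})

test_that("written datasets read back with identical counts and truth", {
  ds <- generate_dataset(generator_params(n_genes = 30,
                                          clip_library_size = 1e4,
                                          ribo_library_size = 1e4,
                                          include_markers = FALSE,
                                          seed = 17))
  dir <- tempfile()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$clip_counts$counts, ds$clip_counts$counts)
  expect_equal(back$ribo_counts$counts, ds$ribo_counts$counts)
  expect_equal(back$truth$truth_class, ds$truth$truth_class)
  expect_equal(sort(transcript_lengths(back$models)),
               sort(transcript_lengths(ds$models)))
})
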