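#' Parameters for the synthetic dataset generator
#'
#' Describes the statistical structure the analysis assumes: RiboTag Input
#' counts are negative-binomial around a log-normal abundance profile, IP
#' counts add cell-type marker enrichment and condition fold-changes for a
#' minority of genes, and CLIP tag counts follow a log-linear relation to
#' RiboTag abundance with per-transcript binding offsets (stringent targets)
#' and condition-specific binding shifts, sampled compositionally
#' (multinomially) to a fixed tag library size.
#'
#' Truth classes are planted on the CLIP-score (log2) scale so that they are
#' commensurate with the classification thresholds: stringent-in-both genes
#' carry binding offset `beta_effect` in both conditions; FMRP-Down genes
#' carry `beta_effect` in control shifted by `delta_down` in Opto;
#' FMRP-Up genes carry `beta_effect + delta_down` in control shifted by
#' `delta_up` in Opto.
#'
#' @param n_genes Number of genes (default 5000).
#' @param isoforms_per_gene Transcripts per gene (default 1; extra isoforms
#'   exist only to exercise representative-transcript selection).
#' @param slope,intercept Log-linear CLIP-vs-RiboTag relation (default 1.0,
#'   -2.0).
#' @param clip_noise_sd Replicate-level CLIP noise, log2 units (default 0.5).
#' @param clip_library_size CLIP tags (UMTs) per replicate (default 2e6).
#' @param ribo_library_size RiboTag reads per sample (default 1e6).
#' @param abund_meanlog,abund_sdlog Log-normal abundance profile (natural
#'   log; default meanlog 3, sdlog 1.5).
#' @param nb_dispersion NB dispersion of RiboTag counts (default 0.05).
#' @param frac_stringent Fraction of genes stringent in both conditions
#'   (default 0.1).
#' @param frac_fmrp_down,frac_fmrp_up Fractions with activity-reduced /
#'   -increased FMRP binding (default 0.05, 0.01).
#' @param beta_effect Binding offset of stringent targets, score units
#'   (default 3).
#' @param delta_down,delta_up Condition binding shifts (default -2, +2).
#' @param frac_ribo_up,frac_ribo_down Fractions with RiboTag condition
#'   fold-changes (default 0.025, 0.03).
#' @param ribo_lfc_effect |log2 fold change| of changed RiboTag genes
#'   (default 1).
#' @param n_clip_reps,n_ribo_reps Biological replicates per condition
#'   (default 4 CLIP, 3 RiboTag).
#' @param include_markers Plant the cell-type marker panel (default TRUE).
#' @param marker_enrichment |log2 IP/Input| planted on marker genes
#'   (default 2; excitatory markers enriched, others depleted).
#' @param pseudocount TPM pseudocount used when forming the log2 RiboTag
#'   abundance that drives CLIP generation (default 0.01, matching the
#'   analysis default).
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated list of class `"generator_params"`.
#' @export
generator_params <- function(n_genes = 5000,
                             isoforms_per_gene = 1,
                             slope = 1.0,
                             intercept = -2.0,
                             clip_noise_sd = 0.5,
                             clip_library_size = 2e6,
                             ribo_library_size = 1e6,
                             abund_meanlog = 3,
                             abund_sdlog = 1.5,
                             nb_dispersion = 0.05,
                             frac_stringent = 0.1,
                             frac_fmrp_down = 0.05,
                             frac_fmrp_up = 0.01,
                             beta_effect = 3,
                             delta_down = -2,
                             delta_up = 2,
                             frac_ribo_up = 0.025,
                             frac_ribo_down = 0.03,
                             ribo_lfc_effect = 1,
                             n_clip_reps = 4,
                             n_ribo_reps = 3,
                             include_markers = TRUE,
                             marker_enrichment = 2,
                             pseudocount = 0.01,
                             seed = 1L) {
  p <- mget(names(formals()))
  fr <- c(frac_stringent, frac_fmrp_down, frac_fmrp_up)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("binding-class fractions must lie in [0,1] and jointly sum to <= 1")
  fr2 <- c(frac_ribo_up, frac_ribo_down)
  if (any(fr2 < 0) || sum(fr2) > 1)
    stop("RiboTag fractions must lie in [0,1] and jointly sum to <= 1")
  if (clip_noise_sd <= 0) stop("clip_noise_sd must be positive")
  if (nb_dispersion < 0) stop("nb_dispersion must be non-negative")
  if (n_genes < 3) stop("need at least 3 genes")
  p$n_genes <- as.integer(n_genes)
  p$isoforms_per_gene <- as.integer(isoforms_per_gene)
  p$seed <- as.integer(seed)
  class(p) <- "generator_params"
  p
}

#' Generate a complete synthetic dataset with known ground truth
#'
#' Produces CLIP tag counts (4 replicates x 2 conditions by default),
#' RiboTag IP and Input counts (3 replicates x 2 conditions), gene models,
#' and a per-transcript truth table. RiboTag condition fold-changes act on
#' the IP samples (ribosome-associated RNA); Input abundance is
#' condition-invariant. CLIP expected log2 TPM per replicate is
#' `intercept + slope * x + beta (+ delta in Opto) + Normal(0, sd)` where
#' `x` is the realized condition-mean log2 RiboTag IP TPM, and tag counts
#' are drawn multinomially to the library size from the implied TPM
#' composition. Because TPM is compositional, the multinomial closure adds
#' a per-replicate constant to the expected line; the constant actually
#' realized is recorded in the `expected_fits` element so recovery tests
#' can compare against the line the data truly follow.
#'
#' @param params A `"generator_params"` object.
#' @return A list of class `"synthetic_dataset"`: `clip_counts`,
#'   `ribo_counts` (both `"count_matrix"`), `models`
#'   (`"transcript_models"`), `truth` (data frame), `expected_fits` (data
#'   frame condition/replicate/slope/intercept_realized), `params`.
#' @export
generate_dataset <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  set.seed(p$seed)
  n <- p$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  marker_set <- rep(NA_character_, n)
  enrich <- rep(0, n)
  if (p$include_markers) {
    panel <- default_marker_panel()
    syms <- unlist(panel$genes, use.names = FALSE)
    sets <- rep(names(panel$genes), lengths(panel$genes))
    k <- min(length(syms), n)
    gene_id[seq_len(k)] <- syms[seq_len(k)]
    marker_set[seq_len(k)] <- sets[seq_len(k)]
    enrich[seq_len(k)] <- p$marker_enrichment *
      panel$direction[sets[seq_len(k)]]
  }
  # binding classes planted on non-marker genes
  eligible <- which(is.na(marker_set))
  n_str <- round(p$frac_stringent * n)
  n_dn <- round(p$frac_fmrp_down * n)
  n_up <- round(p$frac_fmrp_up * n)
  pick <- sample(eligible, min(n_str + n_dn + n_up, length(eligible)))
  idx_str <- pick[seq_len(n_str)]
  idx_dn <- pick[n_str + seq_len(n_dn)]
  idx_up <- pick[n_str + n_dn + seq_len(n_up)]
  beta <- rep(0, n); delta <- rep(0, n)
  beta[idx_str] <- p$beta_effect
  beta[idx_dn] <- p$beta_effect;            delta[idx_dn] <- p$delta_down
  beta[idx_up] <- p$beta_effect + p$delta_down; delta[idx_up] <- p$delta_up
  # truth class under the generator's own thresholds (stringent > 2)
  thr <- 2
  str_ctrl <- beta > thr
  str_opto <- (beta + delta) > thr
  truth_class <- ifelse(str_ctrl & str_opto, "stringent_both",
                 ifelse(str_ctrl, "control_only",
                 ifelse(str_opto, "opto_only", "nontarget")))
  # RiboTag condition fold-changes on non-marker genes
  elig2 <- which(is.na(marker_set))
  n_ru <- round(p$frac_ribo_up * n)
  n_rd <- round(p$frac_ribo_down * n)
  pick2 <- sample(elig2, min(n_ru + n_rd, length(elig2)))
  ribo_lfc <- rep(0, n)
  ribo_lfc[pick2[seq_len(n_ru)]] <- p$ribo_lfc_effect
  ribo_lfc[pick2[n_ru + seq_len(n_rd)]] <- -p$ribo_lfc_effect
  fmrp_dir <- ifelse(delta < 0, "down", ifelse(delta > 0, "up", "unchanged"))
  ribo_dir <- ifelse(ribo_lfc > 0, "up",
                     ifelse(ribo_lfc < 0, "down", "unchanged"))
  quadrant_truth <- ifelse(fmrp_dir == "unchanged" & ribo_dir == "unchanged",
                           "unchanged",
                    ifelse(fmrp_dir == "unchanged",
                           paste0("fmrp_unchanged_ribo_", ribo_dir),
                           paste0("fmrp_", fmrp_dir, "_ribo_", ribo_dir)))
  # per-gene abundance; isoform k gets a geometric share of its gene's level
  base_rel_gene <- stats::rlnorm(n, p$abund_meanlog, p$abund_sdlog)
  iso <- p$isoforms_per_gene
  tx_gene <- rep(seq_len(n), each = iso)
  iso_idx <- rep(seq_len(iso), times = n)
  transcript_id <- paste0(gene_id[tx_gene], ".t", iso_idx)
  rel <- base_rel_gene[tx_gene] * 0.3^(iso_idx - 1)
  n_tx <- length(rel)
  lens <- pmin(pmax(round(stats::rlnorm(n_tx, log(2000), 0.35)), 300), 10000)
  models <- build_gene_models(transcript_id, gene_id[tx_gene], lens)

  nb <- function(mu) {
    if (p$nb_dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / p$nb_dispersion)
    else stats::rpois(length(mu), mu)
  }
  # RiboTag Input: condition-invariant expected composition
  w_in <- rel * lens
  mu_in <- w_in / sum(w_in) * p$ribo_library_size
  # RiboTag IP: marker enrichment; Opto additionally carries the fold-change
  rel_ip_ctrl <- rel * 2^enrich[tx_gene]
  rel_ip_opto <- rel_ip_ctrl * 2^ribo_lfc[tx_gene]
  w_ipc <- rel_ip_ctrl * lens
  w_ipo <- rel_ip_opto * lens
  mu_ip_ctrl <- w_ipc / sum(w_ipc) * p$ribo_library_size
  mu_ip_opto <- w_ipo / sum(w_ipo) * p$ribo_library_size

  ribo_cols <- list(); ribo_sheet <- list()
  for (cond in c("Control", "Opto")) {
    mu_ip <- if (cond == "Control") mu_ip_ctrl else mu_ip_opto
    for (r in seq_len(p$n_ribo_reps)) {
      ribo_cols[[paste0("RiboIP_", cond, "_", r)]] <- nb(mu_ip)
      ribo_cols[[paste0("RiboInput_", cond, "_", r)]] <- nb(mu_in)
      ribo_sheet[[length(ribo_sheet) + 1L]] <- data.frame(
        sample = c(paste0("RiboIP_", cond, "_", r),
                   paste0("RiboInput_", cond, "_", r)),
        assay = c("RiboTag-IP", "RiboTag-Input"),
        condition = cond, replicate = r, stringsAsFactors = FALSE)
    }
  }
  ribo_m <- do.call(cbind, ribo_cols)
  rownames(ribo_m) <- transcript_id
  ribo_counts <- count_matrix(ribo_m, do.call(rbind, ribo_sheet))

  # realized condition-mean log2 RiboTag IP TPM drives CLIP generation,
  # exactly as the downstream regression sees it
  ribo_tpm <- compute_tpm(subset_samples(ribo_counts, assay = "RiboTag-IP"),
                          stats::setNames(lens, transcript_id))
  clip_cols <- list(); clip_sheet <- list()
  exp_fits <- list()
  for (cond in c("Control", "Opto")) {
    x <- condition_ribo_log2(ribo_tpm, ribo_counts$samples[
      ribo_counts$samples$assay == "RiboTag-IP", , drop = FALSE],
      cond, p$pseudocount)
    d <- if (cond == "Opto") delta[tx_gene] else 0
    for (r in seq_len(p$n_clip_reps)) {
      ystar <- p$intercept + p$slope * x + beta[tx_gene] + d +
        stats::rnorm(n_tx, 0, p$clip_noise_sd)
      w <- 2^ystar
      cnt <- stats::rmultinom(1, p$clip_library_size, prob = w * lens)[, 1]
      smp <- paste0("CLIP_", cond, "_", r)
      clip_cols[[smp]] <- cnt
      clip_sheet[[length(clip_sheet) + 1L]] <- data.frame(
        sample = smp, assay = "CLIP", condition = cond, replicate = r,
        stringsAsFactors = FALSE)
      # multinomial closure: expected log2 TPM = ystar + log2(1e6/sum(w))
      exp_fits[[length(exp_fits) + 1L]] <- data.frame(
        condition = cond, replicate = r, slope = p$slope,
        intercept_realized = p$intercept + log2(1e6 / sum(w)),
        stringsAsFactors = FALSE)
    }
  }
  clip_m <- do.call(cbind, clip_cols)
  rownames(clip_m) <- transcript_id
  clip_counts <- count_matrix(clip_m, do.call(rbind, clip_sheet))

  truth <- data.frame(
    transcript_id = transcript_id,
    gene_id = gene_id[tx_gene],
    length = lens,
    base_abundance = log2(rel),
    beta_control = beta[tx_gene],
    delta = delta[tx_gene],
    ribo_log2fc = ribo_lfc[tx_gene],
    truth_class = truth_class[tx_gene],
    quadrant_truth = quadrant_truth[tx_gene],
    marker_set = marker_set[tx_gene],
    is_primary = iso_idx == 1L,
    stringsAsFactors = FALSE)
  structure(list(clip_counts = clip_counts, ribo_counts = ribo_counts,
                 models = models, truth = truth,
                 expected_fits = do.call(rbind, exp_fits), params = p),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$truth), "transcripts,",
      length(unique(x$truth$gene_id)), "genes\n")
  print(table(x$truth$truth_class))
  invisible(x)
}

# Lay transcripts out on chr1..chr5 with a two-exon structure
# (5'UTR | CDS .. intron .. CDS | 3'UTR); minus strand on even transcripts.
build_gene_models <- function(transcript_id, gene_id, lens) {
  n <- length(transcript_id)
  chroms <- paste0("chr", (seq_len(n) - 1L) %% 5L + 1L)
  strands <- ifelse(seq_len(n) %% 2L == 0L, "-", "+")
  offsets <- stats::ave(rep(1L, n), chroms, FUN = cumsum)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    L <- lens[i]
    l5 <- max(50L, round(0.1 * L))
    l3 <- max(50L, round(0.2 * L))
    cds <- L - l5 - l3
    e1 <- l5 + ceiling(cds / 2)  # exon1: 5'UTR + first half of CDS
    intron <- 300L
    s <- (offsets[i] - 1L) * 25000L + 1000L  # 1-based genomic start
    ex1 <- c(s, s + e1 - 1L)
    ex2 <- c(s + e1 + intron, s + e1 + intron + (L - e1) - 1L)
    if (strands[i] == "+") {
      parts <- list(
        five_prime_utr = c(ex1[1], ex1[1] + l5 - 1L),
        CDS_a = c(ex1[1] + l5, ex1[2]),
        CDS_b = c(ex2[1], ex2[1] + (cds - (e1 - l5)) - 1L),
        three_prime_utr = c(ex2[1] + (cds - (e1 - l5)), ex2[2]))
    } else {
      # mirror: 3'UTR at the left end, 5'UTR at the right end
      parts <- list(
        three_prime_utr = c(ex1[1], ex1[1] + l3 - 1L),
        CDS_a = c(ex1[1] + l3, ex1[2]),
        CDS_b = c(ex2[1], ex2[1] + (cds - (e1 - l3)) - 1L),
        five_prime_utr = c(ex2[1] + (cds - (e1 - l3)), ex2[2]))
    }
    ty <- sub("_[ab]$", "", names(parts))
    rows <- rbind(do.call(rbind, parts), exon1 = ex1, exon2 = ex2)
    feats[[i]] <- data.frame(
      chrom = chroms[i],
      start = rows[, 1], end = rows[, 2],
      strand = strands[i],
      type = c(ty, "exon", "exon"),
      gene_id = gene_id[i], transcript_id = transcript_id[i],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand,
    type = df$type, gene_id = df$gene_id, transcript_id = df$transcript_id)
  transcript_models(gr)
}

#' Write transcript models as GTF 2.2
#'
#' Deterministic writer (1-based inclusive coordinates, fixed attribute
#' order) so regenerated fixtures are byte-identical.
#'
#' @param models A `"transcript_models"` object.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  f <- models$features
  mc <- S4Vectors::mcols(f)
  lines <- sprintf(
    '%s\tclipribo\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    as.character(GenomicRanges::seqnames(f)),
    mc$type,
    GenomicRanges::start(f), GenomicRanges::end(f),
    as.character(GenomicRanges::strand(f)),
    mc$gene_id, mc$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Emits the same dialects the readers ingest: count TSVs plus sample
#' sheets, a GTF of gene models, the truth table, the realized expected
#' regression lines, and the generator parameters as YAML. All files are
#' deterministic given the seed.
#'
#' @param ds A `"synthetic_dataset"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file) {
    num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
    df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  cm <- function(x) data.frame(transcript_id = rownames(x$counts),
                               x$counts, check.names = FALSE,
                               stringsAsFactors = FALSE)
  wt(cm(ds$clip_counts), "clip_counts.tsv")
  wt(ds$clip_counts$samples, "clip_samples.tsv")
  wt(cm(ds$ribo_counts), "ribo_counts.tsv")
  wt(ds$ribo_counts$samples, "ribo_samples.tsv")
  wt(ds$truth, "truth.tsv")
  wt(ds$expected_fits, "expected_fits.tsv")
  write_gtf(ds$models, file.path(dir, "models.gtf"))
  prm <- unclass(ds$params)
  yaml::write_yaml(prm, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Read a synthetic dataset written by [write_dataset()]
#'
#' @param dir Directory containing the dataset files.
#' @return A `"synthetic_dataset"` (without regenerating counts).
#' @export
read_dataset <- function(dir) {
  rs <- function(f) utils::read.delim(file.path(dir, f), sep = "\t",
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE)
  clip_samples <- rs("clip_samples.tsv")
  ribo_samples <- rs("ribo_samples.tsv")
  clip_counts <- read_count_table(file.path(dir, "clip_counts.tsv"),
                                  clip_samples)
  ribo_counts <- read_count_table(file.path(dir, "ribo_counts.tsv"),
                                  ribo_samples)
  prm <- yaml::read_yaml(file.path(dir, "params.yaml"))
  params <- do.call(generator_params, prm[names(prm) %in%
                                            names(formals(generator_params))])
  structure(list(clip_counts = clip_counts, ribo_counts = ribo_counts,
                 models = read_gene_models(file.path(dir, "models.gtf")),
                 truth = rs("truth.tsv"),
                 expected_fits = rs("expected_fits.tsv"),
                 params = params),
            class = "synthetic_dataset")
}

#' Materialize a frozen fixture dataset
#'
#' `tiny` is a 50-gene dataset used for regression tests (every truth class
#' represented); `default` is the full-size default configuration. Both are
#' deterministic.
#'
#' @param name `"tiny"` or `"default"`.
#' @param dir Output directory; when NULL the dataset is returned without
#'   writing.
#' @return The `"synthetic_dataset"`, invisibly when written.
#' @export
make_fixture <- function(name = c("tiny", "default"), dir = NULL) {
  name <- match.arg(name)
  params <- switch(name,
    tiny = generator_params(n_genes = 50, clip_library_size = 50000,
                            ribo_library_size = 50000,
                            frac_stringent = 0.2, frac_fmrp_down = 0.1,
                            frac_fmrp_up = 0.1, frac_ribo_up = 0.1,
                            frac_ribo_down = 0.1,
                            include_markers = FALSE, seed = 101L),
    default = generator_params(seed = 2024L))
  ds <- generate_dataset(params)
  if (is.null(dir)) return(ds)
  write_dataset(ds, dir)
  invisible(ds)
}
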