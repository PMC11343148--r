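#' Annotate CLIP tags with genomic feature classes
#'
#' Assigns every tag to exactly one of CDS, 3'UTR, 5'UTR, noncoding exon,
#' intron or intergenic by maximal base overlap with strand-matched
#' features; ties break by the precedence
#' CDS > 3'UTR > 5'UTR > noncoding_exon > intron. UTRs come from explicit
#' `five_prime_utr`/`three_prime_utr` features when the models carry them,
#' otherwise from exonic sequence outside the CDS, split by position
#' relative to the CDS on the transcript's strand. Introns are the gaps
#' between a transcript's exons. Tags on chromosomes absent from the models
#' are labeled intergenic (counted in the `n_unknown_chrom` attribute).
#'
#' @param tags `GRanges` of tags (e.g. from [read_tags_bed()]), strand
#'   required.
#' @param models A `"transcript_models"` object.
#' @return Data frame, one row per tag: `chrom`, `start` (0-based, BED
#'   convention), `end`, `strand`, `replicate`, `label`, `gene_id`.
#' @export
annotate_tags <- function(tags, models) {
  stopifnot(methods::is(tags, "GRanges"),
            inherits(models, "transcript_models"))
  if (any(as.character(GenomicRanges::strand(tags)) == "*"))
    stop("tags must be stranded")
  classes <- feature_classes(models)
  precedence <- c("CDS", "three_prime_utr", "five_prime_utr",
                  "noncoding_exon", "intron")
  n <- length(tags)
  ov <- matrix(0L, n, length(precedence),
               dimnames = list(NULL, precedence))
  gene_best <- matrix(NA_character_, n, length(precedence))
  for (k in seq_along(precedence)) {
    fr <- classes[[precedence[k]]]
    if (is.null(fr) || length(fr) == 0L) next
    # seqlevel mismatches are reported via the unknown-chromosome counter
    hits <- suppressWarnings(GenomicRanges::findOverlaps(tags, fr))
    if (length(hits) == 0L) next
    w <- GenomicRanges::width(IRanges::pintersect(
      IRanges::ranges(tags)[S4Vectors::queryHits(hits)],
      IRanges::ranges(fr)[S4Vectors::subjectHits(hits)]))
    # total overlap per tag within the class (features pre-reduced per gene)
    tot <- tapply(w, S4Vectors::queryHits(hits), sum)
    ov[as.integer(names(tot)), k] <- as.integer(tot)
    # gene with the single largest overlap decides the gene assignment
    ord <- order(S4Vectors::queryHits(hits), -w)
    first <- !duplicated(S4Vectors::queryHits(hits)[ord])
    qh <- S4Vectors::queryHits(hits)[ord][first]
    gene_best[qh, k] <-
      S4Vectors::mcols(fr)$gene_id[S4Vectors::subjectHits(hits)[ord][first]]
  }
  best <- apply(ov, 1, function(v)
    if (all(v == 0L)) 0L else which.max(v))  # which.max takes first = precedence
  label <- ifelse(best == 0L, "intergenic", precedence[pmax(best, 1L)])
  gene <- ifelse(best == 0L, NA_character_,
                 gene_best[cbind(seq_len(n), pmax(best, 1L))])
  known <- as.character(GenomicRanges::seqnames(tags)) %in%
    unique(as.character(GenomicRanges::seqnames(models$features)))
  if (any(!known))
    warning(sum(!known), " tag(s) on chromosomes absent from the models")
  pretty <- c(CDS = "CDS", three_prime_utr = "3'UTR",
              five_prime_utr = "5'UTR", noncoding_exon = "noncoding_exon",
              intron = "intron", intergenic = "intergenic")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(tags)),
    start = GenomicRanges::start(tags) - 1L,  # back to BED convention
    end = GenomicRanges::end(tags),
    strand = as.character(GenomicRanges::strand(tags)),
    replicate = S4Vectors::mcols(tags)$replicate,
    label = unname(pretty[label]),
    gene_id = gene,
    stringsAsFactors = FALSE)
  attr(out, "n_unknown_chrom") <- sum(!known)
  out
}

# Build per-class strand-aware feature GRanges (reduced within gene) from a
# transcript_models object, deriving UTRs and introns where needed.
feature_classes <- function(models) {
  f <- models$features
  ty <- S4Vectors::mcols(f)$type
  cds <- f[ty == "CDS"]
  ex <- f[ty == "exon"]
  utr5 <- f[ty == "five_prime_utr"]
  utr3 <- f[ty == "three_prime_utr"]
  coding_tx <- unique(S4Vectors::mcols(cds)$transcript_id)
  if (length(utr5) == 0L && length(utr3) == 0L && length(cds) > 0L) {
    d <- derive_utrs(ex, cds, coding_tx)
    utr5 <- d$utr5; utr3 <- d$utr3
  }
  nc_ex <- ex[!(S4Vectors::mcols(ex)$transcript_id %in% coding_tx)]
  introns <- derive_introns(ex)
  list(CDS = reduce_by_gene(cds),
       three_prime_utr = reduce_by_gene(utr3),
       five_prime_utr = reduce_by_gene(utr5),
       noncoding_exon = reduce_by_gene(nc_ex),
       intron = reduce_by_gene(introns))
}

reduce_by_gene <- function(gr) {
  if (is.null(gr) || length(gr) == 0L) return(gr)
  grl <- GenomicRanges::split(gr, S4Vectors::mcols(gr)$gene_id)
  red <- GenomicRanges::reduce(grl)
  out <- unlist(red, use.names = TRUE)
  S4Vectors::mcols(out)$gene_id <- names(out)
  names(out) <- NULL
  out
}

derive_introns <- function(ex) {
  if (length(ex) == 0L) return(GenomicRanges::GRanges())
  grl <- GenomicRanges::split(ex, S4Vectors::mcols(ex)$transcript_id)
  gaps <- GenomicRanges::psetdiff(unlist(range(grl)), grl)
  tx2gene <- tapply(S4Vectors::mcols(ex)$gene_id,
                    S4Vectors::mcols(ex)$transcript_id, `[`, 1)
  out <- unlist(gaps, use.names = TRUE)
  if (length(out) == 0L) return(GenomicRanges::GRanges())
  S4Vectors::mcols(out)$gene_id <- unname(tx2gene[names(out)])
  S4Vectors::mcols(out)$transcript_id <- names(out)
  names(out) <- NULL
  out
}

# Exonic sequence outside the CDS, split into 5'/3' UTR by position
# relative to the CDS on the transcript's strand.
derive_utrs <- function(ex, cds, coding_tx) {
  u5 <- list(); u3 <- list()
  for (tx in coding_tx) {
    e <- ex[S4Vectors::mcols(ex)$transcript_id == tx]
    cc <- cds[S4Vectors::mcols(cds)$transcript_id == tx]
    if (length(e) == 0L || length(cc) == 0L) next
    utr <- GenomicRanges::setdiff(e, cc, ignore.strand = FALSE)
    if (length(utr) == 0L) next
    minus <- as.character(GenomicRanges::strand(e))[1] == "-"
    cds_start <- min(GenomicRanges::start(cc))
    cds_end <- max(GenomicRanges::end(cc))
    before <- GenomicRanges::end(utr) < cds_start
    after <- GenomicRanges::start(utr) > cds_end
    gid <- S4Vectors::mcols(e)$gene_id[1]
    add <- function(gr) {
      S4Vectors::mcols(gr)$gene_id <- gid
      S4Vectors::mcols(gr)$transcript_id <- tx
      gr
    }
    five <- if (minus) utr[after] else utr[before]
    three <- if (minus) utr[before] else utr[after]
    if (length(five)) u5[[length(u5) + 1L]] <- add(five)
    if (length(three)) u3[[length(u3) + 1L]] <- add(three)
  }
  cat0 <- function(l) if (length(l)) do.call(c, l) else GenomicRanges::GRanges()
  list(utr5 = cat0(u5), utr3 = cat0(u3))
}

#' Feature distribution of CLIP tags by biological complexity
#'
#' Collapses tags to crosslink sites (same chromosome and strand, 5' ends
#' within `site_merge_window` nt; default 0 = exact match), scores each
#' site's biological complexity as the number of replicates containing it,
#' and tabulates the feature-label distribution of sites at every BC floor
#' (BC >= 1 up to the number of replicates). A site's label is the
#' highest-precedence label among its tags.
#'
#' @param ann Per-tag annotation from [annotate_tags()]; the `replicate`
#'   column must be populated.
#' @param site_merge_window Maximum 5'-end distance (nt) for tags to share a
#'   site (default 0).
#' @return A list of class `"bc_distribution"`: `fractions` (matrix, BC
#'   floors x feature labels, rows sum to 1), `site_counts` (sites per BC
#'   floor), `sites` (per-site data frame).
#' @export
bc_distribution <- function(ann, site_merge_window = 0) {
  reps <- unique(ann$replicate)
  n_rep <- length(reps)
  if (n_rep < 2L)
    warning("single replicate: biological complexity is trivially 1")
  five_prime <- ifelse(ann$strand == "+", ann$start, ann$end)
  key_group <- paste(ann$chrom, ann$strand)
  ord <- order(key_group, five_prime)
  site_id <- integer(nrow(ann))
  cur <- 0L
  last_group <- ""
  last_pos <- -Inf
  for (i in ord) {
    if (key_group[i] != last_group ||
        five_prime[i] - last_pos > site_merge_window) {
      cur <- cur + 1L
    }
    site_id[i] <- cur
    last_group <- key_group[i]
    last_pos <- five_prime[i]
  }
  labels_order <- c("CDS", "3'UTR", "5'UTR", "noncoding_exon", "intron",
                    "intergenic")
  lab_rank <- match(ann$label, labels_order)
  bc <- tapply(ann$replicate, site_id, function(r) length(unique(r)))
  site_lab <- labels_order[tapply(lab_rank, site_id, min)]
  sites <- data.frame(site = as.integer(names(bc)),
                      bc = as.integer(bc),
                      label = site_lab,
                      stringsAsFactors = FALSE)
  floors <- seq_len(max(n_rep, 1L))
  fr <- matrix(0, length(floors), length(labels_order),
               dimnames = list(paste0("BC>=", floors), labels_order))
  cnt <- integer(length(floors))
  for (i in floors) {
    sel <- sites$bc >= i
    cnt[i] <- sum(sel)
    if (cnt[i] > 0)
      fr[i, ] <- table(factor(sites$label[sel],
                              levels = labels_order)) / cnt[i]
  }
  structure(list(fractions = fr,
                 site_counts = stats::setNames(cnt, rownames(fr)),
                 sites = sites),
            class = "bc_distribution")
}

#' @export
print.bc_distribution <- function(x, ...) {
  cat("bc_distribution over", nrow(x$sites), "sites\n")
  print(round(x$fractions, 3))
  invisible(x)
}
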