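# Shared helpers: small in-code fixtures for unit tests.

tiny_dir <- function() {
  d <- system.file("extdata", "tiny", package = "clipribo")
  if (!nzchar(d)) skip("tiny fixture not installed")
  d
}

# A minimal CLIP count matrix: 3 transcripts x 4 replicates, one condition.
small_clip_counts <- function(counts = NULL) {
  if (is.null(counts))
    counts <- matrix(c(10, 5, 0,
                       0, 5, 1,
                       7, 2, 3,
                       1, 1, 1), nrow = 3,
                     dimnames = list(c("t1", "t2", "t3"), NULL))
  colnames(counts) <- paste0("CLIP_Control_", seq_len(ncol(counts)))
  count_matrix(counts, data.frame(sample = colnames(counts), assay = "CLIP",
                                  condition = "Control",
                                  replicate = seq_len(ncol(counts))))
}

# Random count matrix with CLIP labels for property tests.
random_count_matrix <- function(n_tx = 20, n_smp = 4) {
  m <- matrix(rpois(n_tx * n_smp, lambda = 30), n_tx,
              dimnames = list(sprintf("t%03d", seq_len(n_tx)),
                              paste0("CLIP_Control_", seq_len(n_smp))))
  count_matrix(m, data.frame(sample = colnames(m), assay = "CLIP",
                             condition = "Control",
                             replicate = seq_len(n_smp)))
}

# Two-gene models on one chromosome for annotation tests.
# geneA (+, chr1): exons 101-300 and 501-700; CDS 151-300 + 501-600;
#   so 5'UTR 101-150, 3'UTR 601-700, intron 301-500.
# geneB (-, chr1): single exon 1001-1400, CDS 1101-1300;
#   minus strand => 5'UTR 1301-1400, 3'UTR 1001-1100.
# geneC (+, chr2): noncoding single exon 101-400.
toy_models <- function() {
  gr <- GenomicRanges::GRanges(
    seqnames = c(rep("chr1", 4), rep("chr1", 1), rep("chr2", 1)),
    ranges = IRanges::IRanges(
      start = c(101, 501, 151, 501, 1001, 101),
      end = c(300, 700, 300, 600, 1400, 400)),
    strand = c("+", "+", "+", "+", "-", "+"),
    type = c("exon", "exon", "CDS", "CDS", "exon", "exon"),
    gene_id = c("geneA", "geneA", "geneA", "geneA", "geneB", "geneC"),
    transcript_id = c("geneA.t1", "geneA.t1", "geneA.t1", "geneA.t1",
                      "geneB.t1", "geneC.t1"))
  cds_b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1101, 1300), "-",
                                  type = "CDS", gene_id = "geneB",
                                  transcript_id = "geneB.t1")
  transcript_models(c(gr, cds_b))
}

# Make a GRanges of tags quickly (1-based inclusive, as read_tags_bed yields).
make_tags <- function(chrom, start, end, strand, replicate = 1L) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand,
                         name = paste0("tag", seq_along(start)), score = 1L,
                         replicate = replicate)
}
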