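toy_gtf <- function() system.file("extdata", "toy_synthetic.gtf",
                                  package = "exonchrom")
toy_fa <- function() system.file("extdata", "toy_synthetic.fa",
                                 package = "exonchrom")
toy_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_annotation(toy_gtf(), toy_fa())
    cache
  }
})

# a random in-memory exon_model-shaped object (no genome) for distance tests
random_mini_model <- function(n_tx = 3, n_exons = 4) {
  strand <- sample(c("+", "-"), 1)
  exs <- list()
  txs <- list()
  for (t in seq_len(n_tx)) {
    start0 <- sample(1000:5000, 1)
    starts <- start0 + cumsum(c(0, sample(200:800, n_exons - 1,
                                          replace = TRUE)))
    widths <- sample(50:150, n_exons, replace = TRUE)
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(starts, width = widths),
                                 strand = strand)
    rank <- if (strand == "-") rev(seq_len(n_exons)) else seq_len(n_exons)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      gene_id = "G1", transcript_id = paste0("T", t), exon_rank = rank)
    exs[[t]] <- gr
    txs[[t]] <- data.frame(
      transcript_id = paste0("T", t), gene_id = "G1", chrom = "chr1",
      strand = strand, n_exons = n_exons,
      tss = if (strand == "-") max(GenomicRanges::end(gr))
            else min(GenomicRanges::start(gr)),
      tts = if (strand == "-") min(GenomicRanges::start(gr))
            else max(GenomicRanges::end(gr)),
      stringsAsFactors = FALSE)
  }
  structure(list(exons = do.call(c, exs), transcripts = do.call(rbind, txs),
                 genome = NULL),
            class = "exon_model")
}

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# simple FASTA writer for inline fixtures
write_fa_tmp <- function(seqs) {
  f <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]]))), f)
  f
}

mappability_track <- function(chrom, start, end, score = 1) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), score = score)
}
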