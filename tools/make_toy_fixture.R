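# Builds the hand-enumerable synthetic toy annotation fixture.
# Candidate-exon expectations (hand enumeration, documented in the tests):
#   gene TA (+): E2 cassette, E3            -> candidates
#   gene TB (+): F2 (40 bp, too short), F3 (GC donor), F4 (500 bp, too long)
#   gene TC (+): G2 (<600 nt from TSS), G3 (overlapped by TD H2)
#   gene TD (+): H2 (overlaps G3; also <600 from TSS)
#   gene TE (+): K2 (first exon of TE.2), K3 -> candidate
#   gene TG (-): M2, M3                      -> candidates
#   gene TH (chrY): Y2 (disallowed chromosome)
# Expected candidates: TA E2 [2001,2150], TA E3 [2901,3050],
#   TE K3 [14751,14900], TG M2 [17901,18050], TG M3 [18751,18900]
set.seed(424242)

chr1_len <- 20500
chrY_len <- 3200
s1 <- sample(c("A", "C", "G", "T"), chr1_len, replace = TRUE)
sY <- sample(c("A", "C", "G", "T"), chrY_len, replace = TRUE)

tx <- list(
  # gene, transcript, strand, chrom, exon starts, exon ends
  list("TA", "TA.1", "+", "chr1", c(1001, 2001, 2901, 3801),
       c(1200, 2150, 3050, 4000)),
  list("TA", "TA.2", "+", "chr1", c(1001, 2901, 3801),
       c(1200, 3050, 4000)),
  list("TB", "TB.1", "+", "chr1", c(5001, 5901, 6600, 7450, 8650),
       c(5200, 5940, 6749, 7949, 8849)),
  list("TC", "TC.1", "+", "chr1", c(9001, 9501, 10401, 11251),
       c(9200, 9650, 10550, 11450)),
  list("TD", "TD.1", "+", "chr1", c(10001, 10480, 11900),
       c(10100, 10600, 11990)),
  list("TE", "TE.1", "+", "chr1", c(13001, 13901, 14751, 15601),
       c(13200, 14050, 14900, 15800)),
  list("TE", "TE.2", "+", "chr1", c(13901, 14751, 15601),
       c(14050, 14900, 15800)),
  list("TG", "TG.1", "-", "chr1", c(17001, 17901, 18751, 19651),
       c(17200, 18050, 18900, 19850)),
  list("TH", "TH.1", "+", "chrY", c(1001, 1901, 2751),
       c(1200, 2050, 2950)))

plant <- function(seqv, starts, ends, strand) {
  for (i in seq_len(length(starts) - 1)) {
    is <- ends[i] + 1
    ie <- starts[i + 1] - 1
    if (strand == "+") {
      seqv[is:(is + 1)] <- c("G", "T")
      seqv[(ie - 1):ie] <- c("A", "G")
    } else {
      seqv[is:(is + 1)] <- c("C", "T")   # revcomp(AG)
      seqv[(ie - 1):ie] <- c("A", "C")   # revcomp(GT)
    }
  }
  seqv
}
for (t in tx) {
  if (t[[4]] == "chr1") s1 <- plant(s1, t[[5]], t[[6]], t[[3]])
  else sY <- plant(sY, t[[5]], t[[6]], t[[3]])
}
# break TB F3's donor: downstream intron [6750, 7449] begins GC, not GT
s1[6750:6751] <- c("G", "C")

lines <- character(0)
for (t in tx) {
  for (i in seq_along(t[[5]])) {
    lines <- c(lines, sprintf(
      '%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      t[[4]], t[[5]][i], t[[6]][i], t[[3]], t[[1]], t[[2]]))
  }
}
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
writeLines(lines, "inst/extdata/toy_synthetic.gtf")

wrap <- function(s) {
  n <- length(s)
  starts <- seq(1, n, by = 60)
  vapply(starts, function(i) paste(s[i:min(i + 59, n)], collapse = ""), "")
}
writeLines(c(">chr1", wrap(s1), ">chrY", wrap(sY)),
           "inst/extdata/toy_synthetic.fa")
cat("wrote fixture\n")
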