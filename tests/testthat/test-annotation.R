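test_that("annotation loading builds ordered transcript models", {
  m <- toy_model()
  expect_equal(nrow(m$transcripts), 9)
  expect_equal(length(unique(m$exons$gene_id)), 7)
  # gene TA: 2 transcripts, 4 distinct exons
  ta <- m$exons[m$exons$gene_id == "TA"]
  expect_equal(length(unique(m$exons$transcript_id[m$exons$gene_id == "TA"])),
               2)
  expect_equal(length(unique(GenomicRanges::start(ta))), 4)
  # minus-strand gene TG: rank 1 is the rightmost exon
  tg <- m$exons[m$exons$transcript_id == "TG.1"]
  expect_equal(GenomicRanges::start(tg[tg$exon_rank == 1]), 19651)
  expect_equal(m$transcripts$tss[m$transcripts$transcript_id == "TG.1"],
               19850)
})

test_that("empty GTF gives an empty model; missing chromosome errors", {
  fa <- write_fa_tmp(list(chr1 = "ACGTACGTACGT"))
  empty <- write_lines_tmp(character(0), ".gtf")
  m <- load_annotation(empty, fa)
  expect_equal(length(m$exons), 0)
  bad <- write_lines_tmp(paste0("chrZ\ttoy\texon\t1\t10\t.\t+\t.\t",
                                'gene_id "g"; transcript_id "t";'), ".gtf")
  expect_error(load_annotation(bad, fa), "chrZ")
})

test_that("candidate selection applies all six criteria (hand enumeration)", {
  cand <- select_candidate_exons(toy_model())
  expect_setequal(
    cand$exon_id,
    c("chr1:2001-2150:+",    # TA cassette E2
      "chr1:2901-3050:+",    # TA internal E3
      "chr1:14751-14900:+",  # TE K3
      "chr1:17901-18050:-",  # TG M2 (minus strand)
      "chr1:18751-18900:-")) # TG M3
  # each exclusion rule is exercised by a specific fixture exon:
  excluded <- c("chr1:5901-5940:+",    # F2: 40 bp, too short
                "chr1:6600-6749:+",    # F3: GC donor (non-canonical)
                "chr1:7450-7949:+",    # F4: 500 bp, too long
                "chr1:9501-9650:+",    # G2: 300 nt from TSS
                "chr1:10401-10550:+",  # G3: overlapped by TD exon
                "chr1:10480-10600:+",  # H2: overlaps G3
                "chr1:13901-14050:+",  # K2: first exon of TE.2
                "chrY:1901-2050:+")    # Y2: disallowed chromosome
  expect_length(intersect(cand$exon_id, excluded), 0)
  # chrY exon passes every other rule: allowing chrY admits it
  cand_y <- select_candidate_exons(toy_model(),
                                   chroms = c("chr1", "chrY"))
  expect_true("chrY:1901-2050:+" %in% cand_y$exon_id)
})

test_that("catalog is invariant to transcript record order", {
  lines <- readLines(toy_gtf())
  set.seed(9)
  shuffled <- write_lines_tmp(sample(lines), ".gtf")
  m2 <- load_annotation(shuffled, toy_fa())
  cand1 <- select_candidate_exons(toy_model())
  cand2 <- select_candidate_exons(m2)
  expect_setequal(cand1$exon_id, cand2$exon_id)
})

test_that("candidate exons carry exact flanking-intron coordinates", {
  cand <- select_candidate_exons(toy_model())
  e2 <- cand[cand$exon_id == "chr1:2001-2150:+"]
  expect_equal(e2$up_intron_start, 1201)
  expect_equal(e2$up_intron_end, 2000)
  expect_equal(e2$down_intron_start, 2151)
  expect_equal(e2$down_intron_end, 2900)
  expect_equal(e2$skip_intron_start, 1201)
  expect_equal(e2$skip_intron_end, 2900)
  # minus-strand exon M2 [17901,18050]: upstream intron is genomic-right
  m2 <- cand[cand$exon_id == "chr1:17901-18050:-"]
  expect_equal(m2$up_intron_start, 18051)
  expect_equal(m2$up_intron_end, 18750)
  expect_equal(m2$down_intron_start, 17201)
  expect_equal(m2$down_intron_end, 17900)
})

test_that("TSS distance equals brute-force minimum over member transcripts", {
  m <- toy_model()
  e2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 2150),
                               strand = "+")
  expect_equal(distance_to_annotated_tss(e2, m), 1000)
  tgm2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(17901, 18050),
                                 strand = "-")
  expect_equal(distance_to_annotated_tss(tgm2, m), 19850 - 18050)
  # randomized models vs exhaustive loop
  set.seed(21)
  for (i in 1:60) {
    mm <- random_mini_model()
    ex <- mm$exons
    pick <- sample(length(ex), 1)
    exon <- GenomicRanges::granges(ex[pick])
    key <- paste0("chr1:", GenomicRanges::start(exon), "-",
                  GenomicRanges::end(exon), ":",
                  as.character(GenomicRanges::strand(exon)))
    keys <- paste0("chr1:", GenomicRanges::start(ex), "-",
                   GenomicRanges::end(ex), ":",
                   as.character(GenomicRanges::strand(ex)))
    member <- unique(ex$transcript_id[keys == key])
    first_nt <- if (as.character(GenomicRanges::strand(exon)) == "-")
      GenomicRanges::end(exon) else GenomicRanges::start(exon)
    brute <- Inf
    for (txid in member) {
      tss <- mm$transcripts$tss[mm$transcripts$transcript_id == txid]
      brute <- min(brute, abs(first_nt - tss))
    }
    expect_equal(distance_to_annotated_tss(exon, mm), brute)
  }
})

test_that("mappable fraction over the acceptor window", {
  e2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 2150),
                               strand = "+")
  # acceptor at 2001; window [1551, 2450]
  expect_equal(mappable_fraction(e2, mappability_track("chr1", 1, 30000)), 1)
  expect_equal(mappable_fraction(e2, mappability_track("chr1", 1551, 2150)),
               600 / 900, tolerance = 1e-12)
  # values below 1 count as unmappable
  half <- c(mappability_track("chr1", 1551, 2000, score = 0.5),
            mappability_track("chr1", 2001, 2450, score = 1))
  expect_equal(mappable_fraction(e2, half), 450 / 900)
  # truncation at chromosome start
  e_near <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300),
                                   strand = "+")
  expect_equal(mappable_fraction(e_near, mappability_track("chr1", 1, 1000)),
               1)
})

test_that("splice-site strength: PWM log-odds scorer", {
  # uniform PWM scores 0 for any sequence
  uni_d <- matrix(0.25, 4, 9)
  uni_a <- matrix(0.25, 4, 23)
  sc <- pwm_scorer(uni_d, uni_a)
  m <- toy_model()
  e2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 2150),
                               strand = "+")
  s <- splice_site_strength(e2, m$genome, sc)
  expect_equal(s$total, 0)
  # consensus-matching site scores the PWM maximum
  don_seq <- as.character(Biostrings::subseq(m$genome[["chr1"]], 2148, 2156))
  cons_d <- matrix(0.04, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  ch <- strsplit(don_seq, "")[[1]]
  for (j in 1:9) cons_d[ch[j], j] <- 0.88
  sc2 <- pwm_scorer(cons_d, uni_a)
  s2 <- splice_site_strength(e2, m$genome, sc2)
  expect_equal(s2$donor, 9 * log2(0.88 / 0.25), tolerance = 1e-12)
  expect_true(s2$donor >= max(colSums(log2(cons_d / 0.25))) - 1e-9)
  # random PWM equals naive per-position log-odds sum
  set.seed(14)
  rp <- matrix(stats::runif(36, 0.05, 0.9), 4)
  rp <- sweep(rp, 2, colSums(rp), "/")
  ra <- matrix(stats::runif(92, 0.05, 0.9), 4)
  ra <- sweep(ra, 2, colSums(ra), "/")
  rownames(rp) <- rownames(ra) <- c("A", "C", "G", "T")
  s3 <- splice_site_strength(e2, m$genome, pwm_scorer(rp, ra))
  acc_seq <- as.character(Biostrings::subseq(m$genome[["chr1"]], 1981, 2003))
  naive <- function(seq, pwm) {
    tot <- 0
    ch <- strsplit(seq, "")[[1]]
    for (j in seq_along(ch)) tot <- tot + log2(pwm[ch[j], j] / 0.25)
    unname(tot)
  }
  expect_equal(s3$total, naive(don_seq, rp) + naive(acc_seq, ra),
               tolerance = 1e-12)
  # N in window -> undefined
  fa_n <- write_fa_tmp(list(c1 = paste0(strrep("A", 30), "N",
                                        strrep("A", 100))))
  gN <- Biostrings::readDNAStringSet(fa_n)
  # N at position 31 falls in the acceptor window [20, 42] of exon [40, 80]
  eN <- GenomicRanges::GRanges("c1", IRanges::IRanges(40, 80), strand = "+")
  sN <- splice_site_strength(eN, gN, sc)
  expect_true(is.na(sN$total))
})

test_that("exon triplets pick nearest non-significant flanks", {
  m <- toy_model()
  e2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 2150),
                               strand = "+")
  none_sig <- data.frame(exon_id = character(0), q_more = numeric(0),
                         q_less = numeric(0))
  tri <- build_exon_triplets(e2, none_sig, m)
  expect_true(tri$complete)
  expect_equal(GenomicRanges::start(tri$upstream), 1001)    # E1
  expect_equal(GenomicRanges::start(tri$downstream), 2901)  # E3
  # adjacent flank significant -> skip to next-nearest (E4)
  sig_e3 <- data.frame(exon_id = "chr1:2901-3050:+",
                       q_more = 0.001, q_less = 0.9)
  tri2 <- build_exon_triplets(e2, sig_e3, m)
  expect_equal(GenomicRanges::start(tri2$downstream), 3801) # E4
  # first/last-exon neighbour exhausted -> incomplete
  sig_e1_e3 <- data.frame(exon_id = c("chr1:1001-1200:+",
                                      "chr1:2901-3050:+",
                                      "chr1:3801-4000:+"),
                          q_more = c(0.001, 0.001, 0.001),
                          q_less = c(0.9, 0.9, 0.9))
  tri3 <- build_exon_triplets(e2, sig_e1_e3, m)
  expect_false(tri3$complete)
})

test_that("junction counting requires exact intron coordinates", {
  cand <- select_candidate_exons(toy_model())
  e2 <- cand[cand$exon_id == "chr1:2001-2150:+"]
  junc <- data.frame(
    chrom = "chr1",
    intron_start = c(1201, 2151, 1201, 1202),
    intron_end =   c(2000, 2900, 2900, 2000),
    strand = "+", cell = "c1", replicate = "rep1",
    count = c(3, 3, 3, 99),   # last row off by one: ignored
    stringsAsFactors = FALSE)
  cc <- count_junctions(junc, e2)
  expect_equal(cc$JIR_up, 3)
  expect_equal(cc$JIR_down, 3)
  expect_equal(cc$JER, 3)
})
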