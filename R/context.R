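#' Gene expression from CAGE clusters
#'
#' Each CAGE cluster is assigned to the closest annotated TSS within
#' \code{radius} nucleotides (gap distance; 0 when the cluster covers the
#' TSS); clusters farther than the radius from every TSS are unassigned.
#' The expression of a gene is the sum of the scores of all clusters
#' assigned to any of its TSSs.  A cluster equidistant from two TSSs goes
#' to the leftmost (smallest coordinate) one.
#'
#' @param cage GRanges of CAGE clusters with a numeric \code{score}.
#' @param tss data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{pos} (one row per annotated TSS; e.g. derived from an
#'   \code{exon_model}'s transcript table).
#' @return Named numeric vector of expression per gene (genes with no
#'   assigned cluster get 0).
#' @export
gene_expression_from_cage <- function(cage, tss, radius = 100) {
  stopifnot(all(c("gene_id", "chrom", "pos") %in% names(tss)))
  genes <- unique(tss$gene_id)
  expr <- stats::setNames(rep(0, length(genes)), genes)
  if (length(cage) == 0 || nrow(tss) == 0) return(expr)
  cchrom <- as.character(GenomicRanges::seqnames(cage))
  cs <- GenomicRanges::start(cage)
  ce <- GenomicRanges::end(cage)
  for (i in seq_along(cage)) {
    cand <- tss[tss$chrom == cchrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    # gap distance from cluster interval to TSS point
    d <- pmax(0, pmax(cand$pos - ce[i], cs[i] - cand$pos))
    within <- which(d <= radius)
    if (length(within) == 0) next
    best <- within[order(d[within], cand$pos[within])][1]
    g <- cand$gene_id[best]
    expr[g] <- expr[g] + cage$score[i]
  }
  expr
}

#' Extract the annotated TSS table from an exon model
#'
#' @param model An \code{exon_model}.
#' @return data.frame with \code{gene_id}, \code{transcript_id},
#'   \code{chrom}, \code{pos}, \code{strand}.
#' @export
annotated_tss <- function(model) {
  stopifnot(inherits(model, "exon_model"))
  tx <- model$transcripts
  data.frame(gene_id = tx$gene_id, transcript_id = tx$transcript_id,
             chrom = tx$chrom, pos = tx$tss, strand = tx$strand,
             stringsAsFactors = FALSE)
}

#' Distance from an exon to the closest used TSS
#'
#' A "used" TSS is a CAGE cluster with score at least \code{min_score},
#' independent of annotation.  The distance is measured from the exon's
#' first nucleotide (5' end in transcription direction) to the nearest
#' qualifying cluster interval on the same chromosome (0 when the cluster
#' covers that position).
#'
#' @param exon Length-1 GRanges.
#' @param cage GRanges of CAGE clusters with \code{score}.
#' @param min_score Minimum cluster score to count as used (default 1).
#' @return Distance in nucleotides, or NA when no qualifying cluster exists
#'   on the chromosome.
#' @export
distance_to_used_tss <- function(exon, cage, min_score = 1) {
  stopifnot(length(exon) == 1)
  chrom <- as.character(GenomicRanges::seqnames(exon))
  used <- cage[as.character(GenomicRanges::seqnames(cage)) == chrom &
                 !is.na(cage$score) & cage$score >= min_score]
  if (length(used) == 0) return(NA_real_)
  first_nt <- if (as.character(GenomicRanges::strand(exon)) == "-")
    GenomicRanges::end(exon) else GenomicRanges::start(exon)
  d <- pmax(0, pmax(GenomicRanges::start(used) - first_nt,
                    first_nt - GenomicRanges::end(used)))
  min(d)
}

#' Tally which cell has the closer active TSS per exon comparison
#'
#' For each promoter-like exon comparison, compares the distance to the
#' closest used TSS in the C-higher versus the C-lower cell line.
#'
#' @param dist_higher,dist_lower Numeric vectors of used-TSS distances (NA
#'   where undefined).
#' @return list of counts: \code{closer_in_Chigher},
#'   \code{closer_in_Clower}, \code{same}, \code{undefined}.
#' @export
compare_tss_proximity <- function(dist_higher, dist_lower) {
  stopifnot(length(dist_higher) == length(dist_lower))
  undef <- is.na(dist_higher) | is.na(dist_lower)
  dh <- dist_higher[!undef]; dl <- dist_lower[!undef]
  list(closer_in_Chigher = sum(dh < dl),
       closer_in_Clower = sum(dh > dl),
       same = sum(dh == dl),
       undefined = sum(undef))
}

#' Count ChIA-PET interactions anchored on an exon
#'
#' An interaction counts when at least one of its two anchors overlaps the
#' (optionally padded) exon interval.
#'
#' @param exon Length-1 GRanges.
#' @param links data.frame in BEDPE-like form: \code{chrom1},
#'   \code{start1}, \code{end1}, \code{chrom2}, \code{start2}, \code{end2}
#'   (1-based closed here; the BEDPE reader converts), plus optional
#'   \code{support}.
#' @param pad Symmetric padding in bp added to the exon (default 0).
#' @return list: \code{count} (number of links) and \code{has_interaction}.
#' @export
count_chia_pet_interactions <- function(exon, links, pad = 0) {
  stopifnot(length(exon) == 1)
  chrom <- as.character(GenomicRanges::seqnames(exon))
  lo <- GenomicRanges::start(exon) - pad
  hi <- GenomicRanges::end(exon) + pad
  ov <- function(c, s, e) c == chrom & s <= hi & e >= lo
  hit <- ov(links$chrom1, links$start1, links$end1) |
    ov(links$chrom2, links$start2, links$end2)
  list(count = sum(hit), has_interaction = any(hit))
}

#' Read a BEDPE interaction file (0-based half-open on disk)
#'
#' @param path BEDPE path; columns 1-6 anchors, optional 7th name, 8th
#'   score used as \code{support}.
#' @return data.frame with 1-based closed anchor coordinates and
#'   \code{support}.
#' @export
read_bedpe <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom1 = df[[1]], start1 = df[[2]] + 1L, end1 = df[[3]],
                    chrom2 = df[[4]], start2 = df[[5]] + 1L, end2 = df[[6]],
                    stringsAsFactors = FALSE)
  out$support <- if (ncol(df) >= 8) as.numeric(df[[8]]) else 1
  out
}

#' Does one chromatin state run connect an exon to its used TSS?
#'
#' Adjacent segments with identical state labels are merged; the answer is
#' TRUE iff the exon midpoint and the TSS position fall inside the same
#' contiguous merged run (a gap in the segmentation between them breaks the
#' run).
#'
#' @param exon Length-1 GRanges.
#' @param tss_pos Genomic position of the used TSS (same chromosome).
#' @param segmentation GRanges with a \code{state} (or \code{name}) label
#'   column.
#' @return Logical.
#' @export
same_state_extension <- function(exon, tss_pos, segmentation) {
  stopifnot(length(exon) == 1)
  chrom <- as.character(GenomicRanges::seqnames(exon))
  seg <- segmentation[as.character(
    GenomicRanges::seqnames(segmentation)) == chrom]
  if (length(seg) == 0) return(FALSE)
  lab <- if (!is.null(seg$state)) seg$state else seg$name
  if (is.null(lab)) stop("segmentation needs a 'state' or 'name' column")
  o <- order(GenomicRanges::start(seg))
  seg <- seg[o]; lab <- lab[o]
  s <- GenomicRanges::start(seg); e <- GenomicRanges::end(seg)
  # merge adjacent same-label segments (contiguous: next start == end + 1)
  run <- cumsum(c(1L, as.integer(
    lab[-1] != lab[-length(lab)] | s[-1] != e[-length(s)] + 1L)))
  mid <- floor((GenomicRanges::start(exon) + GenomicRanges::end(exon)) / 2)
  inside <- function(pos) {
    i <- which(s <= pos & e >= pos)
    if (length(i) == 0) NA_integer_ else run[i[1]]
  }
  r1 <- inside(mid); r2 <- inside(tss_pos)
  !is.na(r1) && !is.na(r2) && r1 == r2
}

#' Mark fold-changes at exons versus their closest used TSS
#'
#' For each promoter-like exon comparison and each mark, computes the
#' C-higher minus C-lower differential EAS (log2, pseudocount 1) on the
#' exon and on a window of +/- \code{tss_halfwidth} bp around the closest
#' used TSS, and tests per mark whether the exon change exceeds the TSS
#' change (paired Wilcoxon signed-rank on the per-exon differences).
#'
#' @param exons GRanges of promoter-like exons (one per comparison).
#' @param tss_pos Numeric vector of used-TSS positions (same order).
#' @param tracks_higher,tracks_lower Named lists of signal GRanges, one per
#'   mark, for the C-higher / C-lower cell line of each comparison.  When a
#'   single cell pair is analyzed these are plain per-mark lists; for mixed
#'   pairs call per pair and rbind.
#' @param tss_halfwidth Half-width of the TSS window (default 200).
#' @param pseudocount For the log2 transform.
#' @return list: \code{per_exon} data.frame (exon index, mark, delta_exon,
#'   delta_tss) and \code{tests} data.frame (mark, paired signed-rank p,
#'   median paired difference).
#' @export
tss_vs_exon_mark_shift <- function(exons, tss_pos, tracks_higher,
                                   tracks_lower, tss_halfwidth = 200,
                                   pseudocount = 1) {
  stopifnot(length(exons) == length(tss_pos),
            identical(names(tracks_higher), names(tracks_lower)))
  marks <- names(tracks_higher)
  tssgr <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(exons)),
    IRanges::IRanges(pmax(1, tss_pos - tss_halfwidth),
                     tss_pos + tss_halfwidth))
  per <- do.call(rbind, lapply(marks, function(m) {
    d_ex <- differential_eas(tracks_lower[[m]], tracks_higher[[m]], exons,
                             transform = "log2", pseudocount = pseudocount)
    d_ts <- differential_eas(tracks_lower[[m]], tracks_higher[[m]], tssgr,
                             transform = "log2", pseudocount = pseudocount)
    data.frame(exon = seq_along(exons), mark = m,
               delta_exon = d_ex, delta_tss = d_ts,
               stringsAsFactors = FALSE)
  }))
  tests <- do.call(rbind, lapply(marks, function(m) {
    sub <- per[per$mark == m, ]
    dd <- sub$delta_exon - sub$delta_tss
    p <- if (all(dd == 0)) 1 else stats::wilcox.test(dd, mu = 0)$p.value
    data.frame(mark = m, p = p, median_diff = stats::median(dd),
               stringsAsFactors = FALSE)
  }))
  list(per_exon = per, tests = tests)
}

#' Hypergeometric motif enrichment in foreground exons
#'
#' Over-representation of each motif among foreground exons relative to the
#' pooled foreground + background universe, by the hypergeometric upper
#' tail, BH-corrected across motifs.  The occurrence matrix is binary
#' (exon x motif), produced by any scanner or supplied directly.
#'
#' @param occurrence Logical/0-1 matrix, rows = exons, columns = motifs.
#' @param foreground Logical or integer index of foreground rows (must be
#'   non-empty and a strict subset of rows).
#' @return data.frame per motif: foreground hits, universe hits, p
#'   (upper-tail hypergeometric), q (BH).  Motifs with no hit anywhere get
#'   p = 1.
#' @export
motif_enrichment <- function(occurrence, foreground) {
  stopifnot(is.matrix(occurrence))
  fg <- if (is.logical(foreground)) which(foreground) else foreground
  if (length(fg) == 0) stop("empty foreground")
  N <- nrow(occurrence)
  nf <- length(fg)
  K <- colSums(occurrence != 0)
  k <- colSums(occurrence[fg, , drop = FALSE] != 0)
  # P(X >= k) with X ~ Hypergeom(K successes, N - K failures, nf draws)
  p <- ifelse(K == 0, 1,
              stats::phyper(k - 1, K, N - K, nf, lower.tail = FALSE))
  data.frame(motif = colnames(occurrence), fg_hits = k, total_hits = K,
             p = p, q = bh_adjust(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' CAGE occupancy over exons versus annotated TSS regions
#'
#' Average CAGE tag signal over each exon, compared with the distribution
#' over annotated-TSS windows; used to check that promoter-like exons are
#' not simply unannotated transcription start sites.
#'
#' @param exons GRanges.
#' @param cage_track Signal GRanges of CAGE tag density.
#' @param tss_windows GRanges of annotated-TSS windows for the reference
#'   distribution (optional).
#' @return list: \code{exon_eas} numeric per exon; \code{tss_eas} numeric
#'   per TSS window (NULL when not supplied).
#' @export
cage_occupancy_in_exons <- function(exons, cage_track, tss_windows = NULL) {
  list(exon_eas = exonic_average_signal(cage_track, exons),
       tss_eas = if (is.null(tss_windows)) NULL
       else exonic_average_signal(cage_track, tss_windows))
}
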