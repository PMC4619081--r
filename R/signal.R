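#' Read a signal track (bedGraph or bigWig) as a GRanges
#'
#' Piecewise-constant, non-negative coverage-style tracks; uncovered
#' positions are treated as signal 0 by all consumers.
#'
#' @param path File path; format inferred from extension by rtracklayer.
#' @return GRanges with a numeric \code{score} column.
#' @export
read_signal_track <- function(path) {
  gr <- rtracklayer::import(path)
  if (is.null(gr$score)) stop("track has no score column: ", path)
  gr
}

#' Exonic average signal (EAS)
#'
#' Arithmetic mean of the per-base track value across each interval.
#' Computed by overlap arithmetic (sum of overlap-width x segment score
#' divided by interval width), which equals the naive per-base mean because
#' tracks are piecewise constant.  Positions not covered by the track
#' contribute 0.
#'
#' @param track GRanges with \code{score} (strandless signal).
#' @param intervals GRanges of query intervals (strand ignored).
#' @return Numeric vector, one mean per interval.
#' @export
exonic_average_signal <- function(track, intervals) {
  stopifnot(all(GenomicRanges::width(intervals) >= 1))
  hits <- GenomicRanges::findOverlaps(intervals, track, ignore.strand = TRUE)
  if (length(hits) == 0) return(numeric(length(intervals)))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov_w <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(intervals)[q], GenomicRanges::ranges(track)[s]))
  contrib <- ov_w * track$score[s]
  tot <- rep(0, length(intervals))
  agg <- tapply(contrib, q, sum)
  tot[as.integer(names(agg))] <- agg
  tot / GenomicRanges::width(intervals)
}

#' Differential exonic average signal between two cell lines
#'
#' Difference of the exonic average signal on the same genomic interval in
#' cell2 minus cell1 (the same orientation convention as delta-PSI).  The
#' default transform is a log2 ratio with pseudocount, which damps
#' depth-driven scale differences; \code{transform = "raw"} gives the plain
#' difference.
#'
#' @param track1,track2 Signal GRanges for cell1 / cell2.
#' @param intervals GRanges.
#' @param transform \code{"log2"} (default) or \code{"raw"}.
#' @param pseudocount Added inside the log2 (default 1).
#' @return Numeric vector of differential signals (cell2 - cell1).
#' @export
differential_eas <- function(track1, track2, intervals,
                             transform = c("log2", "raw"), pseudocount = 1) {
  transform <- match.arg(transform)
  e1 <- exonic_average_signal(track1, intervals)
  e2 <- exonic_average_signal(track2, intervals)
  if (transform == "raw") e2 - e1
  else log2(e2 + pseudocount) - log2(e1 + pseudocount)
}

#' Binned differential-signal profile around exon centers
#'
#' For each exon, a window of \code{width} bp centered on the exon midpoint
#' is split into \code{width / bin} bins and the differential EAS (cell2 -
#' cell1) is computed per bin.  Bins are oriented in transcription
#' direction (reversed for minus-strand exons), so bin 1 is the most
#' upstream.  Windows truncated by the chromosome start are flagged.
#'
#' @param track1,track2 Signal GRanges.
#' @param exons GRanges (strand used for orientation).
#' @param width,bin Window and bin size in bp (defaults 800, 20).
#' @inheritParams differential_eas
#' @return list with \code{profile} (n_exons x n_bins matrix),
#'   \code{mean}, \code{se} (per-bin across exons) and \code{truncated}
#'   (logical per exon).
#' @export
window_profile <- function(track1, track2, exons, width = 800, bin = 20,
                           transform = c("log2", "raw"), pseudocount = 1) {
  transform <- match.arg(transform)
  stopifnot(width %% bin == 0)
  nb <- width %/% bin
  n <- length(exons)
  prof <- matrix(NA_real_, n, nb)
  truncated <- logical(n)
  centers <- floor((GenomicRanges::start(exons) +
                    GenomicRanges::end(exons)) / 2)
  for (i in seq_len(n)) {
    lo <- centers[i] - width %/% 2
    starts <- lo + bin * (0:(nb - 1))
    ends <- starts + bin - 1
    ok <- starts >= 1
    truncated[i] <- any(!ok)
    gr <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(exons))[i],
      IRanges::IRanges(starts[ok], ends[ok]))
    d <- differential_eas(track1, track2, gr, transform = transform,
                          pseudocount = pseudocount)
    vals <- rep(NA_real_, nb)
    vals[ok] <- d
    if (as.character(GenomicRanges::strand(exons))[i] == "-")
      vals <- rev(vals)
    prof[i, ] <- vals
  }
  mu <- colMeans(prof, na.rm = TRUE)
  se <- apply(prof, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  })
  list(profile = prof, mean = mu, se = se, truncated = truncated)
}

# signed-rank p with all-zero guard
.signed_rank_p <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0 || all(x == 0)) return(1)
  stats::wilcox.test(x, mu = 0)$p.value
}

#' Group-level association tests of differential signals
#'
#' For each chromatin feature, tests whether differential signals depart
#' from zero within the more-included and less-included groups (Wilcoxon
#' signed-rank) and whether the two groups differ (Wilcoxon rank-sum).
#' All p-values are Bonferroni-corrected by the number of features (capped
#' at 1).  Direction is the sign of the group median.
#'
#' @param delta_more,delta_less Numeric matrices (rows = exon comparisons,
#'   columns = features, same column names) of differential signals.
#' @param n_features Bonferroni denominator; defaults to the number of
#'   columns.
#' @return data.frame, one row per feature: signed-rank p for each group,
#'   rank-sum p between groups (all Bonferroni-adjusted), and the group
#'   median directions.
#' @export
group_association_test <- function(delta_more, delta_less,
                                   n_features = ncol(delta_more)) {
  stopifnot(ncol(delta_more) == ncol(delta_less),
            identical(colnames(delta_more), colnames(delta_less)))
  if (nrow(delta_more) < 5 || nrow(delta_less) < 5)
    stop("each group needs at least 5 observations")
  adj <- function(p) pmin(1, p * n_features)
  res <- lapply(seq_len(ncol(delta_more)), function(j) {
    xm <- delta_more[, j]; xl <- delta_less[, j]
    rs <- if (all(xm == 0) && all(xl == 0)) 1
    else stats::wilcox.test(xm, xl)$p.value
    data.frame(feature = colnames(delta_more)[j],
               p_signed_more = adj(.signed_rank_p(xm)),
               p_signed_less = adj(.signed_rank_p(xl)),
               p_ranksum = adj(rs),
               direction_more = sign(stats::median(xm, na.rm = TRUE)),
               direction_less = sign(stats::median(xl, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
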