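# Independent brute-force oracles used across tests.  These deliberately
# avoid the code paths they check.

# one-sided Fisher p via explicit hypergeometric enumeration with choose()
oracle_fisher_onesided <- function(a, b, c, d, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  if (tail == "upper") sum(probs[xs >= a]) else sum(probs[xs <= a])
}

# BH from its definition: q(i) = min_{j >= i} min(1, m p_(j) / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# per-base exonic average signal: literal loop over positions
oracle_eas <- function(track_df, chrom, start, end) {
  vals <- numeric(end - start + 1)
  for (pos in start:end) {
    hit <- which(track_df$chrom == chrom & track_df$start <= pos &
                   track_df$end >= pos)
    if (length(hit) > 0) vals[pos - start + 1] <- sum(track_df$score[hit])
  }
  mean(vals)
}

# exact signed-rank null distribution by enumerating all sign assignments
oracle_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  # two-sided: doubled smaller tail, capped at 1 (matches wilcox.test exact)
  mu <- n * (n + 1) / 4
  p <- 2 * min(mean(Ws >= W), mean(Ws <= W))
  min(1, p)
}

# closed-form hypergeometric upper tail for motif enrichment
oracle_hyper_upper <- function(k, K, N, n) {
  xs <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(probs[xs >= k])
}

track_df_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         score = df$score)
}

random_track_df <- function(chrom = "chr1", n_seg = 10, lo = 1, hi = 500) {
  bounds <- sort(sample(lo:hi, n_seg + 1))
  data.frame(chrom = chrom,
             start = bounds[-length(bounds)],
             end = pmax(bounds[-1] - 1, bounds[-length(bounds)]),
             score = round(stats::runif(n_seg, 0, 5), 2))
}
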