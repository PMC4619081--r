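#' Exon inclusion level (percent spliced in) from junction reads
#'
#' The inclusion level (PSI) of a cassette exon is estimated from splice
#' junction reads: \code{JIR} inclusion reads span either exon-to-flank
#' junction (and are therefore counted twice per included molecule), while
#' \code{JER} exclusion reads span the single flank-to-flank skipping
#' junction.  The 0.5 factor corrects the double counting:
#' \deqn{\psi = \frac{0.5\,JIR}{0.5\,JIR + JER}}
#'
#' @param jir Integer vector, junction inclusion reads (upstream + downstream
#'   inclusion junctions, pooled over replicates).
#' @param jer Integer vector, junction exclusion reads.
#' @return Numeric vector of inclusion levels in \[0, 1\]; \code{NA} where
#'   \code{jir + jer == 0} (exon unquantifiable in that cell).
#' @examples
#' inclusion_level(8, 2)   # 0.6667
#' inclusion_level(0, 5)   # 0
#' @export
inclusion_level <- function(jir, jer) {
  stopifnot(all(jir >= 0, na.rm = TRUE), all(jer >= 0, na.rm = TRUE))
  psi <- 0.5 * jir / (0.5 * jir + jer)
  psi[jir + jer == 0] <- NA_real_
  psi
}

#' Replicate concordance filter for inclusion levels
#'
#' Stand-in for the irreproducible discovery rate (IDR) procedure used on
#' ENCODE replicates: an exon passes in a given cell if its two replicate
#' inclusion estimates agree within \code{max_delta}.  An undefined estimate
#' in either replicate fails the exon.
#'
#' @param psi_rep1,psi_rep2 Numeric vectors of replicate inclusion levels
#'   (may contain \code{NA}).
#' @param max_delta Maximum tolerated absolute difference (default 0.1).
#' @return Logical vector: \code{TRUE} where the exon passes.
#' @export
replicate_concordance_filter <- function(psi_rep1, psi_rep2, max_delta = 0.1) {
  ok <- abs(psi_rep1 - psi_rep2) <= max_delta
  ok[is.na(ok)] <- FALSE
  ok
}

#' One-sided Fisher exact tests for differential exon inclusion
#'
#' For each exon a 2x2 table of (inclusion reads, exclusion reads) x
#' (cell1, cell2) is tested with both one-sided Fisher exact tests.
#' \code{p_more} tests for greater inclusion in cell2, \code{p_less} for
#' greater inclusion in cell1 (orientation: "more included" always means
#' higher in cell2 throughout the package).
#'
#' Exons are testable only when there is at least one inclusion read in one
#' cell and at least one exclusion read in the other (either orientation);
#' untestable exons get \code{NA} p-values.
#'
#' @param jir1,jer1 Inclusion / exclusion read counts in cell1 (pooled over
#'   replicates).
#' @param jir2,jer2 Same for cell2.
#' @return A data.frame with columns \code{p_more}, \code{p_less},
#'   \code{testable}.
#' @export
differential_inclusion_test <- function(jir1, jer1, jir2, jer2) {
  stopifnot(length(jir1) == length(jer1),
            length(jir1) == length(jir2),
            length(jir1) == length(jer2))
  testable <- (jir1 >= 1 & jer2 >= 1) | (jir2 >= 1 & jer1 >= 1)
  # Hypergeometric tails of the 2x2 table [jir1 jir2; jer1 jer2].
  # X = inclusion reads observed in cell1, drawn from jir1+jir2 inclusion
  # and jer1+jer2 exclusion reads, with jir1+jer1 draws.
  m <- jir1 + jir2          # white balls: inclusion reads
  n <- jer1 + jer2          # black balls: exclusion reads
  k <- jir1 + jer1          # draws: reads in cell1
  # inclusion greater in cell1 <=> X >= jir1 (upper tail) => p_less
  p_less <- stats::phyper(jir1 - 1, m, n, k, lower.tail = FALSE)
  # inclusion greater in cell2 <=> X <= jir1 (lower tail) => p_more
  p_more <- stats::phyper(jir1, m, n, k, lower.tail = TRUE)
  p_more[!testable] <- NA_real_
  p_less[!testable] <- NA_real_
  data.frame(p_more = pmin(p_more, 1), p_less = pmin(p_less, 1),
             testable = testable)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment; thin wrapper kept as an explicit
#' operation so the correction applied per cell pair and per tail is a
#' single, testable code path.
#'
#' @param p Numeric vector of p-values (NA allowed, passed through).
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Classify tested exons into more / less / notAS sets
#'
#' BH adjustment is applied across all testable exons of one cell pair,
#' separately for each one-sided tail; an exon is \code{more} if its
#' more-tail q is below \code{alpha} (inclusion higher in cell2),
#' \code{less} if the less-tail q is below \code{alpha}, and \code{notAS}
#' otherwise.  The two one-sided tests on the same table cannot both be
#' significant at alpha <= 0.5.
#'
#' @param tests data.frame from [differential_inclusion_test()] (one cell
#'   pair; rows = exons).
#' @param alpha Significance level on BH-adjusted q-values (default 0.05).
#' @return The input with added columns \code{q_more}, \code{q_less},
#'   \code{class} (factor: more/less/notAS, NA where untestable).
#' @export
classify_exons <- function(tests, alpha = 0.05) {
  stopifnot(is.data.frame(tests),
            all(c("p_more", "p_less", "testable") %in% names(tests)))
  q_more <- rep(NA_real_, nrow(tests))
  q_less <- rep(NA_real_, nrow(tests))
  idx <- which(tests$testable)
  q_more[idx] <- bh_adjust(tests$p_more[idx])
  q_less[idx] <- bh_adjust(tests$p_less[idx])
  sig_more <- !is.na(q_more) & q_more < alpha
  sig_less <- !is.na(q_less) & q_less < alpha
  if (any(sig_more & sig_less))
    stop("exon significant in both one-sided tails; inconsistent input")
  cls <- rep(NA_character_, nrow(tests))
  cls[idx] <- "notAS"
  cls[sig_more] <- "more"
  cls[sig_less] <- "less"
  tests$q_more <- q_more
  tests$q_less <- q_less
  tests$class <- factor(cls, levels = c("more", "less", "notAS"))
  tests
}

#' Full differential inclusion call for one cell pair
#'
#' Convenience wrapper: pools replicate counts, applies the replicate
#' concordance filter per cell, computes inclusion levels, runs both
#' one-sided Fisher tests, BH-adjusts and classifies.
#'
#' @param counts data.frame with columns \code{exon_id}, \code{cell},
#'   \code{replicate}, \code{JIR_up}, \code{JIR_down}, \code{JER}.
#' @param cell1,cell2 Cell labels to compare; "more included" means higher
#'   inclusion in \code{cell2}.
#' @param alpha BH significance level.
#' @param max_rep_delta Replicate concordance tolerance on PSI.
#' @return data.frame, one row per exon: \code{exon_id}, pooled counts,
#'   \code{psi1}, \code{psi2}, \code{delta_psi} (= psi2 - psi1),
#'   \code{fold} (= max ratio of the two PSIs), p/q-values and \code{class}.
#' @export
call_differential_inclusion <- function(counts, cell1, cell2, alpha = 0.05,
                                        max_rep_delta = 0.1) {
  stopifnot(all(c("exon_id", "cell", "replicate", "JIR_up", "JIR_down",
                  "JER") %in% names(counts)))
  cells <- unique(counts$cell)
  if (!all(c(cell1, cell2) %in% cells))
    stop("cell labels not present in counts: ",
         paste(setdiff(c(cell1, cell2), cells), collapse = ", "))
  pool_cell <- function(cell) {
    cc <- counts[counts$cell == cell, , drop = FALSE]
    jir <- cc$JIR_up + cc$JIR_down
    pooled <- stats::aggregate(cbind(JIR = jir, JER = cc$JER),
                               by = list(exon_id = cc$exon_id), FUN = sum)
    # replicate concordance on per-replicate PSI
    reps <- split(cc, cc$replicate)
    if (length(reps) >= 2) {
      psi_by_rep <- lapply(reps[1:2], function(r) {
        psi <- inclusion_level(r$JIR_up + r$JIR_down, r$JER)
        stats::setNames(psi, r$exon_id)
      })
      ids <- pooled$exon_id
      pooled$concordant <- replicate_concordance_filter(
        psi_by_rep[[1]][as.character(ids)],
        psi_by_rep[[2]][as.character(ids)],
        max_delta = max_rep_delta)
    } else {
      pooled$concordant <- TRUE
    }
    pooled
  }
  c1 <- pool_cell(cell1)
  c2 <- pool_cell(cell2)
  ids <- sort(union(c1$exon_id, c2$exon_id))
  i1 <- match(ids, c1$exon_id)
  i2 <- match(ids, c2$exon_id)
  jir1 <- ifelse(is.na(i1), 0L, c1$JIR[i1])
  jer1 <- ifelse(is.na(i1), 0L, c1$JER[i1])
  jir2 <- ifelse(is.na(i2), 0L, c2$JIR[i2])
  jer2 <- ifelse(is.na(i2), 0L, c2$JER[i2])
  conc <- ifelse(is.na(i1), FALSE, c1$concordant[i1]) &
          ifelse(is.na(i2), FALSE, c2$concordant[i2])
  tst <- differential_inclusion_test(jir1, jer1, jir2, jer2)
  tst$testable <- tst$testable & conc
  tst$p_more[!tst$testable] <- NA_real_
  tst$p_less[!tst$testable] <- NA_real_
  res <- classify_exons(tst, alpha = alpha)
  psi1 <- inclusion_level(jir1, jer1)
  psi2 <- inclusion_level(jir2, jer2)
  fold <- pmax(psi2 / psi1, psi1 / psi2)
  data.frame(exon_id = ids, cell1 = cell1, cell2 = cell2,
             JIR1 = jir1, JER1 = jer1, JIR2 = jir2, JER2 = jer2,
             psi1 = psi1, psi2 = psi2,
             delta_psi = psi2 - psi1, fold = fold,
             concordant = conc, res,
             stringsAsFactors = FALSE)
}

#' Post-hoc regulation filters on classified exons
#'
#' Keeps significantly regulated exon comparisons that additionally satisfy:
#' effect size (absolute PSI change >= \code{min_abs_delta} OR PSI
#' fold-change >= \code{min_fold}, in either direction), host-gene
#' expression stability (CAGE-derived expression fold between the two cells
#' <= \code{max_expr_fold}), and junction mappability
#' (>= \code{min_mappable} of the 900-bp acceptor window uniquely
#' mappable).  Exons with zero expression in one cell (fold undefined) are
#' excluded.
#'
#' @param calls data.frame from [call_differential_inclusion()] with a
#'   \code{gene_id} column.
#' @param expr1,expr2 Named numeric vectors (by gene id) of gene expression
#'   in cell1 / cell2.
#' @param mappable Named numeric vector (by exon id) of mappable fraction.
#' @param min_abs_delta,min_fold,max_expr_fold,min_mappable Filter
#'   thresholds.
#' @return The subset of \code{calls} with class more/less passing all
#'   filters, with an added \code{expr_fold} column.
#' @export
apply_regulation_filters <- function(calls, expr1, expr2, mappable,
                                     min_abs_delta = 0.1, min_fold = 2,
                                     max_expr_fold = 10, min_mappable = 0.75) {
  stopifnot("gene_id" %in% names(calls))
  reg <- calls[!is.na(calls$class) & calls$class != "notAS", , drop = FALSE]
  if (nrow(reg) == 0) return(reg)
  e1 <- expr1[as.character(reg$gene_id)]
  e2 <- expr2[as.character(reg$gene_id)]
  expr_fold <- pmax(e1 / e2, e2 / e1)
  expr_fold[!is.finite(expr_fold)] <- NA_real_   # zero or missing expression
  reg$expr_fold <- unname(expr_fold)
  mp <- unname(mappable[as.character(reg$exon_id)])
  effect <- abs(reg$delta_psi) >= min_abs_delta |
    (!is.na(reg$fold) & reg$fold >= min_fold)
  keep <- effect &
    !is.na(reg$expr_fold) & reg$expr_fold <= max_expr_fold &
    !is.na(mp) & mp >= min_mappable
  reg[keep, , drop = FALSE]
}

#' Select one exon per gene and direction
#'
#' Genes with many cassette exons (e.g. titin) would otherwise dominate the
#' regulated set, so at most one more-included and one less-included exon is
#' kept per gene: the one with the lowest Fisher p-value in its direction.
#' For the notAS background the exon with the minimal absolute estimated
#' inclusion change is kept instead.  Ties break to the leftmost exon
#' (smallest start coordinate; exon id as final tie-break), so selection is
#' deterministic.
#'
#' @param calls data.frame with \code{gene_id}, \code{exon_id},
#'   \code{class}, p-values and \code{delta_psi}; a \code{start} column is
#'   used for tie-breaking when present.
#' @param mode \code{"regulated"} (default) or \code{"notAS"}.
#' @return Subset of \code{calls}.
#' @export
pick_exon_per_gene <- function(calls, mode = c("regulated", "notAS")) {
  mode <- match.arg(mode)
  if (nrow(calls) == 0) return(calls)
  start <- if ("start" %in% names(calls)) calls$start else rep(0, nrow(calls))
  pick <- function(df, key) {
    o <- order(key, start[as.integer(rownames(df))], df$exon_id)
    df[o[1], , drop = FALSE]
  }
  rownames(calls) <- seq_len(nrow(calls))
  if (mode == "regulated") {
    out <- lapply(c("more", "less"), function(dir) {
      sub <- calls[!is.na(calls$class) & calls$class == dir, , drop = FALSE]
      if (nrow(sub) == 0) return(sub)
      p <- if (dir == "more") sub$p_more else sub$p_less
      do.call(rbind, lapply(split(sub, sub$gene_id), function(df) {
        key <- if (dir == "more") df$p_more else df$p_less
        o <- order(key, start[as.integer(rownames(df))], df$exon_id)
        df[o[1], , drop = FALSE]
      }))
    })
    out <- do.call(rbind, out)
  } else {
    sub <- calls[!is.na(calls$class) & calls$class == "notAS", , drop = FALSE]
    if (nrow(sub) == 0) return(sub)
    out <- do.call(rbind, lapply(split(sub, sub$gene_id), function(df) {
      o <- order(abs(df$delta_psi), start[as.integer(rownames(df))],
                 df$exon_id)
      df[o[1], , drop = FALSE]
    }))
  }
  rownames(out) <- NULL
  out
}

#' Inclusion range of an exon across cells
#'
#' @param psi Numeric vector of per-cell inclusion levels (NA dropped).
#' @return max - min over defined values (0 for a single cell).
#' @export
inclusion_range <- function(psi) {
  psi <- psi[!is.na(psi)]
  if (length(psi) == 0) return(NA_real_)
  max(psi) - min(psi)
}
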