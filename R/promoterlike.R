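#' Column-standardize a differential-signal matrix
#'
#' Each feature column is centered and scaled to unit standard deviation so
#' that k-means distances weight chromatin features equally and cluster
#' means are interpretable in z-units.  Zero-variance columns become all
#' zeros with a warning.
#'
#' @param x Numeric matrix (>= 2 rows) with named feature columns.
#' @return Matrix of the same shape, each column mean 0 / SD 1.
#' @export
standardize_features <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  zero <- sdv == 0 | is.na(sdv)
  if (any(zero)) {
    warning("zero-variance feature column(s): ",
            paste(colnames(x)[zero], collapse = ", "))
    sdv[zero] <- 1
  }
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  z[, zero] <- 0
  z
}

#' K-means partition of exon comparisons by differential chromatin signal
#'
#' Clusters the rows of a (standardized) differential-signal matrix for one
#' direction group (more-included and less-included exon comparisons are
#' clustered separately).  Many random restarts make the partition stable;
#' cluster ids are relabeled in descending order of the mean value of
#' \code{order_by} so labels are comparable across runs.
#'
#' @param x Numeric matrix, rows = exon comparisons of one direction group.
#' @param k Number of clusters (default 4).
#' @param restarts Random restarts (default 100).
#' @param seed Integer RNG seed (required for reproducibility).
#' @param order_by Column name used for stable labeling (default
#'   \code{"H3K9ac"}; falls back to the first column if absent).
#' @return list: \code{cluster} (integer per row), \code{centers}
#'   (k x features, input units), \code{size}, \code{tot_withinss}.
#' @export
kmeans_partition <- function(x, k = 4, restarts = 100, seed,
                             order_by = "H3K9ac") {
  stopifnot(is.matrix(x))
  if (nrow(x) < k) stop("fewer rows (", nrow(x), ") than clusters (", k, ")")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100)
  j <- if (!is.null(colnames(x)) && order_by %in% colnames(x))
    match(order_by, colnames(x)) else 1L
  relabel <- order(km$centers[, j], decreasing = TRUE)
  new_id <- match(seq_len(k), relabel)     # old id -> new id
  list(cluster = new_id[km$cluster],
       centers = km$centers[relabel, , drop = FALSE],
       size = km$size[relabel],
       tot_withinss = km$tot.withinss)
}

#' Within-cluster inertia across a range of k
#'
#' Convenience report for choosing k (the discovery analysis fixed k = 4).
#'
#' @inheritParams kmeans_partition
#' @param ks Integer vector of cluster counts to try (default 2:5).
#' @return data.frame with \code{k} and \code{tot_withinss}.
#' @export
kmeans_inertia <- function(x, ks = 2:5, restarts = 100, seed) {
  do.call(rbind, lapply(ks, function(k) {
    km <- kmeans_partition(x, k = k, restarts = restarts, seed = seed)
    data.frame(k = k, tot_withinss = km$tot_withinss)
  }))
}

#' Select promoter-like clusters
#'
#' A cluster is promoter-like when the mean z-scored differential signal of
#' all three promoter marks (H3K9ac, H3K27ac, H3K4me3) is concordant with
#' the inclusion direction of the group (positive for more-included,
#' negative for less-included) and at least \code{tau} in magnitude for
#' every mark.  This replaces by-eye cluster selection with a deterministic
#' rule.  CTCF and the input control may be clustering features but do not
#' enter the rule.
#'
#' @param partition list from [kmeans_partition()] run on a
#'   \emph{standardized} matrix (centers in z-units).
#' @param direction \code{"more"} or \code{"less"}.
#' @param marks Mark names that must be concordant (default the three
#'   promoter marks).
#' @param tau Minimum absolute mean z per mark (default 1).
#' @return list: \code{clusters} (selected cluster ids, possibly empty) and
#'   \code{promoter_like} (logical per row of the clustered matrix).
#' @export
select_promoter_like_clusters <- function(partition,
                                          direction = c("more", "less"),
                                          marks = c("H3K9ac", "H3K27ac",
                                                    "H3K4me3"),
                                          tau = 1.0) {
  direction <- match.arg(direction)
  centers <- partition$centers
  stopifnot(all(marks %in% colnames(centers)))
  m <- centers[, marks, drop = FALSE]
  ok <- if (direction == "more") rowSums(m >= tau) == length(marks)
  else rowSums(m <= -tau) == length(marks)
  sel <- which(ok)
  list(clusters = sel, promoter_like = partition$cluster %in% sel)
}

#' Assign C-higher / C-lower cell roles for exon comparisons
#'
#' Within one exon comparison, C-higher is the cell line in which the exon
#' is more included.  Ties (equal PSI) cannot be assigned and are dropped
#' from the promoter-like set.
#'
#' @param calls data.frame with \code{cell1}, \code{cell2}, \code{psi1},
#'   \code{psi2}.
#' @return The input with added \code{c_higher}, \code{c_lower} (NA and a
#'   message for ties or undefined PSI).
#' @export
assign_cell_roles <- function(calls) {
  stopifnot(all(c("cell1", "cell2", "psi1", "psi2") %in% names(calls)))
  undef <- is.na(calls$psi1) | is.na(calls$psi2) | calls$psi1 == calls$psi2
  if (any(undef))
    message(sum(undef), " comparison(s) with tied or undefined PSI dropped",
            " from role assignment")
  higher2 <- calls$psi2 > calls$psi1
  calls$c_higher <- ifelse(undef, NA_character_,
                           ifelse(higher2, calls$cell2, calls$cell1))
  calls$c_lower <- ifelse(undef, NA_character_,
                          ifelse(higher2, calls$cell1, calls$cell2))
  calls
}

#' Direction-concordance validation on a held-out cell pair
#'
#' For promoter-like exons measured in a cell pair not used in discovery:
#' among exons with an inclusion difference above \code{min_delta_psi} and
#' a total chromatin difference (sum of the H3K9ac, H3K27ac and H3K4me3
#' differential signals) above \code{min_total_chromatin} in magnitude,
#' the fraction whose chromatin change points the same way as the inclusion
#' change is reported.
#'
#' @param delta_psi Numeric vector, inclusion change on the held-out pair.
#' @param total_chromatin Numeric vector, summed three-mark differential
#'   signal on the same orientation.
#' @param min_delta_psi,min_total_chromatin Eligibility thresholds
#'   (defaults 0.1 and 1).
#' @return list: \code{concordance} (fraction, NA when no eligible exon),
#'   \code{n_eligible}, \code{n_concordant}, \code{verdict} (logical per
#'   input exon, NA when ineligible).
#' @export
holdout_direction_validation <- function(delta_psi, total_chromatin,
                                         min_delta_psi = 0.1,
                                         min_total_chromatin = 1) {
  stopifnot(length(delta_psi) == length(total_chromatin))
  eligible <- !is.na(delta_psi) & !is.na(total_chromatin) &
    abs(delta_psi) > min_delta_psi &
    abs(total_chromatin) > min_total_chromatin
  verdict <- rep(NA, length(delta_psi))
  verdict[eligible] <- sign(total_chromatin[eligible]) ==
    sign(delta_psi[eligible])
  n_el <- sum(eligible)
  list(concordance = if (n_el == 0) NA_real_ else
         sum(verdict[eligible]) / n_el,
       n_eligible = n_el,
       n_concordant = sum(verdict[eligible]),
       verdict = verdict)
}

#' Two-component PCA projection of differential signals
#'
#' Convenience projection for visualising how promoter-like exon
#' comparisons separate from the core of regulated exons.
#'
#' @param x Standardized numeric matrix.
#' @return list: \code{scores} (n x 2), \code{var_explained} (length 2
#'   fractions of total variance), \code{rotation}.
#' @export
pca_projection <- function(x) {
  stopifnot(is.matrix(x))
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       var_explained = ve[seq_len(k)],
       rotation = pc$rotation[, seq_len(k), drop = FALSE])
}
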