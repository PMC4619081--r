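#' Build and validate a discovery run configuration
#'
#' One config drives the whole catalog -> calling -> chromatin ->
#' promoter-like pipeline.  Every threshold of the analysis is a named key
#' with the documented default (600 nt TSS/TTS distance, 50-450 bp length,
#' 0.75 mappability, 0.1 / 2-fold inclusion change, 10-fold expression,
#' alpha 0.05, k = 4, tau 1.0, 100-nt CAGE radius, minimum CAGE score 1).
#'
#' @param gtf,fasta,junctions,mappability File paths (required).
#' @param cage Named list of CAGE BED paths, one per cell.
#' @param tracks Nested named list \code{tracks[[mark]][[cell]]} of signal
#'   track paths; must include the three promoter marks.
#' @param cell_pairs list of length-2 character vectors (cell1, cell2).
#' @param out_dir Output directory.
#' @param alpha,min_abs_delta,min_fold,max_expr_fold,min_mappable,
#'   min_tss_tts_distance,min_len,max_len,cage_radius,min_cage_score,k,tau,
#'   restarts Analysis parameters (documented defaults).
#' @param kmeans_seed Seed for the clustering stage.
#' @param chroms Allowed chromosomes (NULL = all; default all, since
#'   synthetic genomes name their own chromosomes).
#' @param max_rep_delta Replicate concordance tolerance.
#' @return Validated list of class \code{run_config}.
#' @export
run_config <- function(gtf, fasta, junctions, mappability, cage, tracks,
                       cell_pairs, out_dir,
                       alpha = 0.05, min_abs_delta = 0.1, min_fold = 2,
                       max_expr_fold = 10, min_mappable = 0.75,
                       min_tss_tts_distance = 600, min_len = 50,
                       max_len = 450, cage_radius = 100, min_cage_score = 1,
                       k = 4, tau = 1.0, restarts = 100, kmeans_seed = 17,
                       chroms = NULL, max_rep_delta = 0.1) {
  cfg <- as.list(environment())
  files <- c(gtf = gtf, fasta = fasta, junctions = junctions,
             mappability = mappability,
             unlist(cage), unlist(tracks))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0)
    stop("missing input file(s):\n  ",
         paste(names(missing), "=", missing, collapse = "\n  "))
  cells <- names(cage)
  for (p in cell_pairs) {
    if (length(p) != 2 || !all(p %in% cells))
      stop("cell pair references unknown cell(s): ",
           paste(p, collapse = ":"))
  }
  marks <- names(tracks)
  need <- c("H3K9ac", "H3K27ac", "H3K4me3")
  if (!all(need %in% marks))
    stop("tracks must include the promoter marks: ",
         paste(setdiff(need, marks), collapse = ", "))
  stopifnot(alpha > 0, alpha < 1, k >= 2, tau >= 0, restarts >= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full discovery pipeline
#'
#' Stages, in dependency order: candidate-exon catalog from annotation;
#' junction counting and per-pair differential inclusion calls;
#' CAGE-derived gene expression and mappability filters; one exon per gene
#' and direction; differential chromatin signal per clustering feature;
#' standardization and k-means per direction group; promoter-like cluster
#' selection and C-higher / C-lower role assignment.  All stage outputs are
#' written under \code{out_dir} together with a JSON manifest (parameters,
#' seeds and md5 checksums) sufficient to reproduce the run byte for byte.
#'
#' @param cfg A \code{run_config}.
#' @return list: \code{catalog}, per-pair \code{calls}, \code{regulated}
#'   (post-filter picks with feature deltas), \code{partitions} (k-means
#'   per direction), \code{promoter_like} (data.frame of selected exon
#'   comparisons with roles), \code{manifest}, and output \code{paths}.
#' @export
run_discovery <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- load_annotation(cfg$gtf, cfg$fasta)
  catalog <- select_candidate_exons(
    model, min_tss_tts_distance = cfg$min_tss_tts_distance,
    min_len = cfg$min_len, max_len = cfg$max_len, chroms = cfg$chroms)
  junc <- utils::read.delim(cfg$junctions, stringsAsFactors = FALSE)
  counts <- count_junctions(junc, catalog)
  mapp <- read_signal_track(cfg$mappability)
  mfrac <- vapply(seq_along(catalog), function(i)
    mappable_fraction(catalog[i], mapp), numeric(1))
  names(mfrac) <- catalog$exon_id
  tss <- annotated_tss(model)
  cage_gr <- lapply(cfg$cage, read_signal_track)
  expr <- lapply(cage_gr, gene_expression_from_cage, tss = tss,
                 radius = cfg$cage_radius)
  tracks <- lapply(cfg$tracks, function(by_cell)
    lapply(by_cell, read_signal_track))
  cstart <- stats::setNames(GenomicRanges::start(catalog), catalog$exon_id)

  calls_by_pair <- list()
  reg_rows <- list()
  for (p in cfg$cell_pairs) {
    pair_id <- paste(p, collapse = ":")
    calls <- call_differential_inclusion(
      counts, p[1], p[2], alpha = cfg$alpha,
      max_rep_delta = cfg$max_rep_delta)
    calls$gene_id <- catalog$gene_id[match(calls$exon_id, catalog$exon_id)]
    calls$start <- unname(cstart[calls$exon_id])
    calls_by_pair[[pair_id]] <- calls
    reg <- apply_regulation_filters(
      calls, expr[[p[1]]], expr[[p[2]]], mfrac,
      min_abs_delta = cfg$min_abs_delta, min_fold = cfg$min_fold,
      max_expr_fold = cfg$max_expr_fold, min_mappable = cfg$min_mappable)
    reg <- pick_exon_per_gene(reg, mode = "regulated")
    if (nrow(reg) == 0) next
    reg$pair <- pair_id
    # differential chromatin features on the regulated exons
    ex <- catalog[match(reg$exon_id, catalog$exon_id)]
    for (m in names(tracks)) {
      reg[[paste0("delta_", m)]] <- differential_eas(
        tracks[[m]][[p[1]]], tracks[[m]][[p[2]]], ex)
    }
    reg_rows[[pair_id]] <- reg
  }
  regulated <- if (length(reg_rows) > 0) do.call(rbind, reg_rows) else NULL
  if (!is.null(regulated)) rownames(regulated) <- NULL

  marks <- names(cfg$tracks)
  partitions <- list(); pl_calls <- NULL
  if (!is.null(regulated)) {
    feat_cols <- paste0("delta_", marks)
    regulated$promoter_like <- FALSE
    for (dir in c("more", "less")) {
      rows <- which(regulated$class == dir)
      if (length(rows) < cfg$k) next
      x <- as.matrix(regulated[rows, feat_cols])
      colnames(x) <- marks
      z <- standardize_features(x)
      part <- kmeans_partition(z, k = cfg$k, restarts = cfg$restarts,
                               seed = cfg$kmeans_seed)
      sel <- select_promoter_like_clusters(part, direction = dir,
                                           tau = cfg$tau)
      partitions[[dir]] <- list(partition = part, selected = sel$clusters)
      regulated$promoter_like[rows[sel$promoter_like]] <- TRUE
    }
    regulated <- assign_cell_roles(regulated)
    pl_calls <- regulated[regulated$promoter_like &
                            !is.na(regulated$c_higher), , drop = FALSE]
  }

  paths <- .write_outputs(cfg, catalog, calls_by_pair, regulated, pl_calls,
                          partitions)
  manifest <- .write_manifest(cfg, paths)
  list(catalog = catalog, calls = calls_by_pair, regulated = regulated,
       partitions = partitions, promoter_like = pl_calls,
       manifest = manifest, paths = paths)
}

.catalog_bed <- function(catalog, path, names = catalog$exon_id,
                         score = 0) {
  bed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(catalog)),
    start = GenomicRanges::start(catalog) - 1L,   # BED: 0-based half-open
    end = GenomicRanges::end(catalog),
    name = names, score = score,
    strand = as.character(GenomicRanges::strand(catalog)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

.write_outputs <- function(cfg, catalog, calls_by_pair, regulated,
                           pl_calls, partitions) {
  paths <- list()
  paths$catalog_bed <- file.path(cfg$out_dir, "catalog.bed")
  .catalog_bed(catalog, paths$catalog_bed)
  num <- function(df) {   # stable numeric formatting for byte-identity
    for (j in seq_along(df)) if (is.numeric(df[[j]]))
      df[[j]] <- signif(df[[j]], 10)
    df
  }
  for (pair_id in names(calls_by_pair)) {
    p <- file.path(cfg$out_dir,
                   sprintf("calls_%s.tsv", gsub(":", "_vs_", pair_id)))
    utils::write.table(num(calls_by_pair[[pair_id]]), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[[paste0("calls_", pair_id)]] <- p
  }
  if (!is.null(regulated)) {
    paths$regulated_tsv <- file.path(cfg$out_dir, "regulated.tsv")
    utils::write.table(num(regulated), paths$regulated_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    reg_gr <- catalog[match(regulated$exon_id, catalog$exon_id)]
    paths$regulated_bed <- file.path(cfg$out_dir, "regulated.bed")
    .catalog_bed(reg_gr, paths$regulated_bed, names = regulated$pair)
  }
  if (!is.null(pl_calls) && nrow(pl_calls) > 0) {
    pl_gr <- catalog[match(pl_calls$exon_id, catalog$exon_id)]
    paths$promoter_like_bed <- file.path(cfg$out_dir, "promoter_like.bed")
    .catalog_bed(pl_gr, paths$promoter_like_bed, names = pl_calls$pair)
  }
  if (length(partitions) > 0) {
    rep_rows <- list()
    for (dir in names(partitions)) {
      cen <- partitions[[dir]]$partition$centers
      rep_rows[[dir]] <- data.frame(
        direction = dir, cluster = seq_len(nrow(cen)),
        size = partitions[[dir]]$partition$size,
        selected = seq_len(nrow(cen)) %in% partitions[[dir]]$selected,
        signif(cen, 10), stringsAsFactors = FALSE)
    }
    paths$cluster_report <- file.path(cfg$out_dir, "cluster_report.tsv")
    utils::write.table(do.call(rbind, rep_rows), paths$cluster_report,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths
}

.write_manifest <- function(cfg, paths) {
  params <- cfg[setdiff(names(cfg), c("out_dir"))]
  flat <- unlist(paths)
  manifest <- list(
    package = "exonchrom",
    parameters = params[order(names(params))])
  # parameter hash: md5 of the deparsed, name-sorted parameter block
  tf <- tempfile()
  writeLines(paste(utils::capture.output(utils::str(params)),
                   collapse = "\n"), tf)
  manifest$parameter_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  manifest$outputs <- lapply(stats::setNames(nm = names(flat)), function(k)
    list(path = basename(flat[[k]]),
         md5 = unname(tools::md5sum(flat[[k]]))))
  mp <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest$path <- mp
  manifest
}

#' Evaluate discovery results against the simulation truth
#'
#' @param results list from [run_discovery()].
#' @param truth A \code{truth_table} with \code{exon_id} column (as
#'   produced inside [simulate_bundle()]).
#' @return list of class \code{evaluation_report}: confusion counts,
#'   sensitivity and realized FDR for regulated-exon calls and for
#'   promoter-like calls (FDR is NA when nothing was called).
#' @export
evaluate_against_truth <- function(results, truth) {
  stopifnot(!is.null(truth$exon_id))
  reg_called <- if (is.null(results$regulated)) character(0)
  else unique(results$regulated$exon_id)
  unknown <- setdiff(reg_called, truth$exon_id)
  if (length(unknown) > 0)
    stop("called exon ids not present in truth: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  conf <- function(called, positive) {
    tp <- sum(called %in% positive)
    fp <- length(called) - tp
    fn <- length(positive) - tp
    list(tp = tp, fp = fp, fn = fn,
         sensitivity = if (length(positive) == 0) NA_real_
         else tp / length(positive),
         fdr = if (length(called) == 0) NA_real_ else fp / length(called))
  }
  reg_truth <- truth$exon_id[truth$regulated]
  pl_called <- if (is.null(results$promoter_like)) character(0)
  else unique(results$promoter_like$exon_id)
  pl_truth <- truth$exon_id[truth$promoter_like]
  # direction breakdown for regulated calls
  dir_ok <- NA_real_
  if (!is.null(results$regulated) && nrow(results$regulated) > 0) {
    r <- results$regulated
    i <- match(r$exon_id, truth$exon_id)
    both <- !is.na(truth$direction[i]) & !is.na(as.character(r$class))
    if (any(both))
      dir_ok <- mean(as.character(r$class)[both] == truth$direction[i][both])
  }
  structure(list(regulated = conf(reg_called, reg_truth),
                 promoter_like = conf(pl_called, pl_truth),
                 direction_concordance = dir_ok),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  f <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat("Regulated exon calls:    TP", x$regulated$tp, "FP", x$regulated$fp,
      "FN", x$regulated$fn, "| sensitivity", f(x$regulated$sensitivity),
      "FDR", f(x$regulated$fdr), "\n")
  cat("Promoter-like calls:     TP", x$promoter_like$tp, "FP",
      x$promoter_like$fp, "FN", x$promoter_like$fn, "| sensitivity",
      f(x$promoter_like$sensitivity), "FDR", f(x$promoter_like$fdr), "\n")
  cat("Direction concordance of regulated calls:",
      f(x$direction_concordance), "\n")
  invisible(x)
}
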