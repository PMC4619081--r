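#' Simulation configuration
#'
#' Collects every knob of the synthetic multi-omics generator.  Defaults
#' describe the world the analysis was designed for: a minority of cassette
#' exons regulated between cell types (about 3 percent), of which a small
#' subset (4 percent) carries concordant promoter-mark shifts; inclusion
#' changes mostly modest (0.1-0.5); junction sequencing deep enough that
#' PSI is well estimated; two replicates per cell.
#'
#' @param n_genes Number of simulated genes (one cassette exon each).
#' @param exons_per_gene Exons per gene (>= 5 so the cassette and both
#'   flanks are internal).
#' @param cells Character vector of cell-line labels; the first two form
#'   the discovery pair, any further cells are unregulated copies usable as
#'   held-out lines.
#' @param replicates Sequencing replicates per cell (default 2).
#' @param depth Mean junction reads per junction class per replicate
#'   (default 50).
#' @param frac_regulated Fraction of cassette exons with a planted
#'   inclusion change between the discovery pair (default 0.03).
#' @param delta_psi_range Magnitude range of planted inclusion changes
#'   (default c(0.1, 0.5), uniform).
#' @param frac_promoter_like Fraction of regulated exons carrying the
#'   planted promoter-mark shift (default 0.04).
#' @param mark_effect Planted promoter-mark shift in z-units of the
#'   baseline noise (default 2).
#' @param noise_sd SD of baseline log2 signal noise (default 1).
#' @param alt_tss_frac Fraction of promoter-like exons whose C-higher cell
#'   uses an alternative, exon-proximal TSS (default 0.45).
#' @param p_link_higher,p_link_lower Probability that a promoter-like exon
#'   has a ChIA-PET link to its used TSS in the C-higher / C-lower cell
#'   (defaults 0.94 and 0.68).
#' @param frac_same_state Fraction of promoter-like exons sharing one
#'   chromatin-state run with their used TSS (default 0.4).
#' @param seed Integer master seed; all randomness derives from it.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 200, exons_per_gene = 6,
                       cells = c("cellA", "cellB"), replicates = 2,
                       depth = 50, frac_regulated = 0.03,
                       delta_psi_range = c(0.1, 0.5),
                       frac_promoter_like = 0.04, mark_effect = 2,
                       noise_sd = 1, alt_tss_frac = 0.45,
                       p_link_higher = 0.94, p_link_lower = 0.68,
                       frac_same_state = 0.4, seed = 1) {
  stopifnot(n_genes >= 1, exons_per_gene >= 5, length(cells) >= 2,
            replicates >= 1, depth > 0,
            frac_regulated >= 0, frac_regulated <= 1,
            frac_promoter_like >= 0, frac_promoter_like <= 1,
            length(delta_psi_range) == 2,
            delta_psi_range[1] > 0, delta_psi_range[2] <= 1,
            noise_sd > 0,
            alt_tss_frac >= 0, alt_tss_frac <= 1,
            p_link_higher >= 0, p_link_higher <= 1,
            p_link_lower >= 0, p_link_lower <= 1,
            frac_same_state >= 0, frac_same_state <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# derive a deterministic child seed (< 2^31) from the master seed
.child_seed <- function(seed, salt) {
  (as.numeric(seed) * 48271 + salt) %% 2147483587
}

#' Simulate the ground-truth table
#'
#' Draws per-exon true inclusion levels per cell, plants regulated
#' inclusion changes between the first two cells, marks a promoter-like
#' subset among the regulated exons and records C-higher assignments and
#' per-mark planted effects.  This table is the reference every
#' evaluation compares against.
#'
#' @param config A \code{sim_config}.
#' @return data.frame of class \code{truth_table}: one row per cassette
#'   exon with columns \code{exon_idx}, \code{gene_id}, per-cell
#'   \code{psi_<cell>}, \code{regulated}, \code{direction} ("more" = higher
#'   in the second cell, per the package orientation), \code{delta_psi},
#'   \code{promoter_like}, \code{c_higher}, \code{mark_effect}.
#' @export
sim_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.child_seed(config$seed, 1))
  n <- config$n_genes
  cells <- config$cells
  base <- stats::runif(n, 0.15, 0.85)
  n_reg <- round(config$frac_regulated * n)
  reg_idx <- if (n_reg > 0) sort(sample.int(n, n_reg)) else integer(0)
  dmag <- stats::runif(n, config$delta_psi_range[1],
                       config$delta_psi_range[2])
  dsign <- sample(c(-1, 1), n, replace = TRUE)
  # flip infeasible directions instead of clamping, so planted magnitudes
  # are preserved exactly
  dsign[base + dsign * dmag > 0.98] <- -1
  dsign[base + dsign * dmag < 0.02] <- 1
  delta <- numeric(n)
  delta[reg_idx] <- (dmag * dsign)[reg_idx]
  psi1 <- base
  psi2 <- base + delta
  truth <- data.frame(exon_idx = seq_len(n),
                      gene_id = sprintf("G%04d", seq_len(n)),
                      stringsAsFactors = FALSE)
  truth[[paste0("psi_", cells[1])]] <- psi1
  truth[[paste0("psi_", cells[2])]] <- psi2
  for (cl in cells[-(1:2)]) truth[[paste0("psi_", cl)]] <- base
  truth$regulated <- seq_len(n) %in% reg_idx
  truth$delta_psi <- ifelse(truth$regulated, delta, 0)
  truth$direction <- ifelse(!truth$regulated, NA_character_,
                            ifelse(delta > 0, "more", "less"))
  n_pl <- round(config$frac_promoter_like * n_reg)
  pl_idx <- if (n_pl > 0) sort(sample(reg_idx, n_pl)) else integer(0)
  truth$promoter_like <- seq_len(n) %in% pl_idx
  truth$c_higher <- ifelse(!truth$regulated, NA_character_,
                           ifelse(delta > 0, cells[2], cells[1]))
  truth$mark_effect <- ifelse(truth$promoter_like, config$mark_effect, 0)
  class(truth) <- c("truth_table", "data.frame")
  truth
}

#' Simulate a genome and gene annotation harboring the cassette exons
#'
#' Lays out \code{n_genes} genes along one synthetic chromosome, each with
#' \code{exons_per_gene} exons and two transcripts: one including and one
#' skipping the cassette exon (the middle internal exon).  Introns begin GT
#' and end AG in transcription direction (strand-aware in genome space);
#' internal exons sit at least 600 nt from the TSS and TTS; exon lengths
#' fall inside the 50-450 bp catalog band.  Gene strands alternate.
#'
#' @param config A \code{sim_config}.
#' @param truth Truth table from [sim_truth()] (used for gene ids).
#' @return list: \code{genome} (DNAStringSet, one chromosome "chr1"),
#'   \code{gtf} (GRanges of exon records with gene_id/transcript_id/type),
#'   \code{cassette} (GRanges of the intended cassette exons with
#'   \code{exon_id}, \code{exon_idx}, \code{gene_id}), \code{genes}
#'   (data.frame: gene_id, strand, tss, tts, chrom).
#' @export
generate_genome_annotation <- function(config, truth = sim_truth(config)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.child_seed(config$seed, 2))
  n <- config$n_genes
  npg <- config$exons_per_gene
  cas_rank <- ceiling(npg / 2)          # internal; flanks internal too
  if (cas_rank < 3 || cas_rank > npg - 2)
    stop("gene geometry infeasible: cassette exon would not have internal flanks")
  chrom <- "chr1"
  gap <- 2000
  cursor <- 1000
  exon_rows <- list(); gene_rows <- list(); cas_rows <- list()
  for (g in seq_len(n)) {
    strand <- if (g %% 2 == 0) "-" else "+"
    elens <- c(200, sample(80:300, npg - 2, replace = TRUE), 200)
    ilens <- c(800, sample(300:600, npg - 3, replace = TRUE), 800)
    # left-to-right genomic layout; transcription order depends on strand
    starts <- integer(npg); ends <- integer(npg)
    pos <- cursor
    for (i in seq_len(npg)) {
      starts[i] <- pos
      ends[i] <- pos + elens[i] - 1
      pos <- ends[i] + 1 + if (i < npg) ilens[i] else 0
    }
    gene_end <- ends[npg]
    cas_i <- if (strand == "+") cas_rank else npg - cas_rank + 1  # genomic idx
    gid <- truth$gene_id[g]
    exon_rows[[g]] <- data.frame(
      chrom = chrom, start = starts, end = ends, strand = strand,
      gene_id = gid,
      genomic_idx = seq_len(npg), stringsAsFactors = FALSE)
    gene_rows[[g]] <- data.frame(
      gene_id = gid, chrom = chrom, strand = strand,
      tss = if (strand == "+") starts[1] else gene_end,
      tts = if (strand == "+") gene_end else starts[1],
      cas_start = starts[cas_i], cas_end = ends[cas_i],
      stringsAsFactors = FALSE)
    cas_rows[[g]] <- data.frame(
      chrom = chrom, start = starts[cas_i], end = ends[cas_i],
      strand = strand, gene_id = gid, exon_idx = g,
      stringsAsFactors = FALSE)
    cursor <- gene_end + 1 + gap
  }
  chrom_len <- cursor + 1000
  genes <- do.call(rbind, gene_rows)
  exdf <- do.call(rbind, exon_rows)

  # genome sequence with planted splice dinucleotides
  seqchars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  for (g in seq_len(n)) {
    ed <- exon_rows[[g]]
    minus <- ed$strand[1] == "-"
    for (i in seq_len(nrow(ed) - 1)) {
      is <- ed$end[i] + 1          # intron genomic start
      ie <- ed$start[i + 1] - 1    # intron genomic end
      if (minus) {                 # transcription right-to-left
        seqchars[is:(is + 1)] <- c("C", "T")   # revcomp(AG): acceptor end
        seqchars[(ie - 1):ie] <- c("A", "C")   # revcomp(GT): donor start
      } else {
        seqchars[is:(is + 1)] <- c("G", "T")
        seqchars[(ie - 1):ie] <- c("A", "G")
      }
    }
  }
  genome <- Biostrings::DNAStringSet(paste(seqchars, collapse = ""))
  names(genome) <- chrom

  # two transcripts per gene: -I includes the cassette, -S skips it
  mk_tx <- function(ed, gid, suffix, drop_idx = NULL) {
    keep <- if (is.null(drop_idx)) seq_len(nrow(ed))
    else setdiff(seq_len(nrow(ed)), drop_idx)
    GenomicRanges::GRanges(
      ed$chrom[keep], IRanges::IRanges(ed$start[keep], ed$end[keep]),
      strand = ed$strand[keep], type = "exon", gene_id = gid,
      transcript_id = paste0(gid, suffix))
  }
  gtf <- do.call(c, unlist(lapply(seq_len(n), function(g) {
    ed <- exon_rows[[g]]
    cas_i <- which(ed$start == gene_rows[[g]]$cas_start)
    list(mk_tx(ed, genes$gene_id[g], ".I"),
         mk_tx(ed, genes$gene_id[g], ".S", drop_idx = cas_i))
  }), use.names = FALSE))
  GenomeInfoDb::seqlengths(gtf) <- stats::setNames(chrom_len, chrom)

  cas <- do.call(rbind, cas_rows)
  cassette <- GenomicRanges::GRanges(
    cas$chrom, IRanges::IRanges(cas$start, cas$end), strand = cas$strand,
    exon_id = paste0(cas$chrom, ":", cas$start, "-", cas$end, ":",
                     cas$strand),
    exon_idx = cas$exon_idx, gene_id = cas$gene_id)
  GenomeInfoDb::seqlengths(cassette) <- stats::setNames(chrom_len, chrom)
  list(genome = genome, gtf = gtf, cassette = cassette, genes = genes,
       chrom_len = chrom_len)
}

#' Simulate junction read counts from true inclusion levels
#'
#' Per exon, cell and replicate the total junction read count is Poisson
#' with mean \code{3 * depth} (three junction classes at \code{depth} reads
#' each on average).  Reads are inclusion reads with probability
#' \eqn{w = 2\psi / (1 + \psi)} -- the weight obtained by inverting the
#' inclusion-level formula, so that the PSI estimator is centered on the
#' true value -- and inclusion reads split evenly between the upstream and
#' downstream junctions.
#'
#' @param truth A \code{truth_table} (or any data.frame with
#'   \code{exon_idx} and \code{psi_<cell>} columns).
#' @param depth Mean reads per junction class (default from the truth's
#'   config is not stored; pass explicitly, default 50).
#' @param replicates Number of replicates (default 2).
#' @param seed Integer seed.
#' @param cells Cell labels (default: all \code{psi_} columns).
#' @return data.frame: \code{exon_idx}, \code{exon_id} (copied from truth
#'   when present), \code{cell}, \code{replicate}, \code{JIR_up},
#'   \code{JIR_down}, \code{JER}.
#' @export
simulate_junction_counts <- function(truth, depth = 50, replicates = 2,
                                     seed = 1, cells = NULL) {
  psi_cols <- grep("^psi_", names(truth), value = TRUE)
  if (is.null(cells)) cells <- sub("^psi_", "", psi_cols)
  set.seed(seed)
  n <- nrow(truth)
  out <- list()
  for (cl in cells) {
    psi <- truth[[paste0("psi_", cl)]]
    w <- 2 * psi / (1 + psi)
    for (r in seq_len(replicates)) {
      total <- stats::rpois(n, 3 * depth)
      incl <- stats::rbinom(n, total, w)
      up <- stats::rbinom(n, incl, 0.5)
      out[[length(out) + 1]] <- data.frame(
        exon_idx = truth$exon_idx,
        cell = cl, replicate = paste0("rep", r),
        JIR_up = up, JIR_down = incl - up, JER = total - incl,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (!is.null(truth$exon_id))
    res$exon_id <- truth$exon_id[match(res$exon_idx, truth$exon_idx)]
  res
}

#' Write simulated junction counts as a junction TSV
#'
#' Converts exon-keyed counts into the junction-coordinate table the
#' calling module reads (columns chrom, intron_start, intron_end, strand,
#' cell, replicate, count; 1-based closed intron coordinates), using the
#' flanking-intron coordinates carried by the catalog.
#'
#' @param counts data.frame from [simulate_junction_counts()] with
#'   \code{exon_id} matching catalog exon ids.
#' @param catalog GRanges from [select_candidate_exons()].
#' @param path Output TSV path.
#' @return Invisibly, the written data.frame.
#' @export
write_junction_tsv <- function(counts, catalog, path) {
  i <- match(counts$exon_id, catalog$exon_id)
  if (anyNA(i)) stop("counts reference exon ids absent from catalog")
  chrom <- as.character(GenomicRanges::seqnames(catalog))[i]
  strand <- as.character(GenomicRanges::strand(catalog))[i]
  mk <- function(s, e, cnt) data.frame(
    chrom = chrom, intron_start = s, intron_end = e, strand = strand,
    cell = counts$cell, replicate = counts$replicate, count = cnt,
    stringsAsFactors = FALSE)
  df <- rbind(
    mk(catalog$up_intron_start[i], catalog$up_intron_end[i], counts$JIR_up),
    mk(catalog$down_intron_start[i], catalog$down_intron_end[i],
       counts$JIR_down),
    mk(catalog$skip_intron_start[i], catalog$skip_intron_end[i],
       counts$JER))
  df <- df[df$count > 0, , drop = FALSE]
  df <- df[order(df$chrom, df$intron_start, df$intron_end, df$cell,
                 df$replicate), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' Simulate a differential chromatin-signal matrix with planted structure
#'
#' Directly generates the per-comparison differential-signal feature matrix
#' the clustering stage consumes, emulating what the track route
#' (baseline per-bin log2 noise -> exonic average -> cell2 - cell1
#' difference) produces: each feature is the difference of two exon
#' averages of \code{n_bins} independent noise bins, so the feature-level
#' noise SD is \code{noise_sd * sqrt(2 / n_bins)}.  Planted promoter-like
#' rows get a concordant shift of \code{effect} z-units of the per-bin
#' noise on the three promoter marks (sign matching the inclusion
#' direction) and a mild anti-correlated shift on the control feature.
#'
#' @param n Number of exon comparisons (rows).
#' @param planted Integer indices (or logical) of promoter-like rows.
#' @param direction "more" (planted shift positive) or "less" (negative).
#' @param features Feature (column) names; the planted shift applies to
#'   \code{marks}.
#' @param marks Columns receiving the planted shift.
#' @param effect Shift in units of \code{noise_sd} (per-bin z-units).
#' @param noise_sd Baseline per-bin noise SD.
#' @param n_bins Track bins averaged per exon (default 8: a typical
#'   ~200 bp exon at 25 bp track resolution).
#' @param control_feature Optional column getting \code{-0.3 * effect}
#'   (open-chromatin depletion of input DNA); NULL to skip.
#' @param seed Integer seed.
#' @return Numeric matrix n x length(features) with planted rows recorded
#'   in \code{attr(, "planted")}.
#' @export
simulate_delta_matrix <- function(n, planted, direction = c("more", "less"),
                                  features = c("H3K9ac", "H3K27ac",
                                               "H3K4me3", "CTCF",
                                               "control"),
                                  marks = c("H3K9ac", "H3K27ac", "H3K4me3"),
                                  effect = 2, noise_sd = 1, n_bins = 8,
                                  control_feature = "control", seed = 1) {
  direction <- match.arg(direction)
  if (is.logical(planted)) planted <- which(planted)
  set.seed(seed)
  feat_sd <- noise_sd * sqrt(2 / n_bins)
  x <- matrix(stats::rnorm(n * length(features), 0, feat_sd), n,
              dimnames = list(NULL, features))
  sgn <- if (direction == "more") 1 else -1
  x[planted, marks] <- x[planted, marks] + sgn * effect * noise_sd
  if (!is.null(control_feature) && control_feature %in% features)
    x[planted, control_feature] <- x[planted, control_feature] -
      sgn * 0.3 * effect * noise_sd
  attr(x, "planted") <- planted
  x
}

#' Simulate per-mark, per-cell signal tracks
#'
#' Binned (25 bp) piecewise-constant tracks over the simulated chromosome:
#' log-normal baseline noise everywhere; large enrichment at every
#' annotated TSS in every cell; exon-local additive enrichment (on the log2
#' scale, in z-units of the noise) of the three promoter marks at planted
#' promoter-like exons in their C-higher cell only; the input control gets
#' a mild opposite shift there.  Enrichment never extends into flanking
#' exons.
#'
#' @param anno list from [generate_genome_annotation()].
#' @param truth A \code{truth_table}.
#' @param config A \code{sim_config}.
#' @param marks Track names to simulate (default three promoter marks,
#'   CTCF and control).
#' @return Nested list \code{tracks[[mark]][[cell]]} of GRanges with
#'   \code{score}.
#' @export
simulate_signal_tracks <- function(anno, truth, config,
                                   marks = c("H3K9ac", "H3K27ac", "H3K4me3",
                                             "CTCF", "control")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.child_seed(config$seed, 3))
  chrom <- names(anno$genome)
  len <- anno$chrom_len
  bin <- 25
  nb <- ceiling(len / bin)
  starts <- (seq_len(nb) - 1) * bin + 1
  ends <- pmin(starts + bin - 1, len)
  base_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
  cas <- anno$cassette
  pl <- which(truth$promoter_like)
  tss_pos <- anno$genes$tss
  tss_bins <- unique(unlist(lapply(tss_pos, function(p) {
    which(starts <= p + 300 & ends >= p - 300)
  })))
  exon_bins <- lapply(pl, function(i) {
    which(starts <= GenomicRanges::end(cas)[i] &
            ends >= GenomicRanges::start(cas)[i])
  })
  tracks <- list()
  for (m in marks) {
    tracks[[m]] <- list()
    for (cl in config$cells) {
      log2sig <- stats::rnorm(nb, 2, config$noise_sd)
      if (m != "control") log2sig[tss_bins] <- log2sig[tss_bins] + 4
      for (j in seq_along(pl)) {
        i <- pl[j]
        if (identical(truth$c_higher[i], cl)) {
          eff <- if (m %in% c("H3K9ac", "H3K27ac", "H3K4me3"))
            config$mark_effect * config$noise_sd
          else if (m == "control") -0.3 * config$mark_effect * config$noise_sd
          else 0
          log2sig[exon_bins[[j]]] <- log2sig[exon_bins[[j]]] + eff
        }
      }
      gr <- base_gr
      gr$score <- round(2^log2sig, 4)
      GenomeInfoDb::seqlengths(gr) <- stats::setNames(len, chrom)
      tracks[[m]][[cl]] <- gr
    }
  }
  tracks
}

#' Simulate CAGE clusters, ChIA-PET links and chromatin segmentations
#'
#' Per cell line: CAGE clusters with score >= 1 at every used TSS (a small
#' sub-threshold cluster is placed at unused alternative TSSs so the
#' min-score rule is exercised); for a configured fraction of
#' promoter-like exons the C-higher cell activates an alternative TSS
#' close to the exon; ChIA-PET links connect promoter-like exons to their
#' used TSS with the configured per-role probabilities; a chromatin-state
#' segmentation in which a configured fraction of promoter-like exons
#' shares one state run with its used TSS.
#'
#' @param anno list from [generate_genome_annotation()].
#' @param truth A \code{truth_table}.
#' @param config A \code{sim_config}.
#' @return list: \code{cage} (named list of GRanges per cell, score
#'   column), \code{links} (named list of BEDPE-style data.frames per
#'   cell), \code{segmentation} (named list of GRanges with \code{state}),
#'   \code{used_tss} (data.frame: exon_idx, cell, pos of the used TSS
#'   closest to the exon), \code{same_state} (data.frame: exon_idx,
#'   planted same-state flag).
#' @export
simulate_cage_and_links <- function(anno, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.child_seed(config$seed, 4))
  chrom <- names(anno$genome)
  genes <- anno$genes
  cas <- anno$cassette
  cells <- config$cells
  n <- nrow(truth)
  base_score <- round(stats::runif(n, 5, 50), 1)
  pl <- which(truth$promoter_like)
  alt_tss <- rep(NA_real_, n)
  use_alt <- rep(FALSE, n)
  if (length(pl) > 0)
    use_alt[pl] <- stats::runif(length(pl)) < config$alt_tss_frac
  # alternative TSS placed 300 bp transcription-upstream of the exon
  for (i in which(use_alt)) {
    alt_tss[i] <- if (as.character(GenomicRanges::strand(cas))[i] == "-")
      GenomicRanges::end(cas)[i] + 300 else GenomicRanges::start(cas)[i] - 300
  }
  mk_cluster <- function(pos, score) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(pos - 10, pos + 10),
                           score = score)
  }
  share <- rep(FALSE, n)
  share[pl] <- stats::runif(length(pl)) < config$frac_same_state
  cage <- list(); links <- list(); seg <- list()
  used_rows <- list()
  for (cl in cells) {
    grs <- mk_cluster(genes$tss, base_score *
                        round(stats::runif(n, 0.8, 1.25), 2))
    alt_list <- list()
    for (i in which(use_alt)) {
      score <- if (identical(truth$c_higher[i], cl))
        round(stats::runif(1, 5, 20), 1) else 0.5   # sub-threshold: unused
      alt_list[[length(alt_list) + 1]] <- mk_cluster(alt_tss[i], score)
    }
    if (length(alt_list) > 0) grs <- c(grs, do.call(c, alt_list))
    grs <- sort(grs)
    cage[[cl]] <- grs
    # distance bookkeeping: used TSS closest to each cassette exon
    for (i in seq_len(n)) {
      ex <- cas[i]
      used_rows[[length(used_rows) + 1]] <- data.frame(
        exon_idx = i, cell = cl,
        dist = distance_to_used_tss(ex, grs, min_score = 1),
        stringsAsFactors = FALSE)
    }
    # ChIA-PET links for promoter-like exons
    lk <- list()
    for (i in pl) {
      p_link <- if (identical(truth$c_higher[i], cl)) config$p_link_higher
      else config$p_link_lower
      if (stats::runif(1) < p_link) {
        tpos <- if (use_alt[i] && identical(truth$c_higher[i], cl))
          alt_tss[i] else genes$tss[i]
        lk[[length(lk) + 1]] <- data.frame(
          chrom1 = chrom, start1 = GenomicRanges::start(cas)[i] - 50,
          end1 = GenomicRanges::end(cas)[i] + 50,
          chrom2 = chrom, start2 = tpos - 100, end2 = tpos + 100,
          support = stats::rpois(1, 4) + 1, stringsAsFactors = FALSE)
      }
    }
    links[[cl]] <- if (length(lk) > 0) do.call(rbind, lk) else
      data.frame(chrom1 = character(0), start1 = integer(0),
                 end1 = integer(0), chrom2 = character(0),
                 start2 = integer(0), end2 = integer(0),
                 support = numeric(0))
    # segmentation: default alternating states per gene body; for a
    # planted fraction of promoter-like exons one Promoter run spans
    # TSS..exon (the same exons in every cell line)
    segs <- list()
    for (g in seq_len(n)) {
      lo <- min(genes$tss[g], genes$tts[g]) - 500
      hi <- max(genes$tss[g], genes$tts[g]) + 500
      exs <- GenomicRanges::start(cas)[g]; exe <- GenomicRanges::end(cas)[g]
      tpos <- genes$tss[g]
      if (share[g]) {
        runlo <- min(tpos, exs) - 100
        runhi <- max(tpos, exe) + 100
        segs[[length(segs) + 1]] <- data.frame(
          start = c(lo, runlo, runhi + 1),
          end = c(runlo - 1, runhi, hi),
          state = c("Quiescent", "Promoter", "Transcribed"))
      } else {
        # state boundary strictly between the TSS and the exon, so the two
        # never share a run unless planted
        exmid <- floor((exs + exe) / 2)
        cut <- floor((tpos + exmid) / 2)
        left <- if (tpos < exmid) "Promoter" else "Transcribed"
        right <- if (tpos < exmid) "Transcribed" else "Promoter"
        segs[[length(segs) + 1]] <- data.frame(
          start = c(lo, cut + 1), end = c(cut, hi),
          state = c(left, right))
      }
    }
    sd <- do.call(rbind, segs)
    seg[[cl]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(sd$start, sd$end), state = sd$state)
  }
  list(cage = cage, links = links, segmentation = seg,
       used_tss = do.call(rbind, used_rows),
       same_state = data.frame(exon_idx = seq_len(n),
                               planted_same_state = share),
       alt_tss = data.frame(exon_idx = seq_len(n), use_alt = use_alt,
                            alt_tss_pos = alt_tss))
}

#' Write a complete simulated data bundle to disk
#'
#' Generates genome, annotation, junction counts, signal tracks,
#' mappability, CAGE, ChIA-PET and segmentation files plus the truth table,
#' all derived deterministically from the config seed.  The bundle passes
#' every reader in the package.
#'
#' @param config A \code{sim_config}.
#' @param out_dir Output directory (created).
#' @return list: file \code{paths} (named), \code{truth}, \code{anno},
#'   and the in-memory \code{tracks} / \code{context} objects.
#' @export
simulate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- sim_truth(config)
  anno <- generate_genome_annotation(config, truth)
  truth$exon_id <- anno$cassette$exon_id
  paths <- list()
  paths$fasta <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(anno$genome, paths$fasta)
  paths$gtf <- file.path(out_dir, "annotation.gtf")
  rtracklayer::export(anno$gtf, paths$gtf, format = "gtf")
  # junction counts need catalog intron coordinates
  model <- load_annotation(paths$gtf, paths$fasta)
  catalog <- select_candidate_exons(model)
  counts <- simulate_junction_counts(
    truth, depth = config$depth, replicates = config$replicates,
    seed = .child_seed(config$seed, 5), cells = config$cells)
  paths$junctions <- file.path(out_dir, "junctions.tsv")
  write_junction_tsv(counts, catalog, paths$junctions)
  # signal tracks
  tracks <- simulate_signal_tracks(anno, truth, config)
  paths$tracks <- list()
  for (m in names(tracks)) {
    paths$tracks[[m]] <- list()
    for (cl in names(tracks[[m]])) {
      p <- file.path(out_dir, sprintf("%s_%s.bedGraph", m, cl))
      rtracklayer::export(tracks[[m]][[cl]], p, format = "bedGraph")
      paths$tracks[[m]][[cl]] <- p
    }
  }
  # mappability: uniformly mappable
  mapp <- GenomicRanges::GRanges(
    names(anno$genome), IRanges::IRanges(1, anno$chrom_len), score = 1)
  GenomeInfoDb::seqlengths(mapp) <- stats::setNames(
    anno$chrom_len, names(anno$genome))
  paths$mappability <- file.path(out_dir, "mappability.bedGraph")
  rtracklayer::export(mapp, paths$mappability, format = "bedGraph")
  # CAGE / links / segmentation
  ctx <- simulate_cage_and_links(anno, truth, config)
  paths$cage <- list(); paths$links <- list(); paths$segmentation <- list()
  for (cl in config$cells) {
    pc <- file.path(out_dir, sprintf("cage_%s.bed", cl))
    cg <- ctx$cage[[cl]]
    cg$name <- sprintf("cage%04d", seq_along(cg))
    rtracklayer::export(cg, pc, format = "bed")
    paths$cage[[cl]] <- pc
    pb <- file.path(out_dir, sprintf("chiapet_%s.bedpe", cl))
    lk <- ctx$links[[cl]]
    bedpe <- data.frame(lk$chrom1, lk$start1 - 1L, lk$end1, lk$chrom2,
                        lk$start2 - 1L, lk$end2,
                        name = if (nrow(lk)) sprintf("link%03d",
                                                     seq_len(nrow(lk)))
                        else character(0),
                        score = lk$support)
    utils::write.table(bedpe, pb, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths$links[[cl]] <- pb
    ps <- file.path(out_dir, sprintf("chromhmm_%s.bed", cl))
    sg <- ctx$segmentation[[cl]]
    sg$name <- sg$state
    rtracklayer::export(sg, ps, format = "bed")
    paths$segmentation[[cl]] <- ps
  }
  paths$truth <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(paths = paths, truth = truth, anno = anno, catalog = catalog,
       counts = counts, tracks = tracks, context = ctx)
}
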