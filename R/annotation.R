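#' Load a transcript model from GTF annotation plus genome FASTA
#'
#' Reads a GENCODE-style GTF (exon features with \code{gene_id} and
#' \code{transcript_id} attributes) and the matching genome FASTA into an
#' in-memory transcript model.  Coordinates are held as GRanges (1-based,
#' closed), the Bioconductor convention; GTF is 1-based inclusive on disk so
#' no shifting occurs on input.
#'
#' @param gtf_path Path to a GTF file.
#' @param fasta_path Path to the genome FASTA (whole sequences are read into
#'   memory; intended for the compact genomes this package works with).
#' @return An object of class \code{exon_model}: a list with
#'   \describe{
#'     \item{exons}{GRanges, one row per (exon, transcript) with mcols
#'       \code{gene_id}, \code{transcript_id}, \code{exon_rank} (order in
#'       transcription direction).}
#'     \item{transcripts}{data.frame with per-transcript \code{gene_id},
#'       \code{chrom}, \code{strand}, \code{tss}, \code{tts} (genomic
#'       positions of start / termination site).}
#'     \item{genome}{DNAStringSet of chromosome sequences.}
#'   }
#' @export
load_annotation <- function(gtf_path, fasta_path) {
  lines <- readLines(gtf_path, warn = FALSE)
  if (length(grep("^[^#]", lines)) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      gene_id = character(0), transcript_id = character(0),
      type = character(0))
  } else {
    gr <- rtracklayer::import(gtf_path, format = "gtf")
  }
  gr <- gr[gr$type == "exon"]
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (length(gr) > 0) {
    missing <- setdiff(as.character(unique(GenomicRanges::seqnames(gr))),
                       names(genome))
    if (length(missing) > 0)
      stop("chromosome(s) in GTF absent from FASTA: ",
           paste(missing, collapse = ", "))
    if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
        anyNA(gr$gene_id) || anyNA(gr$transcript_id))
      stop("GTF exon records must carry gene_id and transcript_id")
  }
  # order exons within transcript in transcription direction
  ord <- order(gr$transcript_id, ifelse(
    as.character(GenomicRanges::strand(gr)) == "-",
    -GenomicRanges::start(gr), GenomicRanges::start(gr)))
  gr <- gr[ord]
  rank <- if (length(gr) > 0)
    stats::ave(seq_along(gr), gr$transcript_id, FUN = seq_along)
  else integer(0)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = gr$gene_id, transcript_id = gr$transcript_id,
    exon_rank = as.integer(rank))
  tx <- if (length(gr) > 0) {
    sp <- split(gr, gr$transcript_id)
    data.frame(
      transcript_id = names(sp),
      gene_id = vapply(sp, function(x) x$gene_id[1], character(1)),
      chrom = vapply(sp, function(x)
        as.character(GenomicRanges::seqnames(x))[1], character(1)),
      strand = vapply(sp, function(x)
        as.character(GenomicRanges::strand(x))[1], character(1)),
      n_exons = vapply(sp, length, integer(1)),
      tss = vapply(sp, function(x) {
        if (as.character(GenomicRanges::strand(x))[1] == "-")
          max(GenomicRanges::end(x)) else min(GenomicRanges::start(x))
      }, numeric(1)),
      tts = vapply(sp, function(x) {
        if (as.character(GenomicRanges::strand(x))[1] == "-")
          min(GenomicRanges::start(x)) else max(GenomicRanges::end(x))
      }, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(transcript_id = character(0), gene_id = character(0),
               chrom = character(0), strand = character(0),
               n_exons = integer(0), tss = numeric(0), tts = numeric(0))
  }
  structure(list(exons = gr, transcripts = tx, genome = genome),
            class = "exon_model")
}

#' @export
print.exon_model <- function(x, ...) {
  cat("exon_model:", nrow(x$transcripts), "transcripts,",
      length(unique(x$exons$gene_id)), "genes,",
      length(x$genome), "sequences\n")
  invisible(x)
}

# Unique exon keys "chrom:start-end:strand"
.exon_key <- function(gr) {
  paste0(as.character(GenomicRanges::seqnames(gr)), ":",
         GenomicRanges::start(gr), "-", GenomicRanges::end(gr), ":",
         as.character(GenomicRanges::strand(gr)))
}

# strand-aware dinucleotide at genome positions [pos, pos+1] (plus strand
# coords); rc = TRUE returns the reverse complement.
.dinuc <- function(genome, chrom, pos, rc = FALSE) {
  len <- Biostrings::width(genome[chrom])
  if (pos < 1 || pos + 1 > len) return(NA_character_)
  s <- Biostrings::subseq(genome[[chrom]], pos, pos + 1)
  if (rc) s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Select candidate internal cassette exons
#'
#' Filters the annotated exon universe down to exons that can be scored for
#' cassette (skipped-exon) regulation:
#' \enumerate{
#'   \item internal (not first, not last) in every transcript containing
#'     them;
#'   \item not overlapped by any non-identical annotated exon;
#'   \item between \code{min_len} and \code{max_len} bp long;
#'   \item at least \code{min_tss_tts_distance} nt from every annotated TSS
#'     and TTS of the host gene (set \code{tss_scope = "member"} to restrict
#'     to transcripts containing the exon);
#'   \item flanked by canonical splice sites: introns beginning GT and
#'     ending AG in transcription direction;
#'   \item on an allowed chromosome.
#' }
#'
#' @param model An \code{exon_model} from [load_annotation()].
#' @param min_tss_tts_distance,min_len,max_len Numeric filters (defaults
#'   600, 50, 450).
#' @param chroms Allowed chromosome names; default autosomes 1-22 plus X,
#'   with and without the "chr" prefix; \code{NULL} allows all.
#' @param tss_scope \code{"gene"} (default, strictest: every transcript of
#'   the host gene) or \code{"member"}.
#' @return GRanges of candidate exons with mcols: \code{exon_id}
#'   (chrom:start-end:strand), \code{gene_id}, \code{transcript_ids}
#'   (comma-joined), and flanking intron coordinates in genome space
#'   (\code{up_intron_start/end} = intron 5' of the exon in transcription
#'   direction, \code{down_intron_start/end}, \code{skip_intron_start/end}
#'   for the exclusion junction), taken from the member transcript with the
#'   nearest flanking exons.
#' @export
select_candidate_exons <- function(model,
                                   min_tss_tts_distance = 600,
                                   min_len = 50, max_len = 450,
                                   chroms = default_chromosomes(),
                                   tss_scope = c("gene", "member")) {
  stopifnot(inherits(model, "exon_model"))
  tss_scope <- match.arg(tss_scope)
  ex <- model$exons
  empty <- function() {
    g <- GenomicRanges::GRanges()
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(
      exon_id = character(0), gene_id = character(0),
      transcript_ids = character(0),
      up_intron_start = integer(0), up_intron_end = integer(0),
      down_intron_start = integer(0), down_intron_end = integer(0),
      skip_intron_start = integer(0), skip_intron_end = integer(0))
    g
  }
  if (length(ex) == 0) return(empty())
  key <- .exon_key(ex)
  n_in_tx <- stats::ave(ex$exon_rank, ex$transcript_id,
                        FUN = function(r) rep(length(r), length(r)))
  internal <- ex$exon_rank > 1 & ex$exon_rank < n_in_tx
  internal_all <- stats::ave(as.integer(internal), key,
                             FUN = function(v) as.integer(all(v == 1L))) == 1L
  # unique exon table (first occurrence per key) restricted to always-internal
  keep <- internal_all
  uk <- !duplicated(key) & keep
  cand <- ex[uk]
  ckey <- key[uk]
  if (length(cand) == 0) return(empty())

  # (b) overlap by any non-identical exon
  uex <- ex[!duplicated(key)]
  hits <- GenomicRanges::findOverlaps(cand, uex, ignore.strand = TRUE)
  other <- .exon_key(uex)[S4Vectors::subjectHits(hits)] !=
    ckey[S4Vectors::queryHits(hits)]
  overlapped <- ckey %in% ckey[unique(S4Vectors::queryHits(hits)[other])]

  # (c) length
  len_ok <- GenomicRanges::width(cand) >= min_len &
    GenomicRanges::width(cand) <= max_len

  # (d) TSS/TTS distance
  tx <- model$transcripts
  member_tx <- split(ex$transcript_id, key)
  exon5 <- ifelse(as.character(GenomicRanges::strand(cand)) == "-",
                  GenomicRanges::end(cand), GenomicRanges::start(cand))
  exon3 <- ifelse(as.character(GenomicRanges::strand(cand)) == "-",
                  GenomicRanges::start(cand), GenomicRanges::end(cand))
  tss_ok <- vapply(seq_along(cand), function(i) {
    txids <- member_tx[[ckey[i]]]
    use <- if (tss_scope == "gene")
      tx[tx$gene_id == cand$gene_id[i], , drop = FALSE]
    else tx[tx$transcript_id %in% txids, , drop = FALSE]
    pts <- c(use$tss, use$tts)
    d <- pmin(abs(GenomicRanges::start(cand)[i] - pts),
              abs(GenomicRanges::end(cand)[i] - pts))
    all(d >= min_tss_tts_distance)
  }, logical(1))

  # (e) canonical AG-GT: acceptor AG just 5' of the exon, donor GT just 3',
  # in transcription direction
  splice_ok <- vapply(seq_along(cand), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(cand))[i]
    s <- GenomicRanges::start(cand)[i]
    e <- GenomicRanges::end(cand)[i]
    if (as.character(GenomicRanges::strand(cand))[i] == "-") {
      acc <- .dinuc(model$genome, chrom, e + 1, rc = TRUE)  # AG on - strand
      don <- .dinuc(model$genome, chrom, s - 2, rc = TRUE)  # GT on - strand
    } else {
      acc <- .dinuc(model$genome, chrom, s - 2)
      don <- .dinuc(model$genome, chrom, e + 1)
    }
    identical(acc, "AG") && identical(don, "GT")
  }, logical(1))

  # (f) chromosomes
  chrom_ok <- if (is.null(chroms)) rep(TRUE, length(cand))
  else as.character(GenomicRanges::seqnames(cand)) %in% chroms

  sel <- !overlapped & len_ok & tss_ok & splice_ok & chrom_ok
  cand <- cand[sel]
  ckey <- ckey[sel]
  if (length(cand) == 0) return(empty())

  # flanking introns from the member transcript with the closest flanks
  fl <- t(vapply(seq_along(cand), function(i) {
    k <- ckey[i]
    rows <- which(key == k)
    best <- NULL
    for (r in rows) {
      txid <- ex$transcript_id[r]
      txex <- ex[ex$transcript_id == txid]
      rk <- ex$exon_rank[r]
      up <- txex[txex$exon_rank == rk - 1]   # transcription upstream
      dn <- txex[txex$exon_rank == rk + 1]
      minus <- as.character(GenomicRanges::strand(cand))[i] == "-"
      s <- GenomicRanges::start(cand)[i]; e <- GenomicRanges::end(cand)[i]
      if (minus) {
        ui <- c(e + 1, GenomicRanges::start(up) - 1)           # genome coords
        di <- c(GenomicRanges::end(dn) + 1, s - 1)
        si <- c(GenomicRanges::end(dn) + 1, GenomicRanges::start(up) - 1)
      } else {
        ui <- c(GenomicRanges::end(up) + 1, s - 1)
        di <- c(e + 1, GenomicRanges::start(dn) - 1)
        si <- c(GenomicRanges::end(up) + 1, GenomicRanges::start(dn) - 1)
      }
      span <- si[2] - si[1]
      if (is.null(best) || span < best$span)
        best <- list(ui = ui, di = di, si = si, span = span)
    }
    c(best$ui, best$di, best$si)
  }, numeric(6)))
  S4Vectors::mcols(cand) <- S4Vectors::DataFrame(
    exon_id = ckey,
    gene_id = cand$gene_id,
    transcript_ids = vapply(member_tx[ckey], paste, character(1),
                            collapse = ","),
    up_intron_start = as.integer(fl[, 1]), up_intron_end = as.integer(fl[, 2]),
    down_intron_start = as.integer(fl[, 3]),
    down_intron_end = as.integer(fl[, 4]),
    skip_intron_start = as.integer(fl[, 5]),
    skip_intron_end = as.integer(fl[, 6]))
  names(cand) <- NULL
  cand
}

#' Default allowed chromosomes (autosomes 1-22 and X)
#' @return Character vector with and without the "chr" prefix.
#' @export
default_chromosomes <- function() {
  base <- c(1:22, "X")
  c(paste0("chr", base), as.character(base))
}

#' Distance from an exon's first nucleotide to the closest annotated TSS
#'
#' The exon's first nucleotide is its 5' end in transcription direction; the
#' minimum genomic distance to the TSS over all transcripts containing the
#' exon is returned.
#'
#' @param exon A length-1 GRanges (strand required).
#' @param model An \code{exon_model}; membership is determined by exact
#'   coordinate match against the model's exons.
#' @return Non-negative integer distance in nucleotides.
#' @export
distance_to_annotated_tss <- function(exon, model) {
  stopifnot(inherits(model, "exon_model"), length(exon) == 1)
  key <- .exon_key(exon)
  txids <- unique(model$exons$transcript_id[.exon_key(model$exons) == key])
  if (length(txids) == 0) stop("exon not found in model: ", key)
  tx <- model$transcripts[model$transcripts$transcript_id %in% txids, ]
  first_nt <- if (as.character(GenomicRanges::strand(exon)) == "-")
    GenomicRanges::end(exon) else GenomicRanges::start(exon)
  min(abs(first_nt - tx$tss))
}

#' Mappable fraction of the acceptor window
#'
#' Fraction of uniquely mappable positions (track value >= 1) in a window of
#' \code{window} bp centered on the exon's acceptor site (the intron/exon
#' boundary at the exon 5' end in transcription direction).  Positions past
#' the chromosome start are truncated; if the track carries sequence
#' lengths, the window is also truncated at the chromosome end.
#'
#' @param exon Length-1 GRanges.
#' @param mappability GRanges with a numeric \code{score} column (1 =
#'   uniquely mappable); uncovered positions count as unmappable.
#' @param window Window size in bp (default 900).
#' @return Fraction in \[0, 1\] (denominator = positions retained after
#'   truncation).
#' @export
mappable_fraction <- function(exon, mappability, window = 900) {
  stopifnot(length(exon) == 1)
  minus <- as.character(GenomicRanges::strand(exon)) == "-"
  acc <- if (minus) GenomicRanges::end(exon) else GenomicRanges::start(exon)
  half <- floor(window / 2)
  lo <- acc - half
  hi <- lo + window - 1
  lo <- max(1, lo)
  chrom <- as.character(GenomicRanges::seqnames(exon))
  sl <- GenomeInfoDb::seqlengths(mappability)[chrom]
  if (!is.na(sl)) hi <- min(hi, sl)
  win <- GenomicRanges::GRanges(chrom, IRanges::IRanges(lo, hi))
  covered <- mappability[!is.na(mappability$score) & mappability$score >= 1]
  ov <- GenomicRanges::intersect(
    win, GenomicRanges::reduce(GenomicRanges::granges(covered)),
    ignore.strand = TRUE)
  sum(GenomicRanges::width(ov)) / GenomicRanges::width(win)
}

#' Flanking non-regulated exon triplet for a regulated exon
#'
#' Finds the closest transcription-upstream and -downstream exons that (a)
#' share a transcript with the regulated exon and (b) were not called
#' significantly regulated in the same cell pair (both BH q-values >= 0.05,
#' or untested).  Used to test whether chromatin enrichment is local to the
#' regulated exon.
#'
#' @param exon Length-1 GRanges, the regulated exon (must exist in model).
#' @param calls data.frame from [call_differential_inclusion()] keyed by
#'   \code{exon_id}; exons absent from it count as non-significant.
#' @param model An \code{exon_model}.
#' @param alpha Significance threshold on q (default 0.05); a flank
#'   qualifies when both tails have q >= alpha.
#' @return list with \code{upstream}, \code{downstream} (GRanges or NULL)
#'   and \code{complete} (logical).
#' @export
build_exon_triplets <- function(exon, calls, model, alpha = 0.05) {
  stopifnot(inherits(model, "exon_model"), length(exon) == 1)
  key <- .exon_key(exon)
  ex <- model$exons
  exkey <- .exon_key(ex)
  rows <- which(exkey == key)
  if (length(rows) == 0) stop("exon not found in model: ", key)
  qualifies <- function(k) {
    i <- match(k, calls$exon_id)
    if (is.na(i)) return(TRUE)
    qm <- calls$q_more[i]; ql <- calls$q_less[i]
    if (is.na(qm) || is.na(ql)) return(TRUE)
    qm >= alpha && ql >= alpha
  }
  find_side <- function(offset_sign) {
    # walk outward by rank within each member transcript; nearest first
    best <- NULL; best_d <- Inf
    for (r in rows) {
      txid <- ex$transcript_id[r]
      txex <- ex[ex$transcript_id == txid]
      rk <- ex$exon_rank[r]
      step <- 1
      repeat {
        cand_rank <- rk + offset_sign * step
        nb <- txex[txex$exon_rank == cand_rank]
        if (length(nb) == 0) break
        if (qualifies(.exon_key(nb))) {
          d <- GenomicRanges::distance(exon, nb, ignore.strand = TRUE)
          if (is.na(d)) d <- Inf
          if (d < best_d) { best <- nb; best_d <- d }
          break
        }
        step <- step + 1
      }
    }
    best
  }
  up <- find_side(-1L)
  dn <- find_side(+1L)
  list(upstream = up, downstream = dn,
       complete = !is.null(up) && !is.null(dn))
}

#' Position weight matrix log-odds scorer for splice sites
#'
#' Builds a scorer for [splice_site_strength()].  A PWM here is a 4 x w
#' probability matrix (rows A, C, G, T); the score of a sequence is the sum
#' over positions of \code{log2(pwm[base, j] / background[base])}.
#'
#' @param donor_pwm 4 x 9 matrix (3 exonic + 6 intronic positions).
#' @param acceptor_pwm 4 x 23 matrix (20 intronic + 3 exonic positions).
#' @param background Length-4 base probabilities (default uniform).
#' @return Function \code{(donor_seq, acceptor_seq) -> list(donor, acceptor)}
#'   of numeric scores; windows containing N score \code{NA}.
#' @export
pwm_scorer <- function(donor_pwm, acceptor_pwm,
                       background = rep(0.25, 4)) {
  stopifnot(nrow(donor_pwm) == 4, nrow(acceptor_pwm) == 4,
            length(background) == 4)
  bases <- c("A", "C", "G", "T")
  rownames(donor_pwm) <- rownames(acceptor_pwm) <- bases
  names(background) <- bases
  score1 <- function(seq, pwm) {
    ch <- strsplit(seq, "")[[1]]
    ri <- match(ch, bases)
    if (length(ch) != ncol(pwm) || anyNA(ri)) return(NA_real_)
    sum(log2(pwm[cbind(ri, seq_along(ri))] / background[ri]))
  }
  function(donor_seq, acceptor_seq) {
    list(donor = vapply(donor_seq, score1, numeric(1), pwm = donor_pwm,
                        USE.NAMES = FALSE),
         acceptor = vapply(acceptor_seq, score1, numeric(1),
                           pwm = acceptor_pwm, USE.NAMES = FALSE))
  }
}

# strand-aware sequence extraction, 1-based closed genome coords
.get_seq <- function(genome, chrom, start, end, minus) {
  len <- Biostrings::width(genome[chrom])
  if (start < 1 || end > len) return(NA_character_)
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (minus) s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Splice-site strength of an exon
#'
#' Extracts the donor window (last 3 exonic + first 6 intronic nt of the
#' downstream intron, transcription direction) and acceptor window (last 20
#' intronic + first 3 exonic nt), scores them with a pluggable scorer
#' (default conventions follow maxEnt window sizes; maxEnt matrices may be
#' supplied via [pwm_scorer()] but are not bundled), and returns the sum.
#'
#' @param exon Length-1 GRanges.
#' @param genome DNAStringSet.
#' @param scorer Function as returned by [pwm_scorer()].
#' @return list(donor, acceptor, total); \code{total} is NA when either
#'   window contains N or runs off the chromosome (the exon is then excluded
#'   from strength comparisons).
#' @export
splice_site_strength <- function(exon, genome, scorer) {
  stopifnot(length(exon) == 1)
  chrom <- as.character(GenomicRanges::seqnames(exon))
  s <- GenomicRanges::start(exon); e <- GenomicRanges::end(exon)
  minus <- as.character(GenomicRanges::strand(exon)) == "-"
  if (minus) {
    donor_seq <- .get_seq(genome, chrom, s - 6, s + 2, TRUE)
    acceptor_seq <- .get_seq(genome, chrom, e - 2, e + 20, TRUE)
  } else {
    donor_seq <- .get_seq(genome, chrom, e - 2, e + 6, FALSE)
    acceptor_seq <- .get_seq(genome, chrom, s - 20, s + 2, FALSE)
  }
  if (is.na(donor_seq) || is.na(acceptor_seq))
    return(list(donor = NA_real_, acceptor = NA_real_, total = NA_real_))
  sc <- scorer(donor_seq, acceptor_seq)
  total <- sc$donor + sc$acceptor
  list(donor = sc$donor, acceptor = sc$acceptor, total = total)
}

#' Count junction reads supporting inclusion and exclusion of an exon
#'
#' Junctions are identified by exact intron coordinates: \code{JIR_up} /
#' \code{JIR_down} count reads whose split exactly matches the exon's
#' upstream / downstream flanking intron (transcription direction) and
#' \code{JER} reads matching the flank-to-flank skipping intron.
#'
#' @param junctions data.frame with columns \code{chrom},
#'   \code{intron_start}, \code{intron_end} (1-based closed),
#'   \code{strand}, \code{cell}, \code{replicate}, \code{count}.
#' @param catalog GRanges from [select_candidate_exons()] (carries the
#'   flanking-intron coordinates).
#' @return data.frame with one row per (exon, cell, replicate):
#'   \code{exon_id}, \code{cell}, \code{replicate}, \code{JIR_up},
#'   \code{JIR_down}, \code{JER}.
#' @export
count_junctions <- function(junctions, catalog) {
  need <- c("chrom", "intron_start", "intron_end", "strand", "cell",
            "replicate", "count")
  stopifnot(all(need %in% names(junctions)))
  jkey <- paste0(junctions$chrom, ":", junctions$intron_start, "-",
                 junctions$intron_end, ":", junctions$strand)
  chrom <- as.character(GenomicRanges::seqnames(catalog))
  strand <- as.character(GenomicRanges::strand(catalog))
  ukey <- paste0(chrom, ":", catalog$up_intron_start, "-",
                 catalog$up_intron_end, ":", strand)
  dkey <- paste0(chrom, ":", catalog$down_intron_start, "-",
                 catalog$down_intron_end, ":", strand)
  skey <- paste0(chrom, ":", catalog$skip_intron_start, "-",
                 catalog$skip_intron_end, ":", strand)
  groups <- unique(junctions[, c("cell", "replicate")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sel <- junctions$cell == groups$cell[g] &
      junctions$replicate == groups$replicate[g]
    cnt <- stats::setNames(junctions$count[sel], jkey[sel])
    cnt <- tapply(junctions$count[sel], jkey[sel], sum)
    look <- function(k) {
      v <- cnt[k]; v[is.na(v)] <- 0; as.integer(v)
    }
    data.frame(exon_id = catalog$exon_id,
               cell = groups$cell[g], replicate = groups$replicate[g],
               JIR_up = look(ukey), JIR_down = look(dkey), JER = look(skey),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
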