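# reference-space width consumed by a CIGAR string (M/D/N/=/X advance)
.cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1L]]
    if (ops[1L] == -1L) return(0L)
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    op <- sub("^\\d+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# SAM/BAM -> one 3'-end event per passing read
.sam_to_events <- function(path, library, min_mapq) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "mapq", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  keep <- !is.na(b$pos) & !is.na(b$mapq) & b$mapq >= min_mapq
  if (!any(keep)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character()))
  }
  chrom <- as.character(b$rname)[keep]
  start0 <- b$pos[keep] - 1L # SAM POS is 1-based
  end0 <- start0 + .cigar_ref_width(b$cigar[keep])
  aln_strand <- as.character(b$strand)[keep]
  if (library == "reverse") {
    # sequenced 5' base marks the transcript 3' end on the opposite strand
    pos <- ifelse(aln_strand == "+", start0, end0 - 1L)
    strand <- ifelse(aln_strand == "+", "-", "+")
  } else {
    pos <- ifelse(aln_strand == "+", end0 - 1L, start0)
    strand <- aln_strand
  }
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             stringsAsFactors = FALSE)
}

#' Per-base 3'-end count track
#'
#' Builds a strand-specific track counting the most 3' transcribed base of
#' each read. Input is either a data frame of 3'-end events (`chrom`,
#' `pos`, `strand`, optional `count`; positions are taken as transcript 3'
#' ends directly, as emitted by the simulator) or a path to a SAM/BAM file
#' of aligned reads. For SAM/BAM input with a `"reverse"` library, each
#' read contributes at its alignment's 5'-most reference base with the
#' strand flipped; with `"forward"`, at its 3'-most base on the alignment
#' strand. Alignments below `min_mapq` are discarded before counting, and
#' `mapped_reads` is the number of contributing reads.
#'
#' @param x Event data frame or SAM/BAM path.
#' @param genome A [genome_seq].
#' @param library `"reverse"` (default, matching 3'-end sequencing with a
#'   reverse library prep) or `"forward"`. Ignored for event input.
#' @param min_mapq Minimum mapping quality when consuming SAM/BAM
#'   (default 255, unique STAR alignments).
#' @param label Track label.
#' @return A raw-count [signal_track] with `mapped_reads` set.
#' @export
three_prime_end_track <- function(x, genome, library = c("reverse", "forward"),
                                  min_mapq = 255L, label = "") {
  library <- match.arg(library)
  if (is.character(x) && length(x) == 1L) {
    x <- .sam_to_events(x, library, min_mapq)
  }
  stopifnot(is.data.frame(x))
  if (is.null(x$count)) x$count <- 1L
  track <- signal_track(genome, label = label)
  if (nrow(x) > 0L) {
    if (any(!x$strand %in% c("+", "-"))) {
      stop("event strand must be '+' or '-'", call. = FALSE)
    }
    if (any(!x$chrom %in% names(genome$lengths)) ||
        any(x$pos < 0) || any(x$pos >= genome$lengths[x$chrom])) {
      stop("3'-end event beyond chromosome bounds", call. = FALSE)
    }
    for (chrom in unique(x$chrom)) {
      for (strand in c("+", "-")) {
        e <- x[x$chrom == chrom & x$strand == strand, , drop = FALSE]
        if (nrow(e) == 0L) next
        v <- track$values[[chrom]][[strand]]
        agg <- rowsum(e$count, e$pos)
        v[as.integer(rownames(agg)) + 1L] <- v[as.integer(rownames(agg)) + 1L] +
          agg[, 1L]
        track$values[[chrom]][[strand]] <- v
      }
    }
  }
  track$mapped_reads <- sum(x$count)
  track
}

#' Counts-per-million scaling
#'
#' Multiplies every per-base value by `1e6 / mapped_reads`, the scale
#' factor used for per-million normalized coverage tracks.
#'
#' @param track A raw [signal_track] with `mapped_reads > 0`.
#' @return The scaled track (`scaled = TRUE`).
#' @export
cpm_scale <- function(track) {
  stopifnot(inherits(track, "signal_track"))
  if (is.na(track$mapped_reads) || track$mapped_reads <= 0) {
    stop("cannot scale a track with mapped_reads = 0", call. = FALSE)
  }
  if (track$scaled) stop("track is already scaled", call. = FALSE)
  sf <- 1e6 / track$mapped_reads
  track$values <- lapply(track$values, function(v) {
    list("+" = v[["+"]] * sf, "-" = v[["-"]] * sf)
  })
  track$scale_factor <- sf
  track$scaled <- TRUE
  track
}

# both-strand signal summed in consecutive left-closed bins, chroms
# concatenated; the final partial bin is included
.binned_signal <- function(track, binsize) {
  unlist(lapply(names(track$values), function(chrom) {
    v <- track$values[[chrom]][["+"]] + track$values[[chrom]][["-"]]
    idx <- (seq_along(v) - 1L) %/% binsize
    as.numeric(rowsum(v, idx))
  }), use.names = FALSE)
}

#' Replicate similarity (Spearman over genomic bins)
#'
#' Signal is summed over both strands in consecutive 1 kb bins and tracks
#' compared pairwise by Spearman correlation (average ranks for ties).
#'
#' @param tracks List of >= 2 [signal_track]s on the same genome.
#' @param binsize Bin width in bp.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
replicate_correlation <- function(tracks, binsize = 1000L) {
  if (length(tracks) < 2L) stop("need >= 2 tracks", call. = FALSE)
  for (t in tracks[-1L]) {
    if (!.same_genome(tracks[[1L]], t)) {
      stop("tracks are on different genomes", call. = FALSE)
    }
  }
  m <- vapply(tracks, .binned_signal, binsize = binsize,
              numeric(length(.binned_signal(tracks[[1L]], binsize))))
  labs <- vapply(seq_along(tracks), function(i) {
    if (nzchar(tracks[[i]]$label)) tracks[[i]]$label else paste0("track", i)
  }, character(1))
  colnames(m) <- make.unique(labs)
  stats::cor(m, method = "spearman")
}

#' Merge biological replicates
#'
#' Per-base raw counts are summed and `mapped_reads` accumulated. Mixing
#' scaled and raw tracks is rejected.
#'
#' @param tracks List of raw [signal_track]s on the same genome.
#' @return A merged raw track.
#' @export
merge_replicates <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  if (any(vapply(tracks, function(t) isTRUE(t$scaled), logical(1)))) {
    stop("cannot merge scaled tracks (merge raw counts, then scale)",
         call. = FALSE)
  }
  out <- tracks[[1L]]
  for (t in tracks[-1L]) {
    if (!.same_genome(out, t)) {
      stop("tracks are on different genomes", call. = FALSE)
    }
    for (chrom in names(out$values)) {
      out$values[[chrom]][["+"]] <- out$values[[chrom]][["+"]] +
        t$values[[chrom]][["+"]]
      out$values[[chrom]][["-"]] <- out$values[[chrom]][["-"]] +
        t$values[[chrom]][["-"]]
    }
  }
  out$mapped_reads <- sum(vapply(tracks, function(t) t$mapped_reads,
                                 numeric(1)))
  out$label <- paste0(out$label, if (length(tracks) > 1L) "_merged" else "")
  out
}
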