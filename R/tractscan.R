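#' Find maximal homopolymer runs in a sequence
#'
#' Scans a DNA string for maximal runs of a single base. `N` never extends
#' a run. Coordinates are 0-based half-open within the supplied sequence.
#'
#' @param seq DNA string over {A,C,G,T,N}.
#' @param min_len Minimum run length to report (>= 1).
#' @param bases Bases whose runs are reported.
#' @return Data frame with columns `start`, `end`, `base`, `length`,
#'   sorted by `start`.
#' @export
find_homopolymer_runs <- function(seq, min_len = 5L,
                                  bases = c("A", "C", "G", "T")) {
  if (length(bases) == 0L) stop("empty base set", call. = FALSE)
  if (min_len < 1L) stop("min_len must be >= 1", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      base = character(), length = integer()))
  }
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values %in% bases & r$lengths >= min_len
  out <- data.frame(start = starts[keep], end = ends[keep],
                    base = r$values[keep], length = r$lengths[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# convergent overlapping opposite-strand ORF pairs -> their overlap regions.
# "Convergent" = the plus-strand gene lies 5'-most, so the two 3' ends face
# each other inside the overlap.
.convergent_overlaps <- function(genes) {
  out <- list()
  plus <- genes[genes$strand == "+", , drop = FALSE]
  minus <- genes[genes$strand == "-", , drop = FALSE]
  for (i in seq_len(nrow(plus))) {
    p <- plus[i, ]
    hit <- minus$chrom == p$chrom & minus$start < p$end & p$start < minus$end &
      p$start < minus$start
    for (j in which(hit)) {
      m <- minus[j, ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = p$chrom, start = max(p$start, m$start),
        end = min(p$end, m$end), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  do.call(rbind, out)
}

#' Scan extended ORFs for homopolymer tracts
#'
#' Each protein-coding, non-mitochondrial gene is extended 500 bp (by
#' default) downstream in a strand-aware manner and its coding-strand
#' sequence scanned for maximal homopolymer runs of at least `min_len`.
#' Runs that overlap more than one same-strand extended ORF, runs inside
#' the overlap of a convergent overlapping opposite-strand ORF pair, and
#' mitochondrial genes are discarded. Extensions are clamped at chromosome
#' ends.
#'
#' @param genome A [genome_seq].
#' @param genes Gene-model data frame ([gene_models()]); largest-ORF
#'   selection is assumed done.
#' @param flank Downstream extension in bp.
#' @param min_len Minimum run length.
#' @param bases Bases to scan.
#' @return Data frame of tracts: `chrom`, `start`, `end` (genomic, 0-based
#'   half-open), `base` (coding-strand identity), `length`, `gene_id`,
#'   `strand`, `region` (`"orf"` if the run overlaps the ORF, else
#'   `"downstream_flank"`), logical `in_orf`/`in_flank`, and
#'   `three_prime_end` (strand-aware last transcribed base of the run).
#' @export
scan_extended_orfs <- function(genome, genes, flank = 500L, min_len = 5L,
                               bases = c("A", "C", "G", "T")) {
  genes <- gene_models(genes)
  genes <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  keep_genes <- genes[!genes$is_mito, , drop = FALSE]
  conv <- .convergent_overlaps(keep_genes)

  # extended window per gene (strand-aware downstream extension, clamped)
  win_start <- ifelse(keep_genes$strand == "+", keep_genes$start,
                      pmax(keep_genes$start - flank, 0L))
  win_end <- ifelse(keep_genes$strand == "+",
                    pmin(keep_genes$end + flank,
                         genome$lengths[keep_genes$chrom]),
                    keep_genes$end)

  rows <- vector("list", nrow(keep_genes))
  for (i in seq_len(nrow(keep_genes))) {
    g <- keep_genes[i, ]
    ws <- win_start[i]; we <- win_end[i]
    if (we <= ws) next
    s <- get_seq(genome, g$chrom, ws, we, g$strand)
    runs <- find_homopolymer_runs(s, min_len = min_len, bases = bases)
    if (nrow(runs) == 0L) next
    if (g$strand == "+") {
      gs <- ws + runs$start; ge <- ws + runs$end
    } else {
      gs <- we - runs$end; ge <- we - runs$start
    }
    in_orf <- gs < g$end & ge > g$start
    in_flank <- if (g$strand == "+") ge > g$end else gs < g$start
    rows[[i]] <- data.frame(
      chrom = g$chrom, start = gs, end = ge, base = runs$base,
      length = runs$length, gene_id = g$gene_id, strand = g$strand,
      region = ifelse(in_orf, "orf", "downstream_flank"),
      in_orf = in_orf, in_flank = in_flank,
      three_prime_end = if (g$strand == "+") ge - 1L else gs,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      base = character(), length = integer(),
                      gene_id = character(), strand = character(),
                      region = character(), in_orf = logical(),
                      in_flank = logical(), three_prime_end = integer()))
  }

  # discard: run resolvable to >1 same-strand extended ORF
  n_hits <- vapply(seq_len(nrow(out)), function(k) {
    sum(keep_genes$chrom == out$chrom[k] & keep_genes$strand == out$strand[k] &
          win_start < out$end[k] & out$start[k] < win_end)
  }, integer(1))
  out <- out[n_hits <= 1L, , drop = FALSE]

  # discard: runs inside convergent overlapping opposite-strand ORF pairs
  if (nrow(conv) > 0L && nrow(out) > 0L) {
    in_conv <- vapply(seq_len(nrow(out)), function(k) {
      any(conv$chrom == out$chrom[k] & conv$start < out$end[k] &
            out$start[k] < conv$end)
    }, logical(1))
    out <- out[!in_conv, , drop = FALSE]
  }
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run-length frequency table by base and region
#'
#' Counts maximal-run lengths between `min_len` and `max_len` per base,
#' separately for runs overlapping the original ORF and runs overlapping
#' the downstream flank. A run overlapping both regions counts once in
#' each. Lengths above `max_len` accumulate in a `"<max_len>+"` bin.
#'
#' @param tracts Output of [scan_extended_orfs()].
#' @param min_len,max_len Length range of the table.
#' @return Tidy data frame `base` x `length` x `region` with a `count`
#'   column.
#' @export
tract_length_frequency <- function(tracts, min_len = 5L, max_len = 20L) {
  len_levels <- c(as.character(min_len:max_len), paste0(max_len, "+"))
  grid <- expand.grid(base = c("A", "C", "G", "T"), length = len_levels,
                      region = c("orf", "downstream_flank"),
                      stringsAsFactors = FALSE)
  grid$count <- 0L
  if (nrow(tracts) > 0L) {
    lab <- ifelse(tracts$length > max_len, paste0(max_len, "+"),
                  as.character(tracts$length))
    for (region in c("orf", "downstream_flank")) {
      sel <- if (region == "orf") tracts$in_orf else tracts$in_flank
      if (!any(sel)) next
      tab <- table(base = tracts$base[sel], length = lab[sel])
      for (b in rownames(tab)) for (l in colnames(tab)) {
        k <- grid$base == b & grid$length == l & grid$region == region
        grid$count[k] <- as.integer(tab[b, l])
      }
    }
  }
  grid
}

#' Longest-run profile around termination sites
#'
#' For every site, the +/-`flank` bp window is read on the site strand and,
#' for each base, the single largest homopolymer run is located (ties go to
#' the 5'-most run on the site strand). Only the run's strand-aware 3'-end
#' position is recorded and mapped into `nbins` equal bins across the
#' window; counts are summed over sites. Windows truncated by chromosome
#' ends are dropped (count reported as attribute `n_dropped`).
#'
#' @param sites Data frame with `chrom`, `pos` (0-based), `strand`.
#' @param genome A [genome_seq].
#' @param flank Half-window in bp.
#' @param nbins Number of bins across the 2*`flank` window.
#' @param min_run Minimum length for a run to count (a single base is not a
#'   run).
#' @return Integer matrix base x bin, with attribute `n_dropped`.
#' @export
flank_longest_run_profile <- function(sites, genome, flank = 500L,
                                      nbins = 100L, min_run = 2L) {
  if (is.null(sites$strand) || anyNA(sites$strand) ||
      !all(sites$strand %in% c("+", "-"))) {
    stop("every site needs a strand", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = 4L, ncol = nbins,
                   dimnames = list(bases, NULL))
  binwidth <- 2 * flank / nbins
  dropped <- 0L
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]; pos <- sites$pos[i]; strand <- sites$strand[i]
    L <- genome$lengths[[chrom]]
    ws <- pos - flank; we <- pos + flank
    if (is.null(L) || ws < 0 || we > L) {
      dropped <- dropped + 1L
      next
    }
    s <- get_seq(genome, chrom, ws, we, strand)
    runs <- find_homopolymer_runs(s, min_len = min_run, bases = bases)
    if (nrow(runs) == 0L) next
    for (b in bases) {
      rb <- runs[runs$base == b, , drop = FALSE]
      if (nrow(rb) == 0L) next
      best <- rb[order(-rb$length, rb$start), , drop = FALSE][1L, ]
      offset <- best$end - 1L # 3' end of the run in window coordinates
      bin <- min(floor(offset / binwidth) + 1L, nbins)
      counts[b, bin] <- counts[b, bin] + 1L
    }
  }
  attr(counts, "n_dropped") <- dropped
  counts
}
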