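#' Per-base treatment/control ratio track
#'
#' Computes `r = (t + c) / (w + c)` per base and strand, where `c` is a
#' pseudocount (default 3) that keeps the ratio finite where both tracks
#' are zero. Both inputs must be per-million scaled.
#'
#' @param treatment,control Scaled [signal_track]s on the same genome.
#' @param pseudocount Positive pseudocount added to both tracks.
#' @return A `ratio_track` (a [signal_track] of ratios).
#' @export
ratio_track <- function(treatment, control, pseudocount = 3) {
  stopifnot(inherits(treatment, "signal_track"),
            inherits(control, "signal_track"))
  if (!.same_genome(treatment, control)) {
    stop("treatment and control are on different genomes", call. = FALSE)
  }
  if (!isTRUE(treatment$scaled) || !isTRUE(control$scaled)) {
    stop("ratio requires per-million scaled tracks (see cpm_scale)",
         call. = FALSE)
  }
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  out <- treatment
  for (chrom in names(out$values)) {
    for (strand in c("+", "-")) {
      t <- treatment$values[[chrom]][[strand]]
      w <- control$values[[chrom]][[strand]]
      out$values[[chrom]][[strand]] <- (t + pseudocount) / (w + pseudocount)
    }
  }
  out$label <- sprintf("ratio(%s/%s)", treatment$label, control$label)
  out$scale_factor <- 1
  out$mapped_reads <- NA_real_
  class(out) <- c("ratio_track", class(out))
  out
}

#' Call termination islands downstream of genes
#'
#' For every protein-coding, non-mitochondrial gene the strand-matched
#' `window` bp immediately downstream of the ORF 3' end is scanned for
#' maximal runs of consecutive bases with ratio strictly greater than
#' `threshold`. Each run becomes an island, clipped to the region and
#' carrying the gene's strand; a single downstream region may contain
#' several islands. Islands separated by a sub-threshold base are not
#' merged, and width-1 islands are retained by default.
#'
#' @param ratio A `ratio_track` from [ratio_track()].
#' @param genes Gene-model data frame.
#' @param window Downstream region width in bp.
#' @param threshold Strict ratio threshold (default 2).
#' @param min_width Minimum island width in bp.
#' @return Data frame of islands: `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `max_ratio`, `mean_ratio`, `width`.
#' @export
call_termination_islands <- function(ratio, genes, window = 1000L,
                                     threshold = 2, min_width = 1L) {
  stopifnot(inherits(ratio, "signal_track"))
  genes <- gene_models(genes)
  genes <- genes[genes$biotype == "protein_coding" & !genes$is_mito, ,
                 drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    L <- ratio$chrom_lengths[[g$chrom]]
    if (is.null(L)) next
    if (g$strand == "+") {
      rs <- g$end; re <- min(g$end + window, L)
    } else {
      re <- g$start; rs <- max(g$start - window, 0L)
    }
    if (re <= rs) next
    v <- ratio$values[[g$chrom]][[g$strand]][(rs + 1L):re]
    above <- v > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    for (k in which(r$values)) {
      s <- rs + starts[k]; e <- rs + ends[k]
      if (e - s < min_width) next
      vals <- v[(starts[k] + 1L):ends[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = s, end = e, strand = g$strand,
        gene_id = g$gene_id, max_ratio = max(vals), mean_ratio = mean(vals),
        width = e - s, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), gene_id = character(),
                      max_ratio = numeric(), mean_ratio = numeric(),
                      width = integer()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract target and background sequences around islands
#'
#' For each island, the target is the `n` nt immediately 5' of the island
#' on the gene strand and the background the `n` nt immediately 3' of it
#' (both reverse-complemented for minus-strand genes). Islands too close to
#' a chromosome end are dropped with a warning.
#'
#' @param islands Output of [call_termination_islands()].
#' @param genome A [genome_seq].
#' @param n Flank width in nt (default 10).
#' @return List with `targets`, `backgrounds` (character vectors) and
#'   `islands` (the retained island rows).
#' @export
extract_motif_regions <- function(islands, genome, n = 10L) {
  if (n <= 0L) stop("n must be positive", call. = FALSE)
  keep <- logical(nrow(islands))
  targets <- backgrounds <- character(nrow(islands))
  for (i in seq_len(nrow(islands))) {
    chrom <- islands$chrom[i]
    L <- genome$lengths[[chrom]]
    s <- islands$start[i]; e <- islands$end[i]
    if (s - n < 0 || e + n > L) next
    keep[i] <- TRUE
    if (islands$strand[i] == "+") {
      targets[i] <- get_seq(genome, chrom, s - n, s)
      backgrounds[i] <- get_seq(genome, chrom, e, e + n)
    } else {
      targets[i] <- get_seq(genome, chrom, e, e + n, strand = "-")
      backgrounds[i] <- get_seq(genome, chrom, s - n, s, strand = "-")
    }
  }
  if (any(!keep)) {
    warning(sprintf("%d island(s) too close to a chromosome end dropped",
                    sum(!keep)), call. = FALSE)
  }
  list(targets = targets[keep], backgrounds = backgrounds[keep],
       islands = islands[keep, , drop = FALSE])
}

# region-level k-mer hits: a region counts once however often the k-mer
# occurs; no reverse-strand matching
.kmer_region_hits <- function(seqs, k) {
  hits <- lapply(seqs, function(s) {
    nc <- nchar(s)
    if (nc < k) return(character(0))
    unique(substring(s, 1:(nc - k + 1L), k:nc))
  })
  table(unlist(hits))
}

#' k-mer enrichment of target vs background regions
#'
#' A stand-in for de novo motif discovery: every k-mer present in the
#' target regions is tested for region-level enrichment against the
#' background regions with a one-sided Fisher exact test (hypergeometric
#' tail), and p-values are Benjamini-Hochberg adjusted across all tested
#' k-mers. Results are ranked by q-value, then descending fold enrichment.
#'
#' @param targets,backgrounds Character vectors of equal-length DNA regions.
#' @param k_range Motif widths to test (default 5..10).
#' @param max_report Number of top motifs returned.
#' @return Data frame: `kmer`, `k`, `target_hits`, `background_hits`,
#'   `fold_enrichment`, `p_value`, `q_value`.
#' @export
kmer_enrichment <- function(targets, backgrounds, k_range = 5:10,
                            max_report = 25L) {
  if (length(targets) == 0L || length(backgrounds) == 0L) {
    stop("empty target or background set", call. = FALSE)
  }
  n_t <- length(targets); n_b <- length(backgrounds)
  res <- list()
  for (k in k_range) {
    th_tab <- .kmer_region_hits(targets, k)
    if (length(th_tab) == 0L) next
    kmers <- names(th_tab)
    bh_all <- .kmer_region_hits(backgrounds, k)
    bh <- as.integer(bh_all[kmers])
    bh[is.na(bh)] <- 0L
    th <- as.integer(th_tab)
    # one-sided Fisher exact = hypergeometric upper tail
    p <- stats::phyper(th - 1L, th + bh, (n_t - th) + (n_b - bh), n_t,
                       lower.tail = FALSE)
    fold <- (th / n_t) / (bh / n_b)
    res[[length(res) + 1L]] <- data.frame(
      kmer = kmers, k = k, target_hits = th,
      background_hits = bh, fold_enrichment = fold, p_value = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$q_value, -out$fold_enrichment, out$p_value,
                   out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, max_report)
}

#' Motif occurrence summary over target regions and genes
#'
#' Counts target regions containing at least one hit of a motif (plain or
#' IUPAC) and genes with at least one such region.
#'
#' @param motif_regions Output of [extract_motif_regions()].
#' @param motif A k-mer or IUPAC pattern.
#' @param n_genes Total number of genes considered (for reporting).
#' @return List: `regions_with_motif`, `total_regions`, `genes_with_motif`,
#'   `total_genes`.
#' @export
motif_region_summary <- function(motif_regions, motif, n_genes = NA_integer_) {
  targets <- motif_regions$targets
  if (length(targets) == 0L) {
    return(list(regions_with_motif = 0L, total_regions = 0L,
                genes_with_motif = 0L, total_genes = n_genes))
  }
  hits <- Biostrings::vcountPattern(
    motif, Biostrings::DNAStringSet(targets), fixed = FALSE) > 0L
  genes_hit <- unique(motif_regions$islands$gene_id[hits])
  list(regions_with_motif = sum(hits), total_regions = length(targets),
       genes_with_motif = length(genes_hit), total_genes = n_genes)
}

#' Distribution of motif positions downstream of poly(A) sites
#'
#' For every hit (a strand-aware motif 3'-end position with a gene), the
#' distance from the gene's canonical poly(A) 3' edge is computed on the
#' transcription axis and binned. Hits upstream of the poly(A) site are
#' tallied separately.
#'
#' @param hits Data frame with `chrom`, `pos` (0-based motif 3'-end),
#'   `strand`, `gene_id`.
#' @param polya_sites Output of [assign_polya_sites()].
#' @param max_dist Maximum downstream distance retained.
#' @param binwidth Histogram bin width in bp.
#' @return List: `histogram` (data frame `bin_start`, `bin_end`, `count`),
#'   `negative_count`, `distances`, `ecdf`.
#' @export
motif_position_distribution <- function(hits, polya_sites, max_dist = 1000L,
                                        binwidth = 10L) {
  canon <- polya_sites[polya_sites$canonical %in% TRUE, , drop = FALSE]
  d <- rep(NA_real_, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    site <- canon[canon$gene_id %in% hits$gene_id[i], , drop = FALSE]
    if (nrow(site) == 0L) next
    site <- site[1L, ]
    # poly(A) 3'-edge base: last transcribed base of the site interval
    edge <- if (site$strand == "+") site$end - 1L else site$start
    d[i] <- if (hits$strand[i] == "+") hits$pos[i] - edge else edge - hits$pos[i]
  }
  d <- d[!is.na(d)]
  neg <- sum(d < 0)
  dd <- d[d >= 0 & d < max_dist]
  edges <- seq(0L, max_dist, by = binwidth)
  counts <- as.integer(table(cut(dd, edges, right = FALSE,
                                 include.lowest = FALSE)))
  list(histogram = data.frame(bin_start = edges[-length(edges)],
                              bin_end = edges[-1L], count = counts),
       negative_count = neg, distances = dd,
       ecdf = if (length(dd)) stats::ecdf(dd) else NULL)
}
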