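#' Filter, merge and gene-assign poly(A) sites
#'
#' Sites with score strictly greater than `score_min` are kept, overlapping
#' kept sites merged into non-overlapping intervals (score = maximum), and
#' each merged interval assigned to the nearest upstream protein-coding
#' gene whose ORF 3' end lies within `max_dist` bp, inheriting that gene's
#' strand. Unassignable sites are retained with `gene_id = NA` (they still
#' participate in the 50 bp exclusion of terminator tracts). A gene's
#' canonical site is its assigned site nearest the ORF end.
#'
#' @param polya Either a data frame with `chrom`, `start`, `end`, `score`,
#'   `strand`, or a list `list(plus = path, minus = path)` of score-valued
#'   bedGraph files.
#' @param genes Gene-model data frame.
#' @param score_min Strict score threshold (default 3).
#' @param max_dist Maximum ORF-end-to-site distance in bp (inclusive).
#' @return Data frame of merged sites: `chrom`, `start`, `end`, `score`,
#'   `strand` (gene strand where assigned, else the site's own), `gene_id`,
#'   `dist`, `canonical`.
#' @export
assign_polya_sites <- function(polya, genes, score_min = 3, max_dist = 500L) {
  if (is.list(polya) && !is.data.frame(polya)) {
    plus <- .read_bedgraph(polya$plus)
    minus <- .read_bedgraph(polya$minus)
    plus$strand <- if (nrow(plus)) "+" else character(0)
    minus$strand <- if (nrow(minus)) "-" else character(0)
    polya <- rbind(plus, minus)
    names(polya)[names(polya) == "value"] <- "score"
  }
  stopifnot(is.data.frame(polya))
  if (!is.numeric(polya$score) || anyNA(polya$score)) {
    stop("malformed score column", call. = FALSE)
  }
  genes <- gene_models(genes)
  genes <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  kept <- polya[polya$score > score_min, , drop = FALSE]
  if (nrow(kept) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric(),
                      strand = character(), gene_id = character(),
                      dist = integer(), canonical = logical()))
  }
  # merge strictly overlapping intervals per chrom+strand, score = max
  merged <- list()
  for (key in unique(paste(kept$chrom, kept$strand))) {
    b <- kept[paste(kept$chrom, kept$strand) == key, , drop = FALSE]
    b <- b[order(b$start, b$end), , drop = FALSE]
    cs <- b$start[1L]; ce <- b$end[1L]; sc <- b$score[1L]
    for (i in seq_len(nrow(b))[-1L]) {
      if (b$start[i] < ce) {
        ce <- max(ce, b$end[i]); sc <- max(sc, b$score[i])
      } else {
        merged[[length(merged) + 1L]] <- data.frame(
          chrom = b$chrom[1L], start = cs, end = ce, score = sc,
          strand = b$strand[1L], stringsAsFactors = FALSE)
        cs <- b$start[i]; ce <- b$end[i]; sc <- b$score[i]
      }
    }
    merged[[length(merged) + 1L]] <- data.frame(
      chrom = b$chrom[1L], start = cs, end = ce, score = sc,
      strand = b$strand[1L], stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, merged)

  sites$gene_id <- NA_character_
  sites$dist <- NA_integer_
  for (i in seq_len(nrow(sites))) {
    cand <- genes[genes$chrom == sites$chrom[i] &
                    genes$strand == sites$strand[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    d <- ifelse(cand$strand == "+", sites$start[i] - cand$end,
                cand$start - sites$end[i])
    ok <- d >= 0 & d <= max_dist
    if (!any(ok)) next
    j <- which(ok)[which.min(d[ok])]
    sites$gene_id[i] <- cand$gene_id[j]
    sites$dist[i] <- as.integer(d[j])
  }
  sites$canonical <- FALSE
  for (g in unique(stats::na.omit(sites$gene_id))) {
    k <- which(sites$gene_id == g)
    sites$canonical[k[which.min(sites$dist[k])]] <- TRUE
  }
  sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

# strand-aware 3' edge position of a poly(A) interval: the position just
# past the last transcribed base (half-open on the transcription axis)
.polya_3p_edge <- function(site) {
  if (site$strand == "+") site$end else site$start
}

#' Candidate terminator tracts downstream of poly(A) sites
#'
#' Scans the `window` bp downstream of each gene's canonical poly(A) site
#' (on the gene strand) for maximal homopolymer runs of at least `min_len`.
#' Tracts within `exclusion` bp (edge-to-edge, inclusive) of any kept
#' poly(A) site, or overlapping any snRNA/snoRNA/rRNA/tRNA annotation, are
#' discarded. Each surviving tract's strand-aware 3' end is recorded as its
#' anchor for coverage profiling.
#'
#' @param genome A [genome_seq].
#' @param polya_sites Output of [assign_polya_sites()].
#' @param genes Gene-model data frame.
#' @param min_len Minimum run length (the analysis is run at 5, 6, 7 and 8).
#' @param window Downstream scan window in bp.
#' @param exclusion Exclusion distance around kept poly(A) sites in bp.
#' @param ncrna Optional data frame of non-coding RNA intervals (`chrom`,
#'   `start`, `end`) to exclude.
#' @param bases Bases to scan.
#' @return Data frame of tracts with `chrom`, `start`, `end`, `base`,
#'   `length`, `gene_id`, `strand`, `three_prime_end`.
#' @export
candidate_terminator_tracts <- function(genome, polya_sites, genes,
                                        min_len = 6L, window = 1000L,
                                        exclusion = 50L, ncrna = NULL,
                                        bases = c("A", "C", "G", "T")) {
  genes <- gene_models(genes)
  genes <- genes[genes$biotype == "protein_coding" & !genes$is_mito, ,
                 drop = FALSE]
  assigned <- polya_sites[!is.na(polya_sites$gene_id) &
                            polya_sites$canonical, , drop = FALSE]
  rows <- list()
  for (g in genes$gene_id) {
    gene <- genes[genes$gene_id == g, , drop = FALSE][1L, ]
    site <- assigned[assigned$gene_id == g, , drop = FALSE]
    if (nrow(site) == 0L) {
      warning(sprintf("gene %s has no assigned poly(A) site; skipped", g),
              call. = FALSE)
      next
    }
    site <- site[1L, ]
    L <- genome$lengths[[gene$chrom]]
    if (gene$strand == "+") {
      ws <- .polya_3p_edge(site); we <- min(ws + window, L)
    } else {
      we <- .polya_3p_edge(site); ws <- max(we - window, 0L)
    }
    if (we <= ws) next
    s <- get_seq(genome, gene$chrom, ws, we, gene$strand)
    runs <- find_homopolymer_runs(s, min_len = min_len, bases = bases)
    if (nrow(runs) == 0L) next
    if (gene$strand == "+") {
      gs <- ws + runs$start; ge <- ws + runs$end
    } else {
      gs <- we - runs$end; ge <- we - runs$start
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = gene$chrom, start = gs, end = ge, base = runs$base,
      length = runs$length, gene_id = g, strand = gene$strand,
      three_prime_end = if (gene$strand == "+") ge - 1L else gs,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      base = character(), length = integer(),
                      gene_id = character(), strand = character(),
                      three_prime_end = integer()))
  }
  out <- do.call(rbind, rows)

  # edge-to-edge gap to any kept poly(A) site <= exclusion -> discard
  near_pa <- vapply(seq_len(nrow(out)), function(k) {
    p <- polya_sites[polya_sites$chrom == out$chrom[k], , drop = FALSE]
    if (nrow(p) == 0L) return(FALSE)
    gap <- pmax(p$start - out$end[k], out$start[k] - p$end, 0L)
    any(gap <= exclusion)
  }, logical(1))
  out <- out[!near_pa, , drop = FALSE]

  if (!is.null(ncrna) && nrow(ncrna) > 0L && nrow(out) > 0L) {
    hit <- vapply(seq_len(nrow(out)), function(k) {
      any(ncrna$chrom == out$chrom[k] & ncrna$start < out$end[k] &
            out$start[k] < ncrna$end)
    }, logical(1))
    out <- out[!hit, , drop = FALSE]
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
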