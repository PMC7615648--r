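#' Signal matrix around anchor points
#'
#' Builds an anchors x offsets matrix of sense-strand signal in the window
#' `[-upstream, +downstream)` around each anchor (offset 0 = the anchor
#' base). Minus-strand anchors read the minus-strand track right-to-left,
#' so every row is oriented 5'->3' on the anchor strand. Anchors whose
#' window leaves the chromosome are dropped (reported via attribute
#' `n_dropped`). With `binsize > 1` the signal is averaged within each bin.
#'
#' @param track A [signal_track] (typically scaled coverage).
#' @param anchors Data frame with `chrom`, `pos` (0-based), `strand` and an
#'   optional `id` column used as row names.
#' @param upstream,downstream Window extent in bp.
#' @param binsize Bin width; must divide `upstream + downstream`.
#' @return A numeric matrix of class `signal_matrix` with attributes
#'   `offsets` (bin-start offsets) and `n_dropped`.
#' @export
signal_matrix <- function(track, anchors, upstream = 20L, downstream = 20L,
                          binsize = 1L) {
  stopifnot(inherits(track, "signal_track"))
  width <- upstream + downstream
  if (width %% binsize != 0L) {
    stop("binsize must divide upstream + downstream", call. = FALSE)
  }
  if (is.null(anchors$id)) {
    anchors$id <- paste0(anchors$chrom, ":", anchors$pos, ":", anchors$strand)
  }
  offs <- seq(-upstream, downstream - 1L)
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(anchors))) {
    chrom <- anchors$chrom[i]; pos <- anchors$pos[i]
    strand <- anchors$strand[i]
    L <- track$chrom_lengths[[chrom]]
    gpos <- if (strand == "+") pos + offs else pos - offs
    if (is.null(L) || min(gpos) < 0L || max(gpos) >= L) {
      dropped <- dropped + 1L
      next
    }
    rows[[anchors$id[i]]] <- track$values[[chrom]][[strand]][gpos + 1L]
  }
  if (length(rows) == 0L) stop("no anchors left after clipping", call. = FALSE)
  m <- do.call(rbind, rows)
  colnames(m) <- as.character(offs)
  if (binsize > 1L) {
    grp <- rep(seq_len(width / binsize), each = binsize)
    m <- t(apply(m, 1L, function(r) tapply(r, grp, mean)))
    colnames(m) <- as.character(offs[seq(1L, width, by = binsize)])
  }
  structure(m, offsets = as.integer(colnames(m)), n_dropped = dropped,
            class = c("signal_matrix", class(m)))
}

#' Outlier-anchor blacklist
#'
#' Per sample, the `top_n` anchors with the largest row-maximum signal are
#' flagged (ties broken by row order); the blacklist is the union across
#' samples, so it never exceeds `top_n` times the number of samples.
#' Matrices with fewer than `top_n` rows flag all their rows.
#'
#' @param matrices List of [signal_matrix] objects sharing an anchor set.
#' @param top_n Number of outliers flagged per sample.
#' @return Character vector of blacklisted anchor ids.
#' @export
build_blacklist <- function(matrices, top_n = 100L) {
  stopifnot(length(matrices) >= 1L)
  ids <- rownames(matrices[[1L]])
  for (m in matrices[-1L]) {
    if (!identical(rownames(m), ids)) {
      stop("matrices must share the same anchor set", call. = FALSE)
    }
  }
  bl <- character(0)
  for (m in matrices) {
    rmax <- apply(m, 1L, max)
    ord <- order(-rmax, seq_along(rmax))
    bl <- union(bl, rownames(m)[ord[seq_len(min(top_n, nrow(m)))]])
  }
  sort(bl)
}

#' Mean metagene profile
#'
#' Arithmetic per-column mean over retained (non-blacklisted) anchors, plus
#' the row order (descending row sum) used for heatmap export.
#'
#' @param matrix A [signal_matrix].
#' @param blacklist Optional character vector of anchor ids to exclude.
#' @return List: `profile` (named numeric, one value per offset),
#'   `n_anchors`, `offsets`, `heatmap_order` (retained ids by descending
#'   row sum).
#' @export
mean_profile <- function(matrix, blacklist = NULL) {
  keep <- setdiff(rownames(matrix), blacklist)
  if (length(keep) == 0L) stop("all anchors blacklisted", call. = FALSE)
  m <- matrix[keep, , drop = FALSE]
  rs <- rowSums(m)
  list(profile = colMeans(m), n_anchors = length(keep),
       offsets = attr(matrix, "offsets"),
       heatmap_order = keep[order(-rs, seq_along(rs))])
}
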