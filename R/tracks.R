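#' Strand-specific per-base signal track
#'
#' A `signal_track` stores one non-negative numeric value per base per
#' strand for every chromosome of a genome, together with bookkeeping used
#' by the coverage module: `mapped_reads` (the read total used for
#' counts-per-million scaling), `scale_factor` and a `scaled` flag. Raw
#' 3'-end count tracks carry integer values and `scale_factor = 1`.
#'
#' @param genome A [genome_seq] the track is defined on.
#' @param label Free-text label carried through to outputs.
#' @return A zero-filled `signal_track`.
#' @export
signal_track <- function(genome, label = "") {
  stopifnot(inherits(genome, "genome_seq"))
  values <- lapply(genome$lengths, function(L) {
    list("+" = numeric(L), "-" = numeric(L))
  })
  names(values) <- names(genome$lengths)
  structure(
    list(values = values, chrom_lengths = genome$lengths, label = label,
         scale_factor = 1, mapped_reads = NA_real_, scaled = FALSE),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track '%s'> %d chromosome(s); total signal %.6g; %s\n",
              x$label, length(x$values), track_sum(x),
              if (x$scaled) sprintf("scaled (factor %.6g)", x$scale_factor)
              else "raw"))
  invisible(x)
}

#' Access the per-base values of one chromosome strand
#'
#' @param track A [signal_track].
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @return Numeric vector of per-base values.
#' @export
track_values <- function(track, chrom, strand) {
  stopifnot(inherits(track, "signal_track"), strand %in% c("+", "-"))
  v <- track$values[[chrom]]
  if (is.null(v)) stop(sprintf("unknown chromosome '%s'", chrom), call. = FALSE)
  v[[strand]]
}

#' Total signal in a track (both strands)
#'
#' @param track A [signal_track].
#' @return A number.
#' @export
track_sum <- function(track) {
  sum(vapply(track$values, function(v) sum(v[["+"]]) + sum(v[["-"]]),
             numeric(1)))
}

.same_genome <- function(a, b) {
  identical(names(a$chrom_lengths), names(b$chrom_lengths)) &&
    identical(as.integer(a$chrom_lengths), as.integer(b$chrom_lengths))
}

# parse one bedGraph file into a data frame, ignoring track/browser headers
.read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(parts) < 4L)) {
    stop("malformed bedGraph line (need 4 columns)", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  data.frame(chrom = m[, 1], start = as.integer(m[, 2]),
             end = as.integer(m[, 3]), value = as.numeric(m[, 4]),
             stringsAsFactors = FALSE)
}

#' Read a strand-specific bedGraph pair into a signal track
#'
#' Intervals are expanded to per-base values; uncovered positions are 0.
#' Overlapping intervals, negative values and out-of-bounds intervals are
#' rejected. Minus-strand signal is stored as non-negative values from its
#' own file, never negated.
#'
#' @param plus_bedgraph,minus_bedgraph Paths to the two strand files.
#' @param genome A [genome_seq].
#' @param label Track label.
#' @return A [signal_track].
#' @export
read_signal_track <- function(plus_bedgraph, minus_bedgraph, genome,
                              label = "") {
  track <- signal_track(genome, label = label)
  for (strand in c("+", "-")) {
    path <- if (strand == "+") plus_bedgraph else minus_bedgraph
    bg <- .read_bedgraph(path)
    if (nrow(bg) == 0L) next
    if (any(!bg$chrom %in% names(genome$lengths))) {
      stop("bedGraph chromosome absent from genome", call. = FALSE)
    }
    if (any(bg$value < 0) || anyNA(bg$value)) {
      stop("negative or missing bedGraph value", call. = FALSE)
    }
    for (chrom in unique(bg$chrom)) {
      b <- bg[bg$chrom == chrom, , drop = FALSE]
      b <- b[order(b$start), , drop = FALSE]
      L <- genome$lengths[[chrom]]
      if (any(b$start < 0) || any(b$end > L) || any(b$start >= b$end)) {
        stop(sprintf("bedGraph interval out of bounds on %s", chrom),
             call. = FALSE)
      }
      if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)])) {
        stop(sprintf("overlapping bedGraph intervals on %s", chrom),
             call. = FALSE)
      }
      v <- track$values[[chrom]][[strand]]
      for (i in seq_len(nrow(b))) {
        v[(b$start[i] + 1L):b$end[i]] <- b$value[i]
      }
      track$values[[chrom]][[strand]] <- v
    }
  }
  track
}

#' Write a signal track as a strand-specific bedGraph pair
#'
#' Adjacent equal values are merged into single intervals and zero runs are
#' omitted. Values are printed with 17 significant digits so that a
#' write/read round trip preserves every per-base value exactly. Files are
#' written as `<out_prefix>.plus.bedgraph` / `<out_prefix>.minus.bedgraph`.
#'
#' @param track A [signal_track].
#' @param out_prefix Output path prefix.
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_signal_track <- function(track, out_prefix) {
  stopifnot(inherits(track, "signal_track"))
  paths <- c("+" = paste0(out_prefix, ".plus.bedgraph"),
             "-" = paste0(out_prefix, ".minus.bedgraph"))
  for (strand in c("+", "-")) {
    con <- file(paths[[strand]], "w")
    for (chrom in names(track$values)) {
      v <- track$values[[chrom]][[strand]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (any(keep)) {
        writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                           .num17(r$values[keep])), con)
      }
    }
    close(con)
  }
  invisible(paths)
}
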