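#' Genome sequence container
#'
#' A `genome_seq` holds uppercase chromosome sequences over the alphabet
#' {A,C,G,T,N} together with their lengths. All coordinates in this package
#' are 0-based half-open; conversions to and from 1-based formats (GFF3,
#' FASTA substring arithmetic) happen only at I/O boundaries.
#'
#' @param sequences Named character vector, one DNA string per chromosome.
#' @return An object of class `genome_seq` with elements `seq` (named
#'   character) and `lengths` (named integer).
#' @export
genome_seq <- function(sequences) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("every sequence must be named by its chromosome", call. = FALSE)
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate chromosome name", call. = FALSE)
  }
  sequences <- toupper(sequences)
  sequences <- gsub("U", "T", sequences, fixed = TRUE)
  if (any(nchar(sequences) == 0L)) stop("empty sequence record", call. = FALSE)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop(sprintf("non-ACGTN character in sequence '%s'",
                 names(sequences)[bad][1L]), call. = FALSE)
  }
  structure(
    list(seq = sequences,
         lengths = stats::setNames(nchar(sequences), names(sequences))),
    class = "genome_seq"
  )
}

#' Load a genome from FASTA
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any character outside
#' {A,C,G,T,N} is rejected.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A [genome_seq] object.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop(sprintf("FASTA file not found: %s", fasta_path), call. = FALSE)
  }
  ss <- Biostrings::readBStringSet(fasta_path)
  nms <- sub("\\s.*$", "", names(ss))
  genome_seq(stats::setNames(as.character(ss), nms))
}

#' Write a genome to FASTA
#'
#' @param genome A [genome_seq].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_seq"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), path)
  invisible(path)
}

#' Extract a genomic subsequence
#'
#' @param genome A [genome_seq].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` returns the reference sequence, `"-"` its reverse
#'   complement.
#' @return A character scalar.
#' @export
get_seq <- function(genome, chrom, start, end, strand = "+") {
  stopifnot(inherits(genome, "genome_seq"))
  if (!chrom %in% names(genome$seq)) {
    stop(sprintf("unknown chromosome '%s'", chrom), call. = FALSE)
  }
  L <- genome$lengths[[chrom]]
  if (start < 0 || end > L || start >= end) {
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, L), call. = FALSE)
  }
  s <- substring(genome$seq[[chrom]], start + 1L, end)
  if (identical(strand, "-")) s <- .revcomp(s)
  s
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %d chromosome(s), %d bp total\n",
              length(x$seq), sum(x$lengths)))
  invisible(x)
}
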