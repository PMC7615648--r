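# shared fixtures: everything is generated in code at test time

# alternating ACGT background of length n: contains no homopolymer run >= 2
acgt_background <- function(n) {
  paste(rep(c("A", "C", "G", "T"), length.out = n), collapse = "")
}

# overwrite genome sequence at a 0-based half-open interval; refuses plant
# positions where the flanking background base would extend the run (keeps
# planted runs maximal at exactly their planted length)
plant_seq <- function(genome, chrom, start, piece) {
  s <- genome$seq[[chrom]]
  first <- substr(piece, 1L, 1L)
  last <- substr(piece, nchar(piece), nchar(piece))
  if (start > 0L && substr(s, start, start) == first) {
    stop("fixture error: 5' neighbour extends the planted run")
  }
  after <- start + nchar(piece) + 1L
  if (after <= nchar(s) && substr(s, after, after) == last) {
    stop("fixture error: 3' neighbour extends the planted run")
  }
  substr(s, start + 1L, start + nchar(piece)) <- piece
  genome$seq[[chrom]] <- s
  genome
}

# build a signal track and set per-base values directly
make_track <- function(genome, values = list(), label = "t",
                       mapped_reads = NA_real_, scaled = FALSE) {
  tr <- signal_track(genome, label = label)
  for (chrom in names(values)) {
    for (strand in names(values[[chrom]])) {
      v <- values[[chrom]][[strand]]
      stopifnot(length(v) <= genome$lengths[[chrom]])
      full <- numeric(genome$lengths[[chrom]])
      full[seq_along(v)] <- v
      tr$values[[chrom]][[strand]] <- full
    }
  }
  tr$mapped_reads <- mapped_reads
  tr$scaled <- scaled
  tr
}

# independent brute-force oracle for homopolymer runs, via regex
oracle_runs <- function(seq, min_len, bases = c("A", "C", "G", "T")) {
  out <- list()
  for (b in bases) {
    m <- gregexpr(sprintf("%s{%d,}", b, min_len), seq)[[1L]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    out[[b]] <- data.frame(start = as.integer(m) - 1L,
                           end = as.integer(m) - 1L + len,
                           base = b, length = len,
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      base = character(), length = integer()))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# small hand-built annotation exercising every discard rule:
# g1 keeps its tract; g2/g3 share a window (double assignment); g4/g5 are a
# convergent overlapping pair; gm is mitochondrial
discard_rule_fixture <- function() {
  genome <- genome_seq(c(chrA = acgt_background(3000),
                         chrM = acgt_background(500)))
  genome <- plant_seq(genome, "chrA", 501, "TTTTTTTT")   # g1 flank, survives
  genome <- plant_seq(genome, "chrA", 1300, "AAAAAA")    # g2+g3 windows
  genome <- plant_seq(genome, "chrA", 1702, "TTTTTT")    # g3 flank, survives
  genome <- plant_seq(genome, "chrA", 2321, "GGGGGG")    # convergent overlap
  genome <- plant_seq(genome, "chrM", 350, "TTTTTT")     # mito
  genes <- gene_models(data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "gm"),
    chrom = c(rep("chrA", 5), "chrM"),
    strand = c("+", "+", "+", "+", "-", "+"),
    start = c(100, 700, 1250, 2100, 2300, 100),
    end = c(400, 1000, 1550, 2400, 2600, 300),
    biotype = "protein_coding",
    is_mito = c(rep(FALSE, 5), TRUE)))
  list(genome = genome, genes = genes)
}

# deterministic multi-state FRET step trace (no noise)
step_trace <- function(levels, lengths, dt = 0.1, total = 1000) {
  e <- rep(levels, lengths)
  fret_trajectory(donor = (1 - e) * total, acceptor = e * total,
                  frame_interval_s = dt)
}
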