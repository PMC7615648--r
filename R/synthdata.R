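#' Condition presets for the 3'-end read simulator
#'
#' Read-fate fractions per condition: `frac_polya` (3' ends at the
#' canonical cleavage/poly(A) site), `frac_tract` (3' ends at planted
#' T-tract termination points) and `frac_noise` (uniform over the gene
#' +/- 1 kb). Wild type concentrates signal at poly(A) sites; nuclear
#' depletion of the cleavage endonuclease (Ysh1 anchor-away) or of the
#' torpedo exonuclease (Rat1 anchor-away) shifts signal to T-tract 3'
#' ends. Effect sizes are free parameters of the synthetic world, not
#' measured quantities.
#'
#' @return Data frame with one row per condition.
#' @export
condition_presets <- function() {
  data.frame(
    condition = c("WT", "Ysh1AA", "Rat1AA"),
    frac_polya = c(0.90, 0.30, 0.55),
    frac_tract = c(0.02, 0.45, 0.35),
    frac_noise = c(0.08, 0.25, 0.10),
    stringsAsFactors = FALSE
  )
}

# resample the middle of each unplanted homopolymer run >= 5 until none
# remain; planted intervals (and the tract bases themselves) are untouched
.break_background_runs <- function(chars, planted_start, planted_end) {
  bases <- c("A", "C", "G", "T")
  repeat {
    r <- rle(chars)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths # 0-based
    long <- which(r$lengths >= 5L)
    if (length(long) == 0L) return(chars)
    fixed_any <- FALSE
    for (k in long) {
      s <- starts[k]; e <- ends[k]
      if (length(planted_start) &&
          any(planted_start < e & s < planted_end)) next
      mid <- s + (e - s) %/% 2L # 0-based position to resample
      excl <- unique(c(r$values[k],
                       if (mid > 0L) chars[mid],
                       if (mid + 2L <= length(chars)) chars[mid + 2L]))
      chars[mid + 1L] <- sample(setdiff(bases, excl), 1L)
      fixed_any <- TRUE
    }
    if (!fixed_any) return(chars)
  }
}

#' Simulate a synthetic locus set with planted terminator tracts
#'
#' Generates a small genome of non-overlapping protein-coding genes on both
#' strands. Background sequence is i.i.d. uniform over ACGT with all
#' unplanted homopolymer runs >= 5 broken by resampling, so every run >= 5
#' found by a scanner is planted by construction. Each gene receives a
#' 1 bp poly(A) site 50-200 bp downstream of its ORF end (score > 3) and,
#' unless it belongs to the control subset, 1-3 planted T-tracts (coding
#' strand) 60-950 bp downstream of the poly(A) site; the strand-aware 3'
#' end of each terminator tract is a truth termination point. A fraction of
#' tract genes also get an ORF-internal T-tract; a disjoint control subset
#' gets a C- or G-tract in its terminator region instead. Low-score decoy
#' poly(A) entries exercise the strict score filter.
#'
#' @param n_genes Number of genes.
#' @param chrom_len Chromosome length in bp (default: computed to fit).
#' @param tract_len_range Planted tract length range (min >= 6).
#' @param seed RNG seed; runs are byte-identical under a fixed seed.
#' @param n_chroms Number of chromosomes.
#' @param gene_len_range ORF length range in bp.
#' @param orf_tract_frac Fraction of tract genes with an ORF-internal tract.
#' @param control_frac Fraction of genes in the control (C/G tract) subset.
#' @return A `locus_set` list: `genome`, `genes`, `polya_sites`,
#'   `planted_tracts`, `truth_points`, `params`.
#' @export
simulate_genome <- function(n_genes = 50L, chrom_len = NULL,
                            tract_len_range = c(6L, 10L), seed = 1L,
                            n_chroms = 2L, gene_len_range = c(300L, 900L),
                            orf_tract_frac = 0.3, control_frac = 0.2) {
  stopifnot(tract_len_range[1L] >= 6L, n_genes >= 1L)
  gpc <- ceiling(n_genes / n_chroms)
  slot <- 1200L + max(gene_len_range) + 1200L
  if (is.null(chrom_len)) chrom_len <- gpc * slot + 200L
  if (chrom_len < gpc * slot) {
    stop("infeasible packing: chrom_len too small for the requested genes",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    chrom_names <- paste0("chr", utils::as.roman(seq_len(n_chroms)))
    chars <- lapply(seq_len(n_chroms), function(i) {
      sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    })
    names(chars) <- chrom_names

    n_control <- floor(control_frac * n_genes)
    control_ids <- sort(sample(seq_len(n_genes), n_control))
    genes <- list(); polya <- list(); tracts <- list(); truth <- list()
    planted_iv <- stats::setNames(
      lapply(chrom_names, function(x) list(start = integer(), end = integer())),
      chrom_names)

    plant <- function(chrom, start, end, ref_base) {
      chars[[chrom]][(start + 1L):end] <<- ref_base
      if (start > 0L && chars[[chrom]][start] == ref_base) {
        # guard 5' flank so the planted run stays maximal at its length
        chars[[chrom]][start] <<- setdiff(c("C", "G", "A"), ref_base)[1L]
      }
      if (end < chrom_len && chars[[chrom]][end + 1L] == ref_base) {
        chars[[chrom]][end + 1L] <<- setdiff(c("C", "G", "A"), ref_base)[1L]
      }
      planted_iv[[chrom]]$start <<- c(planted_iv[[chrom]]$start, start - 1L)
      planted_iv[[chrom]]$end <<- c(planted_iv[[chrom]]$end, end + 1L)
    }

    for (i in seq_len(n_genes)) {
      chrom <- chrom_names[(i - 1L) %/% gpc + 1L]
      slot_start <- ((i - 1L) %% gpc) * slot
      strand <- if (i %% 2L == 1L) "+" else "-"
      gene_len <- sample(gene_len_range[1L]:gene_len_range[2L], 1L)
      orf_start <- slot_start + 1200L
      orf_end <- orf_start + gene_len
      gid <- sprintf("gene%03d", i)
      genes[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                               start = orf_start, end = orf_end,
                               biotype = "protein_coding", is_mito = FALSE,
                               stringsAsFactors = FALSE)
      d_pa <- sample(50:200, 1L)
      if (strand == "+") {
        pa_start <- orf_end + d_pa
      } else {
        pa_start <- orf_start - d_pa - 1L
      }
      polya[[length(polya) + 1L]] <- data.frame(
        chrom = chrom, start = pa_start, end = pa_start + 1L,
        score = round(stats::runif(1L, 4, 60), 2L), strand = strand,
        stringsAsFactors = FALSE)
      # low-score decoy, removed by the strict score > 3 filter
      if (stats::runif(1L) < 0.3) {
        dec <- if (strand == "+") pa_start + 25L else pa_start - 25L
        polya[[length(polya) + 1L]] <- data.frame(
          chrom = chrom, start = dec, end = dec + 1L,
          score = round(stats::runif(1L, 0.5, 3.0), 2L), strand = strand,
          stringsAsFactors = FALSE)
      }
      # poly(A) 3' edge in half-open transcription coordinates
      pa_edge <- if (strand == "+") pa_start + 1L else pa_start
      is_control <- i %in% control_ids
      n_tr <- if (is_control) 1L else sample(1:3, 1L)
      tract_base <- if (is_control) sample(c("C", "G"), 1L) else "T"
      offs <- sort(sample(seq(60L, 900L, by = 40L), n_tr))
      for (off in offs) {
        len <- sample(tract_len_range[1L]:tract_len_range[2L], 1L)
        if (strand == "+") {
          ts <- pa_edge + off; te <- ts + len
          tp <- te - 1L
        } else {
          te <- pa_edge - off; ts <- te - len
          tp <- ts
        }
        ref_base <- if (strand == "+") tract_base else
          chartr("ACGT", "TGCA", tract_base)
        plant(chrom, ts, te, ref_base)
        tracts[[length(tracts) + 1L]] <- data.frame(
          chrom = chrom, start = ts, end = te, base = tract_base,
          ref_base = ref_base, length = len, region = "terminator",
          gene_id = gid, strand = strand, stringsAsFactors = FALSE)
        if (!is_control) {
          truth[[length(truth) + 1L]] <- data.frame(
            chrom = chrom, pos = tp, strand = strand, gene_id = gid,
            stringsAsFactors = FALSE)
        }
      }
      # ORF-internal T-tract for a fraction of tract genes
      if (!is_control && stats::runif(1L) < orf_tract_frac) {
        len <- sample(tract_len_range[1L]:tract_len_range[2L], 1L)
        mid <- orf_start + gene_len %/% 2L
        ref_base <- if (strand == "+") "T" else "A"
        plant(chrom, mid, mid + len, ref_base)
        tracts[[length(tracts) + 1L]] <- data.frame(
          chrom = chrom, start = mid, end = mid + len, base = "T",
          ref_base = ref_base, length = len, region = "orf",
          gene_id = gid, strand = strand, stringsAsFactors = FALSE)
      }
    }
    for (chrom in chrom_names) {
      chars[[chrom]] <- .break_background_runs(
        chars[[chrom]], planted_iv[[chrom]]$start, planted_iv[[chrom]]$end)
    }
    genome <- genome_seq(vapply(chars, paste, character(1), collapse = ""))
    structure(
      list(genome = genome,
           genes = gene_models(do.call(rbind, genes)),
           polya_sites = do.call(rbind, polya),
           planted_tracts = do.call(rbind, tracts),
           truth_points = do.call(rbind, truth),
           params = list(n_genes = n_genes, chrom_len = chrom_len,
                         tract_len_range = tract_len_range, seed = seed,
                         n_chroms = n_chroms, control_ids = control_ids)),
      class = "locus_set")
  })
}

#' Write the poly(A) sites of a locus set as a bedGraph pair
#'
#' The score column is written as the bedGraph value, matching the
#' strand-specific score-valued bedGraph format used for putative poly(A)
#' site annotation.
#'
#' @param polya_sites Data frame `chrom`, `start`, `end`, `score`, `strand`.
#' @param out_prefix Output path prefix.
#' @return Named vector of the two paths, invisibly.
#' @export
write_polya_bedgraph <- function(polya_sites, out_prefix) {
  paths <- c("+" = paste0(out_prefix, ".plus.bedgraph"),
             "-" = paste0(out_prefix, ".minus.bedgraph"))
  for (strand in c("+", "-")) {
    b <- polya_sites[polya_sites$strand == strand, , drop = FALSE]
    b <- b[order(b$chrom, b$start), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d\t%s", b$chrom, b$start, b$end,
                       .num17(b$score)), paths[[strand]])
  }
  invisible(paths)
}

# per-gene 3'-end event table with multinomial probabilities
.build_event_table <- function(locus_set, frac_polya, frac_tract, frac_noise,
                               weights, polya_jitter = 2L) {
  genes <- locus_set$genes
  genome <- locus_set$genome
  jit_off <- -polya_jitter:polya_jitter
  jit_p <- (polya_jitter + 1L - abs(jit_off)) /
    sum(polya_jitter + 1L - abs(jit_off)) # discrete triangular
  ev <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    w <- weights[i]
    site <- locus_set$polya_sites[
      locus_set$polya_sites$strand == g$strand &
        locus_set$polya_sites$chrom == g$chrom &
        locus_set$polya_sites$score > 3, , drop = FALSE]
    d <- if (g$strand == "+") site$start - g$end else g$start - site$end
    ok <- which(d >= 0 & d <= 500)
    site <- site[ok[which.min(d[ok])], , drop = FALSE]
    pa_last <- if (g$strand == "+") site$end - 1L else site$start
    tp <- locus_set$truth_points[
      locus_set$truth_points$gene_id == g$gene_id, , drop = FALSE]
    f_pa <- frac_polya
    f_tr <- frac_tract
    if (nrow(tp) == 0L) { # genes without tracts: tract mass joins poly(A)
      f_pa <- f_pa + f_tr
      f_tr <- 0
    }
    sgn <- if (g$strand == "+") 1L else -1L
    ev[[length(ev) + 1L]] <- data.frame(
      chrom = g$chrom, pos = pa_last + sgn * jit_off, strand = g$strand,
      gene_id = g$gene_id, class = "polya", prob = w * f_pa * jit_p,
      stringsAsFactors = FALSE)
    if (nrow(tp) > 0L) {
      ev[[length(ev) + 1L]] <- data.frame(
        chrom = g$chrom, pos = tp$pos, strand = g$strand,
        gene_id = g$gene_id, class = "tract",
        prob = w * f_tr / nrow(tp), stringsAsFactors = FALSE)
    }
    L <- genome$lengths[[g$chrom]]
    ns <- max(g$start - 1000L, 0L); ne <- min(g$end + 1000L, L)
    npos <- ns:(ne - 1L)
    ev[[length(ev) + 1L]] <- data.frame(
      chrom = g$chrom, pos = npos, strand = g$strand, gene_id = g$gene_id,
      class = "noise", prob = w * frac_noise / length(npos),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, ev)
  out$prob <- out$prob / sum(out$prob)
  out
}

#' Simulate replicate 3'-end read count tracks for one condition
#'
#' Reads are allocated to genes proportionally to log-normal expression
#' weights (drawn once per call) and, within a gene, split between the
#' canonical poly(A) site (jittered +/-2 bp, discrete triangular), the
#' gene's truth termination points (no jitter) and uniform noise over the
#' gene +/- 1 kb, according to the condition's fractions. Per replicate,
#' counts are a single multinomial draw of `library_size` reads over all
#' 3'-end positions, optionally with gamma (negative-binomial-like)
#' overdispersion of per-gene totals across replicates.
#'
#' @param locus_set Output of [simulate_genome()].
#' @param condition `"WT"`, `"Ysh1AA"` or `"Rat1AA"` (preset fractions), or
#'   override the fractions directly.
#' @param frac_polya,frac_tract,frac_noise Optional overrides; must sum to 1.
#' @param library_size Reads per replicate.
#' @param n_replicates Number of replicates.
#' @param dispersion Gamma overdispersion of per-gene totals (0 = none).
#' @param expr_sdlog Log-normal sd of gene expression weights.
#' @param seed RNG seed.
#' @return List: `tracks` (raw-count [signal_track]s, one per replicate),
#'   `truth` (per-position expected fraction table), `params`.
#' @export
simulate_end_reads <- function(locus_set, condition = "Ysh1AA",
                               frac_polya = NULL, frac_tract = NULL,
                               frac_noise = NULL, library_size = 200000L,
                               n_replicates = 2L, dispersion = 0,
                               expr_sdlog = 0.5, seed = 1L) {
  stopifnot(inherits(locus_set, "locus_set"))
  if (library_size <= 0L) stop("zero library size", call. = FALSE)
  if (nrow(locus_set$genes) == 0L) stop("empty locus set", call. = FALSE)
  preset <- condition_presets()
  if (is.null(frac_polya)) {
    if (!condition %in% preset$condition) {
      stop("unknown condition and no explicit fractions", call. = FALSE)
    }
    p <- preset[preset$condition == condition, ]
    frac_polya <- p$frac_polya; frac_tract <- p$frac_tract
    frac_noise <- p$frac_noise
  }
  if (abs(frac_polya + frac_tract + frac_noise - 1) > 1e-9 ||
      any(c(frac_polya, frac_tract, frac_noise) < 0)) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  withr::with_seed(seed, {
    n <- nrow(locus_set$genes)
    weights <- stats::rlnorm(n, meanlog = 0, sdlog = expr_sdlog)
    weights <- weights / sum(weights)
    ev <- .build_event_table(locus_set, frac_polya, frac_tract, frac_noise,
                             weights)
    tracks <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      p <- ev$prob
      if (dispersion > 0) {
        mult <- stats::rgamma(n, shape = 1 / dispersion, rate = 1 / dispersion)
        names(mult) <- locus_set$genes$gene_id
        p <- p * mult[ev$gene_id]
        p <- p / sum(p)
      }
      counts <- as.integer(stats::rmultinom(1L, library_size, p))
      nz <- counts > 0L
      events <- data.frame(chrom = ev$chrom[nz], pos = ev$pos[nz],
                           strand = ev$strand[nz], count = counts[nz],
                           stringsAsFactors = FALSE)
      tracks[[r]] <- three_prime_end_track(
        events, locus_set$genome,
        label = sprintf("%s_rep%d", condition, r))
    }
    list(tracks = tracks, truth = ev,
         params = list(condition = condition, frac_polya = frac_polya,
                       frac_tract = frac_tract, frac_noise = frac_noise,
                       library_size = library_size,
                       n_replicates = n_replicates, dispersion = dispersion,
                       expr_sdlog = expr_sdlog, seed = seed))
  })
}

#' Simulate state-switching FRET traces with known truth
#'
#' A left-to-right Markov chain over FRET states (means sorted descending
#' from an initial high state near 0.9) with exponential dwell times; the
#' final state is absorbing when its dwell mean is infinite. Donor and
#' acceptor intensities are generated so that acceptor/(acceptor+donor)
#' equals the state mean plus Gaussian noise of sd `emission_sd` (clamped
#' to [0, 1]).
#'
#' @param n_traces Number of traces.
#' @param state_means FRET state means, strictly descending.
#' @param dwell_means_s Per-state exponential dwell means in seconds.
#' @param emission_sd Gaussian emission noise sd (> 0 unless exactly 0 for
#'   noiseless tests).
#' @param frame_interval_s Frame interval in seconds.
#' @param trace_len_s Trace duration in seconds.
#' @param total_intensity Donor + acceptor intensity (arbitrary units).
#' @param seed RNG seed.
#' @return List of [fret_trajectory] objects with `truth_path` set.
#' @export
simulate_fret_traces <- function(n_traces = 100L,
                                 state_means = c(0.9, 0.6, 0.3, 0),
                                 dwell_means_s = c(20, 10, 10, Inf),
                                 emission_sd = 0.05, frame_interval_s = 0.1,
                                 trace_len_s = 200, total_intensity = 1000,
                                 seed = 1L) {
  if (any(state_means < 0 | state_means > 1)) {
    stop("state mean outside [0,1]", call. = FALSE)
  }
  if (is.unsorted(rev(state_means), strictly = TRUE)) {
    stop("state means must be strictly descending", call. = FALSE)
  }
  if (emission_sd < 0) stop("emission_sd must be >= 0", call. = FALSE)
  stopifnot(length(dwell_means_s) == length(state_means))
  n_frames <- round(trace_len_s / frame_interval_s)
  withr::with_seed(seed, {
    lapply(seq_len(n_traces), function(i) {
      path <- integer(0)
      state <- 1L
      while (length(path) < n_frames) {
        dm <- dwell_means_s[state]
        if (is.infinite(dm) || state == length(state_means)) {
          path <- c(path, rep(state, n_frames - length(path)))
          break
        }
        k <- max(1L, round(stats::rexp(1L, 1 / dm) / frame_interval_s))
        path <- c(path, rep(state, min(k, n_frames - length(path))))
        state <- state + 1L
      }
      e <- state_means[path]
      if (emission_sd > 0) e <- e + stats::rnorm(n_frames, 0, emission_sd)
      e <- pmin(pmax(e, 0), 1)
      fret_trajectory(donor = (1 - e) * total_intensity,
                      acceptor = e * total_intensity,
                      frame_interval_s = frame_interval_s,
                      truth_path = path)
    })
  })
}
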