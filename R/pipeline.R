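#' Default pipeline configuration
#'
#' All analysis thresholds default to the values used throughout the
#' termination analysis: 500 bp ORF extension, minimum run length 5,
#' poly(A) score > 3, 1 kb downstream windows, 50 bp poly(A) exclusion,
#' pseudocount 3, ratio threshold 2, 10 nt motif flanks, motif widths
#' 5-10, top-100-per-sample blacklist.
#'
#' @param ... Named overrides of any config entry (nested lists are
#'   replaced wholesale).
#' @return A named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(n_genes = 50L, chrom_len = NULL, n_chroms = 2L,
                    tract_len_range = c(6L, 10L),
                    library_size = 200000L, n_replicates = 2L,
                    dispersion = 0,
                    treatment = "Ysh1AA", control = "WT"),
    flank = 500L, min_len = 5L, score_min = 3, window = 1000L,
    exclusion = 50L, pseudocount = 3, ratio_threshold = 2,
    motif_n = 10L, k_range = c(5L, 10L), blacklist_top_n = 100L,
    metagene_upstream = 20L, metagene_downstream = 20L,
    terminator_min_len = 6L
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], .num10)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end synthetic termination analysis
#'
#' Simulates a genome with planted terminator tracts, simulates replicate
#' 3'-end reads for a treatment and a control condition, builds raw and
#' per-million-scaled merged coverage, replicate QC, the treatment/control
#' ratio track, termination islands, motif-region k-mer enrichment,
#' poly(A)-site assignment with candidate terminator tracts, and a
#' metagene matrix/profile around planted tract 3' ends. Every output is
#' written under `out_dir` and recorded, with md5 checksums, in
#' `manifest.json`; reruns with the same config are bit-identical.
#'
#' @param config A configuration list from [default_config()], or a path
#'   to a JSON file of one.
#' @param out_dir Output directory (created; must not exist unless
#'   `overwrite`).
#' @param overwrite Allow writing into an existing directory.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         overwrite = FALSE) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  base <- default_config()
  for (nm in setdiff(names(base), names(config))) config[[nm]] <- base[[nm]]
  for (nm in setdiff(names(base$simulate), names(config$simulate))) {
    config$simulate[[nm]] <- base$simulate[[nm]]
  }
  if (dir.exists(out_dir) && !overwrite) {
    stop(sprintf("output directory exists: %s", out_dir), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$simulate
  msg <- function(...) message(sprintf(...))

  msg("[simulate] genome with %d genes (seed %d)", sim$n_genes, config$seed)
  locus <- simulate_genome(
    n_genes = sim$n_genes, chrom_len = sim$chrom_len,
    tract_len_range = sim$tract_len_range, seed = config$seed,
    n_chroms = sim$n_chroms)
  write_genome_fasta(locus$genome, file.path(out_dir, "genome.fa"))
  write_genes_gff3(locus$genes, file.path(out_dir, "genes.gff3"))
  write_genes_bed(locus$genes, file.path(out_dir, "genes.bed"))
  write_polya_bedgraph(locus$polya_sites, file.path(out_dir, "polya"))
  .write_tsv(locus$planted_tracts, file.path(out_dir, "truth_tracts.tsv"))
  .write_tsv(locus$truth_points, file.path(out_dir, "truth_points.tsv"))

  conds <- c(sim$treatment, sim$control)
  merged_scaled <- list()
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    msg("[reads] %s: %d x %d reads", cond, sim$n_replicates, sim$library_size)
    reads <- simulate_end_reads(
      locus, condition = cond, library_size = sim$library_size,
      n_replicates = sim$n_replicates, dispersion = sim$dispersion,
      seed = config$seed + ci)
    for (r in seq_along(reads$tracks)) {
      write_signal_track(reads$tracks[[r]],
                         file.path(out_dir, sprintf("%s_rep%d", cond, r)))
    }
    if (length(reads$tracks) >= 2L) {
      qc <- replicate_correlation(reads$tracks)
      .write_tsv(data.frame(pair = rownames(qc)[row(qc)[upper.tri(qc)]],
                            vs = colnames(qc)[col(qc)[upper.tri(qc)]],
                            spearman = qc[upper.tri(qc)]),
                 file.path(out_dir, sprintf("qc_%s.tsv", cond)))
    }
    merged <- merge_replicates(reads$tracks)
    scaled <- cpm_scale(merged)
    scaled$label <- cond
    write_signal_track(scaled, file.path(out_dir, sprintf("%s_merged", cond)))
    merged_scaled[[cond]] <- scaled
  }

  msg("[islands] ratio %s/%s, pseudocount %g, threshold %g",
      sim$treatment, sim$control, config$pseudocount, config$ratio_threshold)
  ratio <- ratio_track(merged_scaled[[sim$treatment]],
                       merged_scaled[[sim$control]],
                       pseudocount = config$pseudocount)
  islands <- call_termination_islands(ratio, locus$genes,
                                      window = config$window,
                                      threshold = config$ratio_threshold)
  .write_tsv(islands, file.path(out_dir, "islands.tsv"))

  motifs <- NULL
  if (nrow(islands) > 0L) {
    regions <- extract_motif_regions(islands, locus$genome,
                                     n = config$motif_n)
    writeLines(c(rbind(sprintf(">target_%d", seq_along(regions$targets)),
                       regions$targets)),
               file.path(out_dir, "targets.fa"))
    writeLines(c(rbind(sprintf(">background_%d",
                               seq_along(regions$backgrounds)),
                       regions$backgrounds)),
               file.path(out_dir, "backgrounds.fa"))
    motifs <- kmer_enrichment(regions$targets, regions$backgrounds,
                              k_range = config$k_range[1L]:config$k_range[2L])
    .write_tsv(motifs, file.path(out_dir, "motifs.tsv"))
  }

  msg("[polya] assignment and terminator tracts (min_len %d)",
      config$terminator_min_len)
  assigned <- assign_polya_sites(locus$polya_sites, locus$genes,
                                 score_min = config$score_min)
  .write_tsv(assigned, file.path(out_dir, "polya_assigned.tsv"))
  term_tracts <- suppressWarnings(candidate_terminator_tracts(
    locus$genome, assigned, locus$genes,
    min_len = config$terminator_min_len, window = config$window,
    exclusion = config$exclusion))
  .write_tsv(term_tracts, file.path(out_dir, "terminator_tracts.tsv"))

  msg("[metagene] +/-%d bp around tract 3' ends", config$metagene_upstream)
  anchors <- data.frame(chrom = term_tracts$chrom,
                        pos = term_tracts$three_prime_end,
                        strand = term_tracts$strand,
                        id = sprintf("%s_%d", term_tracts$gene_id,
                                     term_tracts$three_prime_end))
  mats <- lapply(merged_scaled, signal_matrix, anchors = anchors,
                 upstream = config$metagene_upstream,
                 downstream = config$metagene_downstream)
  blacklist <- build_blacklist(mats, top_n = config$blacklist_top_n)
  writeLines(blacklist, file.path(out_dir, "blacklist.txt"))
  if (length(setdiff(rownames(mats[[sim$treatment]]), blacklist)) == 0L) {
    warning("blacklist covers every anchor; profiling without it",
            call. = FALSE)
    blacklist_used <- character(0)
  } else {
    blacklist_used <- blacklist
  }
  prof <- mean_profile(mats[[sim$treatment]], blacklist = blacklist_used)
  .write_tsv(data.frame(offset = prof$offsets, mean = prof$profile),
             file.path(out_dir, "metagene_profile.tsv"))
  m <- mats[[sim$treatment]]
  .write_tsv(data.frame(anchor = rownames(m),
                        as.data.frame(unclass(m), check.names = FALSE)),
             file.path(out_dir, "metagene_matrix.tsv"))

  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "tterm",
    version = as.character(utils::packageVersion("tterm")),
    seed = config$seed,
    config = config,
    checksums = as.list(tools::md5sum(file.path(out_dir, sort(files))))
  )
  names(manifest$checksums) <- sort(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(locus = locus, tracks = merged_scaled, islands = islands,
                 motifs = motifs, polya = assigned,
                 terminator_tracts = term_tracts, matrices = mats,
                 blacklist = blacklist, profile = prof,
                 manifest = manifest))
}
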