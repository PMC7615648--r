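scaled_pair <- function(genome, t_vals, w_vals, chrom = "chrA") {
  t <- make_track(genome, stats::setNames(list(list("+" = t_vals)), chrom),
                  label = "t", scaled = TRUE)
  w <- make_track(genome, stats::setNames(list(list("+" = w_vals)), chrom),
                  label = "w", scaled = TRUE)
  list(t = t, w = w)
}

test_that("ratio track applies the pseudocount per base", {
  g <- genome_seq(c(chrA = acgt_background(10)))
  tw <- scaled_pair(g, c(0, 9, 5, 2), c(0, 3, 5, 7))
  r <- ratio_track(tw$t, tw$w, pseudocount = 3)
  v <- track_values(r, "chrA", "+")
  expect_equal(v[1], 1)          # 0/0 with pseudocount: 3/3
  expect_equal(v[2], 2)          # (9+3)/(3+3) = 2, the strict boundary
  expect_equal(v[3], 1)          # t = w
  expect_equal(v[5], 1)          # untouched positions
  expect_error(ratio_track(tw$t, tw$w, pseudocount = 0), "pseudocount")
  raw <- make_track(g)
  expect_error(ratio_track(raw, tw$w), "scaled")
})

test_that("island calling matches hand-computed run boundaries", {
  g <- genome_seq(c(chrA = acgt_background(200)))
  genes <- gene_models(data.frame(gene_id = "g", chrom = "chrA",
                                  strand = "+", start = 10L, end = 100L))
  # downstream region [100, 200); craft scaled values giving the ratio row
  # [1, 2.5, 2.5, 1, ...] at positions 100..103 and the r = 2 boundary at 110
  tv <- numeric(200); wv <- numeric(200)
  tv[102:103] <- 4.5           # (4.5+3)/3 = 2.5 at positions 101,102
  tv[111] <- 9; wv[111] <- 3   # exactly 2 at position 110: not > 2
  tv[151:155] <- 27            # (27+3)/3 = 10 at positions 150..154
  tw <- scaled_pair(g, tv, wv)
  isl <- call_termination_islands(ratio_track(tw$t, tw$w), genes)
  expect_equal(nrow(isl), 2L)
  expect_equal(isl$start, c(101L, 150L))
  expect_equal(isl$end, c(103L, 155L))
  expect_equal(isl$gene_id, c("g", "g"))
  expect_equal(isl$max_ratio, c(2.5, 10))
  # maximality: the base on either side of each island is <= threshold
  r <- track_values(ratio_track(tw$t, tw$w), "chrA", "+")
  for (i in seq_len(nrow(isl))) {
    expect_lte(r[isl$start[i]], 2)      # base before (1-based index start)
    expect_lte(r[isl$end[i] + 1L], 2)   # base after
  }
  # no islands above an unreachable threshold
  expect_equal(nrow(call_termination_islands(
    ratio_track(tw$t, tw$w), genes, threshold = Inf)), 0L)
})

test_that("islands are clipped to the 1 kb downstream region", {
  g <- genome_seq(c(chrA = acgt_background(3000)))
  genes <- gene_models(data.frame(gene_id = "g", chrom = "chrA",
                                  strand = "+", start = 100L, end = 500L))
  tv <- numeric(3000); tv[1495:1510] <- 50 # straddles the window end at 1500
  tw <- scaled_pair(g, tv, numeric(3000))
  isl <- call_termination_islands(ratio_track(tw$t, tw$w), genes)
  expect_equal(isl$end, 1500L)
})

test_that("motif regions follow the strand conventions exactly", {
  seqA <- acgt_background(100)
  g <- genome_seq(c(chrA = seqA))
  isl <- data.frame(chrom = "chrA", start = 40L, end = 44L,
                    strand = "+", gene_id = "g")
  reg <- extract_motif_regions(isl, g, n = 10)
  expect_equal(reg$targets, substring(seqA, 31, 40))   # genome[30,40)
  expect_equal(reg$backgrounds, substring(seqA, 45, 54)) # genome[44,54)

  isl$strand <- "-"
  regm <- extract_motif_regions(isl, g, n = 10)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(regm$targets, rc(substring(seqA, 45, 54)))
  expect_equal(regm$backgrounds, rc(substring(seqA, 31, 40)))

  # islands too close to the chromosome end are dropped with a warning
  isl2 <- data.frame(chrom = "chrA", start = c(3L, 40L), end = c(6L, 44L),
                     strand = "+", gene_id = c("a", "b"))
  expect_warning(r2 <- extract_motif_regions(isl2, g, n = 10), "dropped")
  expect_equal(nrow(r2$islands), 1L)
  expect_error(extract_motif_regions(isl, g, n = 0), "positive")
})

test_that("k-mer enrichment separates, nulls and matches the exact test", {
  targets <- rep("TTTTTTTTTT", 20)
  backgrounds <- rep("ACACACACAC", 20)
  res <- kmer_enrichment(targets, backgrounds)
  top8 <- res[res$k == 8, ][1, ]
  expect_equal(top8$kmer, "TTTTTTTT")
  expect_equal(top8$target_hits, 20L)
  expect_equal(top8$background_hits, 0L)

  # identical sets: nothing significant
  set.seed(3)
  same <- replicate(30, paste(sample(c("A", "C", "G", "T"), 10,
                                     replace = TRUE), collapse = ""))
  resn <- kmer_enrichment(same, same)
  expect_true(all(resn$q_value >= 0.05))

  expect_error(kmer_enrichment(character(0), backgrounds), "empty")
})

test_that("the one-sided Fisher p equals a brute-force hypergeometric tail sum", {
  # 2x2 table: 40/50 target hits vs 5/50 background hits
  targets <- c(rep("GATTACAGAT", 40), rep("CCCCCCCCCC", 10))
  backgrounds <- c(rep("GATTACAGAT", 5), rep("CCCCCCCCCC", 45))
  res <- kmer_enrichment(targets, backgrounds, k_range = 10, max_report = 100)
  p_impl <- res$p_value[res$kmer == "GATTACAGAT"]
  # oracle: sum the hypergeometric pmf over the upper tail directly
  m <- 45; n_other <- 55; k_draw <- 50
  p_oracle <- sum(vapply(40:45, function(a) {
    choose(m, a) * choose(n_other, k_draw - a) / choose(m + n_other, k_draw)
  }, numeric(1)))
  expect_equal(p_impl, p_oracle, tolerance = 1e-12)
  # cross-check against stats::fisher.test as an independent route
  ft <- stats::fisher.test(matrix(c(40, 5, 10, 45), 2), alternative = "greater")
  expect_equal(p_impl, ft$p.value, tolerance = 1e-9)
})

test_that("motif region summaries count regions and genes", {
  g <- genome_seq(c(chrA = acgt_background(100)))
  mr <- list(targets = c("TTTTTTTTAC", "ACGTACGTAC", "GGTTTTTTTT"),
             backgrounds = rep("ACGTACGTAC", 3),
             islands = data.frame(gene_id = c("g1", "g2", "g1")))
  s <- motif_region_summary(mr, "TTTTTTTT", n_genes = 10)
  expect_equal(s$regions_with_motif, 2L)
  expect_equal(s$total_regions, 3L)
  expect_equal(s$genes_with_motif, 1L)
  expect_equal(s$total_genes, 10)
  empty <- motif_region_summary(list(targets = character(0),
                                     islands = data.frame(gene_id = character(0))),
                                "TTTTTTTT", n_genes = 5)
  expect_equal(empty$regions_with_motif, 0L)
})

test_that("motif position distances are strand-aware offsets from the poly(A) edge", {
  sites <- data.frame(chrom = "chrA", start = c(500L, 2000L),
                      end = c(501L, 2001L), score = 10,
                      strand = c("+", "-"), gene_id = c("gP", "gM"),
                      dist = 100L, canonical = TRUE)
  hits <- data.frame(chrom = "chrA", pos = c(500L, 620L, 2000L, 1880L, 480L),
                     strand = c("+", "+", "-", "-", "+"),
                     gene_id = c("gP", "gP", "gM", "gM", "gP"))
  d <- motif_position_distribution(hits, sites)
  # at the edge: distance 0 lands in the first bin
  expect_equal(d$histogram$count[1], 2L) # pos 500 (gP) and 2000 (gM)
  # plus-strand +120 and its minus-strand mirror both land in bin 13
  expect_equal(d$histogram$count[13], 2L)
  expect_equal(d$negative_count, 1L)
  expect_equal(sum(d$histogram$count), 4L)
})

test_that("planted termination points are recovered in a low-noise world", {
  # exercises the caller's recovery properties with background noise turned
  # nearly off, so that ratio islands reflect planted truth rather than
  # sampling noise
  ls <- simulate_genome(n_genes = 25, seed = 7)
  tre <- simulate_end_reads(ls, "custom", frac_polya = 0.549,
                            frac_tract = 0.45, frac_noise = 0.001,
                            library_size = 200000, n_replicates = 2, seed = 7)
  ctl <- simulate_end_reads(ls, "custom", frac_polya = 0.989,
                            frac_tract = 0.01, frac_noise = 0.001,
                            library_size = 200000, n_replicates = 2, seed = 7)
  rt <- ratio_track(cpm_scale(merge_replicates(tre$tracks)),
                    cpm_scale(merge_replicates(ctl$tracks)))
  isl <- call_termination_islands(rt, ls$genes)
  tp <- ls$truth_points
  hit <- vapply(seq_len(nrow(isl)), function(i) {
    any(tp$chrom == isl$chrom[i] & tp$strand == isl$strand[i] &
          tp$pos >= isl$start[i] - 1L & tp$pos <= isl$end[i])
  }, logical(1))
  rec <- vapply(seq_len(nrow(tp)), function(i) {
    any(isl$chrom == tp$chrom[i] & isl$strand == tp$strand[i] &
          tp$pos[i] >= isl$start - 1L & tp$pos[i] <= isl$end)
  }, logical(1))
  expect_gte(mean(hit), 0.9)   # precision
  expect_gte(mean(rec), 0.9)   # recall
  # island count is non-increasing in the ratio threshold
  n_by_thr <- vapply(c(1.5, 2, 3, 5), function(th) {
    nrow(call_termination_islands(rt, ls$genes, threshold = th))
  }, numeric(1))
  expect_true(all(diff(n_by_thr) <= 0))
  # the T-rich motif dominates the enrichment ranking
  reg <- extract_motif_regions(isl, ls$genome)
  mt <- kmer_enrichment(reg$targets, reg$backgrounds, max_report = 1000)
  top8 <- mt[mt$k == 8, ][1, ]
  expect_gte(sum(strsplit(top8$kmer, "")[[1]] == "T"), 7)
  # most targets carry >= 5 consecutive T from the planted tract
  expect_gte(mean(grepl("TTTTT", reg$targets)), 0.8)
})
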