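# minimal SAM writer for coverage tests
write_sam <- function(path, chrom_len, aln) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_len), chrom_len))
  rec <- sprintf("r%d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                 seq_len(nrow(aln)), aln$flag, aln$chrom, aln$pos1,
                 aln$mapq, aln$cigar)
  writeLines(c(hdr, rec), path)
}

test_that("event input reproduces simulator counts exactly and conserves reads", {
  ls <- simulate_genome(n_genes = 6, seed = 9)
  sim <- simulate_end_reads(ls, "Ysh1AA", library_size = 20000,
                            n_replicates = 2, seed = 4)
  for (tr in sim$tracks) {
    expect_equal(track_sum(tr), 20000)
    expect_equal(tr$mapped_reads, 20000)
  }
  # rebuilding the track from its own non-zero events is the identity
  tr <- sim$tracks[[1]]
  ev <- do.call(rbind, lapply(names(tr$values), function(chrom) {
    do.call(rbind, lapply(c("+", "-"), function(s) {
      v <- track_values(tr, chrom, s)
      nz <- which(v > 0)
      data.frame(chrom = chrom, pos = nz - 1L, strand = s, count = v[nz])
    }))
  }))
  tr2 <- three_prime_end_track(ev, ls$genome)
  expect_equal(tr2$values, tr$values)
})

test_that("SAM consumption takes the read 5' base with flipped strand (reverse library)", {
  g <- genome_seq(c(chrA = acgt_background(400)))
  sam <- withr::local_tempfile(fileext = ".sam")
  # one plus alignment [100,150), one minus alignment [200,230), one low-mapq
  write_sam(sam, c(chrA = 400L), data.frame(
    flag = c(0L, 16L, 0L), chrom = "chrA", pos1 = c(101L, 201L, 301L),
    mapq = c(255L, 255L, 3L), cigar = c("50M", "30M", "25M")))
  tr <- three_prime_end_track(sam, g, library = "reverse")
  expect_equal(tr$mapped_reads, 2)
  expect_equal(which(track_values(tr, "chrA", "-") == 1) - 1L, 100L)
  expect_equal(which(track_values(tr, "chrA", "+") == 1) - 1L, 229L)

  # forward library: 3'-most base on the alignment strand
  trf <- three_prime_end_track(sam, g, library = "forward")
  expect_equal(which(track_values(trf, "chrA", "+") == 1) - 1L, 149L)
  expect_equal(which(track_values(trf, "chrA", "-") == 1) - 1L, 200L)
})

test_that("strand symmetry: flipping alignment strands and the library flag is a no-op", {
  g <- genome_seq(c(chrA = acgt_background(400)))
  s1 <- withr::local_tempfile(fileext = ".sam")
  s2 <- withr::local_tempfile(fileext = ".sam")
  aln <- data.frame(flag = c(0L, 16L), chrom = "chrA", pos1 = c(51L, 121L),
                    mapq = 255L, cigar = c("40M", "40M"))
  write_sam(s1, c(chrA = 400L), aln)
  aln$flag <- c(16L, 0L)
  write_sam(s2, c(chrA = 400L), aln)
  a <- three_prime_end_track(s1, g, library = "reverse")
  b <- three_prime_end_track(s2, g, library = "forward")
  expect_equal(a$values, b$values)
})

test_that("counts-per-million scaling follows 1e6 / mapped_reads", {
  g <- genome_seq(c(chrA = acgt_background(100)))
  tr <- make_track(g, list(chrA = list("+" = c(4, 0, 2))), mapped_reads = 2e6)
  sc <- cpm_scale(tr)
  expect_equal(sc$scale_factor, 0.5)
  expect_equal(track_values(sc, "chrA", "+")[1:3], c(2, 0, 1))
  # mapped_reads = 1e6 is the identity scaling
  tr$mapped_reads <- 1e6
  expect_equal(cpm_scale(tr)$values, tr$values)
  tr$mapped_reads <- 0
  expect_error(cpm_scale(tr), "mapped_reads = 0")
  expect_error(cpm_scale(cpm_scale(make_track(
    g, list(chrA = list("+" = 1)), mapped_reads = 10))), "already scaled")
})

test_that("scaled genome-wide sum is 1e6 when every read is counted", {
  ls <- simulate_genome(n_genes = 6, seed = 9)
  sim <- simulate_end_reads(ls, "WT", library_size = 50000,
                            n_replicates = 1, seed = 2)
  expect_equal(track_sum(cpm_scale(sim$tracks[[1]])), 1e6)
})

test_that("replicate Spearman is 1 for self, -1 for rank reversal", {
  g <- genome_seq(c(chrA = paste(rep("A", 10000), collapse = "")))
  # one distinct value per 1 kb bin
  v <- rep(0, 10000); v[seq(1, 10000, by = 1000)] <- 1:10
  t1 <- make_track(g, list(chrA = list("+" = v)))
  vr <- rep(0, 10000); vr[seq(1, 10000, by = 1000)] <- 10:1
  t2 <- make_track(g, list(chrA = list("+" = vr)))
  m <- replicate_correlation(list(t1, t1, t2))
  expect_equal(unname(diag(m)), c(1, 1, 1))
  expect_equal(unname(m[1, 2]), 1)
  expect_equal(unname(m[1, 3]), -1)
  g2 <- genome_seq(c(chrB = "ACGT"))
  expect_error(replicate_correlation(list(t1, make_track(g2))), "genome")
})

test_that("replicates of a common expected track correlate strongly", {
  ls <- simulate_genome(n_genes = 10, seed = 1)
  sim <- simulate_end_reads(ls, "WT", library_size = 200000,
                            n_replicates = 2, seed = 12)
  m <- replicate_correlation(sim$tracks)
  expect_gt(m[1, 2], 0.8)
})

test_that("merging replicates sums counts and mapped reads", {
  g <- genome_seq(c(chrA = acgt_background(50)))
  t1 <- make_track(g, list(chrA = list("+" = c(1, 2), "-" = c(0, 3))),
                   mapped_reads = 6)
  expect_equal(merge_replicates(list(t1))$values, t1$values)
  m3 <- merge_replicates(list(t1, t1, t1))
  expect_equal(track_values(m3, "chrA", "+")[1:2], c(3, 6))
  expect_equal(m3$mapped_reads, 18)
  sc <- cpm_scale(t1)
  expect_error(merge_replicates(list(t1, sc)), "scaled")
  # merge-then-scale convention: scale factor uses the summed read total
  expect_equal(cpm_scale(m3)$scale_factor, 1e6 / 18)
})
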