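test_that("homopolymer run finding matches hand-worked examples", {
  expect_equal(nrow(find_homopolymer_runs("ACGT", min_len = 2)), 0L)

  r <- find_homopolymer_runs("AATTTTTTGC", min_len = 5, bases = "T")
  expect_equal(r$start, 2L)
  expect_equal(r$end, 8L)
  expect_equal(r$length, 6L)

  # maximality: one run, no sub-runs
  r2 <- find_homopolymer_runs("TTTTT", min_len = 5)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$start, 0L)
  expect_equal(r2$end, 5L)

  # N never extends a run
  r3 <- find_homopolymer_runs("TTNTTT", min_len = 2, bases = "T")
  expect_equal(r3$length, c(2L, 3L))

  expect_error(find_homopolymer_runs("ACGT", bases = character(0)), "empty")
  expect_error(find_homopolymer_runs("ACGT", min_len = 0), "min_len")
})

test_that("run scanner agrees with the regex oracle on random sequences", {
  set.seed(11)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
    for (ml in c(1L, 5L, 8L)) {
      got <- find_homopolymer_runs(s, min_len = ml)
      expect_identical(got, oracle_runs(s, ml), label = sprintf("seq %d ml %d", i, ml))
    }
  }
})

test_that("extended-ORF scan applies window clamping", {
  # plus-strand gene [100,400) on a 600 bp chromosome: window clamps to 600
  genome <- genome_seq(c(chrA = acgt_background(600)))
  genome <- plant_seq(genome, "chrA", 590, "TTTTTTTTTT")
  genes <- gene_models(data.frame(gene_id = "g", chrom = "chrA",
                                  strand = "+", start = 100L, end = 400L))
  tr <- scan_extended_orfs(genome, genes)
  expect_equal(tr$start, 590L)
  expect_equal(tr$end, 600L)
  expect_equal(tr$region, "downstream_flank")
  expect_equal(tr$three_prime_end, 599L)
})

test_that("discard rules remove multi-gene, convergent and mito matches", {
  fx <- discard_rule_fixture()
  tr <- scan_extended_orfs(fx$genome, fx$genes)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$start, c(501L, 1702L))
  expect_equal(tr$end, c(509L, 1708L))
  expect_equal(tr$gene_id, c("g1", "g3"))
  expect_equal(tr$base, c("T", "T"))
  expect_true(all(tr$region == "downstream_flank"))
})

test_that("extended-ORF scan is order-independent in its gene list", {
  ls <- simulate_genome(n_genes = 8, seed = 5)
  a <- scan_extended_orfs(ls$genome, ls$genes)
  set.seed(1)
  b <- scan_extended_orfs(ls$genome, ls$genes[sample(nrow(ls$genes)), ])
  expect_identical(a, b)
})

test_that("planted terminator tracts within the flank are recovered", {
  ls <- simulate_genome(n_genes = 20, seed = 3)
  tr <- scan_extended_orfs(ls$genome, ls$genes, flank = 500, min_len = 5)
  pt <- ls$planted_tracts
  pt <- pt[pt$region == "terminator" & pt$base == "T", , drop = FALSE]
  # planted tracts whose interval lies within 500 bp of the ORF end
  for (i in seq_len(nrow(pt))) {
    g <- ls$genes[ls$genes$gene_id == pt$gene_id[i], ]
    inside <- if (g$strand == "+") pt$end[i] <= g$end + 500 else
      pt$start[i] >= g$start - 500
    if (!inside) next
    hit <- tr[tr$start == pt$start[i] & tr$end == pt$end[i] &
                tr$chrom == pt$chrom[i], , drop = FALSE]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$region, "downstream_flank")
    expect_equal(hit$gene_id, pt$gene_id[i])
  }
})

test_that("length frequency table counts straddling runs in both regions", {
  expect_true(all(tract_length_frequency(
    data.frame(base = character(), length = integer(), in_orf = logical(),
               in_flank = logical()))$count == 0L))

  tracts <- data.frame(base = c("T", "T", "A"), length = c(7L, 25L, 5L),
                       in_orf = c(FALSE, TRUE, TRUE),
                       in_flank = c(TRUE, TRUE, FALSE))
  tab <- tract_length_frequency(tracts)
  expect_equal(tab$count[tab$base == "T" & tab$length == "7" &
                           tab$region == "downstream_flank"], 1L)
  # length 25 run falls in the 20+ bin, once per overlapped region
  expect_equal(tab$count[tab$base == "T" & tab$length == "20+" &
                           tab$region == "orf"], 1L)
  expect_equal(tab$count[tab$base == "T" & tab$length == "20+" &
                           tab$region == "downstream_flank"], 1L)
  # column sums equal tract counts per region
  expect_equal(sum(tab$count[tab$region == "orf"]), sum(tracts$in_orf))
  expect_equal(sum(tab$count[tab$region == "downstream_flank"]),
               sum(tracts$in_flank))
})

test_that("longest-run profile maps 3' ends to the documented bins", {
  # unique longest T-run with 3' end at offset +37 from the centre
  genome <- genome_seq(c(chrA = acgt_background(2000)))
  genome <- plant_seq(genome, "chrA", 1030, "TTTTTTTT") # ends at 1037
  sites <- data.frame(chrom = "chrA", pos = 1000L, strand = "+")
  prof <- flank_longest_run_profile(sites, genome)
  expect_equal(unname(prof["T", 54L]), 1L) # floor((500 + 37) / 10) 0-based 53
  expect_equal(sum(prof["T", ]), 1L)

  # pure ACGT repeats contain no run >= 2: zero contribution
  prof0 <- flank_longest_run_profile(
    data.frame(chrom = "chrA", pos = 600L, strand = "+"),
    genome_seq(c(chrA = acgt_background(2000))))
  expect_true(all(prof0 == 0L))

  # at most one record per site per base; clipped sites dropped
  ls <- simulate_genome(n_genes = 6, seed = 2)
  sites2 <- data.frame(chrom = ls$truth_points$chrom,
                       pos = ls$truth_points$pos,
                       strand = ls$truth_points$strand)
  p2 <- flank_longest_run_profile(sites2, ls$genome)
  expect_true(all(rowSums(p2) <= nrow(sites2)))
  expect_error(flank_longest_run_profile(
    data.frame(chrom = "chrA", pos = 1L, strand = NA), genome), "strand")
})

test_that("minus-strand sites read the profile window on their own strand", {
  genome <- genome_seq(c(chrA = acgt_background(2000)))
  # A-run on the reference is a T-run on the minus strand; its minus-strand
  # 3' end is the run's leftmost reference base
  genome <- plant_seq(genome, "chrA", 1030, "AAAAAAAA") # [1030,1038)
  prof <- flank_longest_run_profile(
    data.frame(chrom = "chrA", pos = 1000L, strand = "-"), genome)
  # window [500,1500) read right-to-left: offset of base 1030 = 1499-1030=469
  expect_equal(unname(prof["T", floor(469 / 10) + 1L]), 1L)
  expect_equal(sum(prof["T", ]), 1L)
})
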