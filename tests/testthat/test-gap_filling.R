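# Restrained OLC: layout thresholds, protrusion and merged-length
# restrictions, consensus arithmetic, donor scoping.

# constructs a two-contig bin with a known internal gap and a donor spanning
# the junction with the requested flank lengths
bridge_fixture <- function(genome_len = 12000, gap = 100, flank = 400,
                           seed = 51) {
  set.seed(seed)
  genome <- rand_dna(genome_len)
  half <- (genome_len - gap) %/% 2
  t1 <- substr(genome, 1, half)
  t2 <- substr(genome, half + gap + 1, genome_len)
  donor <- substr(genome, half - flank + 1, half + gap + flank)
  list(genome = genome, t1 = t1, t2 = t2, donor = donor, gap = gap)
}

test_that("a spanning donor bridges two contigs with exact length arithmetic", {
  fx <- bridge_fixture()
  bins <- list(B = c(T1 = fx$t1, T2 = fx$t2))
  dn <- list(B = c(don = fx$donor))
  r <- rolc_round(bins, dn, min_overlap = 300)
  expect_equal(nrow(r$events), 1L)
  expect_equal(r$events$kind, "bridge")
  expect_equal(r$events$overlap_1, 400L)
  expect_equal(r$events$overlap_2, 400L)
  merged <- r$bins$B[["T1+T2"]]
  # the merged sequence IS the genomic segment: l1 + l2 + gap, base-exact
  expect_equal(nchar(merged), nchar(fx$t1) + nchar(fx$t2) + fx$gap)
  expect_equal(merged, substr(fx$genome, 1, 12000))
  expect_equal(length(r$bins$B), 1L)  # contig count decreased by one
})

test_that("layout thresholds and restrictions reject unacceptable donors", {
  # 250 bp flanks fail the 300 bp round-1 threshold
  fx <- bridge_fixture(flank = 250)
  r <- rolc_round(list(B = c(T1 = fx$t1, T2 = fx$t2)),
                  list(B = c(don = fx$donor)), min_overlap = 300)
  expect_equal(nrow(r$events), 0L)

  # 400 bp flanks fail the 500 bp round-2 threshold
  fx2 <- bridge_fixture(flank = 400)
  r2 <- rolc_round(list(B = c(T1 = fx2$t1, T2 = fx2$t2)),
                   list(B = c(don = fx2$donor)), min_overlap = 500)
  expect_equal(nrow(r2$events), 0L)

  # a merged length of 1.2x the summed targets violates the 105% bound:
  # two 1 kb contigs separated by a 400 bp gap
  fx3 <- bridge_fixture(genome_len = 2400, gap = 400, flank = 400)
  r3 <- rolc_round(list(B = c(T1 = fx3$t1, T2 = fx3$t2)),
                   list(B = c(don = fx3$donor)), min_overlap = 300)
  expect_equal(nrow(r3$events), 0L)

  # a donor protruding beyond the target at both ends is rejected
  set.seed(52)
  core <- rand_dna(1000)
  donor <- paste0(rand_dna(500), core, rand_dna(500))
  r4 <- rolc_round(list(B = c(T1 = core)), list(B = c(don = donor)),
                   min_overlap = 300)
  expect_equal(nrow(r4$events), 0L)

  # donors below 99% identity over the overlap produce no events
  fx5 <- bridge_fixture()
  bad <- mutate_dna(fx5$donor, 27)  # 3% of 900 bp
  r5 <- rolc_round(list(B = c(T1 = fx5$t1, T2 = fx5$t2)),
                   list(B = c(don = bad)), min_overlap = 300)
  expect_equal(nrow(r5$events), 0L)
})

test_that("extension consumes one end only, with l1 + ld - overlap arithmetic", {
  set.seed(53)
  genome <- rand_dna(10300)
  target <- substr(genome, 1, 10000)
  donor <- substr(genome, 9601, 10300)  # 400 bp overlap + 300 bp novel
  r <- rolc_round(list(B = c(T1 = target)), list(B = c(don = donor)),
                  min_overlap = 300)
  expect_equal(r$events$kind, "extend")
  expect_equal(r$events$merged_len, 10000L + 700L - 400L)
  expect_equal(r$bins$B[["T1"]], genome)
  # the same donor against a short target breaks the 105% bound
  r2 <- rolc_round(list(B = c(T1 = substr(genome, 5000, 10000))),
                   list(B = c(don = donor)), min_overlap = 300)
  expect_equal(nrow(r2$events), 0L)
})

test_that("donor collection scopes archived inliers to their ANI group", {
  fx <- make_benchmark("gapfill5", seed = 1)
  # two target bins, archive scoped to T1 only
  donors <- collect_donors(fx$archive, list(donors = "T1"), c("T1", "T2"),
                           fx$pool)
  expect_setequal(donors$T1, fx$donor_ids)
  expect_length(donors$T2, 0L)
  # un-binned contigs are donors everywhere
  donors2 <- collect_donors(fx$archive, list(donors = "T1"), c("T1", "T2"),
                            fx$pool, unbinned = "T_c5")
  expect_true("T_c5" %in% donors2$T2)
  # empty archive and empty pool: no donors, gap filling is a no-op
  empty <- bin_set(list(), name = "archive", stage = "selected")
  expect_length(collect_donors(empty, list(), "T1", fx$pool)$T1, 0L)
  gf0 <- gap_fill(fx$bins, empty, list(), fx$pool)
  expect_equal(gf0$binset$bins, fx$bins$bins)
  expect_equal(nrow(gf0$events), 0L)
})

test_that("gap filling raises N50 and never worsens true bin quality", {
  fx <- make_benchmark("gapfill5", seed = 1)
  gf <- gap_fill(fx$bins, fx$archive, fx$archive_groups, fx$pool)
  expect_gt(gf$stats$n50_after, gf$stats$n50_before)
  ev0 <- evaluate_binset(fx$bins, fx$pool, fx$references)
  ev1 <- evaluate_binset(gf$binset, gf$pool, fx$references)
  expect_gte(ev1$completeness, ev0$completeness)
  expect_lte(ev1$contamination, ev0$contamination)
  # merged sequences contain no foreign bases: every contig is a substring
  # of the true genome
  for (id in gf$binset$bins$T1)
    expect_true(grepl(gf$pool$seqs[[id]], fx$references[["refG"]],
                      fixed = TRUE))
  # determinism: identical inputs give an identical event log
  gf2 <- gap_fill(fx$bins, fx$archive, fx$archive_groups, fx$pool)
  expect_identical(gf$events, gf2$events)
})
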