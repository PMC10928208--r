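# The community generator: determinism, compositional separability,
# defect planting, benchmark fixtures.

test_that("identical spec and seed reproduce the community byte for byte", {
  spec <- community_spec(n_genomes = 3, genome_len_range = c(20000, 30000),
                         seed = 9)
  a <- simulate_community(spec)
  b <- simulate_community(spec)
  expect_identical(a$references, b$references)
  expect_identical(a$pool$seqs, b$pool$seqs)
  expect_identical(a$pool$depths, b$pool$depths)
  c2 <- simulate_community(community_spec(n_genomes = 3,
                                          genome_len_range = c(20000, 30000),
                                          seed = 10))
  expect_false(identical(a$references, c2$references))
})

test_that("the depth table and contigs respect the declared dimensions", {
  com <- simulate_community(community_spec(n_genomes = 4, n_samples = 5,
                                           genome_len_range = c(20000, 30000),
                                           seed = 2))
  expect_equal(ncol(com$pool$depths), 5L)
  expect_equal(nrow(com$pool$depths), length(com$pool$seqs))
  expect_true(all(contig_lengths(com$pool) >= 1000))
  expect_true(all(com$pool$depths >= 0))
  # truth covers every contig exactly once
  expect_setequal(com$truth$contig, names(com$pool$seqs))
  # infeasible spec is refused up front
  expect_error(community_spec(contig_min = 5000,
                              genome_len_range = c(2000, 3000)),
               "infeasible")
})

test_that("genomes carry distinct compositional signatures at divergence 0.1", {
  com <- simulate_community(community_spec(seed = 1))
  cen <- lapply(split(com$truth$contig, com$truth$genome), function(ids)
    tnf_centroid(com$pool$seqs[ids]))
  within <- unlist(lapply(split(com$truth$contig, com$truth$genome),
    function(ids) {
      g <- com$truth$genome[match(ids[1], com$truth$contig)]
      vapply(ids, function(i)
        sqrt(sum((as.numeric(compute_tnf(com$pool$seqs[[i]])) -
                    cen[[g]])^2)), numeric(1))
    }))
  between <- unlist(lapply(names(cen), function(g) {
    ids <- com$truth$contig[com$truth$genome == g]
    other <- setdiff(names(cen), g)
    vapply(ids[1:3], function(i)
      mean(vapply(other, function(h)
        sqrt(sum((as.numeric(compute_tnf(com$pool$seqs[[i]])) -
                    cen[[h]])^2)), numeric(1))), numeric(1))
  }))
  expect_gt(mean(between), mean(within))
})

test_that("zero defect rates reproduce the truth bins with empty labels", {
  com <- simulate_community(community_spec(n_genomes = 3,
                                           genome_len_range = c(20000, 30000),
                                           seed = 4))
  pc <- plant_defects(com)
  expect_equal(lapply(pc$bins$bins, sort),
               lapply(split(com$truth$contig, com$truth$genome), sort))
  expect_equal(nrow(pc$labels$redundant_bins), 0L)
  expect_equal(nrow(pc$labels$contaminants), 0L)
  expect_equal(nrow(pc$labels$withheld), 0L)
  expect_length(pc$unbinned, 0L)
})

test_that("defect labels are exhaustive and exclusive", {
  com <- simulate_community(community_spec(seed = 3))
  pc <- plant_defects(com, redundancy_rate = 0.2, contamination_rate = 0.05,
                      withheld_rate = 0.1)
  lb <- pc$labels
  # every original contig is exactly one of: native-binned, contaminant
  # (foreign-binned), withheld
  binned <- unlist(pc$bins$bins, use.names = FALSE)
  orig <- com$truth$contig
  expect_setequal(c(binned[!grepl("_r$", binned)], pc$unbinned), orig)
  expect_length(intersect(lb$contaminants$contig, lb$withheld$contig), 0L)
  # duplicate bins are all labeled
  expect_setequal(lb$redundant_bins$bin,
                  grep("_dup$", names(pc$bins$bins), value = TRUE))
  # contaminants really sit in a foreign bin
  for (i in seq_len(nrow(lb$contaminants)))
    expect_true(lb$contaminants$contig[i] %in%
                  pc$bins$bins[[lb$contaminants$to[i]]])
})

test_that("planted duplicates expose the coverage-scale factor to Eq. 2-style recovery", {
  com <- simulate_community(community_spec(
    n_genomes = 1, genome_len_range = c(300000, 300000), seed = 1))
  pc <- plant_defects(com, redundancy_rate = 1)
  rb <- pc$labels$redundant_bins
  p <- pair_inliers(pc$bins$bins[[rb$bin[1]]],
                    pc$bins$bins[[rb$source_bin[1]]], pc$pool)
  expect_gt(nrow(p), 3)
  x_bar <- depth_normalization_ratio(p)
  expect_lt(abs(x_bar - rb$scale[1]) / rb$scale[1], 0.05)
})

test_that("benchmark bundles are named, labeled, and regenerate identically", {
  expect_error(make_benchmark("nope"), "redundancy40")
  fx <- make_benchmark("redundancy40", seed = 1)
  expect_equal(sum(fx$pairs$redundant), 20L)
  expect_equal(sum(!fx$pairs$redundant), 20L)
  gapfx <- make_benchmark("gapfill5", seed = 1)
  expect_length(gapfx$bins$bins$T1, 5L)
  expect_length(gapfx$donor_ids, 3L)
  expect_true(all(contig_lengths(gapfx$pool, gapfx$donor_ids) >= 800))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_benchmark("gapfill5", dir = d1, seed = 1)
  make_benchmark("gapfill5", dir = d2, seed = 1)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})
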