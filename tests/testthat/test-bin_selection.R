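# Hybrid merging, ANI grouping, core coverage ranges (inlier screen),
# depth-normalization ratio, delta coverage, redundancy decisions.

test_that("hybrid merging joins same-contig bins and leaves others alone", {
  pool <- tiny_pool()
  a <- bin_set(list(b1 = c("c1", "c2", "c3"), b2 = c("c4", "c5", "c6")),
               name = "setA")
  b <- bin_set(list(b1 = c("c1", "c2", "c3")), name = "setB")
  hyb <- merge_hybrid_bins(list(a, b), pool)
  expect_equal(length(hyb$bins), 2L)
  merged <- hyb$bins[[grep("hybrid", names(hyb$bins))]]
  expect_setequal(merged, c("c1", "c2", "c3"))  # deduplicated union

  # 2/3 of contigs shared (>= 0.8 by bp? construct around the threshold)
  pool2 <- pool_from_seqs(setNames(
    c(rand_dna(4000), rand_dna(4000), rand_dna(1000), rand_dna(1000)),
    c("big1", "big2", "sm1", "sm2")))
  over <- bin_set(list(x = c("big1", "big2", "sm1"),
                       y = c("big1", "big2", "sm2")))   # 8/9 bp shared
  under <- bin_set(list(x = c("big1", "sm1"), y = c("sm1", "big2")))
  # x,y share sm1 only: 1000/5000 = 0.2
  expect_equal(length(merge_hybrid_bins(over, pool2)$bins), 1L)
  expect_equal(length(merge_hybrid_bins(under, pool2)$bins), 2L)

  dis <- bin_set(list(p = "c1", q = "c2", r = "c3"))
  expect_equal(merge_hybrid_bins(dis, pool)$bins, dis$bins)
})

test_that("ANI grouping is single-linkage with either-direction edges", {
  set.seed(31)
  genome <- rand_dna(20000)
  ctgs <- split_genome(genome, 8, "g")
  pool <- pool_from_seqs(ctgs)
  bs <- bin_set(list(A = paste0("g", 1:5), B = paste0("g", 3:7),
                     C = paste0("g", 5:8), D = paste0("g", 1:2)))
  # A-B share 3/5 contigs (ani 100, af 60); B-C share 3/5; A-C share 1/5
  # (af 20 < 50); D is 2/5 of A (af 40 one way, 100 the other: edge via
  # either-direction rule)
  groups <- group_bins(bs, pool)
  expect_equal(length(groups), 1L)
  expect_setequal(groups[[1]], c("A", "B", "C", "D"))

  # unrelated genomes stay singletons
  pool2 <- pool_from_seqs(c(u1 = rand_dna(5000), u2 = rand_dna(5000)))
  g2 <- group_bins(bin_set(list(U = "u1", V = "u2")), pool2)
  expect_equal(length(g2), 2L)

  # exact duplicates are grouped at ani 100 / af 100
  g3 <- group_bins(bin_set(list(P = "u1", Q = "u1")), pool2)
  expect_equal(length(g3), 1L)
})

test_that("core coverage range matches an independent percentile oracle", {
  # degenerate ties: inclusive default keeps every contig, strict voids
  r <- core_coverage_range(rep(10, 8), k = 0)
  expect_true(all(in_coverage_range(r, rep(10, 8))))
  rs <- core_coverage_range(rep(10, 8), k = 0, strict = TRUE)
  expect_false(any(in_coverage_range(rs, rep(10, 8))))

  x <- c(10, 10, 10, 1000)
  r2 <- core_coverage_range(x, k = 2)
  expect_equal(in_coverage_range(r2, x), brute_inliers(x, 2))
  expect_false(in_coverage_range(r2, 1000))

  expect_error(core_coverage_range(numeric(0)), "one depth")

  set.seed(32)
  depths <- runif(200, 1, 80)
  for (k in c(0, 0.5, 1, 2)) {
    r3 <- core_coverage_range(depths, k = k)
    expect_equal(in_coverage_range(r3, depths), brute_inliers(depths, k),
                 info = paste("k =", k))
  }
})

test_that("inlier pairing honors ANI and length thresholds", {
  set.seed(33)
  genome <- rand_dna(24000)
  ctgs <- split_genome(genome, 8, "x")
  copies <- setNames(ctgs, paste0(names(ctgs), "_r"))
  pool <- contig_pool(
    c(ctgs, copies),
    depths = matrix(c(rep(20, 8), rep(40, 8)), ncol = 1,
                    dimnames = list(c(names(ctgs), names(copies)), "S1")))
  pairs <- pair_inliers(names(ctgs), names(copies), pool)
  # identical copies: every inlier pairs with its twin at ANI 100
  expect_true(all(pairs$ani == 100))
  expect_equal(pairs$contig_b, paste0(pairs$contig_a, "_r"))
  expect_true(all(pairs$cov_a == 20 & pairs$cov_b == 40))

  # both-below-1000bp contigs can never pair
  short <- setNames(vapply(1:4, function(i) rand_dna(800), character(1)),
                    paste0("s", 1:4))
  shortc <- setNames(short, paste0(names(short), "_r"))
  pool2 <- pool_from_seqs(c(short, shortc))
  expect_equal(nrow(pair_inliers(names(short), names(shortc), pool2)), 0L)

  # unrelated genomes: nothing reaches ANI 99
  u1 <- split_genome(rand_dna(12000), 4, "u")
  u2 <- split_genome(rand_dna(12000), 4, "v")
  pool3 <- pool_from_seqs(c(u1, u2))
  expect_equal(nrow(pair_inliers(names(u1), names(u2), pool3)), 0L)
})

test_that("depth normalization ratio follows the pairwise mean of ratios", {
  mk <- function(ca, cb) data.frame(cov_a = ca, cov_b = cb)
  expect_equal(depth_normalization_ratio(mk(c(4, 8, 20), c(2, 4, 10))), 2)
  expect_equal(depth_normalization_ratio(mk(c(7, 7), c(7, 7))), 1)
  expect_equal(depth_normalization_ratio(mk(c(20, 30, 45), c(10, 20, 30))),
               5 / 3)
  # zero denominator replaced by the 0.01 pseudocount
  expect_equal(depth_normalization_ratio(mk(1, 0)), 100)
  expect_error(depth_normalization_ratio(mk(numeric(0), numeric(0))),
               "no inlier pairs")
})

test_that("delta coverage arithmetic and swap consistency", {
  expect_equal(delta_coverage(30, 15, 2), 0)
  expect_equal(delta_coverage(50, 20, 2), 10)
  set.seed(34)
  for (i in 1:20) {
    mu_a <- runif(1, 1, 100); mu_b <- runif(1, 1, 100)
    x <- runif(1, 0.2, 5)
    # swapping the bins with the reciprocal ratio rescales delta by x
    expect_equal(delta_coverage(mu_a, mu_b, x),
                 x * delta_coverage(mu_b, mu_a, 1 / x))
  }
})

test_that("redundancy verdicts: threshold rule, no-evidence path, model guard", {
  stats <- list(n_pairs = 3L, x_bar = 1, delta = 0, mu_a = 20, mu_b = 20,
                inlier_bp_a = 1e5, inlier_bp_b = 1e5, disp_a = 0.1,
                disp_b = 0.1)
  expect_equal(classify_redundancy(stats, w = 5)$verdict, "redundant")
  stats$delta <- 7
  expect_equal(classify_redundancy(stats, w = 5)$verdict, "nonredundant")
  stats$n_pairs <- 0L
  expect_equal(classify_redundancy(stats)$verdict, "no-evidence")
  stats$n_pairs <- 3L
  expect_error(classify_redundancy(stats, mode = "model"),
               "train_redundancy_model")
})

test_that("nonredundant selection keeps the larger bin and archives the rest", {
  set.seed(35)
  genome <- rand_dna(60000)
  ctgs <- split_genome(genome, 12, "m")
  dup <- setNames(ctgs[1:10], paste0(names(ctgs)[1:10], "_r"))  # ~17% less bp
  depths <- matrix(rep(c(20, 30), c(12, 10)), ncol = 1,
                   dimnames = list(c(names(ctgs), names(dup)), "S1"))
  pool <- contig_pool(c(ctgs, dup), depths = depths)
  bs <- bin_set(list(full = names(ctgs), part = names(dup)))
  sel <- select_nonredundant(bs, pool)
  expect_equal(names(sel$selected$bins), "full")
  expect_equal(names(sel$archive$bins), "part")
  expect_equal(sel$archive_groups$part, "full")
  expect_equal(sel$decisions$verdict, "redundant")
  # the union of selected + archived ids equals the input set's ids
  expect_setequal(c(names(sel$selected$bins), names(sel$archive$bins)),
                  names(bs$bins))

  # distinct genomes: everything survives
  other <- split_genome(rand_dna(40000), 8, "o")
  pool2 <- pool_from_seqs(c(ctgs, other))
  bs2 <- bin_set(list(X = names(ctgs), Y = names(other)))
  sel2 <- select_nonredundant(bs2, pool2)
  expect_setequal(names(sel2$selected$bins), c("X", "Y"))
  expect_equal(length(sel2$archive$bins), 0L)
  # unrelated genomes never even group, so no pairwise decision is logged;
  # forcing them into one group exercises the no-evidence retention path
  sel2b <- select_nonredundant(bs2, pool2, groups = list(c("X", "Y")))
  expect_equal(sel2b$decisions$verdict, "no-evidence")
  expect_setequal(names(sel2b$selected$bins), c("X", "Y"))

  # all-singleton groups: selection is the identity
  sel3 <- select_nonredundant(bs2, pool2,
                              groups = list("X", "Y"))
  expect_equal(sel3$selected$bins, bs2$bins)
})
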