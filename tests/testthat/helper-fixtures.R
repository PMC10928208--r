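# Shared fixture builders and independent oracles. Oracles are deliberately
# naive re-implementations, kept separate from the package code paths they
# check.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly n positions (never to the same base)
mutate_dna <- function(seq, n) {
  v <- strsplit(seq, "")[[1]]
  ix <- sample(length(v), n)
  v[ix] <- vapply(v[ix], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(v, collapse = "")
}

rc_naive <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# brute-force canonical TNF: enumerate every 4-bp window, skip windows with
# N, fold onto min(kmer, revcomp(kmer)), normalize
brute_tnf <- function(seq) {
  kmers <- substring(seq, seq_len(nchar(seq) - 3), seq_len(nchar(seq) - 3) + 3)
  kmers <- kmers[!grepl("N", kmers)]
  canon <- vapply(kmers, function(k) min(k, rc_naive(k)), character(1))
  all4 <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                            c("A","C","G","T"), c("A","C","G","T"))[, 4:1],
                1, paste, collapse = "")
  levels <- sort(unique(vapply(all4, function(k) min(k, rc_naive(k)),
                               character(1))))
  counts <- table(factor(canon, levels = levels))
  out <- as.numeric(counts)
  if (sum(out) > 0) out <- out / sum(out)
  names(out) <- levels
  out
}

# independent linear-interpolation percentile (type-7 convention written out)
brute_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# brute-force inlier classification for the interquartile coverage range
brute_inliers <- function(x, k, strict = FALSE) {
  q1 <- brute_percentile(x, 0.25)
  q3 <- brute_percentile(x, 0.75)
  lo <- q1 - k * (q3 - q1)
  hi <- q3 + k * (q3 - q1)
  if (strict) x > lo & x < hi else x >= lo & x <= hi
}

# a tiny hand-built pool: 2 "genomes" of 3 contigs each, 2 samples
tiny_pool <- function(seed = 42) {
  set.seed(seed)
  seqs <- setNames(vapply(1:6, function(i) rand_dna(1500), character(1)),
                   paste0("c", 1:6))
  depths <- matrix(c(10, 10, 10, 30, 30, 30,
                     12, 12, 12, 33, 33, 33),
                   ncol = 2, dimnames = list(names(seqs), c("S1", "S2")))
  contig_pool(seqs, depths = depths)
}

# split a genome into contigs of given length, returning a named vector
split_genome <- function(genome, n, prefix = "c") {
  L <- nchar(genome)
  cuts <- round(seq(0, L, length.out = n + 1))
  setNames(substring(genome, cuts[-(n + 1)] + 1, cuts[-1]),
           sprintf("%s%d", prefix, seq_len(n)))
}

# pool from named sequences with constant per-sample depths
pool_from_seqs <- function(seqs, depth = 20, n_samples = 2) {
  depths <- matrix(depth, nrow = length(seqs), ncol = n_samples,
                   dimnames = list(names(seqs),
                                   paste0("S", seq_len(n_samples))))
  contig_pool(seqs, depths = depths)
}
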