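# Sequence-level primitives: canonical tetranucleotide frequency, fragment-
# mapping ANI/AF, and suffix-prefix overlap detection. These are shared by
# bin selection (ANI grouping, inlier pairing), refinement (composition
# outliers) and gap filling (overlap layout).

.corebin_env <- new.env(parent = emptyenv())

#' Reverse complement of a DNA string
#' @param seq character scalar over A,C,G,T,N.
#' @return the reverse complement, same alphabet.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# 256 -> 136 canonical fold: each 4-mer maps to the lexicographically smaller
# of itself and its reverse complement. Cached after first use.
.tnf_map <- function() {
  if (!is.null(.corebin_env$tnf_map)) return(.corebin_env$tnf_map)
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4)
  rc <- revcomp(kmers)
  canon <- pmin(kmers, rc)
  levels <- sort(unique(canon))
  .corebin_env$tnf_map <- list(kmers = kmers, canon = canon, levels = levels)
  .corebin_env$tnf_map
}

#' Canonical tetranucleotide frequency of a sequence
#'
#' Slides a 4-bp window with step 1; windows containing \code{N} are skipped;
#' each 4-mer is folded onto the lexicographically smaller of itself and its
#' reverse complement (136 canonical tetranucleotides), and counts are
#' normalized to frequencies. A sequence with no valid 4-mer yields the
#' all-zero vector. TNF is therefore invariant under reverse complement.
#'
#' @param seq DNA string (character scalar).
#' @return named numeric vector of length 136 with attribute
#'   \code{n_windows}, the number of valid 4-bp windows counted.
#' @export
compute_tnf <- function(seq) {
  map <- .tnf_map()
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), 4)
  folded <- vapply(split(counts[map$kmers], map$canon), sum, numeric(1))
  folded <- folded[map$levels]
  n <- sum(folded)
  out <- if (n > 0) folded / n else folded
  attr(out, "n_windows") <- n
  out
}

#' Length-weighted TNF centroid of a set of sequences
#'
#' Equivalent to computing TNF on the pooled windows of all sequences: each
#' sequence's frequency vector is weighted by its number of valid windows, so
#' long, reliable contigs dominate the centroid.
#'
#' @param seqs character vector of DNA strings.
#' @return named numeric vector of length 136.
#' @export
tnf_centroid <- function(seqs) {
  tnfs <- lapply(seqs, compute_tnf)
  w <- vapply(tnfs, function(x) attr(x, "n_windows"), numeric(1))
  m <- do.call(rbind, lapply(tnfs, as.numeric))
  tot <- sum(w)
  out <- if (tot > 0) colSums(m * w) / tot else colSums(m) * 0
  names(out) <- .tnf_map()$levels
  out
}

# Chop sequences into fragments of `fragment_len`; a terminal remainder
# shorter than `min_tail` is merged into the preceding fragment (or kept
# whole when the sequence itself is shorter than one fragment).
.fragment_seqs <- function(seqs, fragment_len = 1000L, min_tail = 500L) {
  out <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    L <- nchar(s)
    if (L <= fragment_len) {
      out[[length(out) + 1L]] <- data.frame(
        qid = id, qstart = 1L, qend = L, frag = s)
      next
    }
    starts <- seq(1L, L, by = fragment_len)
    ends <- pmin(starts + fragment_len - 1L, L)
    nlast <- ends[length(ends)] - starts[length(starts)] + 1L
    if (length(starts) > 1L && nlast < min_tail) {
      ends[length(ends) - 1L] <- L
      starts <- starts[-length(starts)]
      ends <- ends[-length(ends)]
    }
    out[[length(out) + 1L]] <- data.frame(
      qid = id, qstart = starts, qend = ends,
      frag = substring(s, starts, ends))
  }
  do.call(rbind, out)
}

# Map fragments against target sequences in both orientations; returns the
# per-fragment best hit (more seed votes, then higher identity).
.map_fragments <- function(frags, targets, k = 16L, band_frac = 0.05) {
  fwd <- cpp_fragment_map(frags, as.character(targets), k, band_frac)
  rev <- cpp_fragment_map(revcomp(frags), as.character(targets), k, band_frac)
  take_rev <- rev$votes > fwd$votes |
    (rev$votes == fwd$votes & !is.na(rev$identity) & !is.na(fwd$identity) &
       rev$identity > fwd$identity)
  take_rev[is.na(take_rev)] <- FALSE
  out <- fwd
  out[take_rev, ] <- rev[take_rev, ]
  out$orientation <- ifelse(take_rev, "revcomp", "forward")
  out
}

#' Fragment-mapping average nucleotide identity (ANI) and aligned fraction
#'
#' The query set is chopped into fixed-length fragments (terminal remainders
#' are merged into the previous fragment so no query base is dropped). Each
#' fragment is seeded against the target set by shared 16-mers in both
#' orientations and aligned to its best hit with a banded edit-distance
#' alignment (band 5\% of the fragment length); identity counts gaps as
#' mismatches. A fragment counts as aligned when its best target window
#' covers at least \code{min_cov} of the fragment. \code{ani} is the mean
#' identity of aligned fragments; \code{af} is 100 times the aligned query
#' bases over the total query bases. When no fragment aligns, \code{ani} is
#' \code{NA} (an undefined sentinel, never a fake 0).
#'
#' @param query,target named character vectors of DNA sequences (both
#'   non-empty).
#' @param fragment_len fragment size in bases (default 1000).
#' @param k seed k-mer size (default 16).
#' @param band_frac alignment band as a fraction of fragment length.
#' @param min_cov minimum fraction of the fragment the best alignment must
#'   cover to count as aligned (default 0.8).
#' @return list of class \code{ani_result}: \code{ani}, \code{af},
#'   \code{n_fragments_aligned}, \code{n_fragments}.
#' @export
compute_ani <- function(query, target, fragment_len = 1000L, k = 16L,
                        band_frac = 0.05, min_cov = 0.8) {
  stopifnot(length(query) >= 1, length(target) >= 1)
  fr <- .fragment_seqs(query, fragment_len)
  hits <- .map_fragments(fr$frag, target, k, band_frac)
  flen <- nchar(fr$frag)
  aligned <- hits$target > 0 & hits$covered >= min_cov
  ani <- if (any(aligned)) mean(hits$identity[aligned]) else NA_real_
  af <- 100 * sum(flen[aligned]) / sum(nchar(query))
  structure(list(ani = ani, af = af,
                 n_fragments_aligned = sum(aligned),
                 n_fragments = nrow(fr)),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ANI %s  AF %.1f%%  (%d/%d fragments aligned)\n",
              if (is.na(x$ani)) "undefined" else sprintf("%.2f%%", x$ani),
              x$af, x$n_fragments_aligned, x$n_fragments))
  invisible(x)
}

#' Suffix-prefix and containment overlaps between a donor and target contigs
#'
#' Anchors the donor (both orientations) on each target with exact 21-mers,
#' takes the best shared diagonal, and scores the implied overlap region with
#' a banded edit-distance identity. Only candidates with overlap length at
#' least \code{min_len} and identity at least \code{min_identity} are
#' returned. Protrusion flags describe the oriented donor relative to the
#' target: \code{donor_protrudes_left} means the (oriented) donor extends
#' beyond the target's left (5') end. Candidates are ordered by decreasing
#' overlap length, then decreasing identity, then target id — ties are
#' broken deterministically.
#'
#' @param donor named character scalar (one contig).
#' @param targets named character vector of target contigs.
#' @param min_len minimum overlap length in bases (>= 1).
#' @param min_identity minimum percent identity of the overlap.
#' @param k anchor k-mer size (default 21).
#' @return data.frame with one row per candidate: \code{donor_id, target_id,
#'   overlap_len, identity, orientation, donor_protrudes_left,
#'   donor_protrudes_right, donor_start, donor_end, target_start,
#'   target_end} (1-based inclusive coordinates of the overlap on the
#'   oriented donor and on the target).
#' @export
find_overlaps <- function(donor, targets, min_len, min_identity = 99, k = 21L) {
  stopifnot(min_len >= 1, length(donor) == 1, !is.null(names(donor)))
  rows <- list()
  for (orient in c("forward", "revcomp")) {
    dseq <- if (orient == "forward") donor[[1]] else revcomp(donor[[1]])
    ld <- nchar(dseq)
    for (tid in names(targets)) {
      tseq <- targets[[tid]]
      lt <- nchar(tseq)
      hit <- cpp_best_diagonal(dseq, tseq, k)
      if (hit$votes == 0) next
      d <- hit$diag  # donor pos p (0-based) pairs with target pos p + d
      ds <- max(0L, -d)              # overlap start on donor (0-based)
      de <- min(ld, lt - d)          # overlap end on donor (exclusive)
      ol <- de - ds
      if (ol < min_len) next
      dsub <- substr(dseq, ds + 1L, de)
      tsub <- substr(tseq, ds + d + 1L, de + d)
      band <- max(10L, as.integer(0.02 * ol))
      edits <- cpp_banded_edit(dsub, tsub, band)
      ident <- 100 * max(0, ol - edits) / ol
      if (ident < min_identity) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor_id = names(donor), target_id = tid,
        overlap_len = ol, identity = ident, orientation = orient,
        donor_protrudes_left = d < 0L,
        donor_protrudes_right = d + ld > lt,
        donor_start = ds + 1L, donor_end = de,
        target_start = ds + d + 1L, target_end = de + d)
    }
  }
  if (!length(rows))
    return(data.frame(donor_id = character(), target_id = character(),
                      overlap_len = integer(), identity = numeric(),
                      orientation = character(),
                      donor_protrudes_left = logical(),
                      donor_protrudes_right = logical(),
                      donor_start = integer(), donor_end = integer(),
                      target_start = integer(), target_end = integer()))
  out <- do.call(rbind, rows)
  # keep the better orientation per target, then order deterministically
  out <- out[order(out$target_id, -out$overlap_len, -out$identity,
                   out$orientation), , drop = FALSE]
  out <- out[!duplicated(out$target_id), , drop = FALSE]
  out <- out[order(-out$overlap_len, -out$identity, out$target_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
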