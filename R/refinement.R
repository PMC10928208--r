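# Refinement: multidimensional IQR outlier removal over tetranucleotide
# composition, pairwise coverage ratios (CCC) and depth, followed by
# iterative link-based retrieval of un-binned contigs.

#' Coverage correlation coefficient vector of a contig
#'
#' For every unordered sample pair (a < b) the ratio \code{cov_a / cov_b} of
#' the contig's depths in the two samples. Both terms are floored at the
#' pseudocount \code{eps} so all ratios are finite and positive. With a
#' single sample the vector is empty (composition alone is tested).
#'
#' @param depths numeric depth vector of one contig (length = sample count).
#' @param eps pseudocount floor (default 0.01).
#' @return named numeric vector of length \code{S*(S-1)/2}.
#' @export
compute_ccc <- function(depths, eps = 0.01) {
  s <- length(depths)
  if (s < 2) return(numeric(0))
  pr <- utils::combn(s, 2)
  d <- pmax(depths, eps)
  out <- d[pr[1, ]] / d[pr[2, ]]
  names(out) <- paste0("ccc_", pr[1, ], "_", pr[2, ])
  out
}

# Per-contig dimension matrix for a set of contigs: TNF distance to the
# length-weighted centroid, each CCC dimension, and mean depth. The centroid
# may be supplied (e.g. computed from bin members when screening a candidate).
.bin_dims <- function(ids, pool, centroid = NULL) {
  seqs <- pool$seqs[ids]
  if (is.null(centroid)) centroid <- tnf_centroid(seqs)
  tnf_dist <- vapply(seqs, function(s)
    sqrt(sum((as.numeric(compute_tnf(s)) - centroid)^2)), numeric(1))
  if (ncol(pool$depths) >= 2) {
    ccc <- matrix(vapply(ids, function(i) compute_ccc(pool$depths[i, ]),
                         compute_ccc(pool$depths[ids[1], ])),
                  ncol = choose(ncol(pool$depths), 2), byrow = TRUE)
    colnames(ccc) <- names(compute_ccc(pool$depths[ids[1], ]))
  } else {
    ccc <- matrix(numeric(0), nrow = length(ids))
  }
  m <- cbind(tnf_dist = unname(tnf_dist), ccc,
             mean_depth = unname(contig_mean_depth(pool, ids)))
  rownames(m) <- ids
  m
}

#' Multidimensional IQR outlier detection for one bin
#'
#' Tested dimensions are (i) the Euclidean distance of each contig's
#' canonical TNF vector to the bin's length-weighted mean TNF, (ii) every
#' pairwise coverage-ratio (CCC) dimension, and (iii) the across-sample mean
#' depth. For each dimension the interquartile inlier range is computed at
#' every k in \code{k_values} (reported for diagnostics); a contig is an
#' outlier iff it falls outside the range of \emph{any} dimension at
#' \code{operative_k}. Bins with fewer than 4 contigs have too little
#' quartile support and are never pruned.
#'
#' @param ids contig ids of the bin.
#' @param pool \code{contig_pool} with depths.
#' @param k_values IQR multipliers to report (default \code{c(0, 0.5, 1, 2)}).
#' @param operative_k the k actually used for the verdict (default 2, the
#'   most conservative of the reported values).
#' @param strict strict range bounds (see \code{\link{core_coverage_range}}).
#' @return data.frame with one row per contig: \code{contig_id,
#'   tnf_distance, flagged_dims} (comma-separated names at operative k),
#'   \code{is_outlier}; attribute \code{ranges} holds the per-dimension
#'   \code{coverage_range} objects at every k.
#' @export
multidim_iqr_outliers <- function(ids, pool, k_values = c(0, 0.5, 1, 2),
                                  operative_k = 2, strict = FALSE) {
  m <- .bin_dims(ids, pool)
  ranges <- list()
  flagged <- matrix(FALSE, nrow = length(ids), ncol = ncol(m),
                    dimnames = list(ids, colnames(m)))
  if (length(ids) >= 4) {
    for (kk in sort(unique(c(k_values, operative_k)))) {
      rk <- lapply(seq_len(ncol(m)), function(j)
        core_coverage_range(m[, j], k = kk, strict = strict))
      names(rk) <- colnames(m)
      ranges[[as.character(kk)]] <- rk
      if (kk == operative_k)
        for (j in seq_len(ncol(m)))
          flagged[, j] <- !in_coverage_range(rk[[j]], m[, j])
    }
  }
  out <- data.frame(
    contig_id = ids,
    tnf_distance = unname(m[, "tnf_dist"]),
    flagged_dims = apply(flagged, 1, function(f)
      paste(colnames(m)[f], collapse = ",")),
    is_outlier = unname(rowSums(flagged) > 0))
  rownames(out) <- NULL
  attr(out, "ranges") <- ranges
  out
}

#' Remove flagged outlier contigs from a bin set
#'
#' Flagged contigs leave their bins and join the un-binned pool — they stay
#' available for retrieval elsewhere, which is how genuine multi-copy
#' sequences can be re-homed instead of destroyed. Bins whose remaining
#' length falls below \code{min_bin_bp} are dissolved entirely into the
#' pool.
#'
#' @param binset a \code{bin_set} (stage selected).
#' @param verdicts named list (per bin id) of verdict data.frames from
#'   \code{\link{multidim_iqr_outliers}}.
#' @param pool the \code{contig_pool}.
#' @param min_bin_bp dissolution floor in bases (default 50000).
#' @return list: \code{binset} (outlier-depleted bins, stage refined),
#'   \code{unbinned} (character vector of pooled contig ids).
#' @export
remove_outliers <- function(binset, verdicts, pool, min_bin_bp = 50000) {
  bins <- list(); unbinned <- character()
  for (b in names(binset$bins)) {
    ids <- binset$bins[[b]]
    v <- verdicts[[b]]
    out_ids <- if (is.null(v)) character() else v$contig_id[v$is_outlier]
    keep <- setdiff(ids, out_ids)
    unbinned <- c(unbinned, intersect(ids, out_ids))
    if (!length(keep) || sum(contig_lengths(pool, keep)) < min_bin_bp) {
      unbinned <- c(unbinned, keep)
    } else {
      bins[[b]] <- keep
    }
  }
  list(binset = bin_set(bins, name = binset$name, stage = "refined",
                        sources = binset$sources[names(bins)]),
       unbinned = unbinned)
}

# Does a candidate contig fit a bin's composition + coverage profile at k?
# Ranges are computed from the bin's current members only; the candidate's
# TNF distance is measured against the members' centroid.
.contig_fits_bin <- function(id, bin_ids, pool, k = 2, strict = FALSE) {
  if (length(bin_ids) < 4) return(FALSE)
  centroid <- tnf_centroid(pool$seqs[bin_ids])
  members <- .bin_dims(bin_ids, pool, centroid = centroid)
  cand <- .bin_dims(id, pool, centroid = centroid)
  for (j in seq_len(ncol(members))) {
    r <- core_coverage_range(members[, j], k = k, strict = strict)
    if (!in_coverage_range(r, cand[1, j])) return(FALSE)
  }
  TRUE
}

#' Retrieve un-binned contigs through link tracking
#'
#' Iteratively assigns un-binned contigs to outlier-depleted bins. In each
#' iteration a contig is assigned to a bin iff (a) its summed link support
#' to that bin's current members reaches \code{min_support}, (b) that bin is
#' the unique support maximizer (a strict tie skips the contig), and (c) the
#' contig passes the bin's composition + coverage inlier screen at
#' \code{k}. Newly assigned contigs contribute their links in the next
#' iteration; the process stops at a fix point (or after \code{max_iter}
#' iterations, with a warning). A final core-sequence-identification pass
#' over the refined set re-checks redundancy.
#'
#' @param odbs outlier-depleted \code{bin_set}.
#' @param unbinned character vector of un-binned contig ids.
#' @param pool \code{contig_pool} with depths.
#' @param links a \code{link_table} (empty table: no-op).
#' @param min_support minimum summed link support (default 3).
#' @param k IQR multiplier of the admission screen (default 2).
#' @param max_iter iteration guard (default 20).
#' @param recheck_redundancy run the final CSI pass (default TRUE).
#' @param w threshold for the CSI pass.
#' @return list: \code{binset} (refined \code{bin_set}), \code{unbinned}
#'   (ids still unassigned), \code{log} (data.frame: iteration, contig, bin,
#'   support), \code{csi} (decision log of the final pass, or NULL).
#' @export
retrieve_sequences <- function(odbs, unbinned, pool, links,
                               min_support = 3, k = 2, max_iter = 20,
                               recheck_redundancy = TRUE, w = 5) {
  bins <- odbs$bins
  log_rows <- list()
  iter <- 0L
  pending <- sort(unbinned)
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      warning("retrieval did not reach a fix point after ", max_iter,
              " iterations")
      break
    }
    # assignments are decided against the bins as they stood at the start
    # of the iteration; newly assigned contigs only contribute links (and
    # membership) from the next iteration on
    frozen <- bins
    assigned <- character()
    for (id in pending) {
      sup <- vapply(frozen, function(ids) link_support(links, id, ids),
                    numeric(1))
      if (!length(sup) || max(sup) < min_support) next
      best <- which(sup == max(sup))
      if (length(best) != 1) next  # strict tie: never assign
      b <- names(frozen)[best]
      if (!.contig_fits_bin(id, frozen[[b]], pool, k = k)) next
      bins[[b]] <- c(bins[[b]], id)
      assigned <- c(assigned, id)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        iteration = iter, contig = id, bin = b, support = max(sup))
    }
    pending <- setdiff(pending, assigned)
    if (!length(assigned)) break
  }
  refined <- bin_set(bins, name = odbs$name, stage = "refined",
                     sources = setNames(rep("refined", length(bins)),
                                        names(bins)))
  csi <- NULL
  if (recheck_redundancy && length(bins) > 1) {
    sel <- select_nonredundant(refined, pool, w = w)
    pending <- sort(c(pending,
                      setdiff(unlist(sel$archive$bins, use.names = FALSE),
                              unlist(sel$selected$bins, use.names = FALSE))))
    refined <- bin_set(sel$selected$bins, name = odbs$name,
                       stage = "refined",
                       sources = sel$selected$sources)
    csi <- sel$decisions
  }
  list(binset = refined, unbinned = pending,
       log = if (length(log_rows)) do.call(rbind, log_rows)
         else data.frame(iteration = integer(), contig = character(),
                         bin = character(), support = numeric()),
       csi = csi)
}
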