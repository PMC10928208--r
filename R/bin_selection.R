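# Bin selection: merge multi-binner outputs into hybrid bins, group them by
# ANI/AF, identify core (inlier) contigs per bin from the interquartile
# coverage range, and remove redundant bins by depth-normalized coverage
# comparison. The decision interface offers a transparent fixed threshold
# (default) and a small trainable fully connected classifier.

#' Merge redundant binner outputs into hybrid bins
#'
#' Builds a graph over all input bins with an edge whenever the
#' length-weighted contig overlap — shared bp over the smaller bin's bp —
#' reaches \code{threshold}. Each connected component becomes one hybrid bin,
#' the union of its members' contigs deduplicated by contig id. Singleton
#' components pass through unchanged (original bin id kept).
#'
#' @param binsets list of \code{bin_set} objects referencing one shared pool.
#' @param pool the shared \code{contig_pool}.
#' @param threshold minimum shared-bp fraction to merge (default 0.8).
#' @return a \code{bin_set} with stage \code{hybrid}.
#' @export
merge_hybrid_bins <- function(binsets, pool, threshold = 0.8) {
  if (inherits(binsets, "bin_set")) binsets <- list(binsets)
  bins <- list()
  for (bs in binsets)
    for (b in names(bs$bins)) {
      key <- if (b %in% names(bins)) paste(bs$name, b, sep = ".") else b
      bins[[key]] <- bs$bins[[b]]
    }
  n <- length(bins)
  keys <- names(bins)
  lens <- contig_lengths(pool)
  bp <- vapply(bins, function(ids) sum(lens[ids]), numeric(1))
  edges <- matrix(integer(), ncol = 2)
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    keep <- apply(pairs, 2, function(p) {
      shared <- intersect(bins[[p[1]]], bins[[p[2]]])
      length(shared) > 0 &&
        sum(lens[shared]) / min(bp[p[1]], bp[p[2]]) >= threshold
    })
    edges <- t(pairs[, keep, drop = FALSE])
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  out <- list(); src <- character()
  # deterministic order: components sorted by their smallest member key
  comp_ids <- split(seq_len(n), comp)
  ord <- order(vapply(comp_ids, function(ix) min(keys[ix]), character(1)))
  hyb_n <- 0L
  for (ix in comp_ids[ord]) {
    if (length(ix) == 1L) {
      out[[keys[ix]]] <- bins[[ix]]
      src[keys[ix]] <- "passthrough"
    } else {
      hyb_n <- hyb_n + 1L
      id <- sprintf("hybrid_%03d", hyb_n)
      out[[id]] <- unique(unlist(bins[ix], use.names = FALSE))
      src[id] <- paste(sort(keys[ix]), collapse = "+")
    }
  }
  bin_set(out, name = "hybrid", stage = "hybrid", sources = src, pool = pool)
}

#' Group bins by ANI and aligned fraction
#'
#' Computes fragment ANI in both directions for every bin pair; an edge
#' exists when either direction reaches \code{ani_min} and \code{af_min}.
#' Groups are the connected components (single linkage); bins with no
#' qualifying partner form singleton groups.
#'
#' @param binset a hybrid \code{bin_set}.
#' @param pool the shared \code{contig_pool}.
#' @param ani_min minimum ANI percent (default 99).
#' @param af_min minimum aligned fraction percent (default 50).
#' @return list of character vectors of bin ids (sorted within and across
#'   groups), with attribute \code{pairs}: the pairwise ANI table.
#' @export
group_bins <- function(binset, pool, ani_min = 99, af_min = 50) {
  ids <- sort(names(binset$bins))
  n <- length(ids)
  pair_rows <- list()
  edges <- matrix(integer(), ncol = 2)
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    keep <- logical(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      a <- ids[pairs[1, j]]; b <- ids[pairs[2, j]]
      sa <- pool$seqs[binset$bins[[a]]]; sb <- pool$seqs[binset$bins[[b]]]
      ab <- compute_ani(sa, sb)
      ba <- compute_ani(sb, sa)
      ok <- (!is.na(ab$ani) && ab$ani >= ani_min && ab$af >= af_min) ||
        (!is.na(ba$ani) && ba$ani >= ani_min && ba$af >= af_min)
      keep[j] <- ok
      pair_rows[[j]] <- data.frame(
        bin_a = a, bin_b = b,
        ani_ab = ab$ani, af_ab = ab$af, ani_ba = ba$ani, af_ba = ba$af,
        grouped = ok)
    }
    edges <- t(pairs[, keep, drop = FALSE])
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  groups <- lapply(split(ids, comp), sort)
  groups <- groups[order(vapply(groups, `[`, character(1), 1))]
  names(groups) <- NULL
  attr(groups, "pairs") <- if (length(pair_rows)) do.call(rbind, pair_rows)
    else NULL
  groups
}

#' Core coverage range (interquartile inlier interval)
#'
#' Computes \code{Q1} and \code{Q3} of the supplied depths by
#' linear-interpolation percentiles, \code{IQR = Q3 - Q1}, and the inlier
#' interval \code{[Q1 - k*IQR, Q3 + k*IQR]}. Comparison is inclusive by
#' default; \code{strict = TRUE} uses strict inequalities, which voids the
#' interval entirely whenever the quartiles tie at \code{k = 0} (every value
#' on the boundary becomes an outlier) — the inclusive default avoids that
#' degeneracy for uniform-coverage bins.
#'
#' @param depths numeric vector of per-contig coverage values (>= 1 value).
#' @param k non-negative IQR multiplier.
#' @param strict use strict inequalities at the bounds.
#' @return object of class \code{coverage_range} with fields \code{q1, q3,
#'   iqr, k, lo, hi, strict}.
#' @export
core_coverage_range <- function(depths, k = 0, strict = FALSE) {
  if (length(depths) < 1) stop("at least one depth value required")
  stopifnot(k >= 0)
  q <- unname(quantile(depths, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr, k = k,
                 lo = q[1] - k * iqr, hi = q[2] + k * iqr, strict = strict),
            class = "coverage_range")
}

#' Test values against a coverage range
#' @param range a \code{coverage_range}.
#' @param x numeric vector.
#' @return logical vector: inlier (TRUE) / outlier (FALSE).
#' @export
in_coverage_range <- function(range, x) {
  if (range$strict) x > range$lo & x < range$hi
  else x >= range$lo & x <= range$hi
}

#' Inlier contigs of a bin at a given k
#'
#' Applies \code{\link{core_coverage_range}} to the across-sample mean depths
#' of the bin's contigs.
#'
#' @param ids contig ids of the bin.
#' @param pool \code{contig_pool} with depths attached.
#' @param k IQR multiplier (0 for core-contig identification).
#' @param strict strict bounds.
#' @return character vector of inlier contig ids.
#' @export
bin_inliers <- function(ids, pool, k = 0, strict = FALSE) {
  d <- contig_mean_depth(pool, ids)
  r <- core_coverage_range(d, k, strict)
  ids[in_coverage_range(r, d)]
}

#' Pair inlier contigs across two bins
#'
#' Inliers of both bins (at \code{k = 0}) are aligned across the bins;
#' candidate pairs must reach \code{ani_min} percent identity and both
#' contigs must be at least \code{min_len} bases. Each contig appears in at
#' most one pair: pairs are accepted greedily by descending ANI, ties broken
#' by longer aligned length, then lexicographic ids.
#'
#' @param ids_a,ids_b contig ids of the two bins.
#' @param pool \code{contig_pool} with depths.
#' @param ani_min minimum pairwise ANI (default 99).
#' @param min_len minimum contig length for both members (default 1000).
#' @param k IQR multiplier for the inlier screen (default 0).
#' @return data.frame with one row per pair: \code{contig_a, contig_b, ani,
#'   len_a, len_b, cov_a, cov_b} (cov = across-sample mean depth).
#' @export
pair_inliers <- function(ids_a, ids_b, pool, ani_min = 99, min_len = 1000L,
                         k = 0) {
  empty <- data.frame(contig_a = character(), contig_b = character(),
                      ani = numeric(), alen = numeric(),
                      len_a = integer(), len_b = integer(),
                      cov_a = numeric(), cov_b = numeric())
  in_a <- bin_inliers(ids_a, pool, k)
  in_b <- bin_inliers(ids_b, pool, k)
  in_a <- in_a[contig_lengths(pool, in_a) >= min_len]
  in_b <- in_b[contig_lengths(pool, in_b) >= min_len]
  if (!length(in_a) || !length(in_b)) return(empty)
  tseqs <- pool$seqs[in_b]
  cand <- list()
  for (a in in_a) {
    fr <- .fragment_seqs(pool$seqs[a])
    hits <- .map_fragments(fr$frag, tseqs)
    flen <- nchar(fr$frag)
    ok <- hits$target > 0 & hits$covered >= 0.8
    if (!any(ok)) next
    for (tix in sort(unique(hits$target[ok]))) {
      sel <- ok & hits$target == tix
      ani <- mean(hits$identity[sel])
      if (ani < ani_min) next
      cand[[length(cand) + 1L]] <- data.frame(
        contig_a = a, contig_b = in_b[tix], ani = ani,
        alen = sum(flen[sel]))
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$ani, -cand$alen, cand$contig_a, cand$contig_b), ,
               drop = FALSE]
  used_a <- character(); used_b <- character(); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$contig_a[i] %in% used_a || cand$contig_b[i] %in% used_b) next
    keep[i] <- TRUE
    used_a <- c(used_a, cand$contig_a[i])
    used_b <- c(used_b, cand$contig_b[i])
  }
  out <- cand[keep, , drop = FALSE]
  out$len_a <- unname(contig_lengths(pool, out$contig_a))
  out$len_b <- unname(contig_lengths(pool, out$contig_b))
  out$cov_a <- unname(contig_mean_depth(pool, out$contig_a))
  out$cov_b <- unname(contig_mean_depth(pool, out$contig_b))
  rownames(out) <- NULL
  out
}

#' Depth normalization ratio between paired inliers
#'
#' The mean, over inlier pairs, of the coverage ratio of the pair members:
#' \code{x_bar = (1/n) * sum(cov_a_i / cov_b_i)}, using each contig's mean
#' depth across samples. A zero denominator is replaced by the pseudocount
#' \code{eps}.
#'
#' @param pairs data.frame from \code{\link{pair_inliers}} (n >= 1 rows).
#' @param eps pseudocount for zero denominators (default 0.01).
#' @return the ratio (numeric scalar).
#' @export
depth_normalization_ratio <- function(pairs, eps = 0.01) {
  if (nrow(pairs) == 0)
    stop("no inlier pairs: the no-evidence path retains both bins")
  den <- ifelse(pairs$cov_b == 0, eps, pairs$cov_b)
  mean(pairs$cov_a / den)
}

#' Delta coverage between two bins
#'
#' Absolute difference between bin A's mean inlier coverage and bin B's mean
#' inlier coverage rescaled by the depth normalization ratio:
#' \code{delta = |mu_a - x_bar * mu_b|}. The means are over \emph{all}
#' inliers of each bin, paired and unpaired.
#'
#' @param mu_a,mu_b mean inlier coverage of bins A and B.
#' @param x_bar depth normalization ratio.
#' @return non-negative numeric scalar.
#' @export
delta_coverage <- function(mu_a, mu_b, x_bar) {
  abs(mu_a - x_bar * mu_b)
}

#' Compare two bins for redundancy (core sequence identification)
#'
#' Runs the full pairwise comparison: inlier identification at \code{k},
#' inlier pairing, depth-normalization ratio, delta coverage, and the
#' redundancy verdict via \code{\link{classify_redundancy}}.
#'
#' @param bin_a,bin_b contig id vectors of the two bins.
#' @param pool \code{contig_pool} with depths.
#' @param mode \code{"threshold"} or \code{"model"}.
#' @param w decision threshold for threshold mode.
#' @param model fitted model from \code{\link{train_redundancy_model}}
#'   (model mode).
#' @param k IQR multiplier for inlier identification (default 0).
#' @param ani_min,min_len inlier-pair filters.
#' @return a \code{redundancy_decision} list: \code{n_pairs, x_bar, mu_a,
#'   mu_b, delta, w, verdict} plus bin summaries.
#' @export
compare_bins <- function(bin_a, bin_b, pool, mode = c("threshold", "model"),
                         w = 5, model = NULL, k = 0, ani_min = 99,
                         min_len = 1000L) {
  mode <- match.arg(mode)
  pairs <- pair_inliers(bin_a, bin_b, pool, ani_min, min_len, k)
  in_a <- bin_inliers(bin_a, pool, k)
  in_b <- bin_inliers(bin_b, pool, k)
  mu_a <- mean(contig_mean_depth(pool, in_a))
  mu_b <- mean(contig_mean_depth(pool, in_b))
  lens <- contig_lengths(pool)
  stats <- list(
    n_pairs = nrow(pairs),
    x_bar = if (nrow(pairs)) depth_normalization_ratio(pairs) else NA_real_,
    mu_a = mu_a, mu_b = mu_b,
    inlier_bp_a = sum(lens[in_a]), inlier_bp_b = sum(lens[in_b]),
    disp_a = sd(contig_mean_depth(pool, in_a)) / max(mu_a, 1e-9),
    disp_b = sd(contig_mean_depth(pool, in_b)) / max(mu_b, 1e-9))
  stats$delta <- if (nrow(pairs))
    delta_coverage(mu_a, mu_b, stats$x_bar) else NA_real_
  classify_redundancy(stats, mode = mode, w = w, model = model)
}

#' Decide whether a bin pair is redundant
#'
#' Threshold mode declares the pair redundant when \code{delta < w}. Model
#' mode scores the pair with a small fully connected classifier (see
#' \code{\link{train_redundancy_model}}) and decides at probability 0.5.
#' With zero inlier pairs there is no evidence either way and both bins are
#' retained (\code{verdict = "no-evidence"}).
#'
#' @param stats list with \code{n_pairs, x_bar, delta, mu_a, mu_b,
#'   inlier_bp_a, inlier_bp_b, disp_a, disp_b} (see
#'   \code{\link{compare_bins}}).
#' @param mode \code{"threshold"} or \code{"model"}.
#' @param w fixed decision threshold (coverage units) for threshold mode.
#' @param model fitted classifier for model mode.
#' @return a \code{redundancy_decision} list with \code{verdict} one of
#'   \code{"redundant", "nonredundant", "no-evidence"}.
#' @export
classify_redundancy <- function(stats, mode = c("threshold", "model"), w = 5,
                                model = NULL) {
  mode <- match.arg(mode)
  if (stats$n_pairs == 0) {
    verdict <- "no-evidence"
  } else if (mode == "threshold") {
    verdict <- if (stats$delta < w) "redundant" else "nonredundant"
  } else {
    if (is.null(model))
      stop("model mode needs a fitted model; train one with ",
           "train_redundancy_model() or use mode = 'threshold'")
    p <- predict(model$fit, .redundancy_features(stats))[, 1]
    verdict <- if (p >= 0.5) "redundant" else "nonredundant"
  }
  structure(c(stats, list(w = w, mode = mode, verdict = verdict)),
            class = "redundancy_decision")
}

# Feature row for the classifier; delta is also scaled by mean coverage so
# the decision is not tied to the absolute depth of the community.
.redundancy_features <- function(stats) {
  data.frame(
    delta = stats$delta,
    delta_rel = stats$delta / max(stats$mu_a, 1e-9),
    x_bar = stats$x_bar,
    n_pairs = stats$n_pairs,
    log_bp_ratio = log(max(stats$inlier_bp_a, 1) /
                         max(stats$inlier_bp_b, 1)),
    disp_a = stats$disp_a, disp_b = stats$disp_b)
}

#' Train the redundancy classifier on labeled pairs
#'
#' Fits a single-hidden-layer fully connected network (via
#' \code{nnet::nnet}) on the comparison statistics of labeled synthetic bin
#' pairs, e.g. the output of \code{\link{make_benchmark}("redundancy40")}.
#' Pairs with zero inlier pairs carry no signal and are dropped (they follow
#' the no-evidence path at prediction time too).
#'
#' @param decisions list of \code{redundancy_decision} objects (or the stats
#'   lists from \code{\link{compare_bins}}).
#' @param labels logical vector: TRUE for truly redundant pairs.
#' @param hidden hidden-layer size (default 4).
#' @param seed RNG seed for weight initialization.
#' @return list of class \code{redundancy_model} with the fitted net.
#' @export
train_redundancy_model <- function(decisions, labels, hidden = 4, seed = 1) {
  feats <- do.call(rbind, lapply(decisions, .redundancy_features))
  keep <- vapply(decisions, function(d) d$n_pairs > 0, logical(1))
  feats <- feats[keep, , drop = FALSE]
  y <- as.numeric(labels[keep])
  set.seed(seed)
  fit <- nnet::nnet(feats, y, size = hidden, decay = 0.01, maxit = 500,
                    trace = FALSE)
  structure(list(fit = fit, features = colnames(feats)),
            class = "redundancy_model")
}

#' Remove redundant bins within ANI groups
#'
#' Computes pairwise redundancy decisions within every group and removes, for
#' each redundant pair, the bin with the smaller total inlier bp (ties broken
#' by keeping the lexicographically smaller id). Pairs are processed by
#' ascending delta (strongest redundancy evidence first); a bin already
#' removed is skipped, so the two members of a redundant pair are never both
#' removed. Removed bins are archived, with their group's surviving members
#' recorded, so their inliers can later serve as gap-filling donors.
#'
#' @param binset the hybrid \code{bin_set}.
#' @param pool \code{contig_pool} with depths.
#' @param groups output of \code{\link{group_bins}}.
#' @param mode,w,model,k passed to \code{\link{compare_bins}}.
#' @return list: \code{selected} (\code{bin_set}, stage selected),
#'   \code{archive} (\code{bin_set} of removed bins), \code{archive_groups}
#'   (named list: archived bin id -> surviving group member ids),
#'   \code{decisions} (data.frame log: bin_a, bin_b, n_pairs, x_bar, delta,
#'   w, verdict).
#' @export
select_nonredundant <- function(binset, pool, groups = NULL,
                                mode = "threshold", w = 5, model = NULL,
                                k = 0) {
  if (is.null(groups)) groups <- group_bins(binset, pool)
  log_rows <- list()
  removed <- character()
  decisions <- list()
  for (grp in groups) {
    if (length(grp) < 2) next
    pairs <- utils::combn(grp, 2)
    ds <- lapply(seq_len(ncol(pairs)), function(j)
      compare_bins(binset$bins[[pairs[1, j]]], binset$bins[[pairs[2, j]]],
                   pool, mode = mode, w = w, model = model, k = k))
    ord <- order(vapply(ds, function(d)
      if (is.na(d$delta)) Inf else d$delta, numeric(1)),
      pairs[1, ], pairs[2, ])
    for (j in ord) {
      d <- ds[[j]]
      a <- pairs[1, j]; b <- pairs[2, j]
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        bin_a = a, bin_b = b, n_pairs = d$n_pairs,
        x_bar = if (is.na(d$x_bar)) NA_real_ else d$x_bar,
        delta = if (is.na(d$delta)) NA_real_ else d$delta,
        w = d$w, verdict = d$verdict)
      if (d$verdict != "redundant") next
      if (a %in% removed || b %in% removed) next
      drop <- if (d$inlier_bp_a < d$inlier_bp_b) a
        else if (d$inlier_bp_b < d$inlier_bp_a) b
        else max(a, b)
      removed <- c(removed, drop)
    }
  }
  keep <- setdiff(names(binset$bins), removed)
  selected <- bin_set(binset$bins[keep], name = "selected",
                      stage = "selected", sources = binset$sources[keep])
  archive <- if (length(removed))
    bin_set(binset$bins[removed], name = "archive", stage = "selected",
            sources = binset$sources[removed])
  else bin_set(list(), name = "archive", stage = "selected")
  archive_groups <- lapply(setNames(removed, removed), function(r) {
    grp <- groups[[which(vapply(groups, function(g) r %in% g, logical(1)))]]
    setdiff(grp, removed)
  })
  dec_log <- if (length(log_rows)) do.call(rbind, log_rows)
    else data.frame(bin_a = character(), bin_b = character(),
                    n_pairs = integer(), x_bar = numeric(), delta = numeric(),
                    w = numeric(), verdict = character())
  list(selected = selected, archive = archive,
       archive_groups = archive_groups, decisions = dec_log)
}
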