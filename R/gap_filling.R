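# Restrained overlap-layout-consensus (rOLC) gap filling. Inlier contigs of
# archived redundant bins (plus still-un-binned contigs) act as donors that
# extend bin contigs at one end or bridge two bin contigs across a gap, in
# two rounds of increasing overlap stringency. Two restrictions guard
# against chimeric over-extension: a donor protruding beyond the target at
# both ends is rejected, and the merged sequence must stay under 105% of the
# summed target length(s). At overlap disagreements the consensus keeps the
# target base (targets passed refinement QC; donors did not).

#' Contig N50
#' @param lengths integer vector of contig lengths.
#' @return the N50 in bases (0 for empty input).
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) return(0)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Collect gap-filling donors for each refined bin
#'
#' Archived redundant bins are passed through the refinement outlier filter
#' (operative \code{k}); the surviving inliers become donors scoped to the
#' bins of the ANI group their source bin belonged to. Contigs still in the
#' un-binned pool are additional donors for every bin.
#'
#' @param archive \code{bin_set} of removed redundant bins.
#' @param archive_groups named list: archived bin id -> surviving group
#'   member bin ids (from \code{\link{select_nonredundant}}).
#' @param target_bins character vector of refined bin ids.
#' @param pool \code{contig_pool} with depths.
#' @param unbinned character vector of un-binned contig ids.
#' @param k operative IQR multiplier of the outlier filter (default 2).
#' @return named list: target bin id -> character vector of donor contig ids.
#' @export
collect_donors <- function(archive, archive_groups, target_bins, pool,
                           unbinned = character(), k = 2) {
  donors <- setNames(lapply(target_bins, function(b) sort(unique(unbinned))),
                     target_bins)
  for (ab in names(archive$bins)) {
    v <- multidim_iqr_outliers(archive$bins[[ab]], pool, operative_k = k)
    surv <- v$contig_id[!v$is_outlier]
    if (!length(surv)) next
    scope <- intersect(archive_groups[[ab]], target_bins)
    for (b in scope) donors[[b]] <- sort(unique(c(donors[[b]], surv)))
  }
  donors
}

# One donor's acceptable layout events against one bin's current contigs.
# Returns a list of event descriptors (kind extend/bridge) that respect the
# protrusion and 105%-length restrictions.
.donor_events <- function(donor_id, donor_seq, contigs, min_overlap,
                          min_identity) {
  cands <- find_overlaps(setNames(donor_seq, donor_id), contigs,
                         min_len = min_overlap, min_identity = min_identity)
  events <- list()
  if (!nrow(cands)) return(events)
  lens <- nchar(contigs)
  ld <- nchar(donor_seq)
  # restriction (1): a donor longer than the target at both ends is rejected
  cands <- cands[!(cands$donor_protrudes_left & cands$donor_protrudes_right), ,
                 drop = FALSE]
  if (!nrow(cands)) return(events)
  suf <- cands[cands$donor_protrudes_right & !cands$donor_protrudes_left &
                 cands$target_end == lens[cands$target_id], , drop = FALSE]
  pre <- cands[cands$donor_protrudes_left & !cands$donor_protrudes_right &
                 cands$target_start == 1L, , drop = FALSE]
  # bridges: donor covers the tail of T1 and the head of T2
  if (nrow(suf) && nrow(pre)) {
    for (i in seq_len(nrow(suf))) for (j in seq_len(nrow(pre))) {
      if (suf$target_id[i] == pre$target_id[j]) next
      if (suf$orientation[i] != pre$orientation[j]) next
      de1 <- suf$donor_end[i]; ds2 <- pre$donor_start[j]
      if (ds2 <= de1) next  # donor middle must be a forward walk
      l1 <- lens[suf$target_id[i]]; l2 <- lens[pre$target_id[j]]
      gap <- ds2 - de1 - 1L
      merged_len <- l1 + gap + l2
      if (merged_len >= 1.05 * (l1 + l2)) next  # restriction (2)
      events[[length(events) + 1L]] <- list(
        kind = "bridge", donor_id = donor_id,
        targets = c(suf$target_id[i], pre$target_id[j]),
        orientation = suf$orientation[i],
        overlaps = c(suf$overlap_len[i], pre$overlap_len[j]),
        identity = mean(c(suf$identity[i], pre$identity[j])),
        gap_from = de1 + 1L, gap_to = ds2 - 1L, merged_len = merged_len)
    }
  }
  # extensions: donor protrudes past exactly one target end
  for (ext in list(suf, pre)) {
    if (!nrow(ext)) next
    for (i in seq_len(nrow(ext))) {
      lt <- lens[ext$target_id[i]]
      right <- ext$donor_protrudes_right[i]
      add <- if (right) ld - ext$donor_end[i] else ext$donor_start[i] - 1L
      if (add <= 0) next
      merged_len <- lt + add
      if (merged_len >= 1.05 * lt) next  # restriction (2)
      events[[length(events) + 1L]] <- list(
        kind = "extend", donor_id = donor_id, targets = ext$target_id[i],
        orientation = ext$orientation[i], overlaps = ext$overlap_len[i],
        identity = ext$identity[i], side = if (right) "right" else "left",
        donor_cut = if (right) ext$donor_end[i] else ext$donor_start[i],
        merged_len = merged_len)
    }
  }
  events
}

#' One round of restrained overlap-layout-consensus
#'
#' For each bin, donors are overlapped with the bin's contigs
#' (\code{\link{find_overlaps}}); the Layout step accepts extensions (donor
#' protrudes past exactly one end of one contig) and bridges (donor covers
#' the tail of one contig and the head of another, each overlap at least
#' \code{min_overlap} at \code{min_identity} or better), subject to the two
#' restrictions described above. The Consensus keeps target bases at every
#' overlap disagreement. Events are applied greedily by descending total
#' overlap length (ties by identity, then donor id); each donor and each
#' target contig is consumed at most once per round.
#'
#' @param bin_seqs named list: bin id -> named character vector of contig
#'   sequences.
#' @param donor_seqs named list: bin id -> named character vector of donor
#'   sequences.
#' @param min_overlap minimum overlap length (300 in round 1, 500 in round 2).
#' @param min_identity minimum percent identity (default 99).
#' @param round round label for the event log.
#' @param members optional named list per bin: contig id -> character vector
#'   of source pool contig ids (tracked through merges for depth
#'   bookkeeping).
#' @return list: \code{bins} (updated \code{bin_seqs}), \code{events}
#'   (data.frame log), \code{consumed} (donor ids used), \code{members}
#'   (updated membership map).
#' @export
rolc_round <- function(bin_seqs, donor_seqs, min_overlap, min_identity = 99,
                       round = 1L, members = NULL) {
  if (is.null(members))
    members <- lapply(bin_seqs, function(ct)
      setNames(as.list(names(ct)), names(ct)))
  consumed <- character()
  ev_rows <- list()
  for (b in names(bin_seqs)) {
    dn <- donor_seqs[[b]]
    if (is.null(dn) || !length(dn)) next
    contigs <- bin_seqs[[b]]
    events <- list()
    for (d in names(dn))
      events <- c(events, .donor_events(d, dn[[d]], contigs, min_overlap,
                                        min_identity))
    if (!length(events)) next
    ord <- order(-vapply(events, function(e) sum(e$overlaps), numeric(1)),
                 -vapply(events, function(e) e$identity, numeric(1)),
                 vapply(events, function(e) e$donor_id, character(1)),
                 vapply(events, function(e) e$targets[1], character(1)))
    used_t <- character()
    for (e in events[ord]) {
      if (e$donor_id %in% consumed || any(e$targets %in% used_t)) next
      dseq <- if (e$orientation == "forward") dn[[e$donor_id]]
        else revcomp(dn[[e$donor_id]])
      if (e$kind == "bridge") {
        t1 <- e$targets[1]; t2 <- e$targets[2]
        mid <- if (e$gap_to >= e$gap_from)
          substr(dseq, e$gap_from, e$gap_to) else ""
        merged <- paste0(contigs[[t1]], mid, contigs[[t2]])
        newid <- paste0(t1, "+", t2)
        contigs <- contigs[setdiff(names(contigs), c(t1, t2))]
        contigs[[newid]] <- merged
        members[[b]][[newid]] <- c(members[[b]][[t1]], members[[b]][[t2]])
        members[[b]][[t1]] <- NULL; members[[b]][[t2]] <- NULL
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          bin = b, round = round, kind = "bridge", donor_id = e$donor_id,
          target_1 = t1, target_2 = t2, overlap_1 = e$overlaps[1],
          overlap_2 = e$overlaps[2], identity = e$identity,
          merged_len = nchar(merged), merged_id = newid)
      } else {
        t1 <- e$targets[1]
        merged <- if (e$side == "right")
          paste0(contigs[[t1]], substr(dseq, e$donor_cut + 1L, nchar(dseq)))
        else paste0(substr(dseq, 1L, e$donor_cut - 1L), contigs[[t1]])
        contigs[[t1]] <- merged
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          bin = b, round = round, kind = "extend", donor_id = e$donor_id,
          target_1 = t1, target_2 = NA_character_, overlap_1 = e$overlaps[1],
          overlap_2 = NA_integer_, identity = e$identity,
          merged_len = nchar(merged), merged_id = t1)
      }
      consumed <- c(consumed, e$donor_id)
      used_t <- c(used_t, e$targets)
    }
    bin_seqs[[b]] <- contigs
  }
  list(bins = bin_seqs,
       events = if (length(ev_rows)) do.call(rbind, ev_rows)
         else data.frame(bin = character(), round = integer(),
                         kind = character(), donor_id = character(),
                         target_1 = character(), target_2 = character(),
                         overlap_1 = integer(), overlap_2 = integer(),
                         identity = numeric(), merged_len = integer(),
                         merged_id = character()),
       consumed = consumed, members = members)
}

#' Gap-fill refined bins with donors from archived redundant bins
#'
#' Runs rOLC round 1 (overlaps of at least \code{round1_overlap} bp) and
#' then round 2 at the more stringent \code{round2_overlap} bp on the
#' round-1 output; donors consumed in round 1 are not reused. A final
#' core-sequence-identification pass dereplicates the result (merged contigs
#' inherit the length-weighted mean depth of their source contigs), and
#' per-bin contiguity statistics are reported before and after.
#'
#' @param refined refined \code{bin_set}.
#' @param archive,archive_groups archive from
#'   \code{\link{select_nonredundant}}.
#' @param pool \code{contig_pool} with depths.
#' @param unbinned un-binned contig ids (additional donors).
#' @param round1_overlap,round2_overlap overlap thresholds (300/500 bp).
#' @param min_identity minimum overlap identity (default 99).
#' @param k operative k of the donor outlier filter.
#' @param recheck_redundancy run the final CSI pass (default TRUE).
#' @param w threshold of the CSI pass.
#' @return list: \code{binset} (stage gapfilled), \code{pool} (augmented
#'   with merged contigs), \code{events} (merge log), \code{stats}
#'   (per-bin n_contigs and N50 before/after), \code{csi}.
#' @export
gap_fill <- function(refined, archive, archive_groups, pool,
                     unbinned = character(), round1_overlap = 300L,
                     round2_overlap = 500L, min_identity = 99, k = 2,
                     recheck_redundancy = TRUE, w = 5) {
  bin_seqs <- lapply(refined$bins, function(ids)
    as.list(pool$seqs[ids]))
  bin_seqs <- lapply(bin_seqs, function(x) unlist(x))
  donor_ids <- collect_donors(archive, archive_groups, names(refined$bins),
                              pool, unbinned, k = k)
  donor_seqs <- lapply(donor_ids, function(ids) pool$seqs[ids])
  before <- data.frame(
    bin = names(bin_seqs),
    n_contigs_before = vapply(bin_seqs, length, integer(1)),
    n50_before = vapply(bin_seqs, function(x) n50(nchar(x)), numeric(1)))
  r1 <- rolc_round(bin_seqs, donor_seqs, round1_overlap, min_identity,
                   round = 1L)
  donor_seqs2 <- lapply(donor_seqs, function(x)
    x[setdiff(names(x), r1$consumed)])
  r2 <- rolc_round(r1$bins, donor_seqs2, round2_overlap, min_identity,
                   round = 2L, members = r1$members)
  events <- rbind(r1$events, r2$events)
  # augment the pool: merged contigs get the length-weighted mean depth of
  # their source contigs
  seqs <- pool$seqs
  depths <- pool$depths
  final_bins <- list()
  for (b in names(r2$bins)) {
    ids <- names(r2$bins[[b]])
    for (id in ids) {
      if (!id %in% names(seqs)) {
        seqs[[id]] <- r2$bins[[b]][[id]]
        src <- r2$members[[b]][[id]]
        lw <- contig_lengths(pool, src)
        depths <- rbind(depths, matrix(
          colSums(pool$depths[src, , drop = FALSE] * lw) / sum(lw),
          nrow = 1, dimnames = list(id, colnames(depths))))
      } else if (!identical(unname(seqs[[id]]), unname(r2$bins[[b]][[id]]))) {
        seqs[[id]] <- r2$bins[[b]][[id]]  # extended in place
      }
    }
    final_bins[[b]] <- ids
  }
  pool2 <- contig_pool(seqs, depths = depths, samples = pool$samples)
  gapfilled <- bin_set(final_bins, name = refined$name, stage = "gapfilled",
                       sources = setNames(rep("gapfilled",
                                              length(final_bins)),
                                          names(final_bins)),
                       pool = pool2)
  csi <- NULL
  if (recheck_redundancy && length(final_bins) > 1) {
    sel <- select_nonredundant(gapfilled, pool2, w = w)
    gapfilled <- bin_set(sel$selected$bins, name = refined$name,
                         stage = "gapfilled", sources = sel$selected$sources,
                         pool = pool2)
    csi <- sel$decisions
  }
  after <- data.frame(
    bin = names(gapfilled$bins),
    n_contigs_after = vapply(gapfilled$bins, length, integer(1)),
    n50_after = vapply(gapfilled$bins, function(ids)
      n50(nchar(pool2$seqs[ids])), numeric(1)))
  stats <- merge(before, after, by = "bin", all = TRUE)
  list(binset = gapfilled, pool = pool2, events = events, stats = stats,
       csi = csi)
}
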