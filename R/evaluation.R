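# Reference-based bin quality evaluation: every bin contig is
# fragment-aligned against a set of reference genomes; completeness is the
# fraction of the majority reference covered, contamination the fraction of
# aligned bases landing on other references, and quality =
# completeness - 5 * contamination with the standard tier labels.

#' Quality tier membership flags
#'
#' The three named tiers: \emph{baseline} (completeness >= 35 and
#' contamination <= 20), \emph{MAG} (quality = completeness -
#' 5 * contamination >= 50), and \emph{high} (completeness >= 90 and
#' contamination <= 5). The tiers are independent definitions, not nested
#' cut-points, so all three flags are reported.
#'
#' @param completeness,contamination percentages in [0, 100] (vectorized).
#' @return data.frame with logical columns \code{baseline, mag, high} and
#'   numeric \code{quality}.
#' @export
tier_flags <- function(completeness, contamination) {
  quality <- completeness - 5 * contamination
  data.frame(baseline = completeness >= 35 & contamination <= 20,
             mag = quality >= 50,
             high = completeness >= 90 & contamination <= 5,
             quality = quality)
}

#' Single tier label for a bin
#' @inheritParams tier_flags
#' @return character: the best tier among \code{high > mag > baseline},
#'   else \code{"fail"}.
#' @export
quality_tier <- function(completeness, contamination) {
  f <- tier_flags(completeness, contamination)
  ifelse(f$high, "high",
         ifelse(f$mag, "mag",
                ifelse(f$baseline, "baseline", "fail")))
}

#' Evaluate one bin against reference genomes
#'
#' Each bin contig is chopped into fragments and mapped against all
#' references (\code{\link{compute_ani}} machinery); a contig is assigned to
#' the reference receiving the most aligned bases (or to none when nothing
#' aligns). The majority reference is the one maximizing the bin's total
#' aligned bp. Completeness is 100 times the number of majority-reference
#' positions covered by aligned fragments (each position counted once) over
#' the reference length; contamination is 100 times the aligned bp landing
#' on non-majority references over all aligned bp.
#'
#' @param bin_seqs named character vector: the bin's contig sequences.
#' @param references named character vector of reference genome sequences
#'   (non-empty).
#' @param min_cov minimum fragment coverage to count as aligned.
#' @return list of class \code{quality_report}: \code{bin_id} (filled by
#'   callers), \code{majority_ref}, \code{completeness}, \code{contamination},
#'   \code{quality}, \code{tier}, \code{flags}, \code{per_ref_bp}.
#' @export
evaluate_bin <- function(bin_seqs, references, min_cov = 0.8) {
  stopifnot(length(references) >= 1)
  fr <- .fragment_seqs(bin_seqs)
  hits <- .map_fragments(fr$frag, references)
  flen <- nchar(fr$frag)
  aligned <- hits$target > 0 & hits$covered >= min_cov
  per_ref_bp <- setNames(numeric(length(references)), names(references))
  if (any(aligned)) {
    bp <- tapply(flen[aligned], names(references)[hits$target[aligned]], sum)
    per_ref_bp[names(bp)] <- bp
  }
  if (sum(per_ref_bp) == 0) {
    rep <- list(majority_ref = NA_character_, completeness = 0,
                contamination = 0, quality = 0, tier = "fail",
                flags = tier_flags(0, 0), per_ref_bp = per_ref_bp)
    class(rep) <- "quality_report"
    return(rep)
  }
  maj <- names(per_ref_bp)[which.max(per_ref_bp)]
  maj_ix <- which(names(references) == maj)
  on_maj <- aligned & hits$target == maj_ix
  cov_ranges <- IRanges::reduce(IRanges::IRanges(
    start = hits$tstart[on_maj], end = hits$tend[on_maj]))
  covered <- sum(IRanges::width(IRanges::restrict(
    cov_ranges, start = 1L, end = nchar(references[[maj]]))))
  completeness <- 100 * covered / nchar(references[[maj]])
  contamination <- 100 * (sum(per_ref_bp) - per_ref_bp[[maj]]) /
    sum(per_ref_bp)
  rep <- list(majority_ref = maj,
              completeness = min(100, completeness),
              contamination = contamination,
              quality = min(100, completeness) - 5 * contamination,
              tier = quality_tier(min(100, completeness), contamination),
              flags = tier_flags(min(100, completeness), contamination),
              per_ref_bp = per_ref_bp)
  class(rep) <- "quality_report"
  rep
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("ref %s: completeness %.1f%%, contamination %.1f%%, quality %.1f (%s)\n",
              if (is.na(x$majority_ref)) "<none>" else x$majority_ref,
              x$completeness, x$contamination, x$quality, x$tier))
  invisible(x)
}

#' Evaluate every bin of a bin set
#' @param binset a \code{bin_set}.
#' @param pool the \code{contig_pool} providing sequences.
#' @param references named character vector of reference genomes.
#' @return data.frame, one row per bin: \code{bin_id, majority_ref,
#'   completeness, contamination, quality, tier, baseline, mag, high}.
#' @export
evaluate_binset <- function(binset, pool, references) {
  rows <- lapply(names(binset$bins), function(b) {
    r <- evaluate_bin(pool$seqs[binset$bins[[b]]], references)
    data.frame(bin_id = b, majority_ref = r$majority_ref,
               completeness = r$completeness,
               contamination = r$contamination, quality = r$quality,
               tier = r$tier, baseline = r$flags$baseline, mag = r$flags$mag,
               high = r$flags$high)
  })
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(bin_id = character(), majority_ref = character(),
                    completeness = numeric(), contamination = numeric(),
                    quality = numeric(), tier = character(),
                    baseline = logical(), mag = logical(), high = logical())
  rownames(out) <- NULL
  out
}

#' Summarize a table of quality reports
#' @param reports data.frame from \code{\link{evaluate_binset}}.
#' @return one-row data.frame: bin counts per tier definition and
#'   mean/sd of completeness, contamination and quality.
#' @export
summarize_reports <- function(reports) {
  n <- nrow(reports)
  data.frame(
    n_bins = n,
    n_baseline = if (n) sum(reports$baseline) else 0L,
    n_mag = if (n) sum(reports$mag) else 0L,
    n_high = if (n) sum(reports$high) else 0L,
    mean_completeness = if (n) mean(reports$completeness) else NA_real_,
    sd_completeness = if (n > 1) sd(reports$completeness) else NA_real_,
    mean_contamination = if (n) mean(reports$contamination) else NA_real_,
    sd_contamination = if (n > 1) sd(reports$contamination) else NA_real_,
    mean_quality = if (n) mean(reports$quality) else NA_real_,
    sd_quality = if (n > 1) sd(reports$quality) else NA_real_)
}
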