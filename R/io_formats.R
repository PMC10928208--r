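# On-disk artifacts: contig pools (FASTA), bin sets (directories of FASTA),
# depth tables (plain or MetaBAT2/jgi dialect), link tables. All readers
# validate strictly; contig ids are compared as exact strings.

#' Construct a contig pool
#'
#' A contig pool holds the assembled contigs shared by all bin sets, plus
#' (once a depth table is attached) the per-sample mean depth of every contig.
#'
#' @param seqs named character vector or \code{Biostrings::DNAStringSet} of
#'   uppercase DNA sequences over \code{A,C,G,T,N}.
#' @param depths optional numeric matrix, one row per contig (rownames =
#'   contig ids), one column per sample; all values finite and >= 0.
#' @param samples optional character vector of sample names (defaults to the
#'   column names of \code{depths}).
#' @return an object of class \code{contig_pool}.
#' @export
contig_pool <- function(seqs, depths = NULL, samples = NULL) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all contigs must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig id: ", names(seqs)[duplicated(names(seqs))][1])
  if (any(nchar(seqs) == 0)) stop("empty sequence for contig: ",
                                  names(seqs)[nchar(seqs) == 0][1])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("non-ACGTN characters in contig: ", names(seqs)[bad][1])
  if (!is.null(depths)) {
    depths <- as.matrix(depths)
    if (is.null(samples)) samples <- colnames(depths)
    stopifnot(!is.null(rownames(depths)))
    missing <- setdiff(names(seqs), rownames(depths))
    if (length(missing))
      stop("contig in pool absent from depth table: ", missing[1])
    depths <- depths[names(seqs), , drop = FALSE]
    if (any(!is.finite(depths)) || any(depths < 0))
      stop("depths must be finite and >= 0")
  }
  structure(list(seqs = seqs, depths = depths, samples = samples),
            class = "contig_pool")
}

#' @export
print.contig_pool <- function(x, ...) {
  cat(sprintf("contig_pool: %d contigs, %s bp, %s\n",
              length(x$seqs), format(sum(nchar(x$seqs)), big.mark = ","),
              if (is.null(x$depths)) "no depths attached"
              else sprintf("%d samples", ncol(x$depths))))
  invisible(x)
}

#' @export
length.contig_pool <- function(x) length(x$seqs)

#' Contig lengths of a pool
#' @param pool a \code{contig_pool}.
#' @param ids optional subset of contig ids.
#' @return named integer vector of lengths in bases.
#' @export
contig_lengths <- function(pool, ids = NULL) {
  if (is.null(ids)) nchar(pool$seqs) else nchar(pool$seqs[ids])
}

#' Mean depth (across samples) of contigs
#' @inheritParams contig_lengths
#' @return named numeric vector; the across-sample mean depth per contig.
#' @export
contig_mean_depth <- function(pool, ids = NULL) {
  stopifnot(!is.null(pool$depths))
  d <- if (is.null(ids)) pool$depths else pool$depths[ids, , drop = FALSE]
  rowMeans(d)
}

#' Read a contig pool from FASTA
#'
#' Sequences are uppercased on input. By default any character outside
#' \code{A,C,G,T,N} is a hard error (strictness surfaces upstream assembly
#' problems); with \code{permissive = TRUE} such characters are mapped to
#' \code{N}. Record ids (first whitespace-delimited token of the header) must
#' be unique and sequences non-empty.
#'
#' @param path FASTA file.
#' @param permissive map non-ACGTN characters to N instead of failing.
#' @return a \code{contig_pool}; iteration order is file order.
#' @export
read_contig_pool <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate contig id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0)) stop("empty sequence for contig: ",
                                  ids[nchar(seqs) == 0][1])
  if (permissive) seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- ids
  contig_pool(seqs)
}

#' Write a contig pool to FASTA (80-column lines)
#' @param pool a \code{contig_pool}.
#' @param path output file.
#' @export
write_contig_pool <- function(pool, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(pool$seqs), path,
                              width = 80L)
  invisible(path)
}

#' Read a per-contig, per-sample depth table
#'
#' Accepts two TSV dialects, auto-detected from the header: a plain dialect
#' (\code{contigName} then one mean-depth column per sample) and the
#' MetaBAT2/jgi dialect (\code{contigName}, \code{contigLen},
#' \code{totalAvgDepth}, then alternating depth and variance columns; the
#' variance columns are ignored). Every contig in the pool must appear in the
#' table (coverage is mandatory); contigs in the table that are not in the
#' pool are skipped with a warning.
#'
#' @param path TSV file with a header row; first column is the contig name.
#' @param pool a \code{contig_pool}; returned with depths attached.
#' @return the pool with \code{depths} (matrix) and \code{samples} filled in.
#' @export
read_depth_table <- function(path, pool) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2) stop("depth table needs a contig column plus depths")
  header <- colnames(tab)
  metabat <- ncol(tab) >= 3 &&
    all(c("contigLen", "totalAvgDepth") %in% header[2:3])
  if (metabat) {
    depth_cols <- seq(4, ncol(tab), by = 2)
  } else {
    depth_cols <- seq(2, ncol(tab))
  }
  samples <- header[depth_cols]
  ids <- tab[[1]]
  vals <- suppressWarnings(
    vapply(depth_cols, function(j) as.numeric(tab[[j]]), numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab))
  bad <- which(!is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-numeric depth at row ", bad[1, 1], " of ", path)
  rownames(vals) <- ids
  extra <- setdiff(ids, names(pool$seqs))
  if (length(extra)) {
    warning("skipping ", length(extra),
            " depth rows for contigs not in pool (e.g. ", extra[1], ")")
    vals <- vals[!(ids %in% extra), , drop = FALSE]
  }
  colnames(vals) <- samples
  contig_pool(pool$seqs, depths = vals, samples = samples)
}

#' Write a depth table (plain dialect)
#' @param pool a \code{contig_pool} with depths attached.
#' @param path output TSV.
#' @export
write_depth_table <- function(pool, path) {
  stopifnot(!is.null(pool$depths))
  df <- data.frame(contigName = rownames(pool$depths),
                   pool$depths, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a bin set
#'
#' @param bins named list; each element is a character vector of contig ids
#'   (unique within the bin, all resolvable in the pool when one is given).
#' @param name label for the set.
#' @param stage one of \code{initial, hybrid, selected, refined, gapfilled}.
#' @param sources optional named character vector of provenance tags.
#' @param pool optional \code{contig_pool} used to validate membership.
#' @return an object of class \code{bin_set}.
#' @export
bin_set <- function(bins, name = "binset", stage = "initial",
                    sources = NULL, pool = NULL) {
  stage <- match.arg(stage,
                     c("initial", "hybrid", "selected", "refined", "gapfilled"))
  if (length(bins) && (is.null(names(bins)) || anyDuplicated(names(bins))))
    stop("bin ids must be unique and non-empty")
  for (b in names(bins)) {
    ids <- bins[[b]]
    if (!length(ids)) stop("bin ", b, " is empty")
    if (anyDuplicated(ids)) stop("duplicate contig id in bin ", b)
    if (!is.null(pool)) {
      miss <- setdiff(ids, names(pool$seqs))
      if (length(miss)) stop("bin ", b, " references unknown contig: ", miss[1])
    }
  }
  if (is.null(sources)) sources <- setNames(rep(stage, length(bins)),
                                            names(bins))
  structure(list(name = name, stage = stage, bins = bins, sources = sources),
            class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("bin_set '%s' (stage %s): %d bins, %d contigs\n", x$name,
              x$stage, length(x$bins), length(unlist(x$bins, use.names = FALSE))))
  invisible(x)
}

#' @export
length.bin_set <- function(x) length(x$bins)

#' Read a bin set from a directory of FASTA files
#'
#' One bin per file (\code{.fa}, \code{.fasta} or \code{.fna}); the bin id is
#' the file stem. Every record id must exist in the pool — bins must
#' reference the shared assembly. Empty files are skipped with a warning.
#'
#' @param dir directory containing at least one FASTA file.
#' @param pool the shared \code{contig_pool}.
#' @param name,stage passed to \code{\link{bin_set}}.
#' @return a \code{bin_set}.
#' @export
read_binset <- function(dir, pool, name = basename(dir), stage = "initial") {
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta|fna)$",
                           full.names = TRUE))
  if (!length(files)) stop("no FASTA files in ", dir)
  bins <- list()
  for (f in files) {
    ss <- Biostrings::readBStringSet(f)
    if (length(ss) == 0) { warning("skipping empty bin file: ", f); next }
    ids <- sub("\\s.*$", "", names(ss))
    miss <- setdiff(ids, names(pool$seqs))
    if (length(miss))
      stop("bin ", basename(f), " references contig not in pool: ", miss[1])
    bins[[sub("\\.(fa|fasta|fna)$", "", basename(f))]] <- ids
  }
  bin_set(bins, name = name, stage = stage, pool = pool)
}

#' Write a bin set to a directory of FASTA files
#'
#' Writes one FASTA per bin (records in sorted id order, 80-column lines) and
#' a \code{manifest.tsv} with columns \code{bin_id, n_contigs, total_bp,
#' stage}. Output is byte-stable across runs.
#'
#' @param binset a \code{bin_set}.
#' @param pool the \code{contig_pool} providing the sequences.
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @export
write_binset <- function(binset, pool, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("directory not empty (use overwrite = TRUE): ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(binset$bins), function(b) {
    ids <- sort(binset$bins[[b]])
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(pool$seqs[ids]),
      file.path(dir, paste0(b, ".fa")), width = 80L)
    data.frame(bin_id = b, n_contigs = length(ids),
               total_bp = sum(nchar(pool$seqs[ids])), stage = binset$stage)
  })
  manifest <- do.call(rbind, rows)
  if (is.null(manifest))
    manifest <- data.frame(bin_id = character(), n_contigs = integer(),
                           total_bp = integer(), stage = character())
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a contig-contig link table
#'
#' TSV with header \code{contig_a<TAB>contig_b<TAB>support}; \code{support}
#' is a positive integer count of read pairs or long reads spanning the two
#' contigs. Lookup is symmetric: \code{(a, b)} and \code{(b, a)} are the same
#' link. Rows are canonicalized so that \code{contig_a < contig_b}; duplicate
#' records of the same pair have their support summed.
#'
#' @param path TSV file.
#' @return a \code{link_table} (data.frame with class attribute).
#' @export
read_link_table <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "integer"))
  if (!identical(colnames(tab), c("contig_a", "contig_b", "support")))
    stop("link table header must be contig_a, contig_b, support")
  link_table(tab$contig_a, tab$contig_b, tab$support)
}

#' Construct a link table
#' @param contig_a,contig_b contig id vectors (pairwise distinct).
#' @param support positive integer counts.
#' @return a \code{link_table}.
#' @export
link_table <- function(contig_a = character(), contig_b = character(),
                       support = integer()) {
  if (any(contig_a == contig_b)) stop("self-links are not allowed")
  if (length(support) && any(support < 1)) stop("support must be >= 1")
  a <- pmin(contig_a, contig_b)
  b <- pmax(contig_a, contig_b)
  df <- data.frame(contig_a = a, contig_b = b,
                   support = as.integer(support))
  if (nrow(df)) {
    agg <- stats::aggregate(support ~ contig_a + contig_b, df, sum)
    df <- agg[order(agg$contig_a, agg$contig_b), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("link_table", "data.frame")
  df
}

#' Write a link table
#' @param links a \code{link_table}.
#' @param path output TSV.
#' @export
write_link_table <- function(links, path) {
  write.table(as.data.frame(links), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Summed link support between one contig and a set of contigs
#' @param links a \code{link_table}.
#' @param id contig id.
#' @param ids target set of contig ids.
#' @return total support (integer).
#' @export
link_support <- function(links, id, ids) {
  sel <- (links$contig_a == id & links$contig_b %in% ids) |
    (links$contig_b == id & links$contig_a %in% ids)
  sum(links$support[sel])
}
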