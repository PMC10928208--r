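# Deterministic synthetic communities: per-genome order-k Markov composition
# models (perturbed from a shared base matrix so genomes carry distinct but
# realistic tetranucleotide signatures), lognormal abundances across samples,
# negative-binomial read-count noise, lognormal contig fragmentation, and
# planted defects (redundant duplicate bins, cross-genome contaminants,
# withheld contigs with link evidence) with exhaustive truth labels.

#' Specification of a synthetic community
#'
#' Defaults describe the standard benchmark conditions: 10 genomes of
#' 60-100 kb sampled from order-3 Markov chains diverged by 0.1 from a
#' shared base composition, 3 samples with lognormal genome abundances
#' (median ~30x depth) and negative-binomial read-count noise, and contigs
#' of lognormal length with a 1 kb floor (matching the pairing-threshold
#' regime).
#'
#' @param n_genomes number of genomes (>= 1).
#' @param genome_len_range genome length range in bases.
#' @param markov_order composition model order (default 3).
#' @param divergence scale of the per-genome log-normal perturbation of the
#'   shared transition matrix; 0 makes all genomes compositionally identical.
#' @param n_samples number of samples (depth-table columns).
#' @param abundance_meanlog,abundance_sdlog lognormal abundance model
#'   (mean depth scale).
#' @param depth_dispersion negative-binomial overdispersion of simulated
#'   read counts (0 = noise-free depths).
#' @param contig_meanlog,contig_sdlog lognormal contig length model.
#' @param contig_min minimum contig length (default 1000).
#' @param read_len nominal read length used to convert depth to read counts.
#' @param seed RNG seed; the same spec and seed give byte-identical output.
#' @return list of class \code{community_spec}.
#' @export
community_spec <- function(n_genomes = 10, genome_len_range = c(60000, 100000),
                           markov_order = 3, divergence = 0.1, n_samples = 3,
                           abundance_meanlog = log(30), abundance_sdlog = 0.6,
                           depth_dispersion = 0.03,
                           contig_meanlog = log(4000), contig_sdlog = 0.35,
                           contig_min = 1000, read_len = 150, seed = 1) {
  stopifnot(n_genomes >= 1, n_samples >= 1, markov_order >= 1,
            divergence >= 0, contig_min >= 1)
  if (contig_min > min(genome_len_range))
    stop("infeasible spec: minimum contig length exceeds genome length")
  structure(list(n_genomes = n_genomes, genome_len_range = genome_len_range,
                 markov_order = markov_order, divergence = divergence,
                 n_samples = n_samples,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 depth_dispersion = depth_dispersion,
                 contig_meanlog = contig_meanlog,
                 contig_sdlog = contig_sdlog, contig_min = contig_min,
                 read_len = read_len, seed = seed),
            class = "community_spec")
}

# NB read-count noise around an expected depth; dispersion 0 is noise-free.
.noisy_depth <- function(expected_depth, len, read_len, dispersion) {
  if (dispersion <= 0) return(expected_depth)
  mu <- expected_depth * len / read_len
  reads <- rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  reads * read_len / len
}

.fragment_genome <- function(len, spec) {
  cuts <- integer()
  pos <- 0L
  while (pos < len) {
    l <- max(spec$contig_min,
             round(rlnorm(1, spec$contig_meanlog, spec$contig_sdlog)))
    pos <- min(pos + l, len)
    cuts <- c(cuts, pos)
  }
  if (length(cuts) > 1 &&
      cuts[length(cuts)] - cuts[length(cuts) - 1] < spec$contig_min)
    cuts <- cuts[-(length(cuts) - 1)]
  starts <- c(1L, head(cuts, -1) + 1L)
  data.frame(start = starts, end = cuts)
}

#' Simulate a ground-truth community
#'
#' Genomes are sampled from per-genome order-k Markov chains whose
#' transition matrices are perturbed from one shared base matrix by the
#' divergence parameter, fragmented into contigs, and assigned per-sample
#' depths = genome abundance with negative-binomial read-count noise. All
#' randomness flows from the spec's single seed.
#'
#' @param spec a \code{\link{community_spec}}.
#' @return list of class \code{community}: \code{spec}, \code{references}
#'   (named genome sequences), \code{pool} (\code{contig_pool} with depths),
#'   \code{truth} (data.frame contig, genome, start, end), \code{abundance}
#'   (genome x sample matrix).
#' @export
simulate_community <- function(spec) {
  set.seed(spec$seed)
  n_ctx <- 4^spec$markov_order
  base <- matrix(rgamma(n_ctx * 4, shape = 5), nrow = n_ctx)
  base <- base / rowSums(base)
  refs <- character(spec$n_genomes)
  names(refs) <- sprintf("G%02d", seq_len(spec$n_genomes))
  trans <- vector("list", spec$n_genomes)
  for (g in seq_len(spec$n_genomes)) {
    tg <- base * exp(spec$divergence * matrix(rnorm(n_ctx * 4), nrow = n_ctx))
    trans[[g]] <- tg / rowSums(tg)
  }
  lens <- sample(spec$genome_len_range[1]:spec$genome_len_range[2],
                 spec$n_genomes, replace = TRUE)
  for (g in seq_len(spec$n_genomes))
    refs[g] <- cpp_markov_seq(lens[g], trans[[g]], spec$markov_order)
  abundance <- matrix(rlnorm(spec$n_genomes * spec$n_samples,
                             spec$abundance_meanlog, spec$abundance_sdlog),
                      nrow = spec$n_genomes,
                      dimnames = list(names(refs),
                                      sprintf("S%d", seq_len(spec$n_samples))))
  seqs <- character(); truth_rows <- list(); depth_rows <- list()
  for (g in seq_len(spec$n_genomes)) {
    gid <- names(refs)[g]
    fr <- .fragment_genome(nchar(refs[g]), spec)
    ids <- sprintf("%s_c%03d", gid, seq_len(nrow(fr)))
    seqs[ids] <- substring(refs[g], fr$start, fr$end)
    truth_rows[[g]] <- data.frame(contig = ids, genome = gid,
                                  start = fr$start, end = fr$end)
    clen <- fr$end - fr$start + 1L
    d <- vapply(seq_len(spec$n_samples), function(s)
      .noisy_depth(rep(abundance[g, s], length(ids)), clen,
                   spec$read_len, spec$depth_dispersion),
      numeric(length(ids)))
    d <- matrix(d, nrow = length(ids),
                dimnames = list(ids, colnames(abundance)))
    depth_rows[[g]] <- d
  }
  pool <- contig_pool(seqs, depths = do.call(rbind, depth_rows))
  structure(list(spec = spec, references = refs, pool = pool,
                 truth = do.call(rbind, truth_rows), abundance = abundance),
            class = "community")
}

#' Plant defects into a truth community
#'
#' Builds the perfect per-genome bins, then plants the scenarios the
#' selection and refinement statistics must resolve:
#' \itemize{
#'   \item \emph{redundant duplicate bins} — a fraction of bins is copied
#'     (emulating the same genome binned from a second assembly): 10-30\% of
#'     the copy's contigs are dropped and its contigs are re-issued under new
#'     ids with depths re-drawn at a coverage scale factor sampled from
#'     \code{coverage_scale_range};
#'   \item \emph{contaminants} — a fraction of each bin's contigs is swapped
#'     in from other genomes;
#'   \item \emph{withheld contigs} — a fraction of each bin's contigs is
#'     moved to the un-binned pool;
#'   \item \emph{links} — genome-adjacent contig pairs receive read-link
#'     support drawn depth-proportionally (Poisson, floored at 1), plus a
#'     configurable rate of false cross-genome links.
#' }
#' Defect labels are exhaustive and exclusive.
#'
#' @param community output of \code{\link{simulate_community}}.
#' @param redundancy_rate fraction of bins to duplicate.
#' @param contamination_rate fraction of foreign contigs planted per bin.
#' @param withheld_rate fraction of contigs withheld per bin.
#' @param coverage_scale_range range of the duplicate coverage scale factor.
#' @param false_link_rate false cross-genome links as a fraction of true
#'   links.
#' @param link_depth_div divisor converting mean depth to expected link
#'   support (default 5).
#' @return list of class \code{planted_community}: \code{pool} (augmented),
#'   \code{bins} (\code{bin_set}, stage initial), \code{unbinned},
#'   \code{links} (\code{link_table}), \code{labels} (list:
#'   \code{redundant_bins}, \code{contaminants}, \code{withheld}),
#'   \code{community}.
#' @export
plant_defects <- function(community, redundancy_rate = 0,
                          contamination_rate = 0, withheld_rate = 0,
                          coverage_scale_range = c(0.5, 2),
                          false_link_rate = 0.02, link_depth_div = 5) {
  stopifnot(redundancy_rate >= 0, redundancy_rate <= 1,
            contamination_rate >= 0, contamination_rate <= 1,
            withheld_rate >= 0, withheld_rate <= 1)
  spec <- community$spec
  set.seed(spec$seed + 1L)
  truth <- community$truth
  bins <- split(truth$contig, truth$genome)
  bins <- bins[sort(names(bins))]
  seqs <- community$pool$seqs
  depths <- community$pool$depths
  # duplicates
  n_dup <- round(redundancy_rate * length(bins))
  dup_rows <- list()
  if (n_dup > 0) {
    dup_genomes <- sort(sample(names(bins), n_dup))
    for (g in dup_genomes) {
      ids <- bins[[g]]
      drop_frac <- runif(1, 0.1, 0.3)
      keep <- sort(sample(ids, max(1, length(ids) -
                                     round(drop_frac * length(ids)))))
      scale <- runif(1, coverage_scale_range[1], coverage_scale_range[2])
      new_ids <- paste0(keep, "_r")
      seqs[new_ids] <- seqs[keep]
      clen <- nchar(seqs[keep])
      d <- vapply(seq_len(spec$n_samples), function(s)
        .noisy_depth(rep(scale * community$abundance[g, s], length(keep)),
                     clen, spec$read_len, spec$depth_dispersion),
        numeric(length(keep)))
      d <- matrix(d, nrow = length(keep),
                  dimnames = list(new_ids, colnames(depths)))
      depths <- rbind(depths, d)
      bins[[paste0(g, "_dup")]] <- new_ids
      dup_rows[[g]] <- data.frame(bin = paste0(g, "_dup"), source_bin = g,
                                  scale = scale)
    }
  }
  # contaminants: swap contigs across genomes
  cont_rows <- list()
  genome_ids <- grep("_dup$", names(bins), invert = TRUE, value = TRUE)
  if (contamination_rate > 0) {
    moved <- character()
    for (g in genome_ids) {
      n_cont <- ceiling(contamination_rate * length(bins[[g]]))
      donors <- setdiff(unlist(bins[setdiff(genome_ids, g)],
                               use.names = FALSE), moved)
      pick <- sort(sample(donors, min(n_cont, length(donors))))
      moved <- c(moved, pick)
      from <- truth$genome[match(pick, truth$contig)]
      for (i in seq_along(pick))
        bins[[from[i]]] <- setdiff(bins[[from[i]]], pick[i])
      bins[[g]] <- c(bins[[g]], pick)
      if (length(pick))
        cont_rows[[g]] <- data.frame(contig = pick, from = from, to = g)
    }
  }
  # withheld contigs
  wh_rows <- list(); unbinned <- character()
  if (withheld_rate > 0) {
    for (g in genome_ids) {
      native <- intersect(bins[[g]], truth$contig[truth$genome == g])
      n_wh <- round(withheld_rate * length(native))
      if (n_wh < 1) next
      pick <- sort(sample(native, n_wh))
      bins[[g]] <- setdiff(bins[[g]], pick)
      unbinned <- c(unbinned, pick)
      wh_rows[[g]] <- data.frame(contig = pick, genome = g)
    }
  }
  # links between genome-adjacent contigs
  pool <- contig_pool(seqs, depths = depths)
  la <- character(); lb <- character(); ls <- integer()
  for (g in genome_ids) {
    ids <- truth$contig[truth$genome == g]
    if (length(ids) < 2) next
    for (i in seq_len(length(ids) - 1)) {
      md <- mean(contig_mean_depth(pool, ids[i:(i + 1)]))
      la <- c(la, ids[i]); lb <- c(lb, ids[i + 1])
      ls <- c(ls, max(1L, rpois(1, md / link_depth_div)))
    }
  }
  n_false <- if (length(genome_ids) < 2) 0L
    else round(false_link_rate * length(ls))
  if (n_false > 0) {
    for (i in seq_len(n_false)) {
      gs <- sample(genome_ids, 2)
      a <- sample(truth$contig[truth$genome == gs[1]], 1)
      b <- sample(truth$contig[truth$genome == gs[2]], 1)
      la <- c(la, a); lb <- c(lb, b); ls <- c(ls, 1L + rpois(1, 0.5))
    }
  }
  labels <- list(
    redundant_bins = if (length(dup_rows)) do.call(rbind, dup_rows)
      else data.frame(bin = character(), source_bin = character(),
                      scale = numeric()),
    contaminants = if (length(cont_rows)) do.call(rbind, cont_rows)
      else data.frame(contig = character(), from = character(),
                      to = character()),
    withheld = if (length(wh_rows)) do.call(rbind, wh_rows)
      else data.frame(contig = character(), genome = character()))
  for (nm in names(labels)) rownames(labels[[nm]]) <- NULL
  structure(list(
    pool = pool,
    bins = bin_set(bins[order(names(bins))], name = "truth",
                   stage = "initial", pool = pool),
    unbinned = sort(unbinned),
    links = link_table(la, lb, ls),
    labels = labels, community = community),
    class = "planted_community")
}

#' Build one of the standard benchmark fixtures
#'
#' The four named fixtures referenced throughout the test-suite, each fully
#' determined by \code{seed}:
#' \describe{
#'   \item{redundancy40}{20 genomes, every bin duplicated with a rescaled
#'     coverage (20 labeled redundant pairs), plus 20 labeled distinct
#'     cross-genome pairs.}
#'   \item{contamination10x5}{10 genomes, 3 samples, 5\% planted foreign
#'     contigs per bin.}
#'   \item{retrieval10}{10 genomes, 10\% of each bin's contigs withheld to
#'     the un-binned pool, with simulated links.}
#'   \item{gapfill5}{one genome split into 5 contigs separated by 100 bp
#'     gaps, with 3 donors spanning gap junctions at 400 bp flanks, plus the
#'     full genome as evaluation reference.}
#' }
#'
#' @param name fixture name (see above).
#' @param dir optional output directory; when given, the fixture artifacts
#'   (FASTA, depth/link/label TSVs) are written there.
#' @param seed RNG seed (default 1).
#' @return the fixture as a list (contents differ per fixture; all include
#'   \code{pool} and truth labels).
#' @export
make_benchmark <- function(name, dir = NULL, seed = 1) {
  known <- c("redundancy40", "contamination10x5", "retrieval10", "gapfill5")
  if (!name %in% known)
    stop("unknown benchmark '", name, "'; options: ",
         paste(known, collapse = ", "))
  fx <- switch(name,
    redundancy40 = {
      spec <- community_spec(n_genomes = 20,
                             genome_len_range = c(30000, 50000), seed = seed)
      com <- simulate_community(spec)
      pc <- plant_defects(com, redundancy_rate = 1)
      gids <- sprintf("G%02d", 1:20)
      pairs <- rbind(
        data.frame(bin_a = paste0(pc$labels$redundant_bins$bin),
                   bin_b = pc$labels$redundant_bins$source_bin,
                   redundant = TRUE),
        data.frame(bin_a = gids, bin_b = gids[c(2:20, 1)],
                   redundant = FALSE))
      list(name = name, pool = pc$pool, bins = pc$bins, pairs = pairs,
           labels = pc$labels, community = com)
    },
    contamination10x5 = {
      com <- simulate_community(community_spec(seed = seed))
      pc <- plant_defects(com, contamination_rate = 0.05)
      c(list(name = name), pc)
    },
    retrieval10 = {
      com <- simulate_community(community_spec(seed = seed))
      pc <- plant_defects(com, withheld_rate = 0.10)
      c(list(name = name), pc)
    },
    gapfill5 = {
      set.seed(seed)
      n_ctx <- 4^3
      base <- matrix(rgamma(n_ctx * 4, shape = 5), nrow = n_ctx)
      base <- base / rowSums(base)
      genome <- cpp_markov_seq(30000L, base, 3L)
      gap <- 100L; n <- 5L
      seg <- (30000L - (n - 1L) * gap) %/% n
      starts <- 1L + (seq_len(n) - 1L) * (seg + gap)
      ends <- starts + seg - 1L
      ends[n] <- 30000L
      cids <- sprintf("T_c%d", seq_len(n))
      seqs <- setNames(substring(genome, starts, ends), cids)
      junctions <- c(1L, 2L, 4L)
      dids <- sprintf("donor_%d", junctions)
      dseqs <- setNames(substring(genome, ends[junctions] - 399L,
                                  starts[junctions + 1L] + 399L), dids)
      all_seqs <- c(seqs, dseqs)
      depths <- matrix(20, nrow = length(all_seqs), ncol = 3,
                       dimnames = list(names(all_seqs), paste0("S", 1:3)))
      pool <- contig_pool(all_seqs, depths = depths)
      bins <- bin_set(list(T1 = cids), name = "gapfill5", stage = "refined",
                      pool = pool)
      archive <- bin_set(list(donors = dids), name = "archive",
                         stage = "selected", pool = pool)
      list(name = name, pool = pool, bins = bins, archive = archive,
           archive_groups = list(donors = "T1"),
           references = c(refG = genome),
           truth = data.frame(contig = cids, start = starts, end = ends),
           donor_ids = dids)
    })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_contig_pool(fx$pool, file.path(dir, "contigs.fasta"))
    write_depth_table(fx$pool, file.path(dir, "depth.tsv"))
    if (!is.null(fx$bins))
      write_binset(fx$bins, fx$pool, file.path(dir, "bins"),
                   overwrite = TRUE)
    if (!is.null(fx$archive) && length(fx$archive$bins))
      write_binset(fx$archive, fx$pool, file.path(dir, "archive"),
                   overwrite = TRUE)
    if (!is.null(fx$links))
      write_link_table(fx$links, file.path(dir, "links.tsv"))
    if (!is.null(fx$references))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(fx$references),
        file.path(dir, "references.fasta"), width = 80L)
    if (!is.null(fx$pairs))
      write.table(fx$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(fx$labels))
      for (nm in names(fx$labels))
        write.table(fx$labels[[nm]], file.path(dir, paste0(nm, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
  }
  fx
}
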