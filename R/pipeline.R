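# Checkpointed orchestration of select -> refine -> gapfill -> eval. Every
# stage writes its bin set (plus logs) under the work directory together
# with a checkpoint record (content hashes + config snapshot); a rerun with
# the same config resumes from the last valid checkpoint and reproduces the
# remaining stages byte-identically. A config that drifted from the recorded
# snapshot refuses to resume unless force = TRUE.

.default_params <- function() {
  list(merge_threshold = 0.8, ani_min = 99, af_min = 50, k_select = 0,
       mode = "threshold", w = 5, operative_k = 2, min_bin_bp = 50000,
       min_support = 3, round1_overlap = 300, round2_overlap = 500,
       min_identity = 99)
}

.read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("contigs", "depth", "bins", "workdir"))
    if (is.null(config[[f]]))
      stop("config error: missing mandatory field '", f, "'")
  params <- .default_params()
  for (nm in names(config$params)) params[[nm]] <- config$params[[nm]]
  config$params <- params
  config
}

.checkpoint_path <- function(workdir) file.path(workdir, "checkpoint.yaml")

.read_checkpoint <- function(workdir) {
  p <- .checkpoint_path(workdir)
  if (file.exists(p)) yaml::read_yaml(p) else list(stages = list())
}

.stage_hash <- function(workdir, stage) {
  manifest <- file.path(workdir, stage, "manifest.tsv")
  if (!file.exists(manifest)) return(NA_character_)
  unname(tools::md5sum(manifest))
}

.write_checkpoint <- function(workdir, ckpt) {
  yaml::write_yaml(ckpt, .checkpoint_path(workdir))
}

# Canonicalize through a YAML round trip so the snapshot compares stably
# with what a checkpoint file read back in would contain.
.config_snapshot <- function(config) {
  config$force <- NULL
  yaml::yaml.load(yaml::as.yaml(config))
}

#' Run the full post-binning pipeline
#'
#' Executes hybrid merging, bin selection, refinement and gap filling (and,
#' when reference genomes are configured, evaluation) as one checkpointed
#' run. The config is a YAML file or list with fields \code{bins} (one or
#' more bin directories), \code{contigs} (FASTA), \code{depth} (TSV),
#' \code{workdir}, optional \code{links} (TSV), \code{refs} (FASTA of
#' reference genomes), \code{permissive}, \code{force}, and a \code{params}
#' block overriding any of: merge_threshold, ani_min, af_min, k_select,
#' mode, w, operative_k, min_bin_bp, min_support, round1_overlap,
#' round2_overlap, min_identity.
#'
#' Each stage writes its bin set and decision logs under
#' \code{workdir/<stage>/}; \code{workdir/checkpoint.yaml} records content
#' hashes and the config snapshot. On rerun, stages with valid checkpoints
#' are loaded instead of recomputed; a changed config refuses to resume
#' unless \code{force} is set.
#'
#' @param config YAML path or list (see above).
#' @return list: \code{binset} (final \code{bin_set}), \code{pool}
#'   (possibly augmented by gap filling), \code{reports} (evaluation
#'   data.frame or NULL), \code{logs} (per-stage logs), \code{workdir}.
#' @export
run_pipeline <- function(config) {
  config <- .read_config(config)
  p <- config$params
  workdir <- config$workdir
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  ckpt <- .read_checkpoint(workdir)
  snap <- .config_snapshot(config)
  if (length(ckpt$stages) && !isTRUE(config$force) &&
      !identical(yaml::as.yaml(ckpt$config), yaml::as.yaml(snap))) {
    old <- unlist(ckpt$config); new <- unlist(snap)
    keys <- union(names(old), names(new))
    drift <- keys[vapply(keys, function(k)
      !identical(unname(old[k]), unname(new[k])), logical(1))]
    stop("config drift since checkpoint (",
         paste(unique(drift), collapse = ", "),
         "); rerun with force: true to discard checkpoints")
  }
  logs <- list()
  message("[corebin] loading inputs")
  pool <- read_contig_pool(config$contigs,
                           permissive = isTRUE(config$permissive))
  pool <- read_depth_table(config$depth, pool)
  binsets <- lapply(config$bins, function(d) read_binset(d, pool))
  links <- if (!is.null(config$links)) read_link_table(config$links)
    else link_table()
  refs <- if (!is.null(config$refs))
    setNames(as.character(Biostrings::readDNAStringSet(config$refs)),
             sub("\\s.*$", "", names(Biostrings::readDNAStringSet(config$refs))))
  else NULL

  valid <- function(stage) {
    h <- ckpt$stages[[stage]]
    !is.null(h) && identical(h, .stage_hash(workdir, stage))
  }
  save_stage <- function(stage, binset) {
    write_binset(binset, pool, file.path(workdir, stage), overwrite = TRUE)
    ckpt$stages[[stage]] <<- .stage_hash(workdir, stage)
    ckpt$config <<- snap
    .write_checkpoint(workdir, ckpt)
  }

  # stage: selected (hybrid merge + grouping + redundancy removal)
  if (valid("selected") && valid("archive")) {
    message("[corebin] resuming from checkpoint: selected")
    selected <- read_binset(file.path(workdir, "selected"), pool,
                            stage = "selected")
    archive <- read_binset(file.path(workdir, "archive"), pool,
                           stage = "selected")
    archive_groups <- yaml::read_yaml(file.path(workdir,
                                                "archive_groups.yaml"))
    archive_groups <- lapply(archive_groups, as.character)
  } else {
    message("[corebin] stage select: merging and dereplicating bins")
    hybrid <- merge_hybrid_bins(binsets, pool,
                                threshold = p$merge_threshold)
    groups <- group_bins(hybrid, pool, ani_min = p$ani_min,
                         af_min = p$af_min)
    sel <- select_nonredundant(hybrid, pool, groups, mode = p$mode,
                               w = p$w, k = p$k_select)
    selected <- sel$selected; archive <- sel$archive
    archive_groups <- sel$archive_groups
    write.table(sel$decisions, file.path(workdir, "select_decisions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(lapply(archive_groups, as.list),
                     file.path(workdir, "archive_groups.yaml"))
    save_stage("archive", archive)
    save_stage("selected", selected)
    logs$select <- sel$decisions
  }

  # stage: refined (outlier removal + retrieval)
  if (valid("refined")) {
    message("[corebin] resuming from checkpoint: refined")
    refined <- read_binset(file.path(workdir, "refined"), pool,
                           stage = "refined")
    unbinned <- readLines(file.path(workdir, "unbinned.txt"))
    unbinned <- unbinned[nzchar(unbinned)]
  } else {
    message("[corebin] stage refine: outlier removal and retrieval")
    verdicts <- lapply(selected$bins, multidim_iqr_outliers, pool = pool,
                       operative_k = p$operative_k)
    odb <- remove_outliers(selected, verdicts, pool,
                           min_bin_bp = p$min_bin_bp)
    unbinned0 <- setdiff(names(pool$seqs),
                         c(unlist(odb$binset$bins, use.names = FALSE),
                           unlist(archive$bins, use.names = FALSE)))
    ret <- retrieve_sequences(odb$binset, sort(unique(c(odb$unbinned,
                                                        unbinned0))),
                              pool, links, min_support = p$min_support,
                              k = p$operative_k, w = p$w)
    refined <- ret$binset; unbinned <- ret$unbinned
    writeLines(unbinned, file.path(workdir, "unbinned.txt"))
    write.table(ret$log, file.path(workdir, "retrieval_log.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    save_stage("refined", refined)
    logs$retrieval <- ret$log
  }

  # stage: gapfilled
  if (valid("gapfilled")) {
    message("[corebin] resuming from checkpoint: gapfilled")
    pool2 <- read_contig_pool(file.path(workdir, "contigs_gapfilled.fasta"))
    pool2 <- read_depth_table(file.path(workdir, "depth_gapfilled.tsv"),
                              pool2)
    gapfilled <- read_binset(file.path(workdir, "gapfilled"), pool2,
                             stage = "gapfilled")
  } else {
    message("[corebin] stage gapfill: restrained overlap-layout-consensus")
    gf <- gap_fill(refined, archive, archive_groups, pool,
                   unbinned = unbinned, round1_overlap = p$round1_overlap,
                   round2_overlap = p$round2_overlap,
                   min_identity = p$min_identity, k = p$operative_k,
                   w = p$w)
    gapfilled <- gf$binset; pool2 <- gf$pool
    write_contig_pool(pool2, file.path(workdir, "contigs_gapfilled.fasta"))
    write_depth_table(pool2, file.path(workdir, "depth_gapfilled.tsv"))
    write.table(gf$events, file.path(workdir, "gapfill_events.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    # save_stage writes with the augmented pool
    write_binset(gapfilled, pool2, file.path(workdir, "gapfilled"),
                 overwrite = TRUE)
    ckpt$stages[["gapfilled"]] <- .stage_hash(workdir, "gapfilled")
    ckpt$config <- snap
    .write_checkpoint(workdir, ckpt)
    logs$gapfill <- gf$events
  }

  reports <- NULL
  if (!is.null(refs)) {
    message("[corebin] stage eval: scoring bins against references")
    reports <- evaluate_binset(gapfilled, pool2, refs)
    write.table(reports, file.path(workdir, "quality_reports.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  message("[corebin] done: ", length(gapfilled$bins), " bins")
  list(binset = gapfilled, pool = pool2, reports = reports, logs = logs,
       workdir = workdir)
}
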