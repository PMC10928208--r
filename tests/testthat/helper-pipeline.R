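# write a planted community to disk in the pipeline's input formats
write_community_inputs <- function(pc, dir, refs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_contig_pool(pc$pool, file.path(dir, "contigs.fasta"))
  write_depth_table(pc$pool, file.path(dir, "depth.tsv"))
  write_binset(pc$bins, pc$pool, file.path(dir, "bins"), overwrite = TRUE)
  write_link_table(pc$links, file.path(dir, "links.tsv"))
  if (!is.null(refs))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs),
                                file.path(dir, "refs.fasta"), width = 80L)
  list(contigs = file.path(dir, "contigs.fasta"),
       depth = file.path(dir, "depth.tsv"),
       bins = list(file.path(dir, "bins")),
       links = file.path(dir, "links.tsv"),
       refs = if (!is.null(refs)) file.path(dir, "refs.fasta") else NULL)
}

# hash every file of a stage directory, for byte-identity comparisons
stage_digest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  setNames(unname(tools::md5sum(files)), basename(files))
}
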