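# Shared fixtures built in code.

# engineered curated reference is deterministic; build once per test run
curated_ref <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- curated_reference()
    ref
  }
})

# a one-row pileup data.frame
pileup_row <- function(pos, strand, nA = 0, nC = 0, nG = 0, nT = 0,
                       sample = "s1", library = "total") {
  data.frame(sample = sample, library = library, pos = pos, strand = strand,
             nA = nA, nC = nC, nG = nG, nT = nT)
}

# quick config for fast, clean simulations (one experiment, no artifacts
# unless switched back on)
clean_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, genome_length = 9000L, n_genes = 3L,
               samples = "s1", strategies = "total",
               coverage = c(total = 500), rrna_boost = c(total = 1),
               n_edits = 12L, carryover_rate = 0, n_rrna_sites = 0L,
               junction_per_boundary = 0L, junction_rate = 0,
               base_error = 0, intergenic_depth = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# write a small FASTA file
write_fasta_lines <- function(seqs, path) {
  lines <- unlist(mapply(function(nm, s) c(paste0(">", nm), s),
                         names(seqs), seqs, SIMPLIFY = FALSE))
  writeLines(lines, path)
  path
}
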