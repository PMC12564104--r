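# Pipeline orchestration and command-line interface: simulate | call |
# filter | annotate | merge | report | run-all over files, with a
# machine-readable JSON run summary and stage-count reconciliation.

#' Run the full editing-discovery pipeline
#'
#' Calls candidates from strand-specific pileups, classifies artifacts,
#' builds the site x experiment matrix, derives the high-confidence set and
#' annotates it at codon level. Inputs are in-memory objects; see
#' [plastedit_cli()] for the file-based interface.
#'
#' @param genome A `plastome`.
#' @param features A `plastid_features` table.
#' @param pileups Pileup data.frame (validated on entry).
#' @param map Optional `coord_map` for cross-sample harmonization.
#' @param min_var_reads,min_vaf Calling thresholds (defaults 3, 0.10).
#' @param junction_window,max_opposite_ratio,max_discordance Artifact
#'   thresholds (defaults 10, 0.10, 0.10).
#' @param min_detected,corroborate High-confidence thresholds (defaults 2,
#'   TRUE).
#' @param out_dir Optional directory; when given, calls, classified calls,
#'   matrix, high-confidence sites, annotated sites, summaries and a JSON
#'   run summary are written there.
#' @param verbose Emit stage-count messages (default TRUE).
#' @return list with `calls`, `classified`, `matrix`, `high_confidence`,
#'   `annotated`, `gene_summary`, `aa_summary`, `spectrum`,
#'   `strategy_comparison`, `summary` (the stage-count list).
#' @export
run_pipeline <- function(genome, features, pileups, map = NULL,
                         min_var_reads = 3L, min_vaf = 0.10,
                         junction_window = 10L, max_opposite_ratio = 0.10,
                         max_discordance = 0.10, min_detected = 2L,
                         corroborate = TRUE, out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  pileups <- validate_pileup(pileups)
  say("pileup records: %d", nrow(pileups))
  calls <- call_candidates(pileups, genome, min_var_reads = min_var_reads,
                           min_vaf = min_vaf)
  say("candidate variants: %d", nrow(calls))
  classified <- filter_artifacts(calls, features, pileups, genome,
                                 junction_window = junction_window,
                                 max_opposite_ratio = max_opposite_ratio,
                                 max_discordance = max_discordance)
  called <- classified[classified$called %in% TRUE, , drop = FALSE]
  flag_any <- Reduce(`|`, lapply(FLAG_COLS, function(f) called[[f]]))
  say("classified: %d called (%d flagged, %d unflagged) + %d sub-threshold",
      nrow(called), sum(flag_any), sum(!flag_any),
      nrow(classified) - nrow(called))
  spectrum <- rrna_partition(called, features)$spectrum
  sm <- build_site_matrix(classified, pileups, genome, map = map)
  say("distinct sites in matrix: %d across %d experiments",
      nrow(sm$sites), nrow(sm$experiments))
  hc <- derive_high_confidence(sm, features, min_detected = min_detected,
                               corroborate = corroborate)
  say("high-confidence sites: %d", nrow(hc))
  # annotate using per-experiment evidence of high-confidence sites
  col_of <- if (is.null(map)) called$pos else
    mapply(function(s, p) pos_to_column(map, s, p), called$sample, called$pos)
  site_key <- paste0("c", col_of, called$strand, ":", called$ref, ">",
                     called$alt)
  hc_calls <- called[site_key %in% hc$site_id, , drop = FALSE]
  annotated <- if (nrow(hc_calls)) {
    annotate_sites(hc_calls, features, genome)
  } else {
    annotate_sites(data.frame(pos = integer(0), strand = character(0),
                              ref = character(0), alt = character(0)),
                   features, genome)
  }
  gene_summary <- summarize_genes(annotated)
  aa_summary <- summarize_amino_acids(annotated)
  strat <- compare_strategies(sm, hc$site_id, classified, features)
  counts <- list(
    n_pileup_records = nrow(pileups),
    n_candidates = nrow(calls),
    n_called = nrow(called),
    n_flagged = sum(flag_any),
    n_unflagged = sum(!flag_any),
    n_flagged_by_class = as.list(colSums(called[FLAG_COLS])),
    n_sub_threshold_records = nrow(classified) - nrow(called),
    n_sites = nrow(sm$sites),
    n_high_confidence = nrow(hc),
    thresholds = list(min_var_reads = min_var_reads, min_vaf = min_vaf,
                      junction_window = junction_window,
                      max_opposite_ratio = max_opposite_ratio,
                      max_discordance = max_discordance,
                      min_detected = min_detected))
  stopifnot(counts$n_called == counts$n_flagged + counts$n_unflagged)
  res <- list(calls = calls, classified = classified, matrix = sm,
              high_confidence = hc, annotated = annotated,
              gene_summary = gene_summary, aa_summary = aa_summary,
              spectrum = spectrum, strategy_comparison = strat,
              summary = counts)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  cls <- res$classified
  cls$flags <- variant_flags(cls)
  w(res$calls, "calls.tsv")
  w(cls, "classified.tsv")
  w(res$matrix$cells, "site_matrix.tsv")
  w(res$high_confidence, "high_confidence.tsv")
  w(res$annotated, "annotated_sites.tsv")
  w(res$gene_summary, "gene_summary.tsv")
  w(res$spectrum, "substitution_spectrum.tsv")
  w(res$strategy_comparison, "strategy_comparison.tsv")
  ix <- intersections(res$matrix)
  w(ix$exact, "intersections.tsv")
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

cli_options <- function() {
  list(
    optparse::make_option("--genome", type = "character", default = NULL),
    optparse::make_option("--gff", type = "character", default = NULL),
    optparse::make_option("--pileup", type = "character", default = NULL,
                          help = "pileup TSV (repeatable, comma-separated)"),
    optparse::make_option("--alignment", type = "character", default = NULL),
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "YAML simulation config"),
    optparse::make_option("--min-var-reads", type = "integer", default = 3L,
                          dest = "min_var_reads"),
    optparse::make_option("--min-vaf", type = "double", default = 0.10,
                          dest = "min_vaf"),
    optparse::make_option("--junction-window", type = "integer",
                          default = 10L, dest = "junction_window"),
    optparse::make_option("--max-opposite-ratio", type = "double",
                          default = 0.10, dest = "max_opposite_ratio"),
    optparse::make_option("--max-discordance", type = "double",
                          default = 0.10, dest = "max_discordance"),
    optparse::make_option("--min-detected", type = "integer", default = 2L,
                          dest = "min_detected"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "plastedit_out"))
}

read_pileups_arg <- function(arg) {
  paths <- unlist(strsplit(arg, ","))
  do.call(rbind, lapply(paths, read_pileup))
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic dataset), `call` (candidate
#' calling), `filter` (artifact classification), `annotate` (codon
#' annotation of call TSVs or of the packaged curated set), `merge` (site x
#' experiment matrix + high-confidence set), `report` (summaries from a
#' prior run directory) and `run-all` (whole pipeline; simulates when given
#' `--config`, otherwise consumes `--genome/--gff/--pileup`). Returns the
#' exit status instead of quitting so it is callable in-process; the
#' installed `plastedit` script wraps it with `quit(status=)`.
#'
#' @param args Character vector of CLI arguments (subcommand first).
#' @return Integer exit status: 0 on success, 2 on usage/validation errors.
#' @export
plastedit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: plastedit <simulate|call|filter|annotate|merge|report|run-all>",
    "[options]")
  if (!length(args)) { message(usage); return(2L) }
  sub <- args[1L]
  if (!sub %in% c("simulate", "call", "filter", "annotate", "merge",
                  "report", "run-all")) {
    message("unknown subcommand '", sub, "'\n", usage)
    return(2L)
  }
  status <- tryCatch({
    opts <- optparse::parse_args(
      optparse::OptionParser(option_list = cli_options()),
      args = args[-1L])
    dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
    switch(sub,
      "simulate" = cli_simulate(opts),
      "call" = cli_call(opts),
      "filter" = cli_filter(opts),
      "annotate" = cli_annotate(opts),
      "merge" = cli_merge(opts),
      "report" = cli_report(opts),
      "run-all" = cli_run_all(opts))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  status
}

cli_load_inputs <- function(opts) {
  if (is.null(opts$genome) || is.null(opts$gff) || is.null(opts$pileup)) {
    stop("--genome, --gff and --pileup are required")
  }
  genome <- read_genome(opts$genome)
  features <- read_annotation(opts$gff, genome)
  pileups <- read_pileups_arg(opts$pileup)
  map <- if (!is.null(opts$alignment)) build_coordinate_map(opts$alignment)
  list(genome = genome, features = features, pileups = pileups, map = map)
}

cli_simulate <- function(opts) {
  cfg <- if (!is.null(opts$config)) read_sim_config(opts$config)
         else sim_config(seed = opts$seed)
  cfg$seed <- opts$seed
  sim <- simulate_dataset(cfg)
  write_genome(sim$genome, file.path(opts$out, "genome.fasta"))
  write_gff3(sim$features, sim$genome, file.path(opts$out, "annotation.gff3"))
  write_pileup(sim$pileups, file.path(opts$out, "pileups.tsv"))
  write_truth(sim$truth, file.path(opts$out, "truth.tsv"))
  write_truth(sim$events, file.path(opts$out, "events.tsv"))
  message("synthetic dataset written to ", opts$out)
}

cli_call <- function(opts) {
  inp <- cli_load_inputs(opts)
  calls <- call_candidates(inp$pileups, inp$genome,
                           min_var_reads = opts$min_var_reads,
                           min_vaf = opts$min_vaf)
  utils::write.table(calls, file.path(opts$out, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message(nrow(calls), " candidates written")
}

cli_filter <- function(opts) {
  inp <- cli_load_inputs(opts)
  calls <- call_candidates(inp$pileups, inp$genome,
                           min_var_reads = opts$min_var_reads,
                           min_vaf = opts$min_vaf)
  cls <- filter_artifacts(calls, inp$features, inp$pileups, inp$genome,
                          junction_window = opts$junction_window,
                          max_opposite_ratio = opts$max_opposite_ratio,
                          max_discordance = opts$max_discordance)
  cls$flags <- variant_flags(cls)
  utils::write.table(cls, file.path(opts$out, "classified.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message(nrow(cls), " classified records written")
}

cli_annotate <- function(opts) {
  if (is.null(opts$genome)) {
    # no inputs: annotate the packaged curated set on its engineered genome
    ref <- curated_reference()
    ann <- annotate_sites(ref$sites, ref$features, ref$genome)
    write_annotated(ann, file.path(opts$out, "annotated_sites.tsv"))
    gs <- summarize_genes(ann)
    utils::write.table(gs, file.path(opts$out, "gene_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message(nrow(ann), " curated sites annotated")
    return(invisible())
  }
  inp <- cli_load_inputs(opts)
  res <- run_pipeline(inp$genome, inp$features, inp$pileups, map = inp$map,
                      min_var_reads = opts$min_var_reads,
                      min_vaf = opts$min_vaf,
                      junction_window = opts$junction_window,
                      max_opposite_ratio = opts$max_opposite_ratio,
                      max_discordance = opts$max_discordance,
                      min_detected = opts$min_detected,
                      out_dir = opts$out)
  message(nrow(res$annotated), " sites annotated")
}

cli_merge <- function(opts) {
  inp <- cli_load_inputs(opts)
  res <- run_pipeline(inp$genome, inp$features, inp$pileups, map = inp$map,
                      min_var_reads = opts$min_var_reads,
                      min_vaf = opts$min_vaf,
                      min_detected = opts$min_detected,
                      out_dir = opts$out)
  message(res$summary$n_high_confidence, " high-confidence sites")
}

cli_report <- function(opts) {
  path <- file.path(opts$out, "summary.json")
  if (!file.exists(path)) stop("no summary.json under ", opts$out,
                               "; run 'run-all' or 'merge' first")
  s <- jsonlite::read_json(path)
  message(paste(sprintf("%s: %s", names(unlist(s)), unlist(s)),
                collapse = "\n"))
}

cli_run_all <- function(opts) {
  if (!is.null(opts$config) || is.null(opts$genome)) {
    cfg <- if (!is.null(opts$config)) read_sim_config(opts$config)
           else sim_config(seed = opts$seed)
    cfg$seed <- opts$seed
    sim <- simulate_dataset(cfg)
    genome <- sim$genome; features <- sim$features; pileups <- sim$pileups
    map <- NULL
    write_truth(sim$truth, file.path(opts$out, "truth.tsv"))
  } else {
    inp <- cli_load_inputs(opts)
    genome <- inp$genome; features <- inp$features
    pileups <- inp$pileups; map <- inp$map
  }
  res <- run_pipeline(genome, features, pileups, map = map,
                      min_var_reads = opts$min_var_reads,
                      min_vaf = opts$min_vaf,
                      junction_window = opts$junction_window,
                      max_opposite_ratio = opts$max_opposite_ratio,
                      max_discordance = opts$max_discordance,
                      min_detected = opts$min_detected,
                      out_dir = opts$out)
  message("pipeline outputs written to ", opts$out)
}
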