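# Cross-sample synthesis: harmonize coordinates across per-sample plastome
# assemblies via a whole-plastome alignment, build the site x experiment
# matrix with detected / sub-threshold / absent statuses, derive the
# high-confidence editing-site set, and compare library strategies.

#' Build per-sample coordinate maps from a whole-plastome alignment
#'
#' Each sample's map is the bijection between its plastome positions and the
#' columns of the multiple alignment (gap columns are unmapped). When
#' `genomes` is supplied, each degapped alignment row must equal the
#' corresponding genome sequence.
#'
#' @param alignment Path to an aligned FASTA, or a named
#'   `Biostrings::DNAStringSet`/character vector of aligned sequences.
#' @param genomes Optional named list of `plastome` objects to validate
#'   against.
#' @return Object of class `coord_map`: per sample an integer vector
#'   `pos2col` (position -> alignment column), plus the alignment length.
#' @export
build_coordinate_map <- function(alignment, genomes = NULL) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    alignment <- Biostrings::readDNAStringSet(alignment)
  }
  nms <- names(alignment)
  seqs <- stats::setNames(toupper(as.character(alignment)), nms)
  if (is.null(names(seqs)) || anyNA(names(seqs))) {
    stop("alignment sequences must be named by sample")
  }
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned sequences differ in length; not a valid alignment")
  }
  maps <- lapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1L]]
    which(chars != "-")
  })
  if (!is.null(genomes)) {
    for (nm in names(maps)) {
      if (is.null(genomes[[nm]])) next
      degapped <- gsub("-", "", seqs[[nm]])
      if (!identical(degapped, genomes[[nm]]$bases)) {
        stop("aligned sequence '", nm, "' does not match its genome")
      }
    }
  }
  structure(list(pos2col = maps, aln_length = nchar(seqs[[1L]])),
            class = "coord_map")
}

#' Map positions between alignment columns and sample coordinates
#'
#' @param map A `coord_map`.
#' @param sample Sample name.
#' @param pos Integer positions in the sample's coordinates (for
#'   `pos_to_column`) or alignment columns (for `column_to_pos`).
#' @return Integer vector; `column_to_pos` returns NA where the sample has a
#'   gap at that column.
#' @export
pos_to_column <- function(map, sample, pos) {
  v <- map$pos2col[[sample]]
  if (is.null(v)) stop("unknown sample '", sample, "' in coordinate map")
  stopifnot(all(pos >= 1L), all(pos <= length(v)))
  v[pos]
}

#' @rdname pos_to_column
#' @export
column_to_pos <- function(map, sample, pos) {
  v <- map$pos2col[[sample]]
  if (is.null(v)) stop("unknown sample '", sample, "' in coordinate map")
  out <- match(pos, v)
  as.integer(out)
}

#' Build the site x experiment matrix
#'
#' Sites are keyed by harmonized coordinate (alignment column when a
#' `coord_map` is given, plastome position otherwise), strand and
#' substitution, seeded from called variants across all experiments. Each
#' cell records `detected` (called under the thresholds), `sub_threshold`
#' (variant reads present but below a threshold), or `absent`, together with
#' the efficiency, variant reads and depth observed in that experiment.
#' Positions falling in a sample's alignment gap are `absent` with note
#' `no_counterpart`.
#'
#' @param classified Classified calls across all experiments (from
#'   [filter_artifacts()]); only `called` coding records seed sites.
#' @param pileups Validated pileups for all experiments.
#' @param genome A `plastome` (shared coordinates), or a named list of
#'   per-sample `plastome`s used with `map`.
#' @param map Optional `coord_map` for cross-sample harmonization.
#' @return Object of class `site_matrix`: list with `sites` (site-level
#'   data.frame incl. aggregated artifact flags), `cells` (long site x
#'   experiment data.frame) and `experiments`.
#' @export
build_site_matrix <- function(classified, pileups, genome, map = NULL) {
  if (is.null(pileups$depth)) pileups <- validate_pileup(pileups)
  calls <- classified[isTRUE_vec(classified$called), , drop = FALSE]
  experiments <- unique(pileups[, c("sample", "library")])
  rownames(experiments) <- NULL
  genome_for <- function(smp) if (inherits(genome, "plastome")) genome
                              else genome[[smp]]
  col_of <- function(smp, pos) {
    if (is.null(map)) pos else pos_to_column(map, smp, pos)
  }
  pos_of <- function(smp, col) {
    if (is.null(map)) col else column_to_pos(map, smp, col)
  }
  if (!nrow(calls)) {
    return(structure(list(
      sites = data.frame(), cells = data.frame(), experiments = experiments),
      class = "site_matrix"))
  }
  calls$column <- mapply(col_of, calls$sample, calls$pos)
  calls$site_id <- paste0("c", calls$column, calls$strand, ":",
                          calls$ref, ">", calls$alt)
  agg_flag <- function(flag) tapply(flag, calls$site_id, any)
  first_of <- function(x) tapply(x, calls$site_id, function(v) v[1L])
  ids <- sort(unique(calls$site_id))
  sites <- data.frame(
    site_id = ids,
    column = as.integer(first_of(calls$column)[ids]),
    strand = as.character(first_of(calls$strand)[ids]),
    ref = as.character(first_of(calls$ref)[ids]),
    alt = as.character(first_of(calls$alt)[ids]),
    substitution = as.character(first_of(calls$substitution_type)[ids]),
    region = as.character(first_of(calls$region)[ids]),
    gene = as.character(first_of(calls$gene)[ids]))
  for (fc in FLAG_COLS) {
    sites[[paste0(fc, "_any")]] <- as.logical(agg_flag(calls[[fc]])[ids])
  }
  # per-cell status
  cells <- list()
  callkey <- paste(calls$site_id, calls$sample, calls$library)
  for (e in seq_len(nrow(experiments))) {
    smp <- experiments$sample[e]; lib <- experiments$library[e]
    spos <- vapply(sites$column, function(cl) pos_of(smp, cl), integer(1))
    status <- rep("absent", nrow(sites))
    eff <- rep(0, nrow(sites)); vr <- rep(0L, nrow(sites))
    dp <- rep(0L, nrow(sites)); note <- rep("", nrow(sites))
    hit <- match(paste(sites$site_id, smp, lib), callkey)
    det <- !is.na(hit)
    status[det] <- "detected"
    eff[det] <- calls$vaf[hit[det]]
    vr[det] <- calls$var_reads[hit[det]]
    dp[det] <- calls$depth[hit[det]]
    note[is.na(spos)] <- "no_counterpart"
    todo <- which(!det & !is.na(spos))
    if (length(todo)) {
      sub <- pileups[pileups$sample == smp & pileups$library == lib, ,
                     drop = FALSE]
      if (nrow(sub)) {
        idx <- match(paste(spos[todo], sites$strand[todo]),
                     paste(sub$pos, sub$strand))
        has <- !is.na(idx)
        if (any(has)) {
          rows <- sub[idx[has], , drop = FALSE]
          effs <- editing_efficiency(rows, sites$alt[todo][has])
          m <- transcript_counts(rows)
          altn <- m[cbind(seq_len(nrow(m)),
                          match(sites$alt[todo][has], colnames(m)))]
          sel <- todo[has]
          present <- altn > 0L
          status[sel[present]] <- "sub_threshold"
          eff[sel] <- effs; vr[sel] <- altn; dp[sel] <- rows$depth
        }
      }
    }
    cells[[e]] <- data.frame(site_id = sites$site_id, sample = smp,
                             library = lib, status = status,
                             efficiency = eff, var_reads = vr, depth = dp,
                             note = note)
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  structure(list(sites = sites, cells = cells, experiments = experiments),
            class = "site_matrix")
}

isTRUE_vec <- function(x) if (is.null(x)) TRUE else x %in% TRUE

#' Wide status matrix of a `site_matrix`
#'
#' @param sm A `site_matrix`.
#' @return Character matrix sites x experiments of statuses.
#' @export
status_matrix <- function(sm) {
  exps <- paste(sm$experiments$sample, sm$experiments$library, sep = ":")
  out <- matrix("absent", nrow(sm$sites), length(exps),
                dimnames = list(sm$sites$site_id, exps))
  key <- paste(sm$cells$sample, sm$cells$library, sep = ":")
  out[cbind(match(sm$cells$site_id, sm$sites$site_id),
            match(key, exps))] <- sm$cells$status
  out
}

#' Derive the high-confidence editing-site set
#'
#' Retains sites that are canonical (C>U or U>C in transcript orientation),
#' outside rRNA regions, on the coding strand of their gene (intergenic
#' sites pass the strand test), not junction- or carryover-flagged in any
#' experiment, and detected in at least `min_detected` experiments. With
#' `corroborate = TRUE` (default) a site detected in exactly `min_detected`
#' experiments must additionally show detected or sub-threshold signal in at
#' least one further experiment, mirroring how minimally-replicated sites
#' are admitted only with corroborating sub-threshold evidence; the rule is
#' skipped when no further experiment exists.
#'
#' @param sm A `site_matrix`.
#' @param features A `plastid_features` table (for coding-strand checks).
#' @param min_detected Minimum experiments with a detected call (default 2).
#' @param corroborate Require extra evidence at the minimum (default TRUE).
#' @return The retained subset of `sm$sites`, with `n_detected` and
#'   `n_sub_threshold` columns.
#' @export
derive_high_confidence <- function(sm, features, min_detected = 2L,
                                   corroborate = TRUE) {
  sites <- sm$sites
  if (!nrow(sites)) return(sites)
  st <- status_matrix(sm)
  sites$n_detected <- rowSums(st == "detected")
  sites$n_sub_threshold <- rowSums(st == "sub_threshold")
  gene_strand <- rep(NA_character_, nrow(sites))
  known <- sites$gene != "intergenic" & !is.na(sites$gene)
  gene_strand[known] <- features$strand[match(sites$gene[known],
                                              features$gene)]
  coding <- is.na(gene_strand) | gene_strand == sites$strand
  keep <- sites$substitution %in% c("C>T", "T>C") &
    sites$region != "rRNA" & coding &
    !sites$flag_junction_any & !sites$flag_carryover_any &
    sites$n_detected >= min_detected
  if (corroborate && ncol(st) > min_detected) {
    at_min <- sites$n_detected == min_detected
    keep <- keep & (!at_min |
                    (sites$n_detected + sites$n_sub_threshold >
                     min_detected))
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact intersection counts across experiments (UpSet-style)
#'
#' Counts sites detected in exactly each subset of experiments, plus
#' per-experiment totals.
#'
#' @param sm A `site_matrix`.
#' @return list with `exact` (data.frame subset, n) and `per_set`
#'   (data.frame experiment, n). Subsets are "+"-joined experiment labels
#'   `sample:library` in experiment order.
#' @export
intersections <- function(sm) {
  st <- status_matrix(sm) == "detected"
  labels <- colnames(st)
  subset_of <- apply(st, 1L, function(r) paste(labels[r], collapse = "+"))
  subset_of <- subset_of[subset_of != ""]
  tab <- table(subset_of)
  exact <- data.frame(subset = names(tab), n = as.integer(tab))
  per_set <- data.frame(experiment = labels, n = as.integer(colSums(st)))
  list(exact = exact, per_set = per_set)
}

#' Compare library strategies against a reference site set
#'
#' For each library strategy: how many reference sites are detected in all
#' of its replicates; how many of its called variants fall in rRNA regions
#' or are noncanonical; and the tally of coding- versus noncoding-strand
#' calls (relative to the gene owning each position).
#'
#' @param sm A `site_matrix`.
#' @param reference Character vector of reference `site_id`s (e.g. from
#'   [derive_high_confidence()]).
#' @param classified Classified calls (for artifact and strand tallies).
#' @param features A `plastid_features` table.
#' @return data.frame with one row per strategy.
#' @export
compare_strategies <- function(sm, reference, classified, features) {
  st <- status_matrix(sm) == "detected"
  libs <- unique(sm$experiments$library)
  calls <- classified[isTRUE_vec(classified$called), , drop = FALSE]
  gene_strand <- feature_strand_at(features, calls$pos)
  rows <- lapply(libs, function(lib) {
    reps <- which(sm$experiments$library == lib)
    in_all <- rowSums(st[, reps, drop = FALSE]) == length(reps)
    sub <- calls[calls$library == lib, , drop = FALSE]
    gs <- gene_strand[calls$library == lib]
    data.frame(
      library = lib, n_replicates = length(reps),
      reference_in_all_replicates =
        sum(sm$sites$site_id %in% reference & in_all),
      rrna_calls = sum(sub$region == "rRNA"),
      noncanonical_calls = sum(sub$flag_noncanonical),
      coding_strand_calls = sum(!is.na(gs) & gs == sub$strand),
      noncoding_strand_calls = sum(!is.na(gs) & gs != sub$strand))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
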