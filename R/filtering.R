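# Artifact classification: the four technical artifact classes seen in
# strand-specific plastid RNA-seq — splice-junction misalignment, dUTP
# second-strand carryover, rRNA modification misincorporation, and strand
# misassignment by the caller — plus canonical-substitution and strand-
# concordance screens. Everything is a *flag*, never a deletion: final
# exclusion policy lives in the high-confidence stage, which keeps the
# filtering auditable.

FLAG_COLS <- c("flag_junction", "flag_rrna", "flag_noncanonical",
               "flag_carryover", "flag_discordant", "flag_reassigned")

# ensure context columns (region, gene, substitution_type) and flag columns
ensure_classified <- function(vs, features = NULL) {
  if (!nrow(vs)) {
    for (cc in c("region", "gene", "substitution_type", FLAG_COLS, "called")) {
      if (is.null(vs[[cc]])) {
        vs[[cc]] <- if (cc %in% c(FLAG_COLS, "called")) logical(0) else character(0)
      }
    }
    return(vs)
  }
  if ((is.null(vs$region) || is.null(vs$gene)) && !is.null(features)) {
    loc <- locate(vs$pos, features)
    vs$region <- loc$region
    vs$gene <- loc$gene
  }
  if (is.null(vs$substitution_type)) {
    vs$substitution_type <- paste0(vs$ref, ">", vs$alt)
  }
  for (fc in FLAG_COLS) if (is.null(vs[[fc]])) vs[[fc]] <- FALSE
  if (is.null(vs$called)) vs$called <- TRUE
  vs
}

# pileup rows as a lookup: transcript-orientation count of `base` on
# (sample, library, pos, strand)
pileup_base_count <- function(pileups, sample, library, pos, strand, base) {
  key <- paste(pileups$sample, pileups$library, pileups$pos, pileups$strand)
  i <- match(paste(sample, library, pos, strand), key)
  m <- transcript_counts(pileups)
  out <- integer(length(i))
  has <- !is.na(i)
  out[has] <- m[cbind(i[has], match(base[has], colnames(m)))]
  out
}

pileup_depth <- function(pileups, sample, library, pos, strand) {
  key <- paste(pileups$sample, pileups$library, pileups$pos, pileups$strand)
  i <- match(paste(sample, library, pos, strand), key)
  out <- integer(length(i))
  out[!is.na(i)] <- pileups$depth[i[!is.na(i)]]
  out
}

#' Correct strand-misassigned calls back to the coding strand
#'
#' A caller occasionally reports a C>U edit as its complementary G>A on the
#' strand opposite the gene. When a G>A call sits antisense to an annotated
#' gene whose coding strand shows the complementary C>U signal dominating in
#' the pileups (coding-strand VAF greater than the call's VAF) and no
#' coding-strand call already exists there, the event is re-expressed as
#' C>U on the coding strand with the coding-strand support, and
#' `flag_reassigned` is set. Applying the operation twice equals applying it
#' once.
#'
#' @param vs Candidate/classified variants data.frame.
#' @param features A `plastid_features` table.
#' @param pileups Validated pileup data.frame.
#' @param genome A `plastome`.
#' @return `vs` with misassigned rows rewritten and flagged.
#' @export
reassign_to_coding_strand <- function(vs, features, pileups, genome) {
  vs <- ensure_classified(vs, features)
  if (!nrow(vs)) return(vs)
  if (is.null(pileups$depth)) pileups <- validate_pileup(pileups)
  gene_strand <- feature_strand_at(features, vs$pos)
  opp <- ifelse(vs$strand == "+", "-", "+")
  cand <- which(vs$substitution_type == "G>A" & !is.na(gene_strand) &
                gene_strand == opp & !vs$flag_reassigned)
  if (!length(cand)) return(vs)
  key <- paste(vs$sample, vs$library, vs$pos, vs$strand, vs$ref, vs$alt)
  for (i in cand) {
    # existing coding-strand C>T call? leave for the carryover detector
    if (paste(vs$sample[i], vs$library[i], vs$pos[i], opp[i], "C", "T") %in% key) next
    cod_alt <- pileup_base_count(pileups, vs$sample[i], vs$library[i],
                                 vs$pos[i], opp[i], "T")
    cod_depth <- pileup_depth(pileups, vs$sample[i], vs$library[i],
                              vs$pos[i], opp[i])
    cod_ref <- strand_base(genome, vs$pos[i], opp[i])
    if (cod_ref != "C" || cod_depth == 0L) next
    cod_vaf <- cod_alt / cod_depth
    if (cod_vaf > vs$vaf[i]) {
      vs$strand[i] <- opp[i]
      vs$ref[i] <- "C"; vs$alt[i] <- "T"
      vs$substitution_type[i] <- "C>T"
      vs$var_reads[i] <- cod_alt
      vs$depth[i] <- cod_depth
      vs$vaf[i] <- cod_vaf
      vs$flag_reassigned[i] <- TRUE
    }
  }
  vs
}

# strand of the gene owning each position (NA if intergenic)
feature_strand_at <- function(features, pos) {
  loc <- locate(pos, features)
  out <- rep(NA_character_, length(pos))
  has <- !is.na(loc$gene)
  if (any(has)) {
    idx <- match(loc$gene[has], features$gene)
    out[has] <- features$strand[idx]
  }
  out
}

#' Flag variants near exon-intron boundaries
#'
#' Reads spanning splice junctions misalign readily, producing spurious
#' mismatches next to intron boundaries. Any variant within `window` bp of
#' an exon-intron boundary (either side) is flagged `flag_junction`; nothing
#' is deleted.
#'
#' @param vs Variants data.frame.
#' @param features A `plastid_features` table (introns derived).
#' @param window Distance in bp (default 10).
#' @return `vs` with `flag_junction` set.
#' @export
junction_filter <- function(vs, features, window = 10L) {
  vs <- ensure_classified(vs, features)
  if (!nrow(vs)) return(vs)
  introns <- features[features$ftype == "intron", , drop = FALSE]
  if (!nrow(introns)) return(vs)
  pts <- c(introns$start, introns$end)
  near <- vapply(vs$pos, function(p) min(abs(p - pts)) <= window, logical(1))
  vs$flag_junction <- vs$flag_junction | near
  vs
}

#' Partition variants by rRNA context and summarize substitution spectra
#'
#' Splits variants into rRNA-region and non-rRNA sets (by [locate()]
#' priority) and tabulates directed substitution types in each partition.
#' rRNA-region rows receive `flag_rrna`.
#'
#' @param vs Variants data.frame.
#' @param features A `plastid_features` table.
#' @return list with `vs` (flagged), `rrna`, `non_rrna`, and `spectrum`: a
#'   data.frame of counts per substitution type per partition.
#' @export
rrna_partition <- function(vs, features) {
  vs <- ensure_classified(vs, features)
  vs$flag_rrna <- vs$flag_rrna | vs$region == "rRNA"
  part <- ifelse(vs$region == "rRNA", "rRNA", "non_rRNA")
  spectrum <- as.data.frame(table(
    substitution_type = factor(vs$substitution_type,
                               levels = SUBSTITUTION_TYPES),
    partition = factor(part, levels = c("rRNA", "non_rRNA"))),
    responseName = "n")
  list(vs = vs,
       rrna = vs[vs$region == "rRNA", , drop = FALSE],
       non_rrna = vs[vs$region != "rRNA", , drop = FALSE],
       spectrum = spectrum)
}

#' Flag noncanonical substitutions
#'
#' Plastid editing is C>U with rare U>C; both pass (in transcript
#' orientation). Every other directed substitution is flagged
#' `flag_noncanonical`.
#'
#' @param vs Variants data.frame.
#' @return `vs` with `flag_noncanonical` set.
#' @export
canonical_filter <- function(vs) {
  vs <- ensure_classified(vs)
  vs$flag_noncanonical <- vs$flag_noncanonical |
    !(vs$substitution_type %in% c("C>T", "T>C"))
  vs
}

#' Detect dUTP second-strand carryover signals
#'
#' Incomplete degradation of the dUTP-marked second cDNA strand mirrors a
#' true coding-strand edit as the complementary substitution on the opposite
#' strand at a small fraction of its signal. An opposite-strand record is
#' flagged `flag_carryover` iff its substitution is the base-complement of a
#' coding-strand call at the same position and its VAF is at most
#' `max_opposite_ratio` times the coding-strand VAF. The coding-strand call
#' itself is never flagged by this rule. For the flag to reach sub-threshold
#' opposite-strand evidence, classify the output of
#' [augment_with_opposite()] (done automatically by [filter_artifacts()]).
#'
#' @param vs Variants data.frame (may include sub-threshold records).
#' @param features A `plastid_features` table.
#' @param max_opposite_ratio Maximum opposite/coding VAF ratio (default
#'   0.10), bracketing the observed 1/2840-1/63 carryover range.
#' @return `vs` with `flag_carryover` set.
#' @export
carryover_detector <- function(vs, features, max_opposite_ratio = 0.10) {
  vs <- ensure_classified(vs, features)
  if (!nrow(vs)) return(vs)
  gene_strand <- feature_strand_at(features, vs$pos)
  key <- paste(vs$sample, vs$library, vs$pos)
  for (i in seq_len(nrow(vs))) {
    j <- which(key == key[i] & vs$strand != vs$strand[i] &
               vs$ref == complement_base(vs$ref[i]) &
               vs$alt == complement_base(vs$alt[i]))
    if (!length(j)) next
    j <- j[1L]
    # the coding-strand member of the pair is the source, never flagged;
    # with no gene context the higher-VAF record is treated as the source
    coding_j <- if (!is.na(gene_strand[i])) gene_strand[i] == vs$strand[j]
                else vs$vaf[j] >= vs$vaf[i]
    if (coding_j && vs$vaf[j] > 0 && vs$called[j] &&
        vs$vaf[i] / vs$vaf[j] <= max_opposite_ratio) {
      vs$flag_carryover[i] <- TRUE
    }
  }
  vs
}

#' Augment calls with opposite-strand evidence at called positions
#'
#' For every called variant, reads the opposite-strand count of the
#' complementary substitution from the pileups and appends any record with
#' at least one supporting read that is not already present, marked
#' `called = FALSE`. This materializes sub-threshold carryover signals so
#' [carryover_detector()] can flag them, even when an unrelated base
#' dominates the opposite-strand non-reference counts.
#'
#' @param vs Called variants data.frame.
#' @param pileups Validated pileup data.frame.
#' @param genome A `plastome` (kept for interface symmetry; counts come from
#'   the pileups).
#' @return `vs` plus appended opposite-strand sub-threshold records.
#' @export
augment_with_opposite <- function(vs, pileups, genome = NULL) {
  if (is.null(vs$called)) vs$called <- rep(TRUE, nrow(vs))
  if (is.null(vs$substitution_type)) {
    vs$substitution_type <- paste0(vs$ref, ">", vs$alt)
  }
  for (fc in FLAG_COLS) if (is.null(vs[[fc]])) vs[[fc]] <- FALSE
  if (!nrow(vs)) return(vs)
  if (is.null(pileups$depth)) pileups <- validate_pileup(pileups)
  # the complementary substitution opposite each call, read straight from
  # the pileups so a minor carryover allele is not hidden by an unrelated
  # major alternative (e.g. a stray error base)
  opp <- ifelse(vs$strand == "+", "-", "+")
  ref2 <- complement_base(vs$ref)
  alt2 <- complement_base(vs$alt)
  var2 <- pileup_base_count(pileups, vs$sample, vs$library, vs$pos, opp, alt2)
  dep2 <- pileup_depth(pileups, vs$sample, vs$library, vs$pos, opp)
  extra <- data.frame(sample = vs$sample, library = vs$library, pos = vs$pos,
                      strand = opp, ref = ref2, alt = alt2,
                      var_reads = as.integer(var2), depth = as.integer(dep2),
                      vaf = ifelse(dep2 > 0, var2 / dep2, 0),
                      multi_allelic = FALSE)
  extra <- extra[extra$var_reads >= 1L, , drop = FALSE]
  extra <- extra[!duplicated(paste(extra$sample, extra$library, extra$pos,
                                   extra$strand, extra$ref, extra$alt)), ,
                 drop = FALSE]
  have <- paste(vs$sample, vs$library, vs$pos, vs$strand, vs$ref, vs$alt)
  extra <- extra[!(paste(extra$sample, extra$library, extra$pos, extra$strand,
                         extra$ref, extra$alt) %in% have), , drop = FALSE]
  if (!nrow(extra)) return(vs)
  extra$called <- FALSE
  extra$substitution_type <- paste0(extra$ref, ">", extra$alt)
  for (fc in FLAG_COLS) extra[[fc]] <- FALSE
  cols <- union(names(vs), names(extra))
  for (cc in setdiff(cols, names(vs))) vs[[cc]] <- NA
  for (cc in setdiff(cols, names(extra))) extra[[cc]] <- NA
  out <- rbind(vs[cols], extra[cols])
  rownames(out) <- NULL
  out
}

#' Flag strand-discordant variants
#'
#' Computes, for each variant, the fraction of variant-supporting reads
#' occurring on the opposite strand: discordance = opposite / (expected +
#' opposite) variant reads, with opposite reads counted for the same genomic
#' change. Variants exceeding `max_discordance` are flagged
#' `flag_discordant` (meaning "needs inspection", not rejection).
#'
#' @param vs Variants data.frame.
#' @param pileups Validated pileup data.frame.
#' @param max_discordance Threshold (default 0.10).
#' @return `vs` with `flag_discordant` set and a `discordance` column.
#' @export
strand_concordance <- function(vs, pileups, max_discordance = 0.10) {
  vs <- ensure_classified(vs)
  if (!nrow(vs)) { vs$discordance <- numeric(0); return(vs) }
  if (is.null(pileups$depth)) pileups <- validate_pileup(pileups)
  opp <- ifelse(vs$strand == "+", "-", "+")
  # same genomic change on the other strand = complement of alt in that
  # strand's transcript orientation
  opp_reads <- pileup_base_count(pileups, vs$sample, vs$library, vs$pos,
                                 opp, complement_base(vs$alt))
  tot <- vs$var_reads + opp_reads
  vs$discordance <- ifelse(tot > 0, opp_reads / tot, 0)
  vs$flag_discordant <- vs$flag_discordant | vs$discordance > max_discordance
  vs
}

#' Run the full artifact classification
#'
#' Applies, in order: strand reassignment, opposite-strand augmentation,
#' then the order-independent flag set (junction, rRNA partition, canonical,
#' carryover, strand concordance).
#'
#' @param vs Called variants (from [call_candidates()]).
#' @param features A `plastid_features` table.
#' @param pileups Validated pileup data.frame.
#' @param genome A `plastome`.
#' @param junction_window Junction window in bp (default 10).
#' @param max_opposite_ratio Carryover VAF ratio ceiling (default 0.10).
#' @param max_discordance Strand-discordance ceiling (default 0.10).
#' @return Classified variants data.frame with context columns and flags.
#' @export
filter_artifacts <- function(vs, features, pileups, genome,
                             junction_window = 10L,
                             max_opposite_ratio = 0.10,
                             max_discordance = 0.10) {
  if (is.null(pileups$depth)) pileups <- validate_pileup(pileups)
  vs <- ensure_classified(vs, features)
  vs <- reassign_to_coding_strand(vs, features, pileups, genome)
  vs <- augment_with_opposite(vs, pileups, genome)
  # context columns may be stale for rewritten/augmented rows
  vs$region <- NULL; vs$gene <- NULL
  vs <- ensure_classified(vs, features)
  vs <- junction_filter(vs, features, window = junction_window)
  vs <- rrna_partition(vs, features)$vs
  vs <- canonical_filter(vs)
  vs <- carryover_detector(vs, features,
                           max_opposite_ratio = max_opposite_ratio)
  vs <- strand_concordance(vs, pileups, max_discordance = max_discordance)
  vs
}

#' Flag set of classified variants as strings
#'
#' @param vs Classified variants data.frame.
#' @return Character vector like `"junction_artifact,rrna_region"`.
#' @export
variant_flags <- function(vs) {
  labels <- c(flag_junction = "junction_artifact", flag_rrna = "rrna_region",
              flag_noncanonical = "noncanonical",
              flag_carryover = "antisense_carryover",
              flag_discordant = "strand_discordant",
              flag_reassigned = "strand_reassigned")
  apply(as.matrix(vs[, names(labels)]), 1L, function(r) {
    paste(labels[which(as.logical(r))], collapse = ",")
  })
}
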