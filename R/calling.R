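# Strand-aware candidate calling from per-base pileups.
#
# Pileup dialect: a header-bearing TSV with columns sample, library, pos,
# strand, nA, nC, nG, nT. Counts are forward-orientation base counts (as
# reads appear against the plastome-forward reference); the strand column is
# the transcript strand the reads were assigned to under the dUTP/RF
# convention. Variants are always *expressed* in transcript orientation: on
# the "-" strand the reference base and the counts are complemented before
# the substitution is named.

PILEUP_COLS <- c("sample", "library", "pos", "strand", "nA", "nC", "nG", "nT")

#' Read a strand-specific pileup TSV
#'
#' @param path TSV with columns sample, library, pos, strand, nA, nC, nG, nT.
#' @return Validated data.frame with a `depth` column appended.
#' @export
read_pileup <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_pileup(df)
}

#' Validate an in-memory pileup table
#'
#' Enforces the pileup contract: required columns, known library strategy,
#' strand in {+,-}, non-negative counts, and unique
#' (sample, library, pos, strand) keys. Computes `depth`.
#'
#' @param df Pileup data.frame.
#' @return The validated data.frame with `depth`.
#' @export
validate_pileup <- function(df) {
  if (!all(PILEUP_COLS %in% names(df))) {
    stop("pileup requires columns: ", paste(PILEUP_COLS, collapse = ", "))
  }
  df <- as.data.frame(df)
  if (!all(df$strand %in% c("+", "-"))) {
    stop("pileup strand must be '+' or '-' (got: ",
         paste(setdiff(unique(df$strand), c("+", "-")), collapse = ","), ")")
  }
  if (!all(df$library %in% c("total", "rrna_depleted", "mrna"))) {
    stop("unknown library strategy: ",
         paste(setdiff(unique(df$library),
                       c("total", "rrna_depleted", "mrna")), collapse = ","))
  }
  cnts <- as.matrix(df[, c("nA", "nC", "nG", "nT")])
  if (any(cnts < 0)) stop("negative base counts in pileup")
  key <- paste(df$sample, df$library, df$pos, df$strand)
  if (anyDuplicated(key)) {
    stop("duplicate (sample, library, pos, strand) rows in pileup")
  }
  df$depth <- as.integer(rowSums(cnts))
  df
}

#' Write a pileup table as TSV
#' @param pileups Pileup data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileups, path) {
  utils::write.table(pileups[, PILEUP_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# transcript-orientation count matrix (cols A,C,G,T) for pileup rows
transcript_counts <- function(df) {
  m <- as.matrix(df[, c("nA", "nC", "nG", "nT")])
  colnames(m) <- c("A", "C", "G", "T")
  minus <- df$strand == "-"
  if (any(minus)) m[minus, ] <- m[minus, c("T", "G", "C", "A")]
  m
}

# core engine shared by strict calling and the relaxed query
query_variants <- function(pileups, genome, min_var_reads, min_vaf) {
  df <- if (is.null(pileups$depth)) validate_pileup(pileups) else pileups
  if (!nrow(df)) return(empty_calls())
  m <- transcript_counts(df)
  ref <- strand_base(genome, df$pos, df$strand)
  bases <- colnames(m)
  ref_i <- match(ref, bases)
  alt_m <- m
  alt_m[cbind(seq_len(nrow(m)), ref_i)] <- -1L  # mask reference base
  best_i <- max.col(alt_m, ties.method = "first")  # tie-break: A<C<G<T order
  var_reads <- alt_m[cbind(seq_len(nrow(m)), best_i)]
  depth <- df$depth
  vaf <- ifelse(depth > 0, var_reads / depth, 0)
  pass <- var_reads >= min_var_reads & vaf >= min_vaf & depth > 0
  # multi-allelic: a second non-reference base also clears both thresholds
  n_passing <- rowSums(alt_m >= pmax(min_var_reads, 1L) &
                       alt_m / pmax(depth, 1L) >= min_vaf)
  out <- data.frame(
    sample = df$sample, library = df$library, pos = df$pos,
    strand = df$strand, ref = ref, alt = bases[best_i],
    var_reads = as.integer(var_reads), depth = as.integer(depth),
    vaf = vaf, multi_allelic = n_passing >= 2L)
  out <- out[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(sample = character(0), library = character(0), pos = integer(0),
             strand = character(0), ref = character(0), alt = character(0),
             var_reads = integer(0), depth = integer(0), vaf = numeric(0),
             multi_allelic = logical(0))
}

#' Call candidate variants under read-support and VAF thresholds
#'
#' Per (sample, library, position, strand), the highest-count non-reference
#' base is emitted as a candidate when it is supported by at least
#' `min_var_reads` strand-specific reads and its variant allele fraction
#' (variant reads / total strand depth over all four bases) is at least
#' `min_vaf`. Multi-allelic records (a second non-reference base also
#' clearing both thresholds) report the major alternative only, with
#' `multi_allelic = TRUE`. Sub-threshold evidence is retrievable with
#' [relaxed_query()].
#'
#' @param pileups Pileup data.frame (see [read_pileup()]).
#' @param genome A `plastome`.
#' @param min_var_reads Minimum variant-supporting reads (default 3).
#' @param min_vaf Minimum variant allele fraction (default 0.10).
#' @return data.frame of candidate variants: sample, library, pos, strand,
#'   ref, alt (transcript orientation), var_reads, depth, vaf,
#'   multi_allelic.
#' @export
call_candidates <- function(pileups, genome, min_var_reads = 3L,
                            min_vaf = 0.10) {
  query_variants(pileups, genome, min_var_reads, min_vaf)
}

#' Relaxed query for sub-threshold variant evidence
#'
#' Same engine as [call_candidates()] with permissive defaults, optionally
#' restricted to positions of interest; used to report sites "present below
#' threshold" (e.g. at 5% or 9% editing frequency) in experiments where they
#' were not formally called.
#'
#' @inheritParams call_candidates
#' @param positions Optional integer vector restricting the query.
#' @param strand Optional strand restriction ("+" or "-").
#' @param min_var_reads Minimum variant reads (default 1).
#' @param min_vaf Minimum VAF (default 0).
#' @return data.frame in the [call_candidates()] layout.
#' @export
relaxed_query <- function(pileups, genome, positions = NULL, strand = NULL,
                          min_var_reads = 1L, min_vaf = 0) {
  df <- if (is.null(pileups$depth)) validate_pileup(pileups) else pileups
  if (!is.null(positions)) df <- df[df$pos %in% positions, , drop = FALSE]
  if (!is.null(strand)) df <- df[df$strand %in% strand, , drop = FALSE]
  query_variants(df, genome, min_var_reads, min_vaf)
}

#' Build strand-specific pileups from a coordinate-sorted SAM/BAM
#'
#' Convenience converter for paired-end, dUTP (RF) strand-specific
#' alignments. The transcript strand is inferred per the RF convention:
#' mate 1 aligns antisense to the transcript, mate 2 sense, so a
#' first-of-pair read on "-" contributes to the "+" pileup. Secondary,
#' supplementary and duplicate-flagged alignments are skipped and a MAPQ
#' floor (default 1) approximates "uniquely mapped".
#'
#' @param path SAM or BAM file, coordinate-sorted.
#' @param genome A `plastome`.
#' @param sample,library Labels for the emitted records.
#' @param min_mapq MAPQ floor (default 1).
#' @return Pileup data.frame in the [read_pileup()] layout.
#' @export
pileup_from_alignments <- function(path, genome, sample = "sample",
                                   library = "total", min_mapq = 1L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$text
  so <- unlist(hdr[names(hdr) == "@HD"])
  if (!any(grepl("^SO:coordinate$", so))) {
    stop("alignments must be coordinate-sorted (header SO:coordinate)")
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, what = c("flag", "seq"),
                                   mapqFilter = min_mapq)
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  if (!length(gal)) {
    return(validate_pileup(cbind(
      data.frame(sample = character(0), library = character(0),
                 pos = integer(0), strand = character(0)),
      matrix(integer(0), 0, 4, dimnames = list(NULL, c("nA","nC","nG","nT"))))))
  }
  fl <- S4Vectors::mcols(gal)$flag
  first_mate <- bitwAnd(fl, 64L) > 0L
  aln_minus <- as.character(BiocGenerics::strand(gal)) == "-"
  # RF: transcript strand is the mate-2 alignment strand
  tx_strand <- ifelse(first_mate, ifelse(aln_minus, "+", "-"),
                      ifelse(aln_minus, "-", "+"))
  at <- GenomicRanges::GRanges(GenomeInfoDb::seqlevels(gal)[1L],
                               IRanges::IRanges(seq_len(genome$length),
                                                width = 1L))
  out <- list()
  for (st in c("+", "-")) {
    sel <- tx_strand == st
    if (!any(sel)) next
    sub <- gal[sel]
    piled <- GenomicAlignments::pileLettersAt(
      S4Vectors::mcols(sub)$seq, GenomeInfoDb::seqnames(sub),
      BiocGenerics::start(sub), GenomicAlignments::cigar(sub), at)
    cnts <- Biostrings::letterFrequency(piled, c("A", "C", "G", "T"))
    keep <- rowSums(cnts) > 0
    out[[st]] <- data.frame(sample = sample, library = library,
                            pos = which(keep), strand = st,
                            nA = cnts[keep, "A"], nC = cnts[keep, "C"],
                            nG = cnts[keep, "G"], nT = cnts[keep, "T"])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  validate_pileup(res)
}
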