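# Codon-level annotation of retained editing sites: gene, spliced-CDS
# position, codon and amino-acid change, plus per-gene and amino-acid
# summaries of the edited codon set.

#' Annotate editing sites with gene context and codon changes
#'
#' Each unique (pos, strand, ref, alt) site is classified by region; CDS
#' sites additionally get their spliced-CDS position, codon change,
#' amino-acid change and codon position via the plastome gene models. The
#' transcript-orientation reference base of every site is checked against
#' the genome — a mismatch is a hard error, since it signals a coordinate
#' bug upstream. When `sites` carries per-experiment evidence (`sample`,
#' `library`, `vaf`, `var_reads`), efficiency and supporting-read ranges are
#' aggregated per site.
#'
#' @param sites data.frame with columns pos, strand, ref, alt (transcript
#'   orientation), optionally sample/library/vaf/var_reads.
#' @param features A `plastid_features` table.
#' @param genome A `plastome`.
#' @return data.frame with one row per unique site: pos, strand, ref, alt,
#'   gene, region, pos_on_gene, ref_codon, alt_codon, codon_change,
#'   aa_change, codon_position (NA outside CDS), and efficiency/read ranges
#'   when evidence columns are present.
#' @export
annotate_sites <- function(sites, features, genome) {
  stopifnot(all(c("pos", "strand", "ref", "alt") %in% names(sites)))
  ok <- strand_base(genome, sites$pos, sites$strand) == sites$ref
  if (!all(ok)) {
    stop("reference base mismatch at position(s) ",
         paste(utils::head(sites$pos[!ok], 5L), collapse = ","),
         ": site ref disagrees with genome (coordinate bug?)")
  }
  key <- paste(sites$pos, sites$strand, sites$ref, sites$alt)
  uniq <- !duplicated(key)
  out <- sites[uniq, c("pos", "strand", "ref", "alt"), drop = FALSE]
  loc <- locate(out$pos, features)
  out$gene <- ifelse(is.na(loc$gene), "intergenic", loc$gene)
  out$region <- loc$region
  out$pos_on_gene <- NA_integer_
  out$ref_codon <- NA_character_
  out$alt_codon <- NA_character_
  out$codon_change <- NA_character_
  out$aa_change <- NA_character_
  out$codon_position <- NA_integer_
  for (i in which(out$region == "CDS")) {
    cc <- codon_context(features, genome, out$pos[i], out$gene[i])
    edited <- apply_edit(cc$ref_codon, cc$codon_position, out$ref[i],
                         out$alt[i])
    out$pos_on_gene[i] <- cc$pos_on_gene
    out$ref_codon[i] <- cc$ref_codon
    out$alt_codon[i] <- edited
    out$codon_change[i] <- paste0(cc$ref_codon, ">", edited)
    out$aa_change[i] <- paste0(translate_codon(cc$ref_codon), ">",
                               translate_codon(edited))
    out$codon_position[i] <- cc$codon_position
  }
  if (all(c("vaf", "var_reads") %in% names(sites))) {
    k <- key[uniq]
    out$eff_min <- as.numeric(round(tapply(sites$vaf, key, min)[k], 4))
    out$eff_max <- as.numeric(round(tapply(sites$vaf, key, max)[k], 4))
    out$reads_min <- as.integer(tapply(sites$var_reads, key, min)[k])
    out$reads_max <- as.integer(tapply(sites$var_reads, key, max)[k])
    out$n_experiments <- as.integer(tapply(sites$vaf, key, length)[k])
  }
  rownames(out) <- NULL
  out[order(out$gene, out$pos_on_gene, out$pos), , drop = FALSE]
}

#' Per-gene counts of CDS editing sites
#'
#' @param annotated Output of [annotate_sites()].
#' @return data.frame `gene`, `n_sites` over CDS sites only; the number of
#'   non-CDS sites is recorded in attribute `non_cds_sites`.
#' @export
summarize_genes <- function(annotated) {
  cds <- annotated[annotated$region == "CDS", , drop = FALSE]
  if (!nrow(cds)) {
    out <- data.frame(gene = character(0), n_sites = integer(0))
  } else {
    tab <- table(cds$gene)
    out <- data.frame(gene = names(tab), n_sites = as.integer(tab))
    out <- out[order(out$gene), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "non_cds_sites") <- sum(annotated$region != "CDS")
  out
}

#' Amino-acid and codon-position distributions of edited codons
#'
#' Counts, over CDS sites only, the amino acids encoded before and after
#' editing and the distribution of edited codon positions (1-3).
#'
#' @param annotated Output of [annotate_sites()].
#' @return list with named count vectors `before`, `after`,
#'   `codon_position`.
#' @export
summarize_amino_acids <- function(annotated) {
  cds <- annotated[annotated$region == "CDS", , drop = FALSE]
  aa_before <- substring(cds$aa_change, 1L, 1L)
  aa_after <- substring(cds$aa_change, 3L, 3L)
  list(before = table_vec(aa_before),
       after = table_vec(aa_after),
       codon_position = table_vec(as.character(cds$codon_position)))
}

table_vec <- function(x) {
  tab <- table(x)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Editing efficiency from pileup counts
#'
#' The fraction of strand-specific reads at a site carrying the edited base,
#' in transcript orientation: alt count / total strand depth.
#'
#' @param record One or more pileup rows (validated layout).
#' @param alt Edited base in transcript orientation (recycled).
#' @return Numeric vector of efficiencies (0 when depth is 0).
#' @export
editing_efficiency <- function(record, alt) {
  if (is.null(record$depth)) record <- validate_pileup(record)
  m <- transcript_counts(record)
  altn <- m[cbind(seq_len(nrow(m)), match(rep_len(alt, nrow(m)),
                                          colnames(m)))]
  ifelse(record$depth > 0, altn / record$depth, 0)
}

#' Write annotated sites as TSV
#' @param annotated Output of [annotate_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated <- function(annotated, path) {
  utils::write.table(annotated, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
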