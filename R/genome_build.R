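# Internal machinery for assembling an engineered plastome from gene blocks.
# Shared by the curated-site fixture builder and the synthetic-data generator.

# A gene spec is a list:
#   gene        symbol
#   ftype       "CDS", "rRNA" or "tRNA"
#   strand      "+" or "-"
#   seq         coding-strand sequence of the transcribed unit body (for CDS:
#               the spliced CDS including stop codon; for rRNA/tRNA: the gene)
#   intron_after  spliced position after which an intron is inserted (or NULL)
#   intron_seq    coding-strand intron sequence (required with intron_after)
#   utr5_seq / utr3_seq  coding-strand UTR sequences (optional)
#
# Blocks are laid left to right with `spacer` intergenic bases between them;
# remaining length up to genome_length (if given) is appended as trailing
# spacer. Returns the genome string, the exon-level feature data.frame and a
# per-gene segment map (transcript-offset -> forward-coordinate) used to
# place non-CDS truth sites.

FILLER_CODONS <- c("GCT", "GGA", "TTC", "ATC", "GAA", "GAT", "AAA", "CTT")

filler_cds <- function(n_codons) {
  paste0(rep_len(FILLER_CODONS, n_codons), collapse = "")
}

filler_bases <- function(n) {
  paste0(rep_len(c("A", "C", "G", "T"), n), collapse = "")
}

assemble_genome <- function(specs, genome_id = "plastome_synthetic",
                            spacer = 200L, genome_length = NULL) {
  pieces <- character(0)
  exons <- list()
  segmaps <- list()
  cursor <- 0L
  for (sp in specs) {
    pieces <- c(pieces, filler_bases(spacer))
    cursor <- cursor + spacer
    # transcript-oriented segments: list of (type, seq)
    segs <- list()
    if (!is.null(sp$utr5_seq)) segs <- c(segs, list(list(type = "UTR5", seq = sp$utr5_seq)))
    if (!is.null(sp$intron_after)) {
      stopifnot(!is.null(sp$intron_seq))
      a <- substring(sp$seq, 1L, sp$intron_after)
      b <- substring(sp$seq, sp$intron_after + 1L, nchar(sp$seq))
      segs <- c(segs, list(list(type = sp$ftype, seq = a),
                           list(type = "intron_raw", seq = sp$intron_seq),
                           list(type = sp$ftype, seq = b)))
    } else {
      segs <- c(segs, list(list(type = sp$ftype, seq = sp$seq)))
    }
    if (!is.null(sp$utr3_seq)) segs <- c(segs, list(list(type = "UTR3", seq = sp$utr3_seq)))

    lens <- vapply(segs, function(s) nchar(s$seq), integer(1))
    tstart <- cumsum(c(1L, lens[-length(lens)]))
    tend <- cumsum(lens)
    total <- sum(lens)
    transcript <- paste0(vapply(segs, `[[`, "", "seq"), collapse = "")
    block <- if (sp$strand == "+") transcript else revcomp(transcript)
    # forward interval of segment i within the block
    fstart <- if (sp$strand == "+") tstart else total - tend + 1L
    fend <- if (sp$strand == "+") tend else total - tstart + 1L
    seg_df <- data.frame(
      gene = sp$gene,
      type = vapply(segs, `[[`, "", "type"),
      t_start = tstart, t_end = tend,
      start = cursor + fstart, end = cursor + fend,
      strand = sp$strand)
    segmaps[[sp$gene]] <- seg_df
    keep <- seg_df$type != "intron_raw"  # introns re-derived from CDS gaps
    exons[[length(exons) + 1L]] <- data.frame(
      gene = sp$gene, ftype = seg_df$type[keep], strand = sp$strand,
      start = seg_df$start[keep], end = seg_df$end[keep])
    pieces <- c(pieces, block)
    cursor <- cursor + nchar(block)
  }
  pieces <- c(pieces, filler_bases(spacer))
  cursor <- cursor + spacer
  if (!is.null(genome_length)) {
    if (genome_length < cursor) {
      stop("genome_length ", genome_length, " too small for gene content (",
           cursor, " bp)")
    }
    pieces <- c(pieces, filler_bases(genome_length - cursor))
    cursor <- genome_length
  }
  genome <- plastome(genome_id, paste0(pieces, collapse = ""))
  exons <- do.call(rbind, exons)
  features <- feature_table(exons, genome$length)
  list(genome = genome, features = features, segments = segmaps)
}

# forward plastome position of transcript-offset `toff` within a segment row
segment_forward_pos <- function(seg_row, toff_in_segment) {
  if (seg_row$strand == "+") {
    seg_row$start + toff_in_segment - 1L
  } else {
    seg_row$end - toff_in_segment + 1L
  }
}

# overwrite a single forward-strand base in a plastome
set_genome_base <- function(genome, pos, base) {
  stopifnot(pos >= 1L, pos <= genome$length)
  substring(genome$bases, pos, pos) <- toupper(base)
  genome$length <- nchar(genome$bases)
  genome
}

#' Write a plastome to FASTA
#'
#' @param genome A `plastome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$bases)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Write a feature table to GFF3
#'
#' Emits `gene` parent records plus CDS/rRNA/tRNA/UTR child features with
#' `gene` attributes, in the dialect consumed by [read_annotation()].
#' Derived introns are not written; they are re-derived on read.
#'
#' @param features A `plastid_features` table.
#' @param genome A `plastome` (for the seqid and length pragma).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, genome, path) {
  gff_type <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                UTR5 = "five_prime_UTR", UTR3 = "three_prime_UTR")
  rows <- features[features$ftype %in% names(gff_type), , drop = FALSE]
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$id, genome$length))
  for (g in unique(rows$gene)) {
    sub <- rows[rows$gene == g, , drop = FALSE]
    lines <- c(lines, paste(genome$id, "plastedit", "gene",
                            min(sub$start), max(sub$end), ".",
                            sub$strand[1L], ".",
                            sprintf("ID=gene-%s;Name=%s;gene=%s", g, g, g),
                            sep = "\t"))
    for (i in seq_len(nrow(sub))) {
      ph <- if (sub$ftype[i] == "CDS") "0" else "."
      lines <- c(lines, paste(genome$id, "plastedit", gff_type[sub$ftype[i]],
                              sub$start[i], sub$end[i], ".", sub$strand[i], ph,
                              sprintf("ID=%s-%s-%d;Parent=gene-%s;gene=%s",
                                      tolower(sub$ftype[i]), g, i, g, g),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
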