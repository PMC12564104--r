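#' Read a plastome sequence from a FASTA file
#'
#' Loads the first record of a (possibly multi-record) FASTA file as the
#' plastome reference. The sequence is uppercased and restricted to the
#' alphabet A/C/G/T/N; anything else is a hard error, since downstream codon
#' arithmetic assumes unambiguous nucleotides.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param circular Logical; whether the molecule is circular. Features
#'   wrapping the origin are not supported, so this is informational only.
#' @return An object of class `plastome`: a list with elements `id`, `bases`
#'   (a single uppercase string), `length` (bp) and `circular`.
#' @export
read_genome <- function(path, circular = FALSE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path)
  plastome(id = names(seqs)[1L], bases = as.character(seqs[[1L]]),
           circular = circular)
}

#' Construct a plastome object from an in-memory sequence
#'
#' @param id Sequence identifier.
#' @param bases Nucleotide string; lowercase accepted, uppercased on input.
#' @param circular Logical flag, see [read_genome()].
#' @return A `plastome` object.
#' @export
plastome <- function(id, bases, circular = FALSE) {
  bases <- toupper(bases)
  if (nchar(bases) == 0L) stop("empty plastome sequence for record '", id, "'")
  bad <- gsub("[ACGTN]", "", bases)
  if (nchar(bad) > 0L) {
    stop("non-nucleotide characters in sequence '", id, "': ",
         paste(unique(strsplit(bad, "")[[1L]]), collapse = ","))
  }
  structure(list(id = id, bases = bases, length = nchar(bases),
                 circular = isTRUE(circular)),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %d bp%s\n", x$id, x$length,
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Forward-strand base(s) at given positions
#'
#' @param genome A `plastome`.
#' @param pos Integer vector of 1-based positions.
#' @return Character vector of single bases on the forward strand.
#' @export
genome_base <- function(genome, pos) {
  stopifnot(all(pos >= 1L), all(pos <= genome$length))
  substring(genome$bases, pos, pos)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Complement of single bases
#' @param base Character vector of single bases.
#' @return Complementary bases.
#' @export
complement_base <- function(base) {
  out <- COMPLEMENT[toupper(base)]
  if (anyNA(out)) stop("cannot complement base(s): ",
                       paste(unique(base[is.na(out)]), collapse = ","))
  unname(out)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Base at a position in transcript orientation
#'
#' On the "+" strand this is the forward base; on the "-" strand it is its
#' complement, so substitutions can always be expressed as seen on the
#' transcript.
#'
#' @inheritParams genome_base
#' @param strand Character vector of "+" or "-".
#' @export
strand_base <- function(genome, pos, strand) {
  b <- genome_base(genome, pos)
  minus <- strand == "-"
  b[minus] <- complement_base(b[minus])
  b
}

# ---- gene features ------------------------------------------------------

FTYPES <- c("CDS", "rRNA", "tRNA", "UTR5", "UTR3", "intron")
REGION_PRIORITY <- c("CDS", "rRNA", "tRNA", "UTR5", "UTR3", "intron")

#' Build a feature table from exon-level intervals
#'
#' The feature table is the package's gene-model container: one row per
#' genomic interval (a CDS exon, an rRNA/tRNA span, a UTR, or a derived
#' intron), in 1-based inclusive plastome-forward coordinates. Intron rows
#' are derived as the gaps between consecutive CDS exons of the same gene.
#'
#' @param exons data.frame with columns `gene`, `ftype`
#'   (CDS/rRNA/tRNA/UTR5/UTR3), `strand` ("+"/"-"), `start`, `end`.
#' @param genome_length Total plastome length in bp; intervals must lie
#'   within it (features may not wrap the origin).
#' @return A `plastid_features` data.frame with derived `intron` rows
#'   appended and an `exon_rank` column (genomic order within gene x ftype).
#' @export
feature_table <- function(exons, genome_length) {
  req <- c("gene", "ftype", "strand", "start", "end")
  if (!all(req %in% names(exons))) {
    stop("feature table requires columns: ", paste(req, collapse = ", "))
  }
  exons <- as.data.frame(exons)[req]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$end < exons$start)) {
    stop("feature with end < start: features wrapping the circular origin ",
         "are not supported (linearized assemblies expected)")
  }
  if (any(exons$start < 1L) || any(exons$end > genome_length)) {
    stop("feature interval outside genome (1..", genome_length, ")")
  }
  if (!all(exons$ftype %in% FTYPES)) {
    stop("unknown feature type(s): ",
         paste(setdiff(unique(exons$ftype), FTYPES), collapse = ","))
  }
  if (!all(exons$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  exons <- exons[order(exons$gene, exons$ftype, exons$start), , drop = FALSE]
  # rank exons genomically within gene x ftype; check non-overlap
  exons$exon_rank <- stats::ave(exons$start, exons$gene, exons$ftype,
                                FUN = seq_along)
  for (key in unique(paste(exons$gene, exons$ftype))) {
    sub <- exons[paste(exons$gene, exons$ftype) == key, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] <= sub$end[-nrow(sub)])) {
      stop("overlapping exons within feature ", key)
    }
  }
  introns <- derive_introns(exons)
  out <- rbind(exons, introns)
  rownames(out) <- NULL
  structure(out, genome_length = genome_length,
            class = c("plastid_features", "data.frame"))
}

# gaps between consecutive CDS exons of one gene become intron rows
derive_introns <- function(exons) {
  cds <- exons[exons$ftype == "CDS", , drop = FALSE]
  out <- cds[0, , drop = FALSE]
  for (g in unique(cds$gene)) {
    sub <- cds[cds$gene == g, , drop = FALSE]
    if (nrow(sub) < 2L) next
    sub <- sub[order(sub$start), , drop = FALSE]
    for (i in seq_len(nrow(sub) - 1L)) {
      out <- rbind(out, data.frame(
        gene = g, ftype = "intron", strand = sub$strand[1L],
        start = sub$end[i] + 1L, end = sub$start[i + 1L] - 1L,
        exon_rank = i))
    }
  }
  out
}

#' Read gene models from a GFF3 annotation
#'
#' Consumes CDS, rRNA, tRNA and explicit UTR features. Gene symbols are taken
#' from the `gene` attribute, falling back to `Name` (first present wins).
#' Introns are derived as gaps between CDS exons of the same gene; no UTR
#' inference is attempted beyond explicit `five_prime_UTR`/`three_prime_UTR`
#' records. A CDS whose spliced length is not a multiple of 3 is kept with a
#' warning and recorded in the `incomplete_cds` attribute.
#'
#' @param path Path to a GFF3 file.
#' @param genome A `plastome`; used to bound coordinates.
#' @return A `plastid_features` table (see [feature_table()]).
#' @export
read_annotation <- function(path, genome) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  keep_map <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                five_prime_UTR = "UTR5", three_prime_UTR = "UTR3",
                UTR5 = "UTR5", UTR3 = "UTR3")
  sel <- type %in% names(keep_map)
  gff <- gff[sel]
  type <- keep_map[type[sel]]
  sym <- if (!is.null(gff$gene)) as.character(gff$gene) else rep(NA_character_, length(gff))
  nm <- if (!is.null(gff$Name)) as.character(gff$Name) else rep(NA_character_, length(gff))
  sym[is.na(sym)] <- nm[is.na(sym)]
  if (anyNA(sym)) stop("GFF3 feature without 'gene' or 'Name' attribute")
  exons <- data.frame(gene = sym, ftype = unname(type),
                      strand = as.character(BiocGenerics::strand(gff)),
                      start = BiocGenerics::start(gff),
                      end = BiocGenerics::end(gff))
  if (any(exons$end > genome$length)) {
    stop("annotation extends beyond genome length (", genome$length, " bp)")
  }
  feats <- feature_table(exons, genome$length)
  # flag CDS genes whose spliced length is not a multiple of 3
  cds <- feats[feats$ftype == "CDS", , drop = FALSE]
  lens <- tapply(cds$end - cds$start + 1L, cds$gene, sum)
  bad <- names(lens)[lens %% 3L != 0L]
  if (length(bad)) {
    warning("CDS length not divisible by 3 for: ", paste(bad, collapse = ", "))
  }
  attr(feats, "incomplete_cds") <- bad
  feats
}

#' Classify plastome positions by gene context
#'
#' Each position receives exactly one region label by the fixed priority
#' CDS > rRNA > tRNA > UTR5 > UTR3 > intron > intergenic, together with the
#' owning gene (the first overlapping gene of the winning class, in genomic
#' order). Use [locate_all()] for every overlapping feature.
#'
#' @param pos Integer vector of 1-based plastome positions.
#' @param features A `plastid_features` table.
#' @return data.frame with columns `pos`, `region`, `gene` (NA when
#'   intergenic).
#' @export
locate <- function(pos, features) {
  glen <- attr(features, "genome_length")
  stopifnot(all(pos >= 1L), all(pos <= glen))
  region <- rep("intergenic", length(pos))
  gene <- rep(NA_character_, length(pos))
  for (ft in rev(REGION_PRIORITY)) {  # low priority first, overwritten later
    sub <- features[features$ftype == ft, , drop = FALSE]
    if (!nrow(sub)) next
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(pos, width = 1L),
      IRanges::IRanges(sub$start, sub$end), select = "first")
    has <- !is.na(hit)
    region[has] <- ft
    gene[has] <- sub$gene[hit[has]]
  }
  data.frame(pos = pos, region = region, gene = gene)
}

#' All features overlapping a single position
#'
#' @param pos A single 1-based plastome position.
#' @param features A `plastid_features` table.
#' @return The overlapping rows of the feature table (possibly empty).
#' @export
locate_all <- function(pos, features) {
  stopifnot(length(pos) == 1L)
  features[features$start <= pos & features$end >= pos, , drop = FALSE]
}

cds_exons <- function(features, gene) {
  sub <- features[features$gene == gene & features$ftype == "CDS", , drop = FALSE]
  if (!nrow(sub)) stop("no CDS feature for gene '", gene, "'")
  sub[order(sub$start), , drop = FALSE]
}

#' Spliced coding-strand CDS sequence of a gene
#'
#' Concatenates the CDS exons in genomic order and reverse-complements the
#' result for minus-strand genes, yielding the sequence in translation
#' orientation.
#'
#' @param features A `plastid_features` table.
#' @param genome A `plastome`.
#' @param gene Gene symbol.
#' @return A single DNA string.
#' @export
spliced_cds <- function(features, genome, gene) {
  ex <- cds_exons(features, gene)
  s <- paste0(substring(genome$bases, ex$start, ex$end), collapse = "")
  if (ex$strand[1L] == "-") s <- revcomp(s)
  s
}

#' Map a plastome position to its spliced-CDS coordinate
#'
#' @param features A `plastid_features` table.
#' @param gene Gene symbol (CDS gene).
#' @param pos 1-based plastome position; must fall in a CDS exon of `gene`.
#' @return 1-based position along the spliced coding-strand CDS.
#' @export
genome_to_gene_pos <- function(features, gene, pos) {
  ex <- cds_exons(features, gene)
  i <- which(ex$start <= pos & ex$end >= pos)
  if (!length(i)) {
    stop("position ", pos, " is not in a CDS exon of '", gene,
         "' (introns have no spliced coordinate)")
  }
  lens <- ex$end - ex$start + 1L
  if (ex$strand[1L] == "+") {
    before <- if (i > 1L) sum(lens[seq_len(i - 1L)]) else 0L
    before + (pos - ex$start[i] + 1L)
  } else {
    after <- if (i < nrow(ex)) sum(lens[(i + 1L):nrow(ex)]) else 0L
    after + (ex$end[i] - pos + 1L)
  }
}

#' Map a spliced-CDS coordinate back to the plastome
#'
#' Inverse of [genome_to_gene_pos()].
#'
#' @inheritParams genome_to_gene_pos
#' @param pos_on_gene 1-based position along the spliced coding-strand CDS.
#' @return 1-based plastome position.
#' @export
gene_to_genome_pos <- function(features, gene, pos_on_gene) {
  ex <- cds_exons(features, gene)
  lens <- ex$end - ex$start + 1L
  if (pos_on_gene < 1L || pos_on_gene > sum(lens)) {
    stop("pos_on_gene ", pos_on_gene, " outside spliced CDS of '", gene, "'")
  }
  if (ex$strand[1L] == "+") {
    cum <- cumsum(lens)
    i <- which(pos_on_gene <= cum)[1L]
    before <- if (i > 1L) cum[i - 1L] else 0L
    ex$start[i] + (pos_on_gene - before - 1L)
  } else {
    cum <- cumsum(rev(lens))  # transcript order = reverse genomic
    j <- which(pos_on_gene <= cum)[1L]
    i <- nrow(ex) - j + 1L
    before <- if (j > 1L) cum[j - 1L] else 0L
    ex$end[i] - (pos_on_gene - before - 1L)
  }
}

#' Codon context of a plastome position within a CDS
#'
#' Computes the 1-based spliced-CDS position, codon index, position within
#' the codon (1-3) and the reference codon read from the spliced
#' coding-strand sequence.
#'
#' @param features A `plastid_features` table.
#' @param genome A `plastome`.
#' @param pos 1-based plastome position inside a CDS exon.
#' @param gene Gene symbol; if `NULL`, resolved via [locate()] (must be CDS).
#' @return A list with `gene`, `pos_on_gene`, `codon_index`,
#'   `codon_position`, `ref_codon`.
#' @export
codon_context <- function(features, genome, pos, gene = NULL) {
  if (is.null(gene)) {
    loc <- locate(pos, features)
    if (loc$region != "CDS") {
      stop("position ", pos, " is not in a CDS (", loc$region, ")")
    }
    gene <- loc$gene
  }
  pog <- genome_to_gene_pos(features, gene, pos)
  codon_index <- (pog - 1L) %/% 3L + 1L
  codon_position <- (pog - 1L) %% 3L + 1L
  cds <- spliced_cds(features, genome, gene)
  ref_codon <- substring(cds, 3L * (codon_index - 1L) + 1L, 3L * codon_index)
  list(gene = gene, pos_on_gene = pog, codon_index = codon_index,
       codon_position = codon_position, ref_codon = ref_codon)
}

#' Translate a codon under the standard genetic code
#'
#' The plastid code is identical to the standard table for all codons in
#' scope; no start-codon special-casing is applied (an edited ACG start is
#' reported as T>M like any internal codon).
#'
#' @param codon Character vector of 3-mers over A/C/G/T.
#' @return One-letter amino-acid codes ("*" for stop).
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (any(nchar(codon) != 3L)) stop("codons must be 3-mers")
  if (any(grepl("[^ACGT]", codon))) {
    stop("ambiguous or non-DNA base in codon(s): ",
         paste(unique(codon[grepl("[^ACGT]", codon)]), collapse = ","))
  }
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Apply a single-base edit to a codon
#'
#' @param codon Reference 3-mer on the coding strand.
#' @param codon_position Position within the codon (1-3) to edit.
#' @param ref Expected reference base at that position (coding strand).
#' @param alt Replacement base.
#' @return The edited 3-mer.
#' @export
apply_edit <- function(codon, codon_position, ref, alt) {
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3L, codon_position %in% 1:3)
  have <- substring(codon, codon_position, codon_position)
  if (have != toupper(ref)) {
    stop("reference mismatch: codon ", codon, " has '", have,
         "' at position ", codon_position, ", expected '", ref, "'")
  }
  substring(codon, codon_position, codon_position) <- toupper(alt)
  codon
}
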