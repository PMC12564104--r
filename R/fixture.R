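# Curated editing-site fixture: the published 38-site high-confidence set
# for the licorice (Glycyrrhiza uralensis) plastome, together with an
# engineered reference genome in which every site occupies its printed
# spliced-CDS position with its printed reference codon. The engineered
# genome lets the codon-annotation machinery be validated against the
# curated table without shipping the full 127 kb plastome.

#' Curated plastid editing-site set
#'
#' Returns the packaged 38-site curated set: 34 codon-level C>U edits in 18
#' protein-coding genes plus four non-CDS sites (an *ndhA* intron site, a
#' *psbF* 5' UTR site, a *psbT* 3' UTR U>C site, and one intergenic site).
#'
#' @return data.frame with one row per site; CDS rows carry `pos_on_gene`,
#'   `ref_codon`, `alt_codon`, `aa_ref`, `aa_alt`, `codon_position`, and the
#'   published editing-efficiency and supporting-read ranges.
#' @export
curated_sites <- function() {
  path <- system.file("extdata", "curated_sites.tsv", package = "plastedit",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# strand layout for the engineered reference; mixes orientations so minus-
# strand spliced arithmetic is exercised by the fixture itself
FIXTURE_STRANDS <- c(
  accD = "+", atpA = "-", ndhA = "+", ndhB = "-", ndhD = "+", ndhE = "-",
  ndhF = "+", ndhG = "-", ndhH = "+", petB = "-", petL = "+", psaI = "-",
  psbF = "+", psbL = "-", psbT = "+", psbZ = "-", rpoA = "+", rpoB = "-",
  rps14 = "+")

FIXTURE_INTRON_AFTER <- 600L   # ndhA: intron inserted after spliced pos 600
FIXTURE_INTRON_LEN <- 320L
FIXTURE_INTRON_SITE <- 150L    # site offset within the intron (coding strand)
FIXTURE_UTR5_LEN <- 60L
FIXTURE_UTR5_SITE <- 30L
FIXTURE_UTR3_LEN <- 80L
FIXTURE_UTR3_SITE <- 40L
FIXTURE_INTERGENIC_POS <- 57L  # inside the leading spacer

#' Engineered reference for the curated site set
#'
#' Builds a compact synthetic plastome plus gene models in which each curated
#' CDS site sits at its published spliced-CDS position with its published
#' reference codon, the *ndhA* gene carries a real intron holding the intron
#' site, *psbF*/*psbT* carry explicit UTR features holding the UTR sites, and
#' one intergenic C is reserved for the intergenic site. An rRNA locus
#' (`rrn16`) is included so region classification is total. Construction is
#' deterministic (no RNG).
#'
#' @return list with `genome` (a `plastome`), `features` (a
#'   `plastid_features` table) and `sites`: the curated table augmented with
#'   plastome coordinates (`pos`), transcript `strand`, and `ref`/`alt`
#'   bases in transcript orientation.
#' @export
curated_reference <- function() {
  tab <- curated_sites()
  cds <- tab[tab$region == "CDS", , drop = FALSE]
  specs <- list()
  for (g in names(FIXTURE_STRANDS)) {
    rows <- cds[cds$gene == g, , drop = FALSE]
    max_codon <- if (nrow(rows)) max((rows$pos_on_gene - 1L) %/% 3L + 1L) else 10L
    n_codons <- max_codon + 5L
    s <- filler_cds(n_codons)
    for (i in seq_len(nrow(rows))) {
      ci <- (rows$pos_on_gene[i] - 1L) %/% 3L + 1L
      substring(s, 3L * (ci - 1L) + 1L, 3L * ci) <- rows$ref_codon[i]
    }
    s <- paste0(s, "TAA")
    sp <- list(gene = g, ftype = "CDS", strand = FIXTURE_STRANDS[[g]], seq = s)
    if (g == "ndhA") {
      intron <- filler_bases(FIXTURE_INTRON_LEN)
      substring(intron, FIXTURE_INTRON_SITE, FIXTURE_INTRON_SITE) <- "C"
      sp$intron_after <- FIXTURE_INTRON_AFTER
      sp$intron_seq <- intron
    }
    if (g == "psbF") {
      u <- filler_bases(FIXTURE_UTR5_LEN)
      substring(u, FIXTURE_UTR5_SITE, FIXTURE_UTR5_SITE) <- "C"
      sp$utr5_seq <- u
    }
    if (g == "psbT") {
      u <- filler_bases(FIXTURE_UTR3_LEN)
      substring(u, FIXTURE_UTR3_SITE, FIXTURE_UTR3_SITE) <- "T"
      sp$utr3_seq <- u
    }
    specs[[g]] <- sp
  }
  specs$rrn16 <- list(gene = "rrn16", ftype = "rRNA", strand = "+",
                      seq = filler_bases(1500L))
  built <- assemble_genome(specs, genome_id = "plastome_curated_synthetic",
                           spacer = 200L)
  genome <- set_genome_base(built$genome, FIXTURE_INTERGENIC_POS, "C")
  features <- built$features

  # plastome coordinates for every curated site
  pos <- integer(nrow(tab))
  strand <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    g <- tab$gene[i]
    if (tab$region[i] == "CDS") {
      pos[i] <- gene_to_genome_pos(features, g, tab$pos_on_gene[i])
      strand[i] <- FIXTURE_STRANDS[[g]]
    } else if (tab$region[i] == "intron") {
      seg <- built$segments[[g]]
      seg <- seg[seg$type == "intron_raw", , drop = FALSE][1L, ]
      pos[i] <- segment_forward_pos(seg, FIXTURE_INTRON_SITE)
      strand[i] <- seg$strand
    } else if (tab$region[i] %in% c("UTR5", "UTR3")) {
      seg <- built$segments[[g]]
      seg <- seg[seg$type == tab$region[i], , drop = FALSE][1L, ]
      off <- if (tab$region[i] == "UTR5") FIXTURE_UTR5_SITE else FIXTURE_UTR3_SITE
      pos[i] <- segment_forward_pos(seg, off)
      strand[i] <- seg$strand
    } else {  # intergenic
      pos[i] <- FIXTURE_INTERGENIC_POS
      strand[i] <- "+"
    }
  }
  sites <- tab
  sites$pos <- pos
  sites$strand <- strand
  sites$ref <- substring(sites$substitution, 1L, 1L)
  sites$alt <- substring(sites$substitution, 3L, 3L)
  # engineering self-checks: transcript-orientation base and codon context
  stopifnot(all(strand_base(genome, sites$pos, sites$strand) == sites$ref))
  for (i in which(sites$region == "CDS")) {
    cc <- codon_context(features, genome, sites$pos[i], sites$gene[i])
    stopifnot(cc$pos_on_gene == sites$pos_on_gene[i],
              cc$codon_position == sites$codon_position[i],
              cc$ref_codon == sites$ref_codon[i])
  }
  list(genome = genome, features = features, sites = sites)
}
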