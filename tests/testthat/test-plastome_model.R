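test_that("read_genome parses the first record, uppercases, and validates", {
  fa <- tempfile(fileext = ".fa")
  write_fasta_lines(c(one = "ACGT", two = "GGGG"), fa)
  g <- read_genome(fa)
  expect_equal(g$length, 4L)
  expect_equal(g$bases, "ACGT")
  expect_equal(g$id, "one")

  write_fasta_lines(c(lc = "acgt"), fa)
  expect_equal(read_genome(fa)$bases, "ACGT")

  expect_error(plastome("bad", "ACXT"), "non-nucleotide")
  writeLines(character(0), fa)
  expect_error(read_genome(fa))
})

test_that("read_annotation derives introns and keeps exon conventions", {
  genome <- plastome("g", strrep("ACGT", 200))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "g\tx\tgene\t10\t299\t.\t+\t.\tID=gene-A;gene=gA",
    "g\tx\tCDS\t10\t99\t.\t+\t0\tID=cds-A1;Parent=gene-A;gene=gA",
    "g\tx\tCDS\t200\t299\t.\t+\t0\tID=cds-A2;Parent=gene-A;gene=gA",
    "g\tx\tgene\t400\t459\t.\t-\t.\tID=gene-B;Name=gB",
    "g\tx\tCDS\t400\t459\t.\t-\t0\tID=cds-B;Parent=gene-B;Name=gB",
    "g\tx\tgene\t500\t700\t.\t+\t.\tID=gene-R;gene=rrnX",
    "g\tx\trRNA\t500\t700\t.\t+\t.\tID=rrna-R;Parent=gene-R;gene=rrnX"),
    gff)
  suppressWarnings(feats <- read_annotation(gff, genome))
  intr <- feats[feats$ftype == "intron", ]
  expect_equal(nrow(intr), 1L)
  expect_equal(c(intr$start, intr$end), c(100L, 199L))
  b <- feats[feats$gene == "gB" & feats$ftype == "CDS", ]
  expect_equal(b$strand, "-")
  expect_true("rrnX" %in% feats$gene[feats$ftype == "rRNA"])
  expect_false("rrnX" %in% feats$gene[feats$ftype == "intron"])
  # exon beyond genome is a hard error
  writeLines(c("##gff-version 3",
               "g\tx\tCDS\t10\t9999\t.\t+\t0\tID=c;gene=gX"), gff)
  expect_error(read_annotation(gff, genome), "beyond genome")
})

test_that("locate applies CDS > rRNA > ... > intergenic priority totally", {
  ref <- curated_ref()
  s <- ref$sites
  loc <- locate(s$pos, ref$features)
  expect_equal(loc$region, s$region)
  expect_equal(sum(loc$region == "intergenic"), 1L)
  # one class per position over the whole genome
  all_loc <- locate(seq_len(ref$genome$length), ref$features)
  expect_true(all(all_loc$region %in% c("CDS", "rRNA", "tRNA", "UTR5",
                                        "UTR3", "intron", "intergenic")))
  expect_equal(nrow(all_loc), ref$genome$length)
  # intron of the multi-exon gene classifies as intron, owned by its gene
  intr <- ref$features[ref$features$ftype == "intron", ][1, ]
  mid <- locate((intr$start + intr$end) %/% 2L, ref$features)
  expect_equal(mid$region, "intron")
  expect_equal(mid$gene, "ndhA")
})

test_that("codon_context reproduces curated spliced positions and codons", {
  ref <- curated_ref()
  cds <- ref$sites[ref$sites$region == "CDS", ]
  for (i in seq_len(nrow(cds))) {
    cc <- codon_context(ref$features, ref$genome, cds$pos[i], cds$gene[i])
    expect_equal(cc$pos_on_gene, cds$pos_on_gene[i])
    expect_equal(cc$codon_position, cds$codon_position[i])
    expect_equal(cc$ref_codon, cds$ref_codon[i])
  }
  # spliced pos 794 -> codon 265 position 2 (accD); 12 -> codon 4 pos 3
  acc <- cds[cds$gene == "accD" & cds$pos_on_gene == 794, ]
  cc <- codon_context(ref$features, ref$genome, acc$pos, "accD")
  expect_equal(cc$codon_index, 265L)
  expect_equal(cc$codon_position, 2L)
  petB <- cds[cds$gene == "petB" & cds$pos_on_gene == 12, ]
  cc <- codon_context(ref$features, ref$genome, petB$pos, "petB")
  expect_equal(cc$codon_index, 4L)
  expect_equal(cc$codon_position, 3L)
  # boundary: first base of a CDS
  first <- gene_to_genome_pos(ref$features, "rps14", 1L)
  cc <- codon_context(ref$features, ref$genome, first, "rps14")
  expect_equal(c(cc$codon_index, cc$codon_position), c(1L, 1L))
  # intron position has no spliced coordinate
  intr <- ref$features[ref$features$ftype == "intron", ][1, ]
  expect_error(codon_context(ref$features, ref$genome, intr$start + 5L,
                             "ndhA"), "intron")
})

test_that("spliced coordinates round-trip on plus, minus and multi-exon genes", {
  ref <- curated_ref()
  genes <- unique(ref$features$gene[ref$features$ftype == "CDS"])
  for (g in genes) {
    len <- nchar(spliced_cds(ref$features, ref$genome, g))
    probe <- unique(c(1L, 2L, len %/% 2L, len - 1L, len))
    for (p in probe) {
      gp <- gene_to_genome_pos(ref$features, g, p)
      expect_equal(genome_to_gene_pos(ref$features, g, gp), p)
    }
  }
  # hand-built minus-strand multi-exon gene round-trips everywhere
  set.seed(42)
  genome <- plastome("m", paste0(sample(c("A", "C", "G", "T"), 120,
                                        replace = TRUE), collapse = ""))
  feats <- feature_table(data.frame(
    gene = "mx", ftype = "CDS", strand = "-",
    start = c(10L, 61L), end = c(39L, 90L)), 120L)
  for (p in 1:60) {
    gp <- gene_to_genome_pos(feats, "mx", p)
    expect_equal(genome_to_gene_pos(feats, "mx", gp), p)
  }
  # spliced sequence equals reverse complement of concatenated exons
  fwd <- paste0(substring(genome$bases, 10, 39),
                substring(genome$bases, 61, 90))
  expect_equal(spliced_cds(feats, genome, "mx"),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(fwd))))
})

test_that("translate_codon follows the standard code and rejects ambiguity", {
  expect_equal(translate_codon(c("TCG", "TTG")), c("S", "L"))
  expect_equal(translate_codon(c("CAT", "TAT")), c("H", "Y"))
  expect_equal(translate_codon(c("ACG", "ATG")), c("T", "M"))
  expect_error(translate_codon("ANG"), "ambiguous")
})

test_that("apply_edit replaces a single base and checks the reference", {
  expect_equal(apply_edit("CCA", 2, "C", "T"), "CTA")
  expect_equal(apply_edit("GTC", 3, "C", "T"), "GTT")
  expect_equal(apply_edit("AAA", 1, "A", "A"), "AAA")
  expect_error(apply_edit("CCA", 1, "G", "T"), "mismatch")
})

test_that("features wrapping the origin are rejected", {
  expect_error(feature_table(data.frame(gene = "w", ftype = "CDS",
                                        strand = "+", start = 90L, end = 10L),
                             100L), "wrap")
})
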