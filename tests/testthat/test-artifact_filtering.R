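# The four artifact classes and the screening flags.

# a minimal genome with a plus-strand 2-exon CDS, a minus-strand CDS and an
# rRNA locus, built once
filter_ref <- local({
  ref <- NULL
  function() {
    if (!is.null(ref)) return(ref)
    # layout: exon1 [101,200], intron [201,300], exon2 [301,400] (gA, +)
    #         CDS [501,600] (gB, -), rRNA [701,900]
    set.seed(99)
    bases <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
    # pin the bases the scenarios rely on (forward strand)
    bases[c(150, 160, 170, 198)] <- "C"   # gA (+): transcript C
    bases[c(550, 560)] <- "G"             # gB (-): transcript C
    genome <- plastome("t", paste0(bases, collapse = ""))
    feats <- feature_table(data.frame(
      gene = c("gA", "gA", "gB", "rrnX"),
      ftype = c("CDS", "CDS", "CDS", "rRNA"),
      strand = c("+", "+", "-", "+"),
      start = c(101L, 301L, 501L, 701L),
      end = c(200L, 400L, 600L, 900L)), 1000L)
    ref <<- list(genome = genome, features = feats)
    ref
  }
})

mkcall <- function(pos, strand, ref, alt, var_reads = 50L, depth = 100L,
                   sample = "s1", library = "total") {
  data.frame(sample = sample, library = library, pos = pos, strand = strand,
             ref = ref, alt = alt, var_reads = var_reads, depth = depth,
             vaf = var_reads / depth, multi_allelic = FALSE)
}

test_that("canonical_filter passes C>U and U>C and flags the rest", {
  vs <- rbind(mkcall(150, "+", "C", "T"), mkcall(160, "+", "T", "C"),
              mkcall(170, "+", "A", "G"), mkcall(180, "+", "T", "G"))
  out <- canonical_filter(vs)
  expect_equal(out$flag_noncanonical, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("junction_filter flags within the window only", {
  fr <- filter_ref()
  vs <- rbind(mkcall(198, "+", "C", "T"),   # 3 bp from the 200|201 boundary
              mkcall(350, "+", "C", "T"),   # 50 bp from any boundary
              mkcall(305, "+", "C", "T"))   # 5 bp into exon 2
  out <- junction_filter(vs, fr$features, window = 10L)
  expect_equal(out$flag_junction, c(TRUE, FALSE, TRUE))
  out25 <- junction_filter(vs, fr$features, window = 2L)
  expect_equal(out25$flag_junction, c(FALSE, FALSE, FALSE))
})

test_that("rrna_partition splits by region and tabulates spectra", {
  fr <- filter_ref()
  vs <- rbind(mkcall(750, "-", "T", "C"), mkcall(800, "-", "A", "G"),
              mkcall(150, "+", "C", "T"), mkcall(550, "-", "C", "T"))
  pp <- rrna_partition(vs, fr$features)
  expect_equal(sort(pp$rrna$pos), c(750, 800))
  expect_equal(sort(pp$non_rrna$pos), c(150, 550))
  expect_true(all(pp$vs$flag_rrna[pp$vs$pos %in% c(750, 800)]))
  sp <- pp$spectrum
  expect_equal(sp$n[sp$partition == "non_rRNA" &
                    sp$substitution_type == "C>T"], 2L)
  expect_equal(sum(sp$n), 4L)
  # all-C>U non-rRNA input: a single active type
  one <- rrna_partition(rbind(mkcall(150, "+", "C", "T"),
                              mkcall(550, "-", "C", "T")), fr$features)
  active <- one$spectrum[one$spectrum$n > 0, ]
  expect_equal(unique(as.character(active$substitution_type)), "C>T")
})

test_that("carryover_detector flags low complementary opposite signals only", {
  fr <- filter_ref()
  # coding C>U on gA (+) at 0.5; opposite-strand G>A at 1/63
  coding <- mkcall(150, "+", "C", "T", 500, 1000)
  opp <- mkcall(150, "-", "G", "A", 8, 504)  # vaf ~1/63
  opp$called <- FALSE
  vs <- carryover_detector(rbind(cbind(coding, called = TRUE), opp),
                           fr$features)
  expect_equal(vs$flag_carryover, c(FALSE, TRUE))
  # opposite C>U with no complementary coding signal: untouched
  lone <- carryover_detector(mkcall(160, "-", "C", "T"), fr$features)
  expect_false(lone$flag_carryover)
  # a 20% opposite signal is not carryover under the default ceiling
  big <- mkcall(170, "-", "G", "A", 20, 100)
  pair <- rbind(cbind(mkcall(170, "+", "C", "T", 50, 100), called = TRUE),
                cbind(big, called = TRUE))
  out <- carryover_detector(pair, fr$features)
  expect_false(any(out$flag_carryover))
})

test_that("strand_concordance computes the shared-denominator fraction", {
  fr <- filter_ref()
  # forward-orientation counts: minus-strand reads matching a forward-C
  # reference appear as nC; T-supporting reads as nT
  pile <- rbind(
    pileup_row(150, "+", nC = 400, nT = 100),
    pileup_row(150, "-", nC = 495, nT = 5),    # 5 opposite T-supporting
    pileup_row(160, "+", nC = 380, nT = 100),
    pileup_row(160, "-", nC = 480, nT = 20),
    pileup_row(170, "+", nC = 400, nT = 100))
  v150 <- mkcall(150, "+", "C", "T", 100, 500)
  v160 <- mkcall(160, "+", "C", "T", 100, 480)
  v170 <- mkcall(170, "+", "C", "T", 100, 500)
  out <- strand_concordance(rbind(v150, v160, v170), pile)
  expect_equal(out$discordance, c(5 / 105, 20 / 120, 0))
  expect_equal(out$flag_discordant, c(FALSE, TRUE, FALSE))
})

test_that("reassign_to_coding_strand rewrites misreported G>A calls", {
  fr <- filter_ref()
  # gB is minus-strand: its coding strand at 550 shows C>T (nG fwd = ref C)
  pile <- rbind(
    pileup_row(550, "-", nG = 500, nA = 500),  # coding C>T at 50%
    pileup_row(550, "+", nG = 995, nA = 5))    # sparse antisense G>A
  # caller misreported the event as G>A on "+" (antisense to gB)
  bad <- mkcall(550, "+", "G", "A", 5, 1000)
  out <- reassign_to_coding_strand(bad, fr$features, pile, fr$genome)
  expect_equal(out$strand, "-")
  expect_equal(paste0(out$ref, ">", out$alt), "C>T")
  expect_equal(out$vaf, 0.5)
  expect_true(out$flag_reassigned)
  # involution-safe: a second application changes nothing
  out2 <- reassign_to_coding_strand(out, fr$features, pile, fr$genome)
  expect_identical(out, out2)
  # an already-coding C>T call is untouched
  good <- mkcall(550, "-", "C", "T", 500, 1000)
  expect_false(reassign_to_coding_strand(good, fr$features, pile,
                                         fr$genome)$flag_reassigned)
  # G>A with no complementary coding-strand signal is untouched
  pile2 <- rbind(pileup_row(560, "-", nG = 1000),
                 pileup_row(560, "+", nG = 95, nA = 5))
  odd <- mkcall(560, "+", "G", "A", 5, 100)
  kept <- reassign_to_coding_strand(odd, fr$features, pile2, fr$genome)
  expect_equal(kept$strand, "+")
  expect_false(kept$flag_reassigned)
})

test_that("flag operations commute", {
  fr <- filter_ref()
  pile <- rbind(
    pileup_row(198, "+", nC = 60, nT = 40),
    pileup_row(150, "+", nC = 50, nT = 50),
    pileup_row(150, "-", nG = 99, nA = 1),
    pileup_row(750, "-", nA = 70, nG = 30),
    pileup_row(550, "-", nG = 50, nA = 50))
  vs0 <- call_candidates(pile, fr$genome, min_var_reads = 1L, min_vaf = 0.005)
  vs0 <- augment_with_opposite(vs0, pile)
  apply_ops <- function(vs, order) {
    for (op in order) {
      vs <- switch(op,
        j = junction_filter(vs, fr$features),
        r = rrna_partition(vs, fr$features)$vs,
        c = canonical_filter(vs),
        k = carryover_detector(vs, fr$features),
        s = strand_concordance(vs, pile))
    }
    vs
  }
  a <- apply_ops(vs0, c("j", "r", "c", "k", "s"))
  b <- apply_ops(vs0, c("s", "k", "c", "r", "j"))
  cols <- c("flag_junction", "flag_rrna", "flag_noncanonical",
            "flag_carryover", "flag_discordant")
  expect_identical(a[cols], b[cols])
})

test_that("synthetic rRNA artifacts reproduce the configured spectrum", {
  cfg <- clean_config(seed = 23L, n_edits = 0L, n_rrna_sites = 60L,
                      rrna_rate = 0.4)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth[sim$truth$class == "rrna_artifact", ]
  calls <- call_candidates(sim$pileups, sim$genome)
  cls <- filter_artifacts(calls, sim$features, sim$pileups, sim$genome)
  got <- cls[cls$called %in% TRUE & cls$flag_rrna, ]
  # every planted rRNA artifact is called and flagged as rRNA-region
  expect_setequal(paste(got$pos, got$strand), paste(tr$pos, tr$strand))
  # truth types follow the configured spectrum within multinomial error
  spec <- cfg$rrna_spectrum
  obs <- table(factor(paste0(tr$ref, ">", tr$alt), levels = names(spec)))
  expected <- nrow(tr) * spec
  tol <- 4 * sqrt(nrow(tr) * spec * (1 - spec)) + 1
  expect_true(all(abs(as.integer(obs) - expected) <= tol))
})
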