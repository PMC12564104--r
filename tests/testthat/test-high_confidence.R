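# Coordinate harmonization, site x experiment matrix, high-confidence set.

test_that("coordinate maps handle identity, insertions and gaps", {
  aln <- c(A = "ACGTACGTAC", B = "ACGTACGTAC")
  m <- build_coordinate_map(aln)
  expect_equal(pos_to_column(m, "A", 1:10), 1:10)
  expect_equal(column_to_pos(m, "B", 1:10), 1:10)

  # B has a 2 bp insertion after position 5: A:6 <-> B:8
  aln2 <- c(A = "ACGTA--CGTAC", B = "ACGTAGGCGTAC")
  m2 <- build_coordinate_map(aln2)
  expect_equal(pos_to_column(m2, "A", 6), 8)
  expect_equal(column_to_pos(m2, "B", pos_to_column(m2, "A", 6)), 8)
  # columns 6-7 are gaps in A: unmapped
  expect_true(is.na(column_to_pos(m2, "A", 6)))
  # genome validation
  expect_error(build_coordinate_map(aln2, genomes = list(
    A = plastome("A", "AAAAAAAAAA"))), "does not match")
})

test_that("mapped positions round-trip through the alignment", {
  aln <- c(s1 = "ACGT--ACGTTTACGT", s2 = "ACGTGGACGT--ACGT",
           s3 = "ACGTGGACGTTTACGT")
  m <- build_coordinate_map(aln)
  for (nm in names(aln)) {
    n <- sum(strsplit(aln[[nm]], "")[[1]] != "-")
    cols <- pos_to_column(m, nm, seq_len(n))
    expect_equal(column_to_pos(m, nm, cols), seq_len(n))
  }
})

test_that("site matrix statuses distinguish detected, sub-threshold, absent", {
  genome <- plastome("g", strrep("C", 100))
  feats <- feature_table(data.frame(gene = "gA", ftype = "CDS", strand = "+",
                                    start = 1L, end = 99L), 100L)
  pile <- rbind(
    pileup_row(10, "+", nC = 50, nT = 50, sample = "s1"),           # detected
    pileup_row(10, "+", nC = 95, nT = 5, sample = "s2"),            # 5% sub
    pileup_row(10, "+", nC = 100, sample = "s3"),                   # absent
    pileup_row(20, "+", nC = 60, nT = 40, sample = "s1"),
    pileup_row(20, "+", nC = 55, nT = 45, sample = "s2"),
    pileup_row(20, "+", nC = 91, nT = 9, sample = "s3"))            # 9% sub
  pile <- validate_pileup(pile)
  calls <- call_candidates(pile, genome)
  cls <- filter_artifacts(calls, feats, pile, genome)
  sm <- build_site_matrix(cls, pile, genome)
  st <- status_matrix(sm)
  expect_equal(st["c10+:C>T", ],
               c("s1:total" = "detected", "s2:total" = "sub_threshold",
                 "s3:total" = "absent"))
  expect_equal(unname(st["c20+:C>T", "s3:total"]), "sub_threshold")
  cell <- sm$cells[sm$cells$site_id == "c20+:C>T" &
                   sm$cells$sample == "s3", ]
  expect_equal(cell$efficiency, 0.09)
  # empty calls give an empty matrix
  empty <- build_site_matrix(cls[0, ], pile, genome)
  expect_equal(nrow(empty$sites), 0L)
})

test_that("high-confidence derivation is monotone and honors corroboration", {
  genome <- plastome("g", strrep("C", 100))
  feats <- feature_table(data.frame(gene = "gA", ftype = "CDS", strand = "+",
                                    start = 1L, end = 99L), 100L)
  mkexp <- function(smp, tpos) {
    rows <- lapply(seq(10, 60, by = 10), function(p) {
      if (p %in% tpos) pileup_row(p, "+", nC = 50, nT = 50, sample = smp)
      else pileup_row(p, "+", nC = 97, nT = 3, sample = smp)
    })
    do.call(rbind, rows)
  }
  # site 10: in all; 20: in 4; 30: in 2 (sub elsewhere); 40: in 1
  pile <- validate_pileup(rbind(
    mkexp("e1", c(10, 20, 30, 40)), mkexp("e2", c(10, 20, 30)),
    mkexp("e3", c(10, 20)), mkexp("e4", c(10, 20)),
    mkexp("e5", c(10)), mkexp("e6", c(10))))
  cls <- filter_artifacts(call_candidates(pile, genome), feats, pile, genome)
  sm <- build_site_matrix(cls, pile, genome)
  hc2 <- derive_high_confidence(sm, feats, min_detected = 2L)
  expect_true(all(c("c10+:C>T", "c20+:C>T", "c30+:C>T") %in% hc2$site_id))
  expect_false("c40+:C>T" %in% hc2$site_id)
  sizes <- vapply(1:6, function(k) {
    nrow(derive_high_confidence(sm, feats, min_detected = k,
                                corroborate = FALSE))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  # corroboration: site 30 is detected twice and sub-threshold elsewhere, so
  # it survives; without any further signal it would not
  expect_true("c30+:C>T" %in%
              derive_high_confidence(sm, feats, min_detected = 2L,
                                     corroborate = TRUE)$site_id)
})

test_that("exact intersection counts equal brute-force subset enumeration", {
  genome <- plastome("g", strrep("C", 200))
  feats <- feature_table(data.frame(gene = "gA", ftype = "CDS", strand = "+",
                                    start = 1L, end = 198L), 200L)
  set.seed(61)
  exps <- data.frame(sample = rep(c("a", "b", "c"), 2),
                     library = rep(c("total", "rrna_depleted"), each = 3))
  npos <- 30L
  member <- matrix(runif(npos * 6) < 0.5, npos, 6)
  pile <- list()
  for (e in seq_len(6)) {
    for (i in seq_len(npos)) {
      p <- i * 3L
      pile[[length(pile) + 1L]] <- pileup_row(
        p, "+", nC = if (member[i, e]) 60 else 100,
        nT = if (member[i, e]) 40 else 0,
        sample = exps$sample[e], library = exps$library[e])
    }
  }
  pile <- validate_pileup(do.call(rbind, pile))
  cls <- filter_artifacts(call_candidates(pile, genome), feats, pile, genome)
  sm <- build_site_matrix(cls, pile, genome)
  ix <- intersections(sm)
  # brute force over all 63 non-empty experiment subsets
  labels <- paste(exps$sample, exps$library, sep = ":")
  st <- status_matrix(sm) == "detected"
  brute <- list()
  for (mask in 1:63) {
    inset <- as.logical(bitwAnd(mask, 2^(0:5)))
    n <- sum(apply(st, 1, function(r) all(r == inset)))
    if (n > 0) brute[[paste(labels[inset], collapse = "+")]] <- n
  }
  got <- stats::setNames(ix$exact$n, ix$exact$subset)
  expect_mapequal(as.list(got), brute)
  expect_equal(sum(ix$exact$n), nrow(sm$sites))
  expect_equal(ix$per_set$n, unname(colSums(st)))
})

test_that("strategy comparison ranks poly(A) below total RNA and counts artifacts", {
  cfg <- sim_config(seed = 29L, samples = c("s1", "s2"),
                    strategies = c("total", "mrna"),
                    genome_length = 24000L)
  sim <- simulate_dataset(cfg)
  pile <- validate_pileup(sim$pileups)
  cls <- filter_artifacts(call_candidates(pile, sim$genome), sim$features,
                          pile, sim$genome)
  sm <- build_site_matrix(cls, pile, sim$genome)
  hc <- derive_high_confidence(sm, sim$features)
  comp <- compare_strategies(sm, hc$site_id, cls, sim$features)
  tot <- comp[comp$library == "total", ]
  mr <- comp[comp$library == "mrna", ]
  expect_lt(mr$reference_in_all_replicates, tot$reference_in_all_replicates)
  # zero-artifact simulation has no rRNA or noncanonical calls
  clean <- simulate_dataset(clean_config(seed = 31L))
  cp <- validate_pileup(clean$pileups)
  ccls <- filter_artifacts(call_candidates(cp, clean$genome),
                           clean$features, cp, clean$genome)
  csm <- build_site_matrix(ccls, cp, clean$genome)
  ccomp <- compare_strategies(csm, character(0), ccls, clean$features)
  expect_true(all(ccomp$rrna_calls == 0))
  expect_true(all(ccomp$noncanonical_calls == 0))
})
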