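test_that("read_pileup validates the TSV dialect", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tlibrary\tpos\tstrand\tnA\tnC\tnG\tnT",
               "s1\ttotal\t101\t+\t0\t90\t0\t10"), path)
  df <- read_pileup(path)
  expect_equal(df$depth, 100L)

  writeLines(c("sample\tlibrary\tpos\tstrand\tnA\tnC\tnG\tnT",
               "s1\ttotal\t101\t+\t0\t90\t0\t10",
               "s1\ttotal\t101\t+\t0\t80\t0\t20"), path)
  expect_error(read_pileup(path), "duplicate")

  writeLines(c("sample\tlibrary\tpos\tstrand\tnA\tnC\tnG\tnT",
               "s1\ttotal\t101\t*\t0\t90\t0\t10"), path)
  expect_error(read_pileup(path), "strand")

  writeLines(c("sample\tlibrary\tpos\tstrand\tnA\tnC\tnG\tnT",
               "s1\ttotal\t101\t+\t-1\t90\t0\t10"), path)
  expect_error(read_pileup(path), "negative")
})

test_that("threshold semantics are exact at the boundaries", {
  genome <- plastome("g", strrep("C", 200))
  # exactly 3 reads and exactly 10% VAF: called
  p <- pileup_row(10, "+", nC = 27, nT = 3)
  expect_equal(nrow(call_candidates(p, genome)), 1L)
  expect_equal(call_candidates(p, genome)$vaf, 0.10)
  # 2 supporting reads: not called
  p2 <- pileup_row(10, "+", nC = 18, nT = 2)
  expect_equal(nrow(call_candidates(p2, genome)), 0L)
  # VAF 0.0999...: not called
  p3 <- pileup_row(10, "+", nC = 9010, nT = 999)
  expect_lt(999 / 10009, 0.10)
  expect_equal(nrow(call_candidates(p3, genome)), 0L)
  # relaxed query surfaces it at its exact VAF
  r <- relaxed_query(p3, genome)
  expect_equal(r$vaf, 999 / 10009)
  # sub-threshold 5% and 9% scenarios retrievable exactly
  p5 <- pileup_row(20, "+", nC = 950, nT = 50)
  expect_equal(relaxed_query(p5, genome)$vaf, 0.05)
  p9 <- pileup_row(30, "+", nC = 910, nT = 90)
  expect_equal(relaxed_query(p9, genome)$vaf, 0.09)
  expect_equal(nrow(call_candidates(rbind(p5, p9), genome)), 0L)
})

test_that("minus-strand calls are expressed in transcript orientation", {
  # forward base G at pos 10; minus-strand reads carrying A (forward) are a
  # C>T edit on the transcript
  genome <- plastome("g", strrep("G", 50))
  p <- pileup_row(10, "-", nG = 80, nA = 20)
  v <- call_candidates(p, genome)
  expect_equal(v$ref, "C")
  expect_equal(v$alt, "T")
  expect_equal(v$vaf, 0.2)
  # same counts on the plus strand read as G>A
  v2 <- call_candidates(pileup_row(10, "+", nG = 80, nA = 20), genome)
  expect_equal(paste0(v2$ref, ">", v2$alt), "G>A")
})

test_that("vaf is exactly var_reads / depth and multi-allelic is flagged", {
  genome <- plastome("g", strrep("C", 50))
  p <- pileup_row(5, "+", nC = 50, nT = 30, nA = 20)
  v <- call_candidates(p, genome)
  expect_equal(v$alt, "T")
  expect_equal(v$vaf, 30 / 100)
  expect_true(v$multi_allelic)
  v1 <- call_candidates(pileup_row(6, "+", nC = 90, nT = 10), genome)
  expect_false(v1$multi_allelic)
  expect_identical(v1$vaf, v1$var_reads / v1$depth)
})

test_that("the called set is monotone non-increasing in both thresholds", {
  set.seed(31)
  genome <- plastome("g", paste0(sample(c("A", "C", "G", "T"), 300,
                                        replace = TRUE), collapse = ""))
  n <- 150
  df <- data.frame(sample = "s1", library = "total",
                   pos = sample(300, n), strand = sample(c("+", "-"), n,
                                                         replace = TRUE),
                   nA = rpois(n, 20), nC = rpois(n, 20),
                   nG = rpois(n, 20), nT = rpois(n, 20))
  df <- df[!duplicated(paste(df$pos, df$strand)), ]
  for (mv in c(1, 3, 5, 10)) {
    for (mf in c(0, 0.05, 0.1, 0.3)) {
      n1 <- nrow(call_candidates(df, genome, mv, mf))
      expect_lte(nrow(call_candidates(df, genome, mv + 2L, mf)), n1)
      expect_lte(nrow(call_candidates(df, genome, mv, mf + 0.05)), n1)
    }
  }
})

test_that("clean simulation gives perfect recall and precision vs truth", {
  cfg <- clean_config(seed = 21L, n_edits = 12L)
  sim <- simulate_dataset(cfg)
  calls <- call_candidates(sim$pileups, sim$genome)
  ed <- sim$truth[sim$truth$class == "edit", ]
  called_keys <- paste(calls$pos, calls$strand, calls$ref, calls$alt)
  truth_keys <- paste(ed$pos, ed$strand, ed$ref, ed$alt)
  expect_setequal(unique(called_keys), truth_keys)
})
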