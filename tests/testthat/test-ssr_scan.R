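test_that("the three-SSR worked construct is reproduced exactly", {
  s <- paste0(strrep("A", 12), "GCGCGCGCGC", strrep("ACGT", 4))
  r <- scan_ssrs(s)
  expect_identical(nrow(r), 3L)
  expect_identical(r$motif, c("A", "GC", "ACGT"))
  expect_identical(r$copies, c(12L, 5L, 4L))
  expect_identical(r$end - r$start + 1L, r$motif_len * r$copies)
  sm <- summarize_ssrs(r)
  expect_identical(unname(sm$by_class[c("mono", "di", "tetra")]), c(1L, 1L, 1L))
  expect_identical(sm$total, 3L)
})

test_that("sub-threshold runs and non-primitive motifs are not reported", {
  expect_identical(nrow(scan_ssrs(strrep("ACGT", 2))), 0L)   # tetra needs 4
  r <- scan_ssrs(strrep("A", 12))
  expect_identical(nrow(r), 1L)                              # never (AA)6
  expect_identical(r$motif, "A")
  expect_identical(nrow(scan_ssrs("")), 0L)
  ## runs containing N are excluded
  expect_identical(nrow(scan_ssrs(paste0(strrep("A", 6), "N", strrep("A", 6)))), 0L)
})

test_that("scanner agrees with the regex oracle on fuzzed sequences", {
  set.seed(33)
  for (i in 1:12) {
    ## low-complexity alphabet makes repeats common
    s <- paste(sample(c("A", "C", "A", "T", "AC", "AT", "AAT"), 600, TRUE),
               collapse = "")
    s <- substr(s, 1, 1500)
    got <- scan_ssrs(s)
    exp <- bf_ssr_scan(s)
    got_key <- sort(paste(got$motif, got$start, got$copies))
    exp_key <- sort(paste(exp$motif, exp$start, exp$copies))
    expect_identical(got_key, exp_key)
  }
})

test_that("reverse-complement scanning preserves canonical motif multiset", {
  set.seed(44)
  for (i in 1:5) {
    s <- paste(sample(c("A", "T", "AT", "AAG", "C"), 500, TRUE), collapse = "")
    a <- scan_ssrs(s)
    b <- scan_ssrs(revcomp(s))
    expect_identical(sort(paste(a$canonical_motif, a$copies)),
                     sort(paste(b$canonical_motif, b$copies)))
  }
})

test_that("region assignment works and IR-duplicated SSRs count twice", {
  set.seed(55)
  ## plant an SSR inside IRb; the IRa copy is its reverse complement
  lsc <- rnd_seq(600)
  irb <- paste0(rnd_seq(40), "C", strrep("A", 12), "C", rnd_seq(46))
  ssc <- rnd_seq(200)
  g <- plastome("g", paste0(lsc, irb, ssc, revcomp(irb)))
  g$structure <- detect_quadripartite(g, min_ir_len = 50)
  r <- scan_ssrs(g)
  mono <- r[r$canonical_motif == "A" & r$copies == 12, ]
  expect_identical(nrow(mono), 2L)               # once per IR copy
  expect_setequal(mono$region, c("IRb", "IRa"))
  sm <- summarize_ssrs(r, g$structure)
  expect_gte(sm$by_region[["IRb"]], 1L)
  expect_gte(sm$by_region[["IRa"]], 1L)
})
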