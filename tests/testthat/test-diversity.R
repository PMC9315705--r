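test_that("hand-computed Pi values are reproduced", {
  ## (1+2+1)/3 pairs / 4 sites
  al <- new_alignment(c(r = "AAAA", s1 = "AAAT", s2 = "AATT"), "r")
  p <- suppressWarnings(sliding_pi(al))
  expect_equal(p$windows$pi[1], 4 / 12)
  expect_identical(p$windows$n_sites[1], 4L)

  ## identical sequences: zero everywhere
  al2 <- new_alignment(c(a = strrep("ACGT", 300), b = strrep("ACGT", 300)), "a")
  expect_true(all(sliding_pi(al2)$windows$pi == 0))

  ## one difference in 1000 bp: 1/500 in windows containing the site
  s1 <- strrep("A", 1000)
  s2 <- paste0(strrep("A", 599), "G", strrep("A", 400))
  p3 <- sliding_pi(new_alignment(c(a = s1, b = s2), "a"))
  w <- p3$windows
  hit <- w$start <= 600 & w$end >= 600
  expect_true(all(abs(w$pi[hit] - 0.002) < 1e-12))
  expect_true(all(w$pi[!hit] == 0))
})

test_that("windows tile the alignment at the configured stride", {
  al <- new_alignment(c(a = rnd_seq(1234), b = rnd_seq(1234)), "a")
  p <- sliding_pi(al, pi_config(500, 250))
  w <- p$windows
  expect_identical(w$start[1], 1L)
  expect_identical(w$end[nrow(w)], 1234L)        # tail covered
  expect_true(all(diff(w$start) <= 250L))
  expect_error(pi_config(100, 200), "step")
})

test_that("sliding Pi equals the all-pairs oracle on fuzzed alignments", {
  set.seed(88)
  for (i in 1:6) {
    ns <- sample(3:6, 1)
    len <- sample(300:800, 1)
    base <- rnd_seq(len)
    rows <- vapply(seq_len(ns), function(k) {
      b <- chars(base)
      idx <- sample(len, sample(3:10, 1))
      b[idx] <- sample(c("A", "C", "G", "T", "-", "N"), length(idx), TRUE)
      unchars(b)
    }, character(1))
    names(rows) <- paste0("s", seq_len(ns))
    al <- new_alignment(rows, "s1")
    p <- sliding_pi(al, pi_config(200, 100))
    for (j in seq_len(nrow(p$windows))) {
      expect_equal(p$windows$pi[j],
                   bf_window_pi(rows, p$windows$start[j], p$windows$end[j]))
    }
  }
})

test_that("Pi is invariant to row order", {
  set.seed(89)
  rows <- c(a = rnd_seq(400), b = rnd_seq(400), c = rnd_seq(400))
  p1 <- sliding_pi(new_alignment(rows, "a"), pi_config(200, 200))
  p2 <- sliding_pi(new_alignment(rows[c(3, 1, 2)], "a"), pi_config(200, 200))
  expect_equal(p1$windows$pi, p2$windows$pi)
})

test_that("per-group Pi isolates within-group variation", {
  base <- rnd_seq(600)
  v1 <- chars(base); v1[100] <- setdiff(c("A", "C", "G", "T"), v1[100])[1]
  rows <- c(a1 = base, a2 = unchars(v1), b1 = base, b2 = base)
  al <- new_alignment(rows, "a1")
  gm <- group_map(names(rows), c("ga", "ga", "gb", "gb"))
  prof <- sliding_pi(al)
  sm <- summarize_pi(prof, al, groups = gm)
  pa <- sm$by_group$pi[sm$by_group$group == "ga"]
  pb <- sm$by_group$pi[sm$by_group$group == "gb"]
  expect_equal(pa, 1 / 600)
  expect_identical(pb, 0)
})

test_that("region summaries and hotspots use the window midpoint", {
  fix <- sim_fixture()
  prof <- sliding_pi(fix$al)
  sm <- summarize_pi(prof, fix$al, structure = fix$sim$ancestor$structure,
                     groups = fix$sim$groups,
                     annotations = fix$sim$ancestor$annotations)
  br <- sm$by_region
  ## the simulated world keeps the IRs free of variation: the exact
  ## region-restricted Pi is zero (window means can straddle junctions)
  expect_identical(br$pi_sites[br$region == "IR"], 0)
  expect_gt(br$pi_sites[br$region == "LSC"], 0)
  ## hotspot windows carry locus labels
  if (nrow(sm$hotspots)) expect_true(all(!is.na(sm$hotspots$locus)))
  ## per-group Pi: wild species polymorphic, domesticated not
  bg <- sm$by_group
  expect_gt(bg$pi[bg$group == "robustum"], 0)
  expect_identical(bg$pi[bg$group == "sinense"], 0)
})
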