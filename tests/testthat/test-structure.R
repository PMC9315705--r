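test_that("constructed quadripartite toy is detected exactly", {
  set.seed(42)
  g <- plastome("toy", make_quadripartite(600, 100, 200))
  qp <- detect_quadripartite(g, min_ir_len = 50)
  expect_identical(qp$lsc_len, 600L)
  expect_identical(qp$ir_len, 100L)
  expect_identical(qp$ssc_len, 200L)
  expect_identical(qp$lsc_len + qp$ssc_len + 2L * qp$ir_len, 1000L)
  ## oracle: longest inverted repeat on the circle agrees
  expect_identical(bf_longest_inverted_repeat(g$sequence), 100L)
})

test_that("detection agrees with the brute-force oracle on fuzzed genomes", {
  set.seed(101)
  for (i in 1:8) {
    lsc <- sample(500:1500, 1); ir <- sample(80:300, 1); ssc <- sample(150:400, 1)
    s <- make_quadripartite(lsc, ir, ssc)
    qp <- detect_quadripartite(plastome("f", s), min_ir_len = 60)
    expect_identical(qp$ir_len, bf_longest_inverted_repeat(s))
    ## tiling invariant
    expect_identical(qp$lsc_len + qp$ssc_len + 2L * qp$ir_len, nchar(s))
    ## revcomp invariant on canonical copy
    cg <- canonicalize(plastome("f", s), qp)
    irb <- substr(cg$sequence, cg$structure$irb[1], cg$structure$irb[2])
    ira <- substr(cg$sequence, cg$structure$ira[1], cg$structure$ira[2])
    expect_identical(ira, revcomp(irb))
  }
})

test_that("detection is invariant to rotation and strand", {
  set.seed(7)
  s <- make_quadripartite(800, 120, 250)
  qp <- detect_quadripartite(plastome("g", s), min_ir_len = 60)
  for (rot in c(137L, 555L, 1100L)) {
    s2 <- paste0(substr(s, rot + 1, nchar(s)), substr(s, 1, rot))
    qp2 <- detect_quadripartite(plastome("r", s2), min_ir_len = 60)
    expect_identical(c(qp2$lsc_len, qp2$ir_len, qp2$ssc_len),
                     c(qp$lsc_len, qp$ir_len, qp$ssc_len))
    ## canonical sequence identical after rotation
    expect_identical(canonicalize(plastome("r", s2), qp2)$sequence,
                     canonicalize(plastome("g", s), qp)$sequence)
  }
  qp3 <- detect_quadripartite(plastome("rc", revcomp(s)), min_ir_len = 60)
  expect_identical(c(qp3$lsc_len, qp3$ir_len, qp3$ssc_len),
                   c(qp$lsc_len, qp$ir_len, qp$ssc_len))
})

test_that("absence and ambiguity of inverted repeats are errors", {
  set.seed(9)
  expect_error(detect_quadripartite(plastome("n", rnd_seq(10000))),
               "structure-not-found")
  ## two distinct repeat pairs of identical length; flanking bases are
  ## chosen non-complementary so neither pair can extend
  r1 <- rnd_seq(100); r2 <- rnd_seq(100)
  s <- paste0(rnd_seq(50),
              "A", r1, "C", rnd_seq(200), "C", revcomp(r1), "A", rnd_seq(200),
              "A", r2, "C", rnd_seq(200), "C", revcomp(r2), "A", rnd_seq(200))
  expect_error(detect_quadripartite(plastome("amb", s), min_ir_len = 60),
               "ambiguous")
})

test_that("canonicalize records the offset and rotates annotations", {
  set.seed(13)
  s <- make_quadripartite(600, 100, 200)
  g <- plastome("g", s)
  g$annotations <- gene_features("rbcL", "CDS", "+", 50, 120)
  qp <- detect_quadripartite(g, min_ir_len = 50)
  rot <- 250L
  g2 <- plastome("g", paste0(substr(s, rot + 1, 1000), substr(s, 1, rot)))
  g2$annotations <- gene_features("rbcL", "CDS", "+", 50 - rot + 1000, 120 - rot + 1000)
  qp2 <- detect_quadripartite(g2, min_ir_len = 50)
  c2 <- canonicalize(g2, qp2)
  expect_identical(c2$sequence, s)
  expect_identical(attr(c2, "offset"), 1000L - rot)
  expect_identical(c2$annotations$start, 50L)
  expect_identical(c2$annotations$end, 120L)
})

test_that("junction report reproduces planted gene contexts", {
  cfg <- sim_config(lsc_len = 8300, ssc_len = 1250, ir_len = 2280)
  anc <- simulate_ancestor(cfg, seed = 5)
  jr <- junction_report(anc)
  expect_identical(jr$gene[jr$junction == "LSC/IRb"], "rps19")
  expect_identical(jr$distance[jr$junction == "LSC/IRb"], 35L)
  expect_identical(jr$gene[jr$junction == "IRb/SSC"], "ndhF")
  expect_identical(jr$distance[jr$junction == "IRb/SSC"], -29L)

  ## a gene starting exactly at a border has distance 0
  g <- plastome("b", make_quadripartite(600, 100, 200))
  g$structure <- detect_quadripartite(g, min_ir_len = 50)
  g$annotations <- gene_features("rps19", "CDS", "+",
                                 g$structure$irb[1], g$structure$irb[1] + 60)
  jr2 <- junction_report(g)
  expect_identical(jr2$distance[jr2$junction == "LSC/IRb"], 0L)

  expect_error(junction_report(plastome("x", rnd_seq(100))), "annotations")
})
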