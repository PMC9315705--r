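test_that("banded pairwise alignment matches the exhaustive aligner", {
  skip_if_not_installed("Biostrings")
  set.seed(7)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  for (i in 1:10) {
    a <- rnd_seq(300)
    b <- chars(a)
    idx <- sample(300, 5)
    b[idx] <- sample(c("A", "C", "G", "T"), 5, TRUE)
    del <- sample(280, 1); b <- b[-(del:(del + 2))]
    ins <- sample(250, 1); b <- append(b, chars(rnd_seq(2)), after = ins)
    b <- unchars(b)
    r <- plastmarker:::cpp_banded_align(a, b, 50L, 1L, -2L, -5L, -1L)
    pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 1)
    expect_true(r$ok)
    expect_identical(r$score, as.integer(Biostrings::score(pa)))
    expect_identical(gsub("-", "", r$ref), a)
    expect_identical(gsub("-", "", r$qry), b)
  }
})

test_that("single deletion aligns with one left-aligned gap column", {
  r <- plastmarker:::cpp_banded_align("ACGTACGT", "ACGACGT", 10L, 1L, -2L, -5L, -1L)
  expect_identical(sum(chars(r$qry) == "-"), 1L)
  al <- new_alignment(c(a = r$ref, b = r$qry), "a")
  v <- call_variants(al)
  expect_identical(nrow(v), 1L)
  expect_identical(v$kind, "InDel")
  ## deleting the T of ACGT|ACGT left-aligns to anchor 3: GT -> G
  expect_identical(v$pos, 3L)
  expect_identical(v$ref, "GT")
  expect_identical(v$alt, "G")
})

test_that("de-gapping any row of a center-star alignment returns its input", {
  set.seed(70)
  ref <- rnd_seq(2000)
  gs <- list(plastome("ref", ref))
  for (i in 1:5) {
    b <- chars(ref)
    idx <- sample(2000, 8); b[idx] <- sample(c("A", "C", "G", "T"), 8, TRUE)
    b <- append(b, chars(rnd_seq(5)), after = sample(1900, 1))
    da <- sample(1800, 1); b <- b[-(da:(da + 3))]
    gs[[i + 1]] <- plastome(paste0("s", i), unchars(b))
  }
  al <- align_plastomes(gs, "ref", band = 50)
  for (g in gs) expect_identical(degap(al, g$id), g$sequence)
  expect_identical(length(al$col_to_ref), nchar(al$seqs[[1]]))
})

test_that("hand alignments give the expected SNP and InDel calls", {
  ## AAAA / AAAT / AATT: SNPs at reference positions 3 and 4
  v <- call_variants(new_alignment(c(r = "AAAA", s1 = "AAAT", s2 = "AATT"), "r"))
  expect_identical(v$pos, c(3L, 4L))
  expect_identical(v$kind, c("SNP", "SNP"))
  expect_identical(unname(attr(v, "calls")[, "s2"]), c("T", "T"))

  ## identical rows: no variants
  expect_identical(nrow(call_variants(
    new_alignment(c(r = "ACGT", s = "ACGT"), "r"))), 0L)

  ## a 27-column gap run merges into exactly one InDel event of 27 bp
  set.seed(3)
  ref <- rnd_seq(200)
  alseqs <- c(r = ref,
              s = paste0(substr(ref, 1, 100), strrep("-", 27),
                         substr(ref, 128, 200)))
  v2 <- call_variants(new_alignment(alseqs, "r"))
  expect_identical(nrow(v2), 1L)
  expect_identical(v2$kind, "InDel")
  expect_identical(nchar(v2$ref) - nchar(v2$alt), 27L)
})

test_that("InDel records are left-aligned regardless of gap placement", {
  refh <- "ACGTTTTTACG"
  v1 <- call_variants(new_alignment(c(r = refh, s = "ACG-TTTTACG"), "r"))
  v2 <- call_variants(new_alignment(c(r = refh, s = "ACGTTTT-ACG"), "r"))
  expect_identical(as.data.frame(v1), as.data.frame(v2))
  expect_identical(v1$pos, 3L)                   # anchored before the T run
})

test_that("variant calls are invariant to sample order", {
  set.seed(71)
  ref <- rnd_seq(300)
  mk <- function(nm, k) {
    b <- chars(ref); i <- sample(300, k)
    b[i] <- sample(c("A", "C", "G", "T"), k, TRUE)
    plastome(nm, unchars(b))
  }
  gs <- list(plastome("r", ref), mk("s1", 4), mk("s2", 6))
  v1 <- call_variants(align_plastomes(gs, "r", band = 30))
  v2 <- call_variants(align_plastomes(gs[c(2, 1, 3)], "r", band = 30))
  core <- function(v) data.frame(v$kind, v$pos, v$ref, v$alt)
  expect_identical(core(v1), core(v2))
  expect_identical(attr(v1, "calls")[, colnames(attr(v1, "calls"))],
                   attr(v2, "calls")[, colnames(attr(v1, "calls"))])
})

test_that("region classification distinguishes CDS, intron and spacers", {
  feat <- bind_features(
    gene_features("ndhF", "CDS", "-", 100, 300),
    gene_features("rpl32", "CDS", "+", 500, 600),
    gene_features("rps16", "CDS", "-", c(700, 820), c(760, 860)),
    gene_features("trnL-UAG", "tRNA", "+", 900, 950))
  al <- new_alignment(c(r = strrep("A", 1000), s = strrep("A", 1000)), "r")
  v <- data.frame(kind = "SNP", pos = c(150L, 420L, 780L, 920L, 50L),
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  class(v) <- c("variant_table", "data.frame")
  v <- classify_regions(v, feat, genome_len = 1000L)
  expect_identical(v$region, c("CDS", "intergenic", "intron", "tRNA",
                               "intergenic"))
  expect_identical(v$locus[1], "ndhF")
  expect_identical(v$locus[2], "ndhF-rpl32")     # flanking-gene labelling
  expect_identical(v$locus[3], "rps16")
  expect_identical(v$locus[5], "trnL-UAG-ndhF") # circular spacer at origin
})

test_that("diagnostic variants require within-group fixation", {
  al <- new_alignment(c(a1 = "AAAA", a2 = "AAAA", b1 = "AATA", b2 = "AATA",
                        c1 = "AACA", c2 = "AATA"), "a1")
  gm <- group_map(c("a1", "a2", "b1", "b2", "c1", "c2"),
                  c("ga", "ga", "gb", "gb", "gc", "gc"))
  v <- call_variants(al)
  dv <- diagnostic_variants(v, gm)
  ## column 3 is polymorphic within gc -> not diagnostic
  expect_identical(nrow(dv), 0L)

  ## three-allele site separating three groups -> three-way
  al2 <- new_alignment(c(a1 = "AAAA", a2 = "AAAA", b1 = "AATA", b2 = "AATA",
                         c1 = "AACA", c2 = "AACA"), "a1")
  dv2 <- diagnostic_variants(call_variants(al2), gm)
  expect_identical(nrow(dv2), 1L)
  expect_identical(dv2$category, "three-way")
  expect_identical(dv2$partition, "ga|gb|gc")

  ## two-vs-rest and one-vs-rest categories
  al3 <- new_alignment(c(a1 = "AAAA", a2 = "AAAA", b1 = "AATA", b2 = "AATA",
                         c1 = "AATA", c2 = "AATA"), "a1")
  dv3 <- diagnostic_variants(call_variants(al3), gm)
  expect_identical(dv3$category, "one-vs-rest")  # ga alone vs gb+gc
  expect_error(diagnostic_variants(v, group_map("a1", "ga")), "absent|groups")
})

test_that("per-class identity counts gaps as differences", {
  feat <- gene_features("rbcL", "CDS", "+", 1, 100)
  r <- strrep("A", 120)
  s <- paste0(strrep("A", 50), "G", strrep("A", 69))  # one mismatch in class
  al <- new_alignment(c(r = r, s = s), "r")
  ri <- region_identity(al, feat)
  exon <- ri[ri$class == "exon", ]
  expect_equal(exon$mean_identity, 99.0)
  expect_identical(exon$n_sites, 100L)
  ## identical rows: 100% everywhere a class exists
  al2 <- new_alignment(c(r = r, s = r), "r")
  ri2 <- region_identity(al2, feat)
  expect_true(all(ri2$mean_identity[ri2$n_sites > 0] == 100))
})
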