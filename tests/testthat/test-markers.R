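test_that("digestion cuts at the enzyme offset and conserves length", {
  expect_identical(digest("AAAATCGAAAAA", "TaqI"), c(5L, 7L))
  expect_identical(digest("AAAAAAA", "TaqI"), 7L)            # zero cuts
  expect_identical(digest("AATCTAGAAA", "XbaI"), c(3L, 7L))
  ## sizes always sum to the product length
  set.seed(12)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "TCGA"), 60, TRUE), collapse = "")
    expect_identical(sum(digest(s, "TaqI")), nchar(s))
    expect_identical(sum(digest(revcomp(s), "TaqI")), nchar(s))
  }
})

test_that("reverse-complement digestion reverses fragments", {
  ## exact for a symmetric cutter; within the 2 bp stagger for TaqI
  sym <- enzyme_spec("Sym4", "GATC", 2)
  set.seed(13)
  for (i in 1:8) {
    s <- paste(sample(c("A", "C", "G", "T", "GATC"), 50, TRUE), collapse = "")
    expect_identical(digest(revcomp(s), sym), rev(digest(s, sym)))
  }
  s <- "AAAATCGAAAAA"
  a <- digest(s, "TaqI"); b <- digest(revcomp(s), "TaqI")
  expect_identical(length(a), length(b))
  expect_true(all(abs(rev(a) - b) <= 2))
})

test_that("in-silico PCR honours orientation, circularity and mismatches", {
  set.seed(5)
  t50 <- rnd_seq(50)
  fwd <- substr(t50, 1, 18)
  rev_p <- revcomp(substr(t50, 33, 50))
  a <- insilico_pcr(fwd, rev_p, t50)
  expect_true(a$amplified)
  expect_identical(a$size, 50L)
  expect_identical(a$product, t50)

  ## swapping primer roles finds the same product, reported on the top strand
  a_sw <- insilico_pcr(rev_p, fwd, t50)
  expect_identical(a_sw$product, t50)

  ## rotation so the amplicon spans the circular origin
  g2 <- plastome("c", paste0(substr(t50, 26, 50), substr(t50, 1, 25)))
  a2 <- insilico_pcr(fwd, rev_p, g2)
  expect_true(a2$amplified)
  expect_identical(a2$product, t50)

  ## absent site is a result, not an exception
  a3 <- insilico_pcr(strrep("G", 18), rev_p, t50)
  expect_false(a3$amplified)
  expect_match(a3$reason, "no binding site")

  ## primer mismatches are incorporated into the product
  fwd_mm <- fwd
  substr(fwd_mm, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(fwd, 5, 5))[1]
  a4 <- insilico_pcr(fwd_mm, rev_p, t50)
  expect_true(a4$amplified)
  expect_identical(substr(a4$product, 5, 5), substr(fwd_mm, 5, 5))
  expect_identical(a4$fwd_mismatches, 1L)

  ## a mismatched 3'-terminal base kills the binding site
  fwd_3p <- fwd
  substr(fwd_3p, 18, 18) <- setdiff(c("A", "C", "G", "T"), substr(fwd, 18, 18))[1]
  expect_false(insilico_pcr(fwd_3p, rev_p, t50)$amplified)

  ## two identical binding contexts produce an ambiguity error
  tdup <- paste0(t50, rnd_seq(20), t50)
  expect_error(insilico_pcr(fwd, rev_p, tdup), "ambiguous")
})

test_that("the hand-built dCAPS toy yields fragments [16,18] vs [34]", {
  tA <- paste0(strrep("A", 15), "TAG", "A", strrep("T", 15))
  tG <- paste0(strrep("A", 15), "TAG", "G", strrep("T", 15))
  al <- new_alignment(c(sA = tA, sB = tG), "sA")
  gm <- group_map(c("sA", "sB"), c("ga", "gb"))
  dv <- diagnostic_variants(call_variants(al), gm)
  d <- design_dcaps(al, dv[1, ], gm, enzymes = enzyme_panel()["TaqI"],
                    constraints = marker_constraints(product_range = c(25, 60)),
                    rules = relaxed_rules(length = c(15, 18)))
  i <- which(d$strand == "+")[1]
  expect_false(is.na(i))
  expect_identical(d$fwd[i], paste0(strrep("A", 15), "TCG"))
  expect_identical(d$introduced[i], 1L)
  expect_false(d$is_caps[i])
  fr <- d$fragments[[i]]
  expect_identical(sort(unname(fr[["ga"]])), c(16L, 18L))    # allele A cut
  expect_identical(unname(fr[["gb"]]), 34L)                  # allele G uncut
  ## self-consistency on the design templates
  val <- validate_marker(d[i, ], list(plastome("sA", tA, circular = FALSE),
                                      plastome("sB", tG, circular = FALSE)), gm)
  expect_true(val$verdict)
})

test_that("a pre-existing site degenerates to a flagged CAPS design", {
  set.seed(9)
  left <- rnd_seq(30); right <- rnd_seq(30)
  tA <- paste0(left, "TCG", "A", right)
  tG <- paste0(left, "TCG", "G", right)
  al <- new_alignment(c(x = tA, y = tG), "x")
  gm <- group_map(c("x", "y"), c("gx", "gy"))
  dv <- diagnostic_variants(call_variants(al), gm)
  d <- design_dcaps(al, dv[1, ], gm, enzymes = enzyme_panel()["TaqI"],
                    constraints = marker_constraints(product_range = c(40, 64)),
                    rules = relaxed_rules(length = c(18, 22)))
  expect_gte(nrow(d), 1L)
  expect_true(any(d$is_caps))
  expect_identical(unique(d$introduced[d$is_caps]), 0L)
})

test_that("InDel markers are designed from clean flanks and sized by group", {
  set.seed(9)
  ref <- rnd_seq(400)
  del <- paste0(substr(ref, 1, 190), substr(ref, 211, 400))   # 20 bp deletion
  alr <- plastmarker:::cpp_banded_align(ref, del, 50L, 1L, -2L, -5L, -1L)
  al <- new_alignment(c(r = alr$ref, s = alr$qry), "r")
  gm <- group_map(c("r", "s"), c("gr", "gs"))
  dv <- diagnostic_variants(call_variants(al), gm)
  mk <- design_indel_markers(al, dv, gm)
  expect_identical(mk$status[1], "ok")
  sz <- mk$sizes[[1]]
  expect_identical(abs(diff(range(unlist(sz)))), 20L)         # the InDel length
  expect_identical(mk$category[1], "one-vs-rest")

  ## a 4 bp InDel is below the resolvability threshold
  del4 <- paste0(substr(ref, 1, 190), substr(ref, 195, 400))
  alr4 <- plastmarker:::cpp_banded_align(ref, del4, 50L, 1L, -2L, -5L, -1L)
  al4 <- new_alignment(c(r = alr4$ref, s = alr4$qry), "r")
  dv4 <- diagnostic_variants(call_variants(al4), gm)
  mk4 <- design_indel_markers(al4, dv4, gm)
  expect_match(mk4$status[1], "resolvable")
})

test_that("marker validation fails on within-group inconsistency", {
  set.seed(10)
  base <- rnd_seq(300)
  del <- paste0(substr(base, 1, 140), substr(base, 161, 300))
  gm <- group_map(c("a1", "a2", "b1"), c("ga", "ga", "gb"))
  fwd <- substr(base, 90, 110)
  rev_p <- revcomp(substr(base, 230, 250))
  genomes_ok <- list(plastome("a1", base), plastome("a2", base),
                     plastome("b1", del))
  mk <- list(fwd = fwd, rev = rev_p)
  expect_true(validate_marker(mk, genomes_ok, gm)$verdict)
  ## one ga sample carries the deletion: inconsistent within group
  genomes_bad <- list(plastome("a1", base), plastome("a2", del),
                      plastome("b1", del))
  val <- validate_marker(mk, genomes_bad, gm)
  expect_false(val$verdict)
  expect_match(paste(val$failures, collapse = " "), "inconsistent")
  ## amplification failure names the sample
  genomes_na <- list(plastome("a1", base), plastome("a2", base),
                     plastome("b1", rnd_seq(300)))
  val2 <- validate_marker(mk, genomes_na, gm)
  expect_false(val2$verdict)
  expect_match(paste(val2$failures, collapse = " "), "b1")
})

test_that("designs on simulated species are allele-specific and validate", {
  fix <- sim_fixture()
  pl <- fix$sim$truth[fix$sim$truth$planted & fix$sim$truth$kind == "SNP", ][1, ]
  i <- which(fix$dv$pos == pl$pos & fix$dv$kind == "SNP")
  d <- design_dcaps(fix$al, fix$dv[i, ], fix$sim$groups, variants = fix$v)
  expect_gte(nrow(d), 1L)
  for (j in seq_len(nrow(d))) {
    fr <- d$fragments[[j]]
    ga <- d$group_allele[[j]]
    cut <- vapply(fr, length, integer(1)) > 1L
    ## exactly the groups carrying the cut allele are digested
    expect_identical(unname(cut), unname(ga == d$cut_allele[j]))
    ## fragments sum to the product size
    for (f in fr) expect_identical(sum(f), d$product_size[j])
    expect_true(validate_marker(d[j, ], fix$sim$genomes, fix$sim$groups)$verdict)
  }
})
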