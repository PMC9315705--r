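annotate_gene <- function(g, gene, start, end, strand = "+", kind = "CDS",
                          fid = gene) {
  f <- gene_features(gene, kind, strand, start, end, feature_id = fid)
  g$annotations <- if (is.null(g$annotations)) f else bind_features(g$annotations, f)
  g
}

test_that("shared single-copy gene extraction splices and filters", {
  set.seed(21)
  s1 <- rnd_seq(500); s2 <- rnd_seq(500); s3 <- rnd_seq(500)
  g1 <- annotate_gene(plastome("t1", s1), "rbcL", 10, 99)
  g1 <- annotate_gene(g1, "ndhF", c(200, 300), c(250, 340), strand = "-")
  g1 <- annotate_gene(g1, "rrnX", 400, 450, kind = "rRNA")
  g2 <- annotate_gene(plastome("t2", s2), "rbcL", 10, 99)
  g2 <- annotate_gene(g2, "ndhF", c(200, 300), c(250, 340), strand = "-")
  g3 <- annotate_gene(plastome("t3", s3), "rbcL", 10, 99)  # no ndhF

  gs <- extract_shared_genes(list(g1, g2, g3))
  expect_identical(names(gs), "rbcL")            # ndhF not shared, rRNA excluded
  expect_identical(gs$rbcL[["t1"]], substr(s1, 10, 99))

  ## minus-strand two-exon gene splices 3'-most part first, reverse-complemented
  gs2 <- extract_shared_genes(list(g1, g2))
  expect_identical(gs2$ndhF[["t1"]],
                   paste0(revcomp(substr(s1, 300, 340)),
                          revcomp(substr(s1, 200, 250))))

  ## IR-duplicated genes (two features sharing a name) are excluded
  g4 <- annotate_gene(plastome("t4", s1), "rbcL", 10, 99)
  g4 <- annotate_gene(g4, "rps19", 110, 150, fid = "rps19")
  g4 <- annotate_gene(g4, "rps19", 410, 450, fid = "rps19.ira")
  g5 <- annotate_gene(plastome("t5", s2), "rbcL", 10, 99)
  g5 <- annotate_gene(g5, "rps19", 110, 150)
  expect_identical(names(extract_shared_genes(list(g4, g5))), "rbcL")

  expect_error(extract_shared_genes(list(g1, plastome("bare", s2))), "bare")
})

test_that("supermatrix concatenation records partitions and taxon order", {
  set.seed(22)
  gs <- list(g1 = c(x = rnd_seq(30), y = rnd_seq(30), z = rnd_seq(30)),
             g2 = c(x = rnd_seq(60), y = rnd_seq(60), z = rnd_seq(60)))
  sm <- suppressWarnings(build_supermatrix(gs))   # random genes may contain stops
  expect_identical(nchar(sm$seqs[[1]]), 90L)
  expect_identical(sm$partitions$start, c(1L, 31L))
  expect_identical(sm$partitions$end, c(30L, 90L))
  ## permuted taxon order yields the identical matrix
  gs_perm <- lapply(gs, function(x) x[c(3, 1, 2)])
  expect_identical(suppressWarnings(build_supermatrix(gs_perm))$seqs, sm$seqs)
  ## internal stop codons warn but are retained
  gs_stop <- list(g1 = c(x = "ATGTAAACCAAACCC", y = "ATGTAAACCAAACCC",
                         z = "ATGTAAACCAAACCC"))
  expect_warning(build_supermatrix(gs_stop), "internal stop")
})

test_that("NJ recovers additive four-taxon distances exactly", {
  ## d(A,B)=2, d(C,D)=4, cross distances 6: the AB|CD split is additive
  d <- matrix(c(0, 2, 6, 6,
                2, 0, 6, 6,
                6, 6, 0, 4,
                6, 6, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- ape::nj(as.dist(d))
  expect_true(ape::is.monophyletic(ape::root(tr, "A"), c("C", "D")))
  ## our brute-force oracle agrees topologically
  bt <- bf_nj(as.dist(d))
  expect_identical(ape::dist.topo(ape::unroot(tr), ape::unroot(bt))[1], 0)
})

test_that("package NJ equals the brute-force Q-criterion oracle", {
  set.seed(23)
  for (i in 1:8) {
    nt <- sample(4:8, 1)
    ## random additive tree -> cophenetic distances, mild perturbation
    rt <- ape::rtree(nt, br = function(n) runif(n, 0.05, 1))
    d0 <- ape::cophenetic.phylo(rt)
    d0 <- d0[order(rownames(d0)), order(colnames(d0))]
    pert <- matrix(runif(nt * nt, 0, 0.01), nt, nt)
    pert <- (pert + t(pert)) / 2; diag(pert) <- 0
    d <- as.dist(d0 + pert)
    t1 <- ape::nj(d)
    t2 <- bf_nj(d)
    expect_identical(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
    ## additive distances (no perturbation) recover the generating topology
    t3 <- ape::nj(as.dist(d0))
    expect_identical(ape::dist.topo(ape::unroot(rt), ape::unroot(t3))[1], 0)
  }
})

test_that("bootstrap trees are seed-reproducible and order-invariant", {
  set.seed(24)
  base <- rnd_seq(400)
  mut <- function(s, k) {
    b <- chars(s); i <- sample(length(b), k)
    b[i] <- sample(c("A", "C", "G", "T"), k, TRUE); unchars(b)
  }
  anc_ab <- mut(base, 10); anc_cd <- mut(base, 10)
  seqs <- c(a = mut(anc_ab, 2), b = mut(anc_ab, 2),
            c = mut(anc_cd, 2), d = mut(anc_cd, 2), o = mut(base, 40))
  t1 <- nj_tree(seqs, "p-distance", bootstrap_n = 200, seed = 5, outgroup = "o")
  t2 <- nj_tree(seqs, "p-distance", bootstrap_n = 200, seed = 5, outgroup = "o")
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  t3 <- nj_tree(seqs[c(3, 5, 1, 4, 2)], "p-distance", bootstrap_n = 200,
                seed = 5, outgroup = "o")
  expect_identical(ape::dist.topo(ape::unroot(t1), ape::unroot(t3))[1], 0)
  expect_true(ape::is.monophyletic(t1, c("a", "b")))
  expect_true(ape::is.monophyletic(t1, c("c", "d")))
})

test_that("JC69 distances reject saturated pairs by name", {
  seqs <- c(x = strrep("A", 100), y = strrep("C", 100), z = strrep("G", 100))
  expect_error(nj_tree(seqs, "JC69", bootstrap_n = 0), "JC69.*x/y")
})
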