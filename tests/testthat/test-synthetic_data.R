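small_cfg <- function(...) {
  sim_config(lsc_len = 8300, ssc_len = 1250, ir_len = 2280, ...)
}

test_that("the same seed reproduces the simulation byte for byte", {
  a <- simulate_plastome_set(small_cfg(), seed = 11)
  b <- simulate_plastome_set(small_cfg(), seed = 11)
  expect_identical(lapply(a$genomes, `[[`, "sequence"),
                   lapply(b$genomes, `[[`, "sequence"))
  expect_identical(a$truth, b$truth)
  c <- simulate_plastome_set(small_cfg(), seed = 12)
  expect_false(identical(a$truth, c$truth))
})

test_that("the ancestor realises the configured quadripartite world", {
  cfg <- small_cfg()
  anc <- simulate_ancestor(cfg, seed = 6)
  qp <- detect_quadripartite(anc, min_ir_len = 500)
  expect_identical(qp$lsc_len, 8300L)
  expect_identical(qp$ssc_len, 1250L)
  expect_identical(qp$ir_len, 2280L)
  expect_identical(nchar(anc$sequence), 8300L + 1250L + 2L * 2280L)
  ## planted SSRs are recovered at their recorded positions
  ssr <- scan_ssrs(anc)
  ps <- attr(anc, "planted_ssrs")
  for (i in seq_len(nrow(ps))) {
    hit <- ssr[ssr$start == ps$start[i] & ssr$motif == ps$motif[i] &
                 ssr$copies == ps$copies[i], ]
    expect_identical(nrow(hit), 1L)
  }
})

test_that("per-species mutation budgets are hit exactly", {
  sim <- simulate_plastome_set(small_cfg(within_snps = c()), seed = 4)
  counts <- table(sim$truth$species[grepl("_1$", sim$truth$sample)],
                  sim$truth$kind[grepl("_1$", sim$truth$sample)])
  expect_identical(counts["spontaneum", "SNP"], 68L)
  expect_identical(counts["spontaneum", "InDel"], 43L)
  expect_identical(counts["robustum", "SNP"], 20L)
  expect_identical(counts["robustum", "InDel"], 12L)
  expect_identical(counts["sinense", "SNP"], 22L)
  expect_identical(counts["sinense", "InDel"], 10L)
  expect_identical(counts["barberi", "SNP"], 22L)
  expect_identical(counts["officinarum", "SNP"], 10L)
  expect_identical(counts["officinarum", "InDel"], 5L)
  ## the two fixed long insertions are present on the spontaneum branch
  sp <- sim$truth[sim$truth$species == "spontaneum" & sim$truth$kind == "InDel", ]
  ins_len <- nchar(sp$alt) - nchar(sp$ref)
  expect_true(all(c(27L, 50L) %in% ins_len))
})

test_that("zero budgets leave the genomes identical to the ancestor", {
  cfg <- small_cfg(branches = list(list(tips = "only", snps = 0L, indels = 0L)),
                   planted = list(), fixed_insertions = list(),
                   within_snps = c(), samples_per_species = 1L)
  sim <- simulate_plastome_set(cfg, seed = 2)
  expect_identical(sim$genomes$only_1$sequence, sim$ancestor$sequence)
  expect_identical(nrow(sim$truth), 0L)
})

test_that("IR mutations are mirrored so both repeats stay complementary", {
  cfg <- small_cfg(ir_snps = 2L, samples_per_species = 1L)
  sim <- simulate_plastome_set(cfg, seed = 8)
  any_ir <- FALSE
  for (g in sim$genomes) {
    qp <- tryCatch(detect_quadripartite(g, min_ir_len = 500),
                   error = function(e) NULL)
    expect_false(is.null(qp))
    cg <- canonicalize(g, qp)              # canonicalize asserts IRa == revcomp(IRb)
    if (qp$ir_len >= 2280L) any_ir <- TRUE
  }
  expect_true(any_ir)
  ## IR truth records come in mirrored pairs
  ir_truth <- sim$truth[sim$truth$pos > 8300 & sim$truth$pos <= 8300 + 2280 |
                          sim$truth$pos > 8300 + 2280 + 1250, ]
  expect_true(nrow(ir_truth) > 0)
  expect_identical(nrow(ir_truth) %% 2L, 0L)

  ## disabling the mirror breaks the complementarity invariant
  cfg2 <- small_cfg(ir_snps = 2L, mirror_ir = FALSE, samples_per_species = 1L)
  sim2 <- simulate_plastome_set(cfg2, seed = 8)
  broken <- vapply(sim2$genomes[-1], function(g) {
    qp <- tryCatch(detect_quadripartite(g, min_ir_len = 2280),
                   error = function(e) NULL)
    is.null(qp) || qp$ir_len < 2280L
  }, logical(1))
  expect_true(any(broken))
})

test_that("truth tables are consistent with exact re-diffing", {
  sim <- simulate_plastome_set(small_cfg(samples_per_species = 1L), seed = 9)
  ids <- c("reference", "officinarum_1", "spontaneum_1")
  al <- align_plastomes(sim$genomes[ids], "reference", band = 200)
  v <- call_variants(al)
  for (sid in ids[-1]) {
    expect_setequal(called_set(v, sid), truth_set(sim$truth, sid))
  }
})
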