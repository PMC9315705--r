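#' Configuration for the plastome-evolution simulator
#'
#' The defaults state the world this package is built for: a quadripartite
#' genome of roughly 141 kb (LSC 83,000, SSC 12,500, IR 22,800 bp), six
#' near-identical species groups whose SNP/InDel counts against the
#' reference match the published per-species budgets (spontaneum 68/43,
#' robustum 20/12, sinense and barberi 22/10 each, officinarum 10/5), two
#' long fixed insertions (27 and 50 bp) on the spontaneum branch, a
#' divergent outgroup, planted SSR motifs, and planted diagnostic variants
#' with clean flanks for marker design. Branch budgets are chosen so the
#' per-species path sums reproduce the published per-species counts while
#' every internal edge of the species tree carries shared mutations (which
#' is what makes the tree recoverable).
#'
#' Mutations are placed uniformly in the single-copy regions: the inverted
#' repeats are kept free of variation by default, which is the observed
#' state (IR diversity of exactly zero). Setting a nonzero `ir_snps` plants
#' additional IR substitutions that are mirrored between the two copies
#' (concerted evolution); `mirror_ir = FALSE` disables the mirroring for
#' negative tests.
#'
#' @param lsc_len,ssc_len,ir_len segment lengths in bp.
#' @param genes gene template (`gene_features` in final genome coordinates)
#'   or `NULL` for [default_gene_template()].
#' @param branches list of branch budget entries
#'   `list(tips = <species>, snps = <n>, indels = <n>)`; tips of the
#'   default tree `((spontaneum,((sinense,barberi),(officinarum,robustum))),outgroup)`.
#' @param samples_per_species samples emitted per species (default 2,
#'   mirroring the two-accessions-per-species validation panels).
#' @param within_snps named vector of per-sample private SNP counts
#'   (within-species polymorphism); defaults put mild polymorphism in the
#'   two wild species only.
#' @param indel_mean mean InDel length (geometric, `1 + rgeom`).
#' @param fixed_insertions named list of fixed insertion lengths per
#'   species tip.
#' @param ssr_motifs list of `list(motif=, copies=)` planted in single-copy
#'   spacers.
#' @param planted list of planted diagnostic events
#'   `list(kind = "SNP"|"InDel", tips = <clade>, len = <indel bp>)`, given
#'   clean conserved flanks wide enough for marker design.
#' @param ir_snps number of mirrored IR substitutions per species tip
#'   (default 0).
#' @param mirror_ir mirror IR mutations into the other copy (default TRUE).
#' @param include_reference emit the unmutated ancestor as sample
#'   `reference` in group `reference`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(lsc_len = 83000L, ssc_len = 12500L, ir_len = 22800L,
                       genes = NULL,
                       branches = default_branch_budgets(),
                       samples_per_species = 2L,
                       within_snps = c(spontaneum = 2L, robustum = 5L),
                       indel_mean = 3,
                       fixed_insertions = list(spontaneum = c(27L, 50L)),
                       ssr_motifs = list(list(motif = "A", copies = 12L),
                                         list(motif = "AT", copies = 8L),
                                         list(motif = "AAG", copies = 5L)),
                       planted = list(
                         list(kind = "SNP", tips = "robustum"),
                         list(kind = "InDel", tips = "spontaneum", len = 15L),
                         list(kind = "InDel", tips = "outgroup", len = 20L)),
                       ir_snps = 0L, mirror_ir = TRUE,
                       include_reference = TRUE) {
  stopifnot(lsc_len > ssc_len, ir_len > 0L)
  cfg <- list(lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
              ir_len = as.integer(ir_len), genes = genes,
              branches = branches,
              samples_per_species = as.integer(samples_per_species),
              within_snps = within_snps, indel_mean = indel_mean,
              fixed_insertions = fixed_insertions, ssr_motifs = ssr_motifs,
              planted = planted, ir_snps = as.integer(ir_snps),
              mirror_ir = isTRUE(mirror_ir),
              include_reference = isTRUE(include_reference))
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @details `default_branch_budgets()` allocates the published per-species
#'   SNP/InDel totals over the edges of the default species tree:
#'   e.g. officinarum = 2+3+5 = 10 SNPs along its root-to-tip path.
#' @export
default_branch_budgets <- function() {
  list(
    list(tips = c("sinense", "barberi", "officinarum", "robustum"),
         snps = 4L, indels = 1L),                      # deep Saccharum edge
    list(tips = c("sinense", "barberi"), snps = 14L, indels = 5L),
    list(tips = c("officinarum", "robustum"), snps = 4L, indels = 1L),
    list(tips = "sinense", snps = 4L, indels = 4L),    # path sum 22/10
    list(tips = "barberi", snps = 4L, indels = 4L),    # path sum 22/10
    list(tips = "officinarum", snps = 2L, indels = 3L),# path sum 10/5
    list(tips = "robustum", snps = 11L, indels = 10L), # path sum 20/12 with the planted SNP
    list(tips = "spontaneum", snps = 68L, indels = 42L), # 42 = 40 + 2 fixed long ins; 43 with the planted one
    list(tips = "outgroup", snps = 200L, indels = 29L)) # 30 with the planted one
}

#' @rdname sim_config
#' @export
default_species_tree <- function() {
  "((spontaneum,((sinense,barberi),(officinarum,robustum))),outgroup);"
}

#' A miniature plastid gene template
#'
#' Places a realistic set of named plastid genes (CDS, tRNA, rRNA) at fixed
#' fractional positions: intron-containing genes (`rps16`, `ycf3` with two
#' introns, `rps12`), the IR-resident `rps19` exactly 35 bp inside IRb, the
#' junction-spanning `ndhF` extending 29 bp into IRb, and IR-duplicated
#' rRNA/tRNA genes mirrored between the repeats. Gene lengths scale with
#' the segment lengths so scaled-down desk genomes stay consistent.
#'
#' @param lsc_len,ssc_len,ir_len segment lengths in bp.
#' @return a `gene_features` table in whole-genome coordinates.
#' @export
default_gene_template <- function(lsc_len, ssc_len, ir_len) {
  sc <- min(1, lsc_len / 83000)
  L <- function(x) max(20L, as.integer(round(x * sc)))
  at <- function(frac) as.integer(round(frac * lsc_len))
  rows <- list()
  add <- function(gene, kind, strand, starts, lens, fid = gene) {
    ends <- starts + lens - 1L
    rows[[length(rows) + 1L]] <<- gene_features(gene, kind, strand,
                                                starts, ends, feature_id = fid)
  }
  ## --- LSC ---------------------------------------------------------------
  add("psbA", "CDS", "-", at(0.004), L(1062))
  add("rps16", "CDS", "-", c(at(0.02), at(0.02) + L(230) + L(860)),
      c(L(230), L(40)))                                # one intron
  add("trnQ-UUG", "tRNA", "-", at(0.042), L(72))
  add("psbM", "CDS", "-", at(0.075), L(105))
  add("petN", "CDS", "+", at(0.09), L(90))
  add("trnC-GCA", "tRNA", "+", at(0.103), L(71))
  add("trnG-GCC", "tRNA", "+", at(0.12), L(71))
  add("trnM-CAU", "tRNA", "+", at(0.138), L(73))
  add("atpA", "CDS", "-", at(0.16), L(1524))
  add("atpF", "CDS", "-", c(at(0.185), at(0.185) + L(410) + L(700)),
      c(L(410), L(145)))
  add("ycf3", "CDS", "-",
      c(at(0.30), at(0.30) + L(153) + L(755), at(0.30) + L(153) + L(755) + L(228) + L(738)),
      c(L(153), L(228), L(124)))                       # two introns
  add("trnS-UGA", "tRNA", "-", at(0.335), L(88))
  add("psbD", "CDS", "+", at(0.35), L(1062))
  add("psbZ", "CDS", "+", at(0.385), L(189))
  add("trnR-UCU", "tRNA", "+", at(0.41), L(72))
  add("rps14", "CDS", "-", at(0.425), L(303))
  add("ndhC", "CDS", "-", at(0.50), L(363))
  add("trnV-UAC", "tRNA", "-", c(at(0.52), at(0.52) + L(39) + L(571)),
      c(L(39), L(37)))
  add("rbcL", "CDS", "+", at(0.56), L(1434))
  add("psaI", "CDS", "+", at(0.59), L(111))
  add("petA", "CDS", "+", at(0.615), L(963))
  add("psbJ", "CDS", "-", at(0.65), L(123))
  add("rpl33", "CDS", "+", at(0.675), L(201))
  add("rps18", "CDS", "+", at(0.70), L(306))
  add("petL", "CDS", "+", at(0.73), L(96))
  add("petG", "CDS", "+", at(0.74), L(114))
  add("rpoC1", "CDS", "-", at(0.80), L(2052))
  add("rps12", "CDS", "-", c(at(0.90), at(0.90) + L(232) + L(536)),
      c(L(232), L(114)))
  add("psbE", "CDS", "-", at(0.95), L(252))
  ## --- IRb (mirrored into IRa below) -------------------------------------
  irb0 <- lsc_len
  ir_genes <- list(
    list(gene = "rps19", kind = "CDS", strand = "+", start = 36L,
         len = min(279L, max(60L, as.integer(ir_len * 0.012)))),
    list(gene = "rrn16", kind = "rRNA", strand = "+",
         start = as.integer(ir_len * 0.30), len = L(1491)),
    list(gene = "trnA-UGC", kind = "tRNA", strand = "+",
         start = as.integer(ir_len * 0.42), len = L(73)),
    list(gene = "rrn23", kind = "rRNA", strand = "+",
         start = as.integer(ir_len * 0.55), len = L(2810)),
    list(gene = "rrn5", kind = "rRNA", strand = "+",
         start = as.integer(ir_len * 0.80), len = L(121)),
    list(gene = "trnN-GUU", kind = "tRNA", strand = "+",
         start = as.integer(ir_len * 0.88), len = L(72)))
  n_total <- lsc_len + 2L * ir_len + ssc_len
  for (g in ir_genes) {
    s <- irb0 + g$start
    e <- s + g$len - 1L
    add(g$gene, g$kind, g$strand, s, g$len, fid = g$gene)
    ## mirrored copy in IRa: local offset t maps to ir_len - t + 1
    s2 <- n_total - (e - irb0) + 1L
    e2 <- n_total - (s - irb0) + 1L
    add(g$gene, g$kind, if (g$strand == "+") "-" else "+",
        s2, e2 - s2 + 1L, fid = paste0(g$gene, ".ira"))
  }
  ## --- ndhF spans the IRb/SSC junction, 29 bp into IRb --------------------
  ssc0 <- lsc_len + ir_len
  ndhf_len <- min(2223L, max(120L, as.integer(ssc_len * 0.17)))
  add("ndhF", "CDS", "-", ssc0 - 28L, ndhf_len)
  ## --- SSC ----------------------------------------------------------------
  ats <- function(frac) ssc0 + as.integer(round(frac * ssc_len))
  add("rpl32", "CDS", "+", ats(0.35), max(20L, as.integer(174 * sc)))
  add("trnL-UAG", "tRNA", "+", ats(0.45), max(20L, as.integer(80 * sc)))
  add("ccsA", "CDS", "+", ats(0.55), max(20L, as.integer(960 * min(sc, ssc_len / 12500))))
  add("ndhD", "CDS", "-", ats(0.80), max(20L, as.integer(1503 * min(sc, ssc_len / 12500))))
  feat <- do.call(bind_features, rows)
  ## overlapping planted features are a configuration error
  o <- order(feat$start)
  fs <- feat[o, ]
  if (any(fs$start[-1L] <= cumsum_max_end(fs)[-nrow(fs)]))
    stop("gene template features overlap")
  feat
}

#' @noRd
cumsum_max_end <- function(fs) Reduce(max, fs$end, accumulate = TRUE)

#' Simulate the ancestral plastome
#'
#' Draws random single-copy and IR sequence, enforces IRa =
#' reverse-complement(IRb) by construction, blocks the four junction bases
#' so that maximal exact IR extension reproduces the configured segment
#' lengths, plants the configured gene features and SSR motifs, and
#' returns a canonical, annotated, structure-bearing [plastome()].
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (mandatory).
#' @return a [plastome()] with attribute `planted_ssrs` (data.frame of the
#'   planted motif runs).
#' @export
simulate_ancestor <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"), !missing(seed))
  set.seed(seed)
  Lc <- config$lsc_len; Sc <- config$ssc_len; Ic <- config$ir_len
  n <- Lc + 2L * Ic + Sc
  rnd <- function(k) sample(c("A", "C", "G", "T"), k, replace = TRUE)
  lsc <- rnd(Lc); irb <- rnd(Ic); ssc <- rnd(Sc)
  ## junction blockers: outward extension pairs LSC end with LSC start,
  ## inward extension pairs SSC start with SSC end
  comp1 <- function(x) comp_chars(x)[1L]
  if (lsc[Lc] == comp1(lsc[1L]))
    lsc[Lc] <- setdiff(c("A", "C", "G", "T"), comp1(lsc[1L]))[1L]
  if (ssc[1L] == comp1(ssc[Sc]))
    ssc[1L] <- setdiff(c("A", "C", "G", "T"), comp1(ssc[Sc]))[1L]
  seq_ch <- c(lsc, irb, ssc, rev(comp_chars(irb)))

  ## plant SSR motifs in fixed single-copy spacers, with run blockers
  planted_ssrs <- NULL
  if (length(config$ssr_motifs)) {
    slots <- as.integer(round(c(0.44, 0.46, 0.475, 0.485, 0.545) * Lc))
    rowsp <- list()
    for (i in seq_along(config$ssr_motifs)) {
      sm <- config$ssr_motifs[[i]]
      motif <- seq_chars(toupper(sm$motif))
      p <- length(motif)
      run <- rep(motif, sm$copies)
      st <- slots[((i - 1L) %% length(slots)) + 1L] + ((i - 1L) %/% length(slots)) * 60L
      en <- st + length(run) - 1L
      seq_ch[st:en] <- run
      ## block extension on both sides (period-p continuation)
      if (seq_ch[st - 1L] == seq_ch[st - 1L + p])
        seq_ch[st - 1L] <- setdiff(c("A", "C", "G", "T"), seq_ch[st - 1L + p])[1L]
      if (seq_ch[en + 1L] == seq_ch[en + 1L - p])
        seq_ch[en + 1L] <- setdiff(c("A", "C", "G", "T"), seq_ch[en + 1L - p])[1L]
      rowsp[[i]] <- data.frame(motif = sm$motif, copies = sm$copies,
                               start = st, end = en, stringsAsFactors = FALSE)
    }
    planted_ssrs <- do.call(rbind, rowsp)
    ## re-mirror IRa in case a blocker touched IR (it cannot, slots are LSC)
    seq_ch[(Lc + Ic + Sc + 1L):n] <- rev(comp_chars(seq_ch[(Lc + 1L):(Lc + Ic)]))
  }

  ## slots for planted diagnostic SNPs: a TCTAG context followed by G, so
  ## that one mutated allele (A) completes an XbaI site outright (CAPS) and
  ## a TaqI site with one introduced primer mismatch (dCAPS) -- the
  ## engineered analogue of the SNP contexts real dCAPS markers sit in
  n_snp_slots <- sum(vapply(config$planted, function(x)
    identical(x$kind, "SNP"), logical(1)))
  dcaps_slots <- integer(0)
  if (n_snp_slots > 0L) {
    fracs <- c(0.272, 0.632, 0.760, 0.812, 0.232)
    for (j in seq_len(n_snp_slots)) {
      pslot <- as.integer(round(fracs[((j - 1L) %% length(fracs)) + 1L] * Lc))
      seq_ch[(pslot - 5L):(pslot - 1L)] <- c("T", "C", "T", "A", "G")
      seq_ch[pslot] <- "G"
      dcaps_slots <- c(dcaps_slots, pslot)
    }
  }
  genes <- config$genes %||% default_gene_template(Lc, Sc, Ic)
  qp <- list(lsc_len = Lc, ssc_len = Sc, ir_len = Ic, lsc_start = 1L,
             genome_len = n, lsc = c(1L, Lc), irb = c(Lc + 1L, Lc + Ic),
             ssc = c(Lc + Ic + 1L, Lc + Ic + Sc), ira = c(Lc + Ic + Sc + 1L, n),
             orientation_note = "synthetic canonical orientation")
  class(qp) <- "quadripartite"
  g <- plastome("reference", chars_seq(seq_ch), species = "reference",
                annotations = genes, structure = qp)
  attr(g, "planted_ssrs") <- planted_ssrs
  attr(g, "dcaps_slots") <- dcaps_slots
  g
}

#' Evolve a sample set from the ancestor
#'
#' Walks the species tree implied by the branch budget list: every branch
#' receives its budgeted number of substitutions (transition:transversion
#' 2:1) and InDels (lengths `1 + Geometric`, mean `indel_mean`, insertions
#' and deletions equally likely), placed uniformly in the single-copy
#' regions outside forbidden zones (planted SSRs, planted diagnostic
#' flanks, junction bases, and a padding margin around every previous
#' event so that events never interact). Mutations on internal branches
#' are shared by all tip species of that clade; planted diagnostic events
#' get wide conserved flanks so markers can be designed on them.
#' IR substitutions (if requested) are mirrored into the opposite repeat
#' unless `mirror_ir` is off.
#'
#' @param ancestor output of [simulate_ancestor()].
#' @param config the same [sim_config()].
#' @param seed RNG seed (mandatory; a full run is byte-reproducible).
#' @return list of class `sim_result`: `genomes` (list of [plastome()]),
#'   `groups` ([group_map()]), `truth` (data.frame: sample, species, kind,
#'   pos, ref, alt, branch, planted flag -- VCF-style anchored,
#'   left-aligned, in reference coordinates), `tree` (true topology,
#'   newick), `ancestor`.
#' @export
evolve <- function(ancestor, config, seed) {
  stopifnot(inherits(config, "sim_config"), !missing(seed))
  set.seed(seed + 1L)
  refseq <- ancestor$sequence
  ref_ch <- seq_chars(refseq)
  n <- length(ref_ch)
  qp <- ancestor$structure
  species <- unique(unlist(lapply(config$branches, `[[`, "tips")))

  ## forbidden zones for random placement
  occupied <- logical(n)
  occupied[c(1L, qp$lsc[2L], qp$ssc[1L], qp$ssc[2L])] <- TRUE
  block <- function(from, to) occupied[max(1L, from):min(n, to)] <<- TRUE
  block(qp$lsc[2L] - 3L, qp$irb[1L] + 3L)   # junction margins
  block(qp$irb[2L] - 3L, qp$ssc[1L] + 3L)
  block(qp$ssc[2L] - 3L, qp$ira[1L] + 3L)
  block(1L, 4L); block(n - 3L, n)
  ps <- attr(ancestor, "planted_ssrs")
  if (!is.null(ps)) for (i in seq_len(nrow(ps))) block(ps$start[i] - 6L, ps$end[i] + 6L)

  sc_pos <- c(qp$lsc[1L]:qp$lsc[2L], qp$ssc[1L]:qp$ssc[2L])
  draw_site <- function(pad) {
    repeat {
      p <- sample(sc_pos, 1L)
      if (!any(occupied[max(1L, p - pad):min(n, p + pad)])) {
        block(p - pad, p + pad)
        return(p)
      }
    }
  }
  mutate_base <- function(b) {
    ts <- c(A = "G", G = "A", C = "T", T = "C")
    tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
    if (stats::runif(1) < 2 / 3) ts[[b]] else sample(tv[[b]], 1L)
  }

  ## place events branch by branch; planted diagnostics first (wide flanks)
  events <- list()
  add_event <- function(kind, pos, ref, alt, tips, branch, planted) {
    events[[length(events) + 1L]] <<- list(kind = kind, pos = pos, ref = ref,
                                           alt = alt, tips = tips,
                                           branch = branch, planted = planted)
  }
  branch_label <- function(tips) paste(tips, collapse = "+")
  slots <- attr(ancestor, "dcaps_slots") %||% integer(0)
  slot_i <- 0L
  for (pl in config$planted) {
    tips <- pl$tips
    if (identical(pl$kind, "SNP")) {
      slot_i <- slot_i + 1L
      if (slot_i <= length(slots)) {
        p <- slots[slot_i]
        block(p - 185L, p + 185L)
        add_event("SNP", p, ref_ch[p], "A", tips, branch_label(tips), TRUE)
      } else {
        p <- draw_site(pad = 180L)
        add_event("SNP", p, ref_ch[p], mutate_base(ref_ch[p]), tips,
                  branch_label(tips), TRUE)
      }
    } else {
      len <- pl$len %||% 15L
      p <- draw_site(pad = 180L + len)
      ## deletion of len bases after anchor p
      add_event("InDel", p, chars_seq(ref_ch[p:(p + len)]), ref_ch[p], tips,
                branch_label(tips), TRUE)
    }
  }
  for (br in config$branches) {
    lab <- branch_label(br$tips)
    nsnp <- br$snps %||% 0L
    for (k in seq_len(nsnp)) {
      p <- draw_site(pad = 2L)
      add_event("SNP", p, ref_ch[p], mutate_base(ref_ch[p]), br$tips, lab, FALSE)
    }
    nind <- br$indels %||% 0L
    fixed <- if (length(br$tips) == 1L)
      config$fixed_insertions[[br$tips]] %||% integer(0) else integer(0)
    lens <- c(fixed,
              1L + stats::rgeom(max(0L, nind - length(fixed)),
                                prob = 1 / config$indel_mean))
    is_fixed <- c(rep(TRUE, length(fixed)), rep(FALSE, length(lens) - length(fixed)))
    for (li in seq_along(lens)) {
      len <- max(1L, as.integer(lens[li]))
      ## configured fixed lengths model the observed long insertions and are
      ## therefore always insertions; random events go either way
      is_ins <- is_fixed[li] || stats::runif(1) < 0.5
      p <- draw_site(pad = len + 8L)
      if (is_ins) {
        ins <- chars_seq(sample(c("A", "C", "G", "T"), len, replace = TRUE))
        add_event("InDel", p, ref_ch[p], paste0(ref_ch[p], ins), br$tips, lab, FALSE)
      } else {
        add_event("InDel", p, chars_seq(ref_ch[p:(p + len)]), ref_ch[p],
                  br$tips, lab, FALSE)
      }
    }
    ## mirrored IR substitutions (tip branches only)
    if (config$ir_snps > 0L && length(br$tips) == 1L) {
      ir_pos <- (qp$irb[1L] + 10L):(qp$irb[2L] - 10L)
      for (k in seq_len(config$ir_snps)) {
        repeat {
          p <- sample(ir_pos, 1L)
          if (!any(occupied[(p - 2L):(p + 2L)])) { block(p - 2L, p + 2L); break }
        }
        add_event("SNP_IR", p, ref_ch[p], mutate_base(ref_ch[p]), br$tips,
                  branch_label(br$tips), FALSE)
      }
    }
  }

  ## normalise events to VCF-style left-aligned records (truth table form)
  norm_event <- function(e) {
    if (e$kind == "SNP" || e$kind == "SNP_IR")
      return(list(pos = e$pos, ref = e$ref, alt = e$alt))
    if (nchar(e$ref) > nchar(e$alt)) {      # deletion: ref = anchor + deleted
      left_align_indel(e$pos, substr(e$ref, 2L, nchar(e$ref)),
                       refseq, insertion = FALSE)
    } else {                                # insertion after anchor
      left_align_indel(e$pos, substr(e$alt, 2L, nchar(e$alt)), refseq,
                       insertion = TRUE)
    }
  }

  ## per-sample private SNPs
  sample_ids <- unlist(lapply(species, function(sp)
    sprintf("%s_%d", sp, seq_len(config$samples_per_species))))
  sample_species <- rep(species, each = config$samples_per_species)
  private <- list()
  for (i in seq_along(sample_ids)) {
    k <- config$within_snps[sample_species[i]]
    k <- if (length(k) != 1L || is.na(k)) 0L else as.integer(k)
    for (j in seq_len(k)) {
      p <- draw_site(pad = 2L)
      private[[length(private) + 1L]] <-
        list(kind = "SNP", pos = p, ref = ref_ch[p],
             alt = mutate_base(ref_ch[p]), tips = sample_ids[i],
             branch = sample_ids[i], planted = FALSE, is_private = TRUE)
    }
  }

  ## apply events to each sample; truth rows along the way
  truth <- list()
  genomes <- list()
  mirror_pos <- function(p) {
    ## IRb offset t pairs with IRa offset ir_len - t + 1
    t <- p - qp$irb[1L] + 1L
    qp$ira[1L] + (qp$ir_len - t + 1L) - 1L
  }
  for (i in seq_along(sample_ids)) {
    sid <- sample_ids[i]; sp <- sample_species[i]
    evs <- c(Filter(function(e) sp %in% e$tips, events),
             Filter(function(e) identical(e$tips, sid), private))
    ## expand mirrored IR substitutions into two physical edits
    phys <- list()
    for (e in evs) {
      phys[[length(phys) + 1L]] <- e
      if (e$kind == "SNP_IR" && config$mirror_ir) {
        phys[[length(phys) + 1L]] <-
          list(kind = "SNP_IR", pos = mirror_pos(e$pos),
               ref = comp_chars(e$ref), alt = comp_chars(e$alt),
               tips = e$tips, branch = e$branch, planted = e$planted)
      }
    }
    ord <- order(vapply(phys, `[[`, 1L, "pos"), decreasing = TRUE)
    ch <- ref_ch
    for (e in phys[ord]) {
      if (startsWith(e$kind, "SNP")) {
        ch[e$pos] <- e$alt
      } else if (nchar(e$ref) > nchar(e$alt)) {
        del <- (e$pos + 1L):(e$pos + nchar(e$ref) - 1L)
        ch <- ch[-del]
      } else {
        ins <- seq_chars(substr(e$alt, 2L, nchar(e$alt)))
        ch <- append(ch, ins, after = e$pos)
      }
    }
    genomes[[sid]] <- plastome(sid, chars_seq(ch), species = sp,
                               circular = TRUE)
    for (e in phys) {
      nm <- norm_event(e)
      truth[[length(truth) + 1L]] <-
        data.frame(sample = sid, species = sp,
                   kind = ifelse(startsWith(e$kind, "SNP"), "SNP", "InDel"),
                   pos = nm$pos, ref = nm$ref, alt = nm$alt,
                   branch = e$branch, planted = e$planted,
                   stringsAsFactors = FALSE)
    }
  }
  if (config$include_reference) {
    genomes <- c(list(reference = ancestor), genomes)
    sample_ids <- c("reference", sample_ids)
    sample_species <- c("reference", sample_species)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample = character(0), species = character(0),
               kind = character(0), pos = integer(0), ref = character(0),
               alt = character(0), branch = character(0), planted = logical(0))
  truth <- truth[order(truth$sample, truth$pos), ]
  rownames(truth) <- NULL
  res <- list(genomes = genomes,
              groups = group_map(sample_ids, sample_species),
              truth = truth, tree = default_species_tree(),
              ancestor = ancestor)
  class(res) <- "sim_result"
  res
}

#' One-call simulation convenience wrapper
#' @param config a [sim_config()].
#' @param seed RNG seed driving both the ancestor and the evolution.
#' @return a `sim_result` (see [evolve()]).
#' @export
simulate_plastome_set <- function(config = sim_config(), seed) {
  anc <- simulate_ancestor(config, seed)
  evolve(anc, config, seed)
}
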