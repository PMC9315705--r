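#' Primer acceptance rules
#'
#' A lightweight, documented rule set standing in for full thermodynamic
#' primer design: length bounds, GC content, Wallace-rule melting
#' temperature (`2(A+T) + 4(G+C)`) and a homopolymer cap. Product sizes --
#' the quantity markers are scored on -- do not depend on the Tm model.
#'
#' @param length allowed primer lengths (bp).
#' @param gc allowed GC fraction range.
#' @param tm allowed Wallace Tm range (degrees C).
#' @param max_homopolymer longest allowed single-base run.
#' @return list of class `primer_rules`.
#' @export
primer_rules <- function(length = c(18L, 26L), gc = c(0.30, 0.70),
                         tm = c(50, 68), max_homopolymer = 5L) {
  structure(list(length = as.integer(length), gc = gc, tm = tm,
                 max_homopolymer = as.integer(max_homopolymer)),
            class = "primer_rules")
}

#' @rdname primer_rules
#' @details `relaxed_rules()` keeps only the length bounds; it exists for
#'   desk-scale toy constructs whose flanks (e.g. long homopolymers) could
#'   never satisfy field rules.
#' @export
relaxed_rules <- function(length = c(18L, 26L)) {
  primer_rules(length = length, gc = c(0, 1), tm = c(-Inf, Inf),
               max_homopolymer = .Machine$integer.max)
}

#' @noRd
check_primer <- function(seq, rules) {
  l <- nchar(seq)
  if (l < rules$length[1L] || l > rules$length[2L]) return("length out of range")
  g <- gc_fraction(seq)
  if (g < rules$gc[1L] || g > rules$gc[2L]) return("GC content out of range")
  t <- wallace_tm(seq)
  if (t < rules$tm[1L] || t > rules$tm[2L]) return("Tm out of range")
  if (max_homopolymer(seq) > rules$max_homopolymer) return("homopolymer too long")
  NULL
}

#' Marker design constraints
#'
#' @param product_range allowed PCR product size range in bp.
#' @param min_size_diff smallest band-size difference resolvable on a
#'   2--3% agarose gel (10 bp).
#' @param max_mismatch mismatches tolerated per primer during in-silico
#'   validation (designed dCAPS primers deliberately carry one).
#' @return list of class `marker_constraints`.
#' @export
marker_constraints <- function(product_range = c(100L, 300L),
                               min_size_diff = 10L, max_mismatch = 2L) {
  structure(list(product_range = as.integer(product_range),
                 min_size_diff = as.integer(min_size_diff),
                 max_mismatch = as.integer(max_mismatch)),
            class = "marker_constraints")
}

## Reference positions safe to put a primer on: no called variant footprint,
## no gap or N in any aligned row.
#' @noRd
conserved_mask <- function(aln, variants) {
  m <- alignment_matrix(aln)
  refpos <- aln$col_to_ref
  R <- max(refpos)
  ok_col <- colSums(m == "-" | m == "N") == 0L
  mask <- rep(TRUE, R)
  bad_ref <- unique(refpos[!ok_col])
  mask[bad_ref[bad_ref >= 1L]] <- FALSE
  ## insertion columns poison the reference base they follow
  ins_cols <- which(colSums(m == "-") > 0L & refpos >= 1L)
  for (i in seq_len(nrow(variants))) {
    fp <- variants$pos[i]:(variants$pos[i] + nchar(variants$ref[i]) - 1L)
    ## one base of slack around InDels so a primer never abuts a gap
    if (variants$kind[i] == "InDel") fp <- c(fp, max(fp) + 1L)
    mask[fp[fp <= R]] <- FALSE
  }
  mask
}

## First acceptable primer near a target. side "left": top-strand primer
## with 3' end scanning leftward from `near`; side "right": bottom-strand
## primer whose top-strand interval starts at `near` scanning rightward.
## Returns list(start, end, seq) in top-strand coordinates or NULL.
#' @noRd
find_flank_primer <- function(refseq, mask, side, near, rules,
                              search_span = 150L, end_range = NULL) {
  n <- nchar(refseq)
  ## longest allowed primer first: with the 3' end pinned, longer means
  ## more specific
  lens <- rev(rules$length[1L]:rules$length[2L])
  for (d in 0:search_span) {
    if (side == "left") {
      e <- near - d
      if (e < min(lens)) break
      for (l in lens) {
        s <- e - l + 1L
        if (s < 1L) next
        if (!all(mask[s:e])) next
        pr <- substr(refseq, s, e)
        if (is.null(check_primer(pr, rules)))
          return(list(start = s, end = e, seq = pr))
      }
    } else {
      s <- near + d
      for (l in lens) {
        e <- s + l - 1L
        if (e > n) next
        ## constrain the 3'-proximal end so the product lands in range
        if (!is.null(end_range) && (e < end_range[1L] || e > end_range[2L])) next
        if (!all(mask[s:e])) next
        pr <- revcomp(substr(refseq, s, e))
        if (is.null(check_primer(pr, rules)))
          return(list(start = s, end = e, seq = pr))
      }
      if (near + d + min(lens) - 1L > n) break
    }
  }
  NULL
}

## are two band patterns distinguishable on a gel?
#' @noRd
band_patterns_distinct <- function(a, b, min_diff) {
  a <- sort(a); b <- sort(b)
  unmatched <- function(x, y)
    any(vapply(x, function(v) min(abs(y - v)) >= min_diff, logical(1)))
  unmatched(a, b) || unmatched(b, a)
}

#' @noRd
group_representatives <- function(aln, groups) {
  ids <- names(aln$seqs)
  gm <- groups[groups$sample %in% ids, ]
  reps <- vapply(split(gm$sample, gm$group), `[`, character(1), 1L)
  reps[groups_of(groups)[groups_of(groups) %in% names(reps)]]
}

#' @noRd
category_from_sizes <- function(sizes) {
  cells <- split(names(sizes), unname(sizes))
  if (length(cells) >= 3L) "three-way"
  else if (min(lengths(cells)) == 1L) "one-vs-rest" else "two-vs-rest"
}

#' Design InDel markers from diagnostic variants
#'
#' For every diagnostic InDel whose allele lengths are resolvable on a gel,
#' primers are placed in flanking sequence conserved across all samples (no
#' variant, gap or N under a primer) so the product size difference between
#' groups equals the InDel length. Expected sizes per group are computed by
#' [insilico_pcr()] on one representative genome per group.
#'
#' @param aln the `plast_alignment` the variants were called from.
#' @param diagnostics a `diagnostic_table` (see [diagnostic_variants()]).
#' @param groups the [group_map()].
#' @param constraints a [marker_constraints()].
#' @param rules a [primer_rules()].
#' @param variants variant table used to define conserved flanks (defaults
#'   to `diagnostics`; pass the full call set when available).
#' @return data.frame of class `indel_marker_table`: one row per attempted
#'   design with `id`, `pos`, `locus`, `fwd`, `rev`, `category`, `status`
#'   (`"ok"` or a failure reason) and a list column `sizes` of per-group
#'   product sizes.
#' @export
design_indel_markers <- function(aln, diagnostics, groups,
                                 constraints = marker_constraints(),
                                 rules = primer_rules(),
                                 variants = diagnostics) {
  idx <- which(diagnostics$kind == "InDel")
  refseq <- degap(aln, aln$ref_id)
  mask <- conserved_mask(aln, variants)
  reps <- group_representatives(aln, groups)
  templates <- lapply(reps, function(id)
    plastome(id, degap(aln, id), circular = TRUE))
  rows <- lapply(seq_along(idx), function(ii) {
    v <- diagnostics[idx[ii], ]
    fail <- function(reason)
      data.frame(id = sprintf("Id%02d", ii), pos = v$pos,
                 locus = v$locus %||% NA_character_,
                 fwd = NA_character_, rev = NA_character_,
                 category = NA_character_, status = reason,
                 stringsAsFactors = FALSE)
    alleles <- c(v$ref, strsplit(v$alt, ",")[[1L]])
    lens <- nchar(alleles)
    if (min(dist(lens)) < constraints$min_size_diff) {
      out <- fail("InDel shorter than resolvable size difference")
      out$sizes <- list(NULL)
      return(out)
    }
    fp_end <- v$pos + nchar(v$ref) - 1L
    fwd <- find_flank_primer(refseq, mask, "left", v$pos, rules)
    if (is.null(fwd)) {
      out <- fail("no conserved forward flank"); out$sizes <- list(NULL); return(out)
    }
    ## reverse primer: first conserved site giving a product in range
    rev_pr <- NULL
    for (s in (fp_end + 1L):(fwd$start + constraints$product_range[2L] - rules$length[1L])) {
      cand <- find_flank_primer(refseq, mask, "right", s, rules, search_span = 0L)
      if (is.null(cand)) next
      size <- cand$end - fwd$start + 1L
      if (size >= constraints$product_range[1L] &&
          size <= constraints$product_range[2L]) { rev_pr <- cand; break }
      if (size > constraints$product_range[2L]) break
    }
    if (is.null(rev_pr)) {
      out <- fail("no conserved reverse flank in product range")
      out$sizes <- list(NULL); return(out)
    }
    sizes <- vapply(templates, function(tp) {
      a <- tryCatch(insilico_pcr(fwd$seq, rev_pr$seq, tp,
                                 max_mismatch = constraints$max_mismatch),
                    error = function(e) list(amplified = FALSE))
      if (a$amplified) a$size else NA_integer_
    }, integer(1))
    if (anyNA(sizes)) {
      out <- fail("amplification failure on a representative")
      out$sizes <- list(sizes); return(out)
    }
    usz <- unique(sizes)
    if (length(usz) < 2L || min(dist(usz)) < constraints$min_size_diff) {
      out <- fail("product sizes not resolvable between groups")
      out$sizes <- list(sizes); return(out)
    }
    out <- data.frame(id = sprintf("Id%02d", ii), pos = v$pos,
                      locus = v$locus %||% NA_character_,
                      fwd = fwd$seq, rev = rev_pr$seq,
                      category = category_from_sizes(sizes), status = "ok",
                      stringsAsFactors = FALSE)
    out$sizes <- list(sizes)
    out
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), pos = integer(0), locus = character(0),
               fwd = character(0), rev = character(0), category = character(0),
               status = character(0))
  class(out) <- c("indel_marker_table", "data.frame")
  out
}

#' Design dCAPS markers for a diagnostic SNP
#'
#' For each enzyme, strand, and placement of the recognition site over the
#' SNP, tries to build a mismatch primer whose 3' terminus sits one base
#' before the SNP and whose introduced substitutions (at most
#' `max_introduced`, never the 3'-terminal base) complete the recognition
#' site for exactly one allele. The primer is paired with an opposing
#' primer in conserved flank, and every candidate is verified by
#' [insilico_pcr()] plus [digest()] on one representative per group; only
#' designs whose per-allele band patterns differ by at least the
#' resolvability threshold are emitted. A placement needing zero introduced
#' mismatches is a plain CAPS marker and is flagged as such.
#'
#' @param aln the `plast_alignment`.
#' @param snp one row of a `diagnostic_table` with `kind == "SNP"` (or any
#'   variant row with a biallelic call set).
#' @param groups the [group_map()].
#' @param enzymes list of [enzyme_spec()] (default: shipped TaqI + XbaI
#'   panel).
#' @param max_introduced maximum introduced primer mismatches (default 1).
#' @param constraints a [marker_constraints()].
#' @param rules a [primer_rules()].
#' @param variants variant table used to define conserved flanks (defaults
#'   to the single SNP row; pass the full call set when available).
#' @return data.frame of class `dcaps_table`, one row per emitted design:
#'   `id`, `enzyme`, `strand`, `pos`, `cut_allele` (on the reference top
#'   strand), `fwd` (the dCAPS/mismatch primer), `rev`, `introduced`,
#'   `is_caps`, `product_size`, plus list columns `fragments` (per-group
#'   band patterns) and `group_allele`. When nothing can be designed the
#'   table is empty and carries per-enzyme failure reasons in attribute
#'   `failures`.
#' @export
design_dcaps <- function(aln, snp, groups, enzymes = enzyme_panel(),
                         max_introduced = 1L,
                         constraints = marker_constraints(),
                         rules = primer_rules(), variants = snp) {
  stopifnot(nrow(snp) == 1L)
  calls <- attr(snp, "calls")
  if (is.null(calls)) stop("snp must carry a call matrix (a diagnostic_table row)")
  check_group_map(groups, colnames(calls))
  gm <- stats::setNames(groups$group, groups$sample)[colnames(calls)]
  per_group <- vapply(split(calls[1L, ], gm), function(a) unique(a)[1L], character(1))
  alleles <- sort(unique(per_group))
  if (length(alleles) != 2L)
    stop("dCAPS design requires a biallelic SNP across the tested groups")
  refseq <- degap(aln, aln$ref_id)
  n <- nchar(refseq)
  ## primers must avoid every variant, not just the assayed SNP; pass the
  ## full call set via `variants` when designing from a larger table
  mask <- conserved_mask(aln, variants)
  reps <- group_representatives(aln, groups)
  templates <- lapply(reps, function(id)
    plastome(id, degap(aln, id), circular = TRUE))
  pos <- snp$pos

  designs <- list()
  failures <- character(0)
  kid <- 0L
  for (enz in enzymes) {
    enz_fail <- character(0)
    k <- nchar(enz$site)
    site <- seq_chars(enz$site)
    for (strand in c("+", "-")) {
      if (strand == "+") {
        ctx <- refseq; m2 <- mask; p <- pos
        all_top <- alleles
      } else {
        ctx <- revcomp(refseq); m2 <- rev(mask); p <- n - pos + 1L
        all_top <- comp_chars(alleles)
      }
      ctx_ch <- seq_chars(ctx)
      for (q in (p - k + 1L):p) {
        if (q < 1L || q + k - 1L > n) next
        req_at_p <- site[p - q + 1L]
        if (!req_at_p %in% all_top) next
        cut_allele_ctx <- req_at_p
        other <- setdiff(all_top, req_at_p)
        if (length(other) != 1L) next      # site matches both alleles: no assay
        ## downstream site bases (beyond the SNP) must already match and be
        ## conserved -- the primer cannot reach them
        dn <- if (q + k - 1L > p) (p + 1L):(q + k - 1L) else integer(0)
        if (length(dn)) {
          if (!all(ctx_ch[dn] == site[dn - q + 1L])) { enz_fail <- c(enz_fail, "site bases beyond SNP absent"); next }
          if (!all(m2[dn])) { enz_fail <- c(enz_fail, "site bases beyond SNP not conserved"); next }
        }
        ## upstream site bases fall under the primer; mismatches are introduced
        up <- if (q <= p - 1L) q:(p - 1L) else integer(0)
        introduced <- up[ctx_ch[up] != site[up - q + 1L]]
        if (length(introduced) > max_introduced) { enz_fail <- c(enz_fail, "too many introduced mismatches"); next }
        if ((p - 1L) %in% introduced) { enz_fail <- c(enz_fail, "introduced mismatch at 3' terminus"); next }
        ## build the mismatch primer: 3' end one base before the SNP,
        ## longest allowed length first
        found <- FALSE
        for (l in rev(rules$length[1L]:rules$length[2L])) {
          s0 <- p - l
          if (s0 < 1L || s0 > q) next      # primer must reach the site start
          reg <- s0:(p - 1L)
          if (!all(m2[reg])) next
          pr <- ctx_ch[reg]
          pr[up - s0 + 1L] <- site[up - q + 1L]
          pr <- chars_seq(pr)
          if (!is.null(check_primer(pr, rules))) next
          opp <- find_flank_primer(ctx, m2, "right", max(p, q + k - 1L) + 1L,
                                   rules,
                                   search_span = constraints$product_range[2L],
                                   end_range = s0 + constraints$product_range - 1L)
          if (is.null(opp)) break
          size <- opp$end - s0 + 1L
          ## verify on one representative per group
          res <- lapply(templates, function(tp)
            tryCatch(insilico_pcr(pr, opp$seq, tp,
                                  max_mismatch = constraints$max_mismatch),
                     error = function(e)
                       list(amplified = FALSE, reason = conditionMessage(e))))
          if (!all(vapply(res, `[[`, logical(1), "amplified"))) { enz_fail <- c(enz_fail, "amplification failure"); break }
          frags <- lapply(res, function(a) digest(a, enz))
          names(frags) <- names(templates)
          ## allele specificity: the site must sit in the product of exactly
          ## the cut allele's groups
          cut_allele_top <- if (strand == "+") cut_allele_ctx else comp_chars(cut_allele_ctx)
          grp_allele <- per_group[names(templates)]
          is_cut_grp <- grp_allele == cut_allele_top
          cut_ok <- vapply(seq_along(frags), function(i) {
            if (is_cut_grp[i]) length(frags[[i]]) > 1L else length(frags[[i]]) == 1L
          }, logical(1))
          if (!all(cut_ok)) { enz_fail <- c(enz_fail, "digest pattern not allele-specific"); break }
          pat_cut <- frags[[which(is_cut_grp)[1L]]]
          pat_uncut <- frags[[which(!is_cut_grp)[1L]]]
          if (!band_patterns_distinct(pat_cut, pat_uncut, constraints$min_size_diff)) {
            enz_fail <- c(enz_fail, "band patterns not resolvable"); break
          }
          kid <- kid + 1L
          row <- data.frame(id = sprintf("d%02d", kid), enzyme = enz$name,
                            strand = strand, pos = pos,
                            cut_allele = cut_allele_top,
                            fwd = pr, rev = opp$seq,
                            introduced = length(introduced),
                            is_caps = length(introduced) == 0L,
                            product_size = res[[1L]]$size,
                            stringsAsFactors = FALSE)
          row$fragments <- list(frags)
          row$group_allele <- list(grp_allele)
          designs[[length(designs) + 1L]] <- row
          found <- TRUE
          break
        }
        if (!found && !length(enz_fail)) enz_fail <- c(enz_fail, "no primer satisfies rules/product range")
      }
    }
    if (!length(designs)) failures[enz$name] <- paste(unique(enz_fail), collapse = "; ")
  }
  out <- if (length(designs)) do.call(rbind, designs) else
    data.frame(id = character(0), enzyme = character(0), strand = character(0),
               pos = integer(0), cut_allele = character(0), fwd = character(0),
               rev = character(0), introduced = integer(0), is_caps = logical(0),
               product_size = integer(0))
  attr(out, "failures") <- failures
  class(out) <- c("dcaps_table", "data.frame")
  out
}

#' Validate a marker on a genome panel
#'
#' Runs the marker's PCR (and digestion, for dCAPS markers) on every
#' genome and checks that the predicted band pattern is constant within
#' groups and distinguishable (by at least the resolvability threshold)
#' between groups that the marker claims to separate.
#'
#' @param marker one row of an `indel_marker_table` or `dcaps_table` (or a
#'   list with `fwd`, `rev` and optional `enzyme`).
#' @param genomes list of [plastome()] objects to genotype.
#' @param groups the [group_map()].
#' @param constraints a [marker_constraints()].
#' @return list with `verdict` (logical), `bands` (per-sample band
#'   patterns), `failures` (character, sample ids that failed to amplify or
#'   groups with inconsistent patterns).
#' @export
validate_marker <- function(marker, genomes, groups,
                            constraints = marker_constraints()) {
  if (is.data.frame(marker)) marker <- as.list(marker[1L, ])
  enz <- marker$enzyme
  if (!is.null(enz) && (is.na(enz) || !nzchar(enz))) enz <- NULL
  ids <- vapply(genomes, function(g) g$id, character(1))
  names(genomes) <- ids
  check_group_map(groups, ids)
  gm <- stats::setNames(groups$group, groups$sample)[ids]
  bands <- list()
  failures <- character(0)
  for (id in ids) {
    a <- tryCatch(insilico_pcr(marker$fwd, marker$rev, genomes[[id]],
                               max_mismatch = constraints$max_mismatch),
                  error = function(e)
                    list(amplified = FALSE, reason = conditionMessage(e)))
    if (!a$amplified) {
      failures <- c(failures, sprintf("%s: %s", id, a$reason))
      bands[[id]] <- integer(0)
      next
    }
    bands[[id]] <- if (is.null(enz)) a$size else digest(a, enz)
  }
  if (length(failures))
    return(list(verdict = FALSE, bands = bands, failures = failures))
  ## constant within groups
  for (g in unique(gm)) {
    pats <- bands[names(gm)[gm == g]]
    if (length(unique(pats)) != 1L)
      failures <- c(failures, sprintf("group %s: inconsistent band pattern", g))
  }
  if (length(failures))
    return(list(verdict = FALSE, bands = bands, failures = failures))
  ## distinct between the cells the marker separates (every pair of groups
  ## with different patterns must be gel-resolvable; and there must be >= 2)
  grp_pat <- lapply(split(names(gm), gm), function(s) bands[[s[1L]]])
  distinct <- 0L
  gg <- names(grp_pat)
  for (i in seq_along(gg)) for (j in seq_len(i - 1L)) {
    if (!identical(grp_pat[[gg[i]]], grp_pat[[gg[j]]])) {
      if (!band_patterns_distinct(grp_pat[[gg[i]]], grp_pat[[gg[j]]],
                                  constraints$min_size_diff)) {
        failures <- c(failures,
                      sprintf("groups %s/%s differ but are not gel-resolvable",
                              gg[i], gg[j]))
      } else distinct <- distinct + 1L
    }
  }
  verdict <- length(failures) == 0L && distinct >= 1L
  if (distinct < 1L) failures <- c(failures, "no group pair distinguished")
  list(verdict = verdict, bands = bands, failures = failures)
}
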