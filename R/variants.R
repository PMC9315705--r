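#' Call SNPs and InDels from a collinear alignment
#'
#' SNPs are called per polymorphic substitution column; consecutive gap
#' columns in one sample are merged into a single InDel event, which is
#' then left-aligned (shifted to the lowest reference coordinate that
#' represents the same edit) and anchored VCF-style on the preceding
#' reference base. Alignment cells containing `N` are treated as missing:
#' they never create an allele, and a sample with `N` at a called site gets
#' a missing call.
#'
#' @param aln a `plast_alignment`.
#' @param reference_id reference row (defaults to the alignment's).
#' @return data.frame of class `variant_table` with columns `kind`
#'   (`"SNP"`/`"InDel"`), `pos` (1-based reference coordinate; for InDels
#'   the anchor base), `ref`, `alt` (comma-separated when multi-allelic),
#'   plus attributes `calls` (variant x sample character matrix of
#'   alleles) and `reference`.
#' @export
call_variants <- function(aln, reference_id = aln$ref_id) {
  if (!reference_id %in% names(aln$seqs))
    stop(sprintf("reference id '%s' absent from alignment", reference_id))
  m <- alignment_matrix(aln)
  samples <- rownames(m)
  others <- setdiff(samples, reference_id)
  refrow <- m[reference_id, ]
  ref_pos <- cumsum(refrow != "-")
  refseq <- chars_seq(refrow[refrow != "-"])

  recs <- list()

  ## ---- SNPs: substitution columns --------------------------------------
  base <- c("A", "C", "G", "T")
  cand <- which(refrow %in% base)
  if (length(others)) {
    sub_m <- m[others, cand, drop = FALSE]
    refc <- matrix(refrow[cand], nrow = length(others), ncol = length(cand),
                   byrow = TRUE)
    poly <- colSums(sub_m != refc & sub_m != "-" & sub_m != "N") > 0L
    for (j in cand[poly]) {
      col <- m[, j]
      alts <- setdiff(unique(col[col %in% base]), refrow[j])
      if (!length(alts)) next
      calls <- ifelse(col %in% base, col, NA_character_)
      recs[[length(recs) + 1L]] <- list(kind = "SNP", pos = ref_pos[j],
                                        ref = refrow[j],
                                        alt = paste(sort(alts), collapse = ","),
                                        calls = calls)
    }
  }

  ## ---- InDels: merged gap runs per sample ------------------------------
  events <- list()
  for (id in others) {
    row <- m[id, ]
    ## deletions: gap runs in the sample over reference bases
    ev_del <- gap_runs(row == "-" & refrow != "-")
    for (k in seq_len(nrow(ev_del))) {
      jj <- ev_del$start[k]:ev_del$end[k]
      delseq <- chars_seq(refrow[jj][refrow[jj] != "-"])
      if (!nchar(delseq) || grepl("N", delseq)) next
      anchor <- ref_pos[ev_del$start[k]] - 1L
      ev <- left_align_indel(anchor, delseq, refseq, insertion = FALSE)
      events[[length(events) + 1L]] <- c(ev, list(sample = id))
    }
    ## insertions: gap runs in the reference where this sample has bases
    ev_ins <- gap_runs(refrow == "-" & row != "-")
    for (k in seq_len(nrow(ev_ins))) {
      jj <- ev_ins$start[k]:ev_ins$end[k]
      insseq <- chars_seq(row[jj][row[jj] != "-"])
      if (!nchar(insseq) || grepl("N", insseq)) next
      anchor <- ref_pos[ev_ins$start[k]]
      ev <- left_align_indel(anchor, insseq, refseq, insertion = TRUE)
      events[[length(events) + 1L]] <- c(ev, list(sample = id))
    }
  }
  if (length(events)) {
    key <- vapply(events, function(e) paste(e$pos, e$ref, sep = ":"), character(1))
    for (kk in unique(key)) {
      ee <- events[key == kk]
      alts <- sort(unique(vapply(ee, function(e) e$alt, character(1))))
      calls <- stats::setNames(rep(ee[[1L]]$ref, length(samples)), samples)
      for (e in ee) calls[e$sample] <- e$alt
      recs[[length(recs) + 1L]] <- list(kind = "InDel", pos = ee[[1L]]$pos,
                                        ref = ee[[1L]]$ref,
                                        alt = paste(alts, collapse = ","),
                                        calls = unname(calls))
    }
  }

  vt <- data.frame(kind = vapply(recs, `[[`, "", "kind"),
                   pos = vapply(recs, function(r) as.integer(r$pos), integer(1)),
                   ref = vapply(recs, `[[`, "", "ref"),
                   alt = vapply(recs, `[[`, "", "alt"),
                   stringsAsFactors = FALSE)
  calls <- matrix(NA_character_, nrow(vt), length(samples),
                  dimnames = list(NULL, samples))
  for (i in seq_along(recs)) calls[i, ] <- recs[[i]]$calls
  o <- order(vt$pos, vt$kind)
  vt <- vt[o, , drop = FALSE]
  rownames(vt) <- NULL
  attr(vt, "calls") <- calls[o, , drop = FALSE]
  attr(vt, "reference") <- reference_id
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' @noRd
gap_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

## Left-align an InDel and express it VCF-style on the reference.
## `anchor` is the reference base immediately left of the event; `seqs` the
## deleted (reference) or inserted (sample) bases. Shifting is possible
## while the last base of the event equals the reference base at the anchor.
#' @noRd
left_align_indel <- function(anchor, seqs, refseq, insertion) {
  k <- nchar(seqs)
  while (anchor >= 1L && substr(refseq, anchor, anchor) == substr(seqs, k, k)) {
    seqs <- paste0(substr(refseq, anchor, anchor), substr(seqs, 1L, k - 1L))
    anchor <- anchor - 1L
  }
  if (anchor < 1L) {
    ## event at the very start: anchor on the base after it instead
    after <- substr(refseq, 1L, 1L)
    if (insertion) list(pos = 1L, ref = after, alt = paste0(seqs, after))
    else list(pos = 1L, ref = paste0(seqs, substr(refseq, k + 1L, k + 1L)),
              alt = substr(refseq, k + 1L, k + 1L))
  } else {
    a <- substr(refseq, anchor, anchor)
    if (insertion) list(pos = anchor, ref = a, alt = paste0(a, seqs))
    else list(pos = anchor, ref = paste0(a, seqs), alt = a)
  }
}

#' Classify variants by genomic region of the reference
#'
#' A position inside an annotated CDS/tRNA/rRNA part gets that class and
#' the gene name; a position inside the gap between two parts of the same
#' feature is an intron; anything else is intergenic, labelled
#' `"upstreamGene-downstreamGene"` in reference orientation (circular, so
#' the last and first genes flank the origin-spanning spacer).
#'
#' @param variants a `variant_table`.
#' @param annotations a `gene_features` table for the reference genome.
#' @param genome_len reference genome length (needed for the circular
#'   spacer at the origin; defaults to the largest feature end).
#' @return the variant table with `region` and `locus` columns filled.
#' @export
classify_regions <- function(variants, annotations, genome_len = NULL) {
  if (is.null(annotations) || nrow(annotations) == 0L)
    stop("classify_regions requires reference annotations")
  cls <- classify_positions(variants$pos, annotations, genome_len)
  variants$region <- cls$region
  variants$locus <- cls$locus
  variants
}

#' @noRd
classify_positions <- function(pos, feat, genome_len = NULL) {
  genome_len <- genome_len %||% max(feat$end)
  spans <- do.call(rbind, lapply(split(feat, feat$feature_id), function(f)
    data.frame(feature_id = f$feature_id[1L], gene = f$gene[1L],
               kind = f$kind[1L], gs = min(f$start), ge = max(f$end),
               stringsAsFactors = FALSE)))
  region <- rep("intergenic", length(pos))
  locus <- rep(NA_character_, length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i]
    inpart <- feat$start <= p & feat$end >= p
    if (any(inpart)) {
      j <- which(inpart)[1L]
      region[i] <- feat$kind[j]
      locus[i] <- feat$gene[j]
      next
    }
    inspan <- spans$gs <= p & spans$ge >= p
    if (any(inspan)) {
      j <- which(inspan)[1L]
      region[i] <- "intron"
      locus[i] <- spans$gene[j]
      next
    }
    ## intergenic: nearest gene ending before p and starting after p (circular)
    d_up <- (p - spans$ge) %% genome_len
    d_dn <- (spans$gs - p) %% genome_len
    locus[i] <- paste0(spans$gene[which.min(d_up)], "-",
                       spans$gene[which.min(d_dn)])
  }
  region[region == "CDS"] <- "CDS"
  list(region = region, locus = locus)
}

#' Find species-diagnostic variants
#'
#' A variant is diagnostic when every sample within each group carries one
#' allele (fixation within group) and at least two groups carry different
#' alleles. The induced partition of groups and the marker category follow:
#' three or more allele classes give `"three-way"`, two classes give
#' `"one-vs-rest"` or `"two-vs-rest"` depending on the size of the smaller
#' class.
#'
#' @param variants a `variant_table`.
#' @param groups a [group_map()] covering every sample in the call matrix.
#' @return subset of `variants` (class `diagnostic_table`) with `partition`
#'   (allele classes as `"g1+g2|g3"` strings) and `category` columns; the
#'   `calls` attribute is subset accordingly.
#' @export
diagnostic_variants <- function(variants, groups) {
  calls <- attr(variants, "calls")
  check_group_map(groups, colnames(calls))
  gm <- stats::setNames(groups$group, groups$sample)[colnames(calls)]
  gnames <- intersect(groups_of(groups), gm)
  if (length(gnames) < 2L) stop("diagnostic analysis requires >= 2 groups")
  keep <- logical(nrow(variants))
  partition <- character(nrow(variants))
  category <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    cl <- calls[i, ]
    if (anyNA(cl)) next                   # missing calls: not testable
    per_group <- vapply(gnames, function(g) {
      a <- unique(cl[gm == g])
      if (length(a) == 1L) a else NA_character_
    }, character(1))
    if (anyNA(per_group)) next            # polymorphic within a group
    if (length(unique(per_group)) < 2L) next
    cells <- split(gnames, per_group)
    cells <- cells[order(vapply(cells, function(x) min(match(x, gnames)), 1L))]
    keep[i] <- TRUE
    partition[i] <- paste(vapply(cells, paste, "", collapse = "+"),
                          collapse = "|")
    category[i] <- if (length(cells) >= 3L) "three-way"
      else if (min(lengths(cells)) == 1L) "one-vs-rest" else "two-vs-rest"
  }
  out <- variants[keep, , drop = FALSE]
  out$partition <- partition[keep]
  out$category <- category[keep]
  rownames(out) <- NULL
  attr(out, "calls") <- calls[keep, , drop = FALSE]
  attr(out, "reference") <- attr(variants, "reference")
  class(out) <- c("diagnostic_table", class(variants))
  out
}

#' Mean pairwise identity per annotation class
#'
#' Columns of the alignment are assigned to classes (tRNA, exon/CDS, rRNA,
#' intron, intergenic) through the reference coordinates; for each class
#' the percent of identical columns is computed for every sequence pair
#' (gap or N columns count as differences) and summarised as mean and
#' standard deviation over pairs.
#'
#' @param aln a `plast_alignment`.
#' @param annotations reference `gene_features`.
#' @return data.frame with `class`, `n_sites`, `mean_identity`,
#'   `sd_identity` (percent).
#' @export
region_identity <- function(aln, annotations) {
  m <- alignment_matrix(aln)
  refpos <- aln$col_to_ref
  reflen <- max(refpos)
  cls_ref <- classify_positions(seq_len(reflen), annotations, reflen)$region
  col_class <- ifelse(refpos == 0L, "intergenic", cls_ref[pmax(refpos, 1L)])
  col_class[col_class == "CDS"] <- "exon"
  classes <- c("tRNA", "exon", "rRNA", "intron", "intergenic")
  pairs <- utils::combn(nrow(m), 2L)
  rows <- lapply(classes, function(cl) {
    jj <- which(col_class == cl)
    if (!length(jj)) {
      return(data.frame(class = cl, n_sites = 0L, mean_identity = NA_real_,
                        sd_identity = NA_real_))
    }
    idents <- apply(pairs, 2L, function(pr) {
      a <- m[pr[1L], jj]; b <- m[pr[2L], jj]
      100 * sum(a == b & a != "-" & a != "N") / length(jj)
    })
    data.frame(class = cl, n_sites = length(jj),
               mean_identity = mean(idents),
               sd_identity = stats::sd(idents))
  })
  do.call(rbind, rows)
}

#' @export
`[.variant_table` <- function(x, i, j, drop = FALSE) {
  calls <- attr(x, "calls")
  out <- NextMethod()
  if (is.data.frame(out)) {
    if (!is.null(calls)) {
      attr(out, "calls") <- if (missing(i)) calls else calls[i, , drop = FALSE]
    }
    attr(out, "reference") <- attr(x, "reference")
    class(out) <- class(x)
  }
  out
}
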