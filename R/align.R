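#' Collinear multiple alignment of near-identical plastomes
#'
#' Builds a center-star multiple alignment around a chosen reference:
#' every other genome is aligned to the reference with a banded global
#' pairwise alignment (Gotoh affine gaps, band `band` columns around the
#' main diagonal), and the pairwise gap patterns are merged into one
#' alignment. This is only appropriate for collinear, near-identical
#' sequences (plastomes of one species complex differ by tens of SNPs and
#' short InDels, no rearrangements), which is why genomes must be
#' canonicalized first and may differ in length by at most 1%.
#'
#' @param genomes list of canonical [plastome()] objects.
#' @param reference_id id of the reference genome (must be in `genomes`).
#' @param band band half-width in columns (default 200).
#' @param max_len_diff maximum tolerated pairwise length difference as a
#'   fraction of the shortest genome (default 0.01).
#' @param match,mismatch,gap_open,gap_ext scoring scheme; the first base of
#'   a gap costs `gap_open + gap_ext`.
#' @return an object of class `plast_alignment`: named character vector
#'   `seqs` (equal-length aligned sequences over `{A,C,G,T,N,-}`),
#'   `ref_id`, and `col_to_ref` (per column, the reference coordinate of
#'   the reference base in or immediately left of that column; 0 for
#'   columns before the first reference base).
#' @export
align_plastomes <- function(genomes, reference_id, band = 200L,
                            max_len_diff = 0.01, match = 1L, mismatch = -2L,
                            gap_open = -5L, gap_ext = -1L) {
  ids <- vapply(genomes, function(g) g$id, character(1))
  names(genomes) <- ids
  if (!reference_id %in% ids) stop(sprintf("reference id '%s' not among genomes", reference_id))
  lens <- vapply(genomes, length, integer(1))
  if ((max(lens) - min(lens)) >= max_len_diff * min(lens))
    stop("collinearity error: pairwise length difference >= 1% of length; supply an external alignment instead")
  ref <- genomes[[reference_id]]$sequence
  R <- nchar(ref)
  others <- setdiff(ids, reference_id)

  ## pairwise alignments to the reference, decomposed per reference position
  pw <- lapply(others, function(id) {
    al <- cpp_banded_align(ref, genomes[[id]]$sequence, as.integer(band),
                           match, mismatch, gap_open, gap_ext)
    if (!isTRUE(al$ok) || isTRUE(al$edge))
      stop(sprintf("collinearity error: banded alignment of '%s' failed or touched the band edge; supply an external alignment", id))
    rac <- seq_chars(al$ref); qac <- seq_chars(al$qry)
    t <- cumsum(rac != "-")              # reference position per column
    is_ref <- rac != "-"
    qchar <- qac[is_ref]                 # sample char over each ref position
    ins_pos <- which(!is_ref)
    ins <- if (length(ins_pos)) split(qac[ins_pos], t[ins_pos]) else list()
    list(qchar = qchar, ins = ins)
  })
  names(pw) <- others

  ## master insertion profile: max inserted length after each ref position
  ins_max <- integer(R + 1L)             # index t+1 holds insertions after t
  for (p in pw) {
    if (length(p$ins)) {
      tt <- as.integer(names(p$ins)) + 1L
      ins_max[tt] <- pmax(ins_max[tt], lengths(p$ins))
    }
  }
  C <- R + sum(ins_max)
  ## insertion columns strictly left of each reference base t:
  ## the leading block plus blocks after positions 1..t-1
  ref_cols <- seq_len(R) + cumsum(ins_max)[seq_len(R)]
  col_to_ref <- rep.int(0:R, times = c(ins_max[1L], 1L + ins_max[-1L]))

  build_row <- function(qchar, ins) {
    row <- rep("-", C)
    row[ref_cols] <- qchar
    for (tn in names(ins)) {
      t <- as.integer(tn)
      v <- ins[[tn]]
      st <- if (t == 0L) 0L else ref_cols[t]
      row[st + seq_along(v)] <- v
    }
    chars_seq(row)
  }
  seqs <- c(stats::setNames(build_row(seq_chars(ref), list()), reference_id),
            vapply(others, function(id) build_row(pw[[id]]$qchar, pw[[id]]$ins),
                   character(1)))
  seqs <- seqs[ids]                      # preserve input order
  new_alignment(seqs, reference_id, col_to_ref)
}

#' @noRd
new_alignment <- function(seqs, ref_id, col_to_ref = NULL) {
  stopifnot(length(unique(nchar(seqs))) == 1L, ref_id %in% names(seqs))
  if (is.null(col_to_ref)) {
    col_to_ref <- cumsum(seq_chars(seqs[[ref_id]]) != "-")
  }
  al <- list(seqs = seqs, ref_id = ref_id, col_to_ref = as.integer(col_to_ref))
  class(al) <- "plast_alignment"
  al
}

#' @export
print.plast_alignment <- function(x, ...) {
  cat(sprintf("plast_alignment: %d sequences x %s columns (reference '%s')\n",
              length(x$seqs), format(nchar(x$seqs[[1L]]), big.mark = ","),
              x$ref_id))
  invisible(x)
}

#' Remove gaps from one alignment row
#' @param aln a `plast_alignment`.
#' @param id sequence id.
#' @return ungapped sequence string.
#' @export
degap <- function(aln, id) gsub("-", "", aln$seqs[[id]], fixed = TRUE)

#' Read an externally computed alignment from aligned FASTA
#'
#' Accepts alignments produced by any MSA tool, decoupling downstream
#' results from the built-in banded aligner.
#'
#' @param path aligned FASTA.
#' @param reference_id which record is the reference (defaults to the
#'   first).
#' @return a `plast_alignment`.
#' @export
read_alignment <- function(path, reference_id = NULL) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- stats::setNames(toupper(as.character(ss)), ids)
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned FASTA rows differ in length")
  new_alignment(seqs, reference_id %||% ids[1L])
}

#' Write an alignment as aligned FASTA
#' @param aln a `plast_alignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  write_sequences(aln$seqs, path)
}

#' @noRd
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  rownames(m) <- names(aln$seqs)
  m
}
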