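#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors, which is what this package stores sequences as.
#'
#' @param x character vector of DNA strings over `{A,C,G,T,N}` (and `-` in
#'   aligned sequences; gaps are preserved in place-reversed order).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' @noRd
chars_seq <- function(x) paste(x, collapse = "")

## complement lookup for single characters (vectors)
#' @noRd
comp_chars <- function(ch) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  out <- map[ch]
  if (anyNA(out)) stop("non-DNA character in sequence")
  unname(out)
}

## rotate a circular sequence so that (1-based) position `start` comes first
#' @noRd
rotate_seq <- function(s, start) {
  n <- nchar(s)
  start <- ((start - 1L) %% n) + 1L
  if (start == 1L) return(s)
  paste0(substr(s, start, n), substr(s, 1L, start - 1L))
}

## normalise raw sequence text: uppercase, U->T, validate alphabet
#' @noRd
normalize_dna <- function(s, id = "<sequence>") {
  s <- toupper(s)
  s <- gsub("U", "T", s, fixed = TRUE)
  bad <- gsub("[ACGTN]", "", s)
  if (nchar(bad) > 0L) {
    stop(sprintf("sequence '%s' contains non-ACGTN characters: %s",
                 id, paste(unique(seq_chars(bad)), collapse = ",")))
  }
  s
}

## GC fraction of a primer/sequence
#' @noRd
gc_fraction <- function(s) {
  ch <- seq_chars(toupper(s))
  sum(ch %in% c("G", "C")) / length(ch)
}

## Wallace-rule melting temperature: 2(A+T) + 4(G+C)
#' @noRd
wallace_tm <- function(s) {
  ch <- seq_chars(toupper(s))
  2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
}

## longest homopolymer run length
#' @noRd
max_homopolymer <- function(s) {
  r <- rle(seq_chars(s))
  max(r$lengths)
}

#' @useDynLib plastmarker, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
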