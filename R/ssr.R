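#' MISA-style SSR search thresholds
#'
#' Minimum number of whole motif copies per motif length. The defaults are
#' the classic plastome settings: mononucleotide runs of at least 10,
#' dinucleotide 5, trinucleotide 5, tetra 4, penta 3 and hexa 3.
#'
#' @param min_copies named or positional integer vector of length 6 (motif
#'   lengths 1--6).
#' @return integer vector of class `ssr_config`.
#' @export
ssr_config <- function(min_copies = c(10L, 5L, 5L, 4L, 3L, 3L)) {
  min_copies <- as.integer(min_copies)
  stopifnot(length(min_copies) == 6L, all(min_copies >= 2L))
  names(min_copies) <- as.character(1:6)
  class(min_copies) <- "ssr_config"
  min_copies
}

#' Scan a plastome for perfect microsatellites
#'
#' Reports every maximal perfect tandem run of a primitive 1--6 bp motif
#' meeting the per-motif-length copy threshold, on forward-strand
#' coordinates. Runs are reported as whole motif copies (a trailing partial
#' copy is trimmed), the MISA convention. Runs containing `N` are excluded,
#' and the sequence is scanned linearly (an SSR present in both IR copies is
#' reported twice, once per copy).
#'
#' @param genome a [plastome()] (or a plain character sequence).
#' @param config an [ssr_config()].
#' @return data.frame of class `ssr_table`: `motif`, `canonical_motif`
#'   (lexicographic minimum over rotations and strand), `motif_len`,
#'   `copies`, `start`, `end`, and `region` (`NA` until
#'   [summarize_ssrs()] or a structure is supplied).
#' @export
scan_ssrs <- function(genome, config = ssr_config()) {
  s <- if (inherits(genome, "plastome")) genome$sequence else
    normalize_dna(genome)
  ch <- seq_chars(s)
  n <- length(ch)
  rows <- list()
  for (p in 1:6) {
    if (n < (config[[p]] * p)) next
    i <- seq_len(n - p)
    cmp <- ch[i] == ch[i + p] & ch[i] != "N"
    r <- rle(cmp)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values)
    for (k in ok) {
      total <- r$lengths[k] + p           # maximal periodic stretch, in bp
      copies <- total %/% p
      if (copies < config[[p]]) next
      st <- starts[k]
      motif <- substr(s, st, st + p - 1L)
      if (!is_primitive(motif)) next
      rows[[length(rows) + 1L]] <-
        data.frame(motif = motif, motif_len = p, copies = copies,
                   start = st, end = st + copies * p - 1L,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(motif = character(0), canonical_motif = character(0),
                      motif_len = integer(0), copies = integer(0),
                      start = integer(0), end = integer(0),
                      region = character(0), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out$canonical_motif <- vapply(out$motif, canonical_motif, character(1))
    out$region <- NA_character_
    out <- out[order(out$start, out$motif_len),
               c("motif", "canonical_motif", "motif_len", "copies",
                 "start", "end", "region")]
    rownames(out) <- NULL
  }
  st <- if (inherits(genome, "plastome")) genome$structure else NULL
  if (!is.null(st)) out$region <- region_of_position(out$start, st)
  class(out) <- c("ssr_table", "data.frame")
  out
}

## a motif is primitive when it is not a whole power of a shorter word
#' @noRd
is_primitive <- function(motif) {
  p <- nchar(motif)
  for (q in seq_len(p - 1L)) {
    if (p %% q != 0L) next
    if (identical(strrep(substr(motif, 1L, q), p %/% q), motif)) return(FALSE)
  }
  TRUE
}

## lexicographic minimum over all rotations of the motif and of its
## reverse complement
#' @noRd
canonical_motif <- function(motif) {
  p <- nchar(motif)
  rots <- function(m) vapply(seq_len(p), function(i) rotate_seq(m, i), character(1))
  min(c(rots(motif), rots(revcomp(motif))))
}

## map 1-based canonical-coordinate positions to quadripartite segments
#' @noRd
region_of_position <- function(pos, st) {
  out <- rep(NA_character_, length(pos))
  out[pos >= st$lsc[1L] & pos <= st$lsc[2L]] <- "LSC"
  out[pos >= st$irb[1L] & pos <= st$irb[2L]] <- "IRb"
  out[pos >= st$ssc[1L] & pos <= st$ssc[2L]] <- "SSC"
  out[pos >= st$ira[1L] & pos <= st$ira[2L]] <- "IRa"
  out
}

#' Summarise an SSR table by motif-length class and region
#'
#' @param records an `ssr_table` from [scan_ssrs()].
#' @param structure optional [detect_quadripartite()] result used to
#'   (re-)assign regions.
#' @return list with `by_class` (named counts mono..hexa), `by_region`
#'   (counts per LSC/IRb/SSC/IRa), and `total`.
#' @export
summarize_ssrs <- function(records, structure = NULL) {
  if (!is.null(structure))
    records$region <- region_of_position(records$start, structure)
  classes <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  by_class <- stats::setNames(integer(6), classes)
  tab <- table(factor(records$motif_len, levels = 1:6))
  by_class[] <- as.integer(tab)
  regions <- c("LSC", "IRb", "SSC", "IRa")
  by_region <- stats::setNames(integer(4), regions)
  tab2 <- table(factor(records$region, levels = regions))
  by_region[] <- as.integer(tab2)
  list(by_class = by_class, by_region = by_region, total = nrow(records))
}
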