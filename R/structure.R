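#' Detect the quadripartite architecture of a circular plastome
#'
#' Finds the longest pair of exact inverted repeats on the circle (seeded by
#' 20-mer matches between the sequence and its reverse complement, extended
#' maximally along the anti-diagonal), labels the longer single-copy segment
#' LSC and the shorter SSC, and reports segment intervals in canonical
#' order LSC--IRb--SSC--IRa.
#'
#' Only exact IR pairs are considered: plastid IRs evolve in concert and the
#' two copies are expected to be identical. Multiple maximal pairs of equal
#' length are an error (ambiguity signals pathological input), as is the
#' absence of any repeat of at least `min_ir_len`.
#'
#' @param genome a [plastome()] (must be circular).
#' @param min_ir_len minimum IR length in bp (default 1000, which excludes
#'   short dispersed repeats).
#' @param seed_len seed k-mer length for the match phase.
#' @return an object of class `quadripartite` with fields `lsc_len`,
#'   `ssc_len`, `ir_len`, `lsc_start` (position in the input genome where
#'   the LSC begins), canonical intervals `lsc`, `irb`, `ssc`, `ira`
#'   (1-based closed, in canonical coordinates), and `orientation_note`.
#' @export
detect_quadripartite <- function(genome, min_ir_len = 1000L, seed_len = 20L) {
  if (!genome$circular) stop("quadripartite detection requires a circular genome")
  s <- genome$sequence
  n <- nchar(s)
  if (n <= 4L * min_ir_len)
    stop("genome shorter than 4 * min_ir_len; no quadripartite structure")

  cand <- find_inverted_repeats(s, min_len = min_ir_len, seed_len = seed_len)
  if (nrow(cand) == 0L)
    stop(sprintf("structure-not-found: no inverted repeat >= %d bp", min_ir_len))
  best_len <- max(cand$len)
  best <- cand[cand$len == best_len, , drop = FALSE]
  if (nrow(best) > 1L)
    stop(sprintf(
      "ambiguous inverted repeats: %d distinct maximal pairs of length %d (at %s)",
      nrow(best), best_len,
      paste(sprintf("%d/%d", best$a1, best$b1), collapse = ", ")))
  if (best_len > n / 2) stop("inverted repeat longer than half the genome")

  a1 <- best$a1; b1 <- best$b1; L <- best$len
  ## two single-copy gaps on the circle between the repeat copies
  gap1 <- (b1 - (a1 + L)) %% n           # after copy A, before copy B
  gap2 <- (a1 - (b1 + L)) %% n           # after copy B, before copy A
  if (gap1 == 0L || gap2 == 0L)
    stop("inverted repeat copies are adjacent; no quadripartite structure")
  if (gap1 >= gap2) {
    lsc_len <- gap1; ssc_len <- gap2
    lsc_start <- ((a1 + L - 1L) %% n) + 1L   # first base after copy A
  } else {
    lsc_len <- gap2; ssc_len <- gap1
    lsc_start <- ((b1 + L - 1L) %% n) + 1L
  }
  qp <- list(lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
             ir_len = as.integer(L), lsc_start = as.integer(lsc_start),
             genome_len = n,
             lsc = c(1L, as.integer(lsc_len)),
             irb = as.integer(c(lsc_len + 1L, lsc_len + L)),
             ssc = as.integer(c(lsc_len + L + 1L, lsc_len + L + ssc_len)),
             ira = as.integer(c(lsc_len + L + ssc_len + 1L, n)),
             orientation_note = "SSC reported as found (flip-flop isomer not normalized)")
  class(qp) <- "quadripartite"
  stopifnot(qp$lsc_len + qp$ssc_len + 2L * qp$ir_len == n)
  qp
}

#' @export
print.quadripartite <- function(x, ...) {
  cat(sprintf("quadripartite structure (%s bp): LSC %d | IRb %d | SSC %d | IRa %d\n",
              format(x$genome_len, big.mark = ","), x$lsc_len, x$ir_len,
              x$ssc_len, x$ir_len))
  invisible(x)
}

## Seeded search for maximal exact inverted repeats on a circle.
## Returns a data.frame a1,b1,len in 1..n coordinates (starts of the two
## copies, forward strand), deduplicated and non-self-overlapping.
#' @noRd
find_inverted_repeats <- function(s, min_len, seed_len = 20L) {
  n <- nchar(s)
  d <- paste0(s, s)                       # doubled circle
  dc <- seq_chars(d)
  rc <- rev(comp_chars(dc))               # reverse complement of doubled seq
  nd <- 2L * n

  ## seed phase: stepped k-mers of d located in revcomp(d) via matchPDict;
  ## any repeat copy of length >= min_len contains at least one stepped seed
  step <- max(1L, min_len - seed_len + 1L)
  ss <- seq.int(1L, nd - seed_len + 1L, by = step)
  km <- substring(d, ss, ss + seed_len - 1L)
  keep <- !grepl("N", km, fixed = TRUE)
  ss <- ss[keep]; km <- km[keep]
  if (!length(ss)) return(data.frame(a1 = integer(0), b1 = integer(0), len = integer(0)))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(km))
  hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(chars_seq(rc)))
  nh <- S4Vectors::elementNROWS(hits)
  if (sum(nh) == 0L) return(data.frame(a1 = integer(0), b1 = integer(0), len = integer(0)))
  pairs <- data.frame(p = rep(ss, nh), q = unlist(lapply(hits, IRanges::start)))
  ## seed (p in d, q in rc) lies on anti-diagonal x + y = const where
  ## y is the d-coordinate of the reverse-complemented base: y = nd - q' + 1
  diag_id <- pairs$p - pairs$q            # constant along one anti-diagonal
  reps <- list()
  for (dg in unique(diag_id)) {
    ## along this diagonal compare d[x] with rc[x - dg]
    x_min <- max(1L, 1L + dg); x_max <- min(nd, nd + dg)
    x <- x_min:x_max
    eq <- dc[x] == rc[x - dg] & dc[x] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts_r <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= min_len)
    for (k in ok) {
      x1 <- x[starts_r[k]]; len <- r$lengths[k]
      ## d-interval of copy A: [x1, x1+len-1]; copy B (via rc mapping):
      y_hi <- nd - (x1 - dg) + 1L         # d-coord paired with x1
      b_start <- y_hi - len + 1L
      reps[[length(reps) + 1L]] <- c(a = x1, b = b_start, len = len)
    }
  }
  if (!length(reps)) return(data.frame(a1 = integer(0), b1 = integer(0), len = integer(0)))
  m <- unique(do.call(rbind, reps))
  a1 <- ((m[, "a"] - 1L) %% n) + 1L
  b1 <- ((m[, "b"] - 1L) %% n) + 1L
  len <- pmin(m[, "len"], n)
  ## normalize pair order and drop (A,B)/(B,A) duplicates
  lo <- pmin(a1, b1); hi <- pmax(a1, b1)
  df <- unique(data.frame(a1 = lo, b1 = hi, len = as.integer(len)))
  ## drop self-overlapping (palindromic) pairs on the circle
  sep1 <- (df$b1 - (df$a1 + df$len)) %% n
  sep2 <- (df$a1 - (df$b1 + df$len)) %% n
  overlap <- (df$b1 - df$a1) < df$len | ((df$a1 + n) - df$b1) < df$len
  df <- df[!overlap & (sep1 > 0L | sep2 > 0L), , drop = FALSE]
  ## drop repeats fully contained in a longer one (same diagonal artifacts
  ## from circle doubling)
  if (nrow(df) > 1L) {
    keep <- rep(TRUE, nrow(df))
    o <- order(-df$len)
    df <- df[o, , drop = FALSE]
    for (i in seq_len(nrow(df))[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (!keep[j]) next
        da <- (df$a1[i] - df$a1[j]) %% n
        db <- (df$b1[j] + df$len[j] - (df$b1[i] + df$len[i])) %% n
        if (da == db && da + df$len[i] <= df$len[j]) { keep[i] <- FALSE; break }
      }
    }
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Rotate a plastome into canonical LSC-first orientation
#'
#' Returns a copy whose sequence starts at the first base of the LSC, so
#' segment order is LSC--IRb--SSC--IRa and nothing wraps the origin.
#' Annotations are rotated along; a feature part that would span the new
#' origin is split in two. The original rotation offset is recorded in
#' attribute `offset` so coordinates can be mapped back
#' (`original = ((canonical - 1 + offset) %% n) + 1`).
#'
#' @param genome a [plastome()].
#' @param structure its [detect_quadripartite()] result (detected on demand
#'   when `NULL`).
#' @return the canonical [plastome()], with `$structure` set.
#' @export
canonicalize <- function(genome, structure = NULL) {
  if (is.null(structure)) structure <- genome$structure
  if (is.null(structure)) structure <- detect_quadripartite(genome)
  n <- nchar(genome$sequence)
  off <- structure$lsc_start - 1L
  out <- genome
  out$sequence <- rotate_seq(genome$sequence, structure$lsc_start)
  if (!is.null(genome$annotations) && nrow(genome$annotations)) {
    feat <- genome$annotations
    ns <- ((feat$start - 1L - off) %% n) + 1L
    ne <- ((feat$end - 1L - off) %% n) + 1L
    wraps <- ns > ne
    if (any(wraps)) {
      extra <- feat[wraps, , drop = FALSE]
      extra$start <- 1L; extra$end <- ne[wraps]
      feat$start <- ns; feat$end <- ne
      feat$end[wraps] <- n
      feat <- rbind(feat, extra)
      feat <- feat[order(feat$feature_id, feat$start), ]
      feat$part <- stats::ave(feat$start, feat$feature_id, FUN = seq_along)
    } else {
      feat$start <- ns; feat$end <- ne
    }
    class(feat) <- c("gene_features", "data.frame")
    out$annotations <- feat
  }
  structure$lsc_start <- 1L
  out$structure <- structure
  attr(out, "offset") <- off
  ## invariant: IRa is the exact reverse complement of IRb
  irb <- substr(out$sequence, structure$irb[1L], structure$irb[2L])
  ira <- substr(out$sequence, structure$ira[1L], structure$ira[2L])
  stopifnot(identical(ira, revcomp(irb)))
  out
}

#' Gene context at the four quadripartite junctions
#'
#' For each junction (LSC/IRb, IRb/SSC, SSC/IRa, IRa/LSC) reports the
#' annotated gene nearest to the boundary, with a signed distance: positive
#' distances are the gap in bp between the gene and the boundary, zero means
#' the gene abuts the boundary, and negative means the gene spans the
#' junction, extending that many bp across it.
#'
#' @param genome an annotated, canonical [plastome()] (see [canonicalize()]).
#' @param structure its quadripartite structure (defaults to
#'   `genome$structure`).
#' @return data.frame with one row per junction: `junction`, `boundary`
#'   (last position of the upstream segment), `gene`, `distance`.
#' @export
junction_report <- function(genome, structure = genome$structure) {
  if (is.null(genome$annotations) || nrow(genome$annotations) == 0L)
    stop("junction_report requires annotations")
  if (is.null(structure)) stop("junction_report requires a detected structure")
  n <- nchar(genome$sequence)
  feat <- genome$annotations
  spans <- do.call(rbind, lapply(split(feat, feat$feature_id), function(f)
    data.frame(feature_id = f$feature_id[1L], gene = f$gene[1L],
               gs = min(f$start), ge = max(f$end), stringsAsFactors = FALSE)))
  boundaries <- c("LSC/IRb" = structure$lsc[2L], "IRb/SSC" = structure$irb[2L],
                  "SSC/IRa" = structure$ssc[2L], "IRa/LSC" = structure$ira[2L])
  rows <- lapply(seq_along(boundaries), function(i) {
    p <- boundaries[[i]]
    ## circular signed distance of each gene span to the boundary point p|p+1
    d_after <- (spans$gs - p - 1L) %% n      # gene begins after the boundary
    d_before <- (p - spans$ge) %% n          # gene ends before the boundary
    covers_p <- (p - spans$gs) %% n < (spans$ge - spans$gs) %% n + 1L
    covers_q <- (((p %% n) + 1L) - spans$gs) %% n < (spans$ge - spans$gs) %% n + 1L
    spanning <- covers_p & covers_q
    dist <- pmin(d_after, d_before)
    dist[spanning] <- -pmin((p - spans$gs[spanning]) %% n + 1L,
                            (spans$ge[spanning] - p) %% n)
    j <- order(abs(dist), spans$gene)[1L]
    data.frame(junction = names(boundaries)[i], boundary = p,
               gene = spans$gene[j], distance = dist[j],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
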