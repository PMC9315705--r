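#' Restriction enzyme specifications
#'
#' The shipped panel holds the two enzymes used for plastome dCAPS work:
#' TaqI (`T^CGA`, 65 degree digestion) and XbaI (`T^CTAGA`, 37 degrees).
#' `cut_offset` is the number of site bases left of the cut on the top
#' strand (`T^CGA` has offset 1).
#'
#' @param name enzyme name.
#' @param site recognition sequence (4--6 bp).
#' @param cut_offset cut position within the site on the top strand.
#' @return list of class `enzyme_spec`.
#' @export
enzyme_spec <- function(name, site, cut_offset) {
  site <- normalize_dna(site, name)
  stopifnot(nchar(site) >= 4L, nchar(site) <= 6L,
            cut_offset >= 0L, cut_offset <= nchar(site))
  structure(list(name = name, site = site, cut_offset = as.integer(cut_offset)),
            class = "enzyme_spec")
}

#' @rdname enzyme_spec
#' @param x enzyme name to look up in the panel.
#' @export
enzyme_panel <- function() {
  list(TaqI = enzyme_spec("TaqI", "TCGA", 1L),
       XbaI = enzyme_spec("XbaI", "TCTAGA", 1L))
}

#' @rdname enzyme_spec
#' @export
get_enzyme <- function(x) {
  if (inherits(x, "enzyme_spec")) return(x)
  panel <- enzyme_panel()
  if (!x %in% names(panel)) stop(sprintf("unknown enzyme '%s'", x))
  panel[[x]]
}

## All binding sites of a primer on a template, as top-strand intervals.
## orientation "+" means the primer extends rightward (matches the top
## strand); "-" means it extends leftward (reverse complement matches).
## The 3'-terminal base must match exactly; up to max_mismatch mismatches
## elsewhere. N in the template counts as a mismatch.
#' @noRd
primer_sites <- function(primer, tmpl_chars, max_mismatch = 2L) {
  out <- list()
  m <- nchar(primer)
  L <- length(tmpl_chars)
  if (L < m) {
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0), orientation = character(0)))
  }
  for (ori in c("+", "-")) {
    pc <- seq_chars(if (ori == "+") primer else revcomp(primer))
    npos <- L - m + 1L
    mm <- integer(npos)
    for (i in seq_len(m)) {
      mm <- mm + (tmpl_chars[i:(npos + i - 1L)] != pc[i])
    }
    ## exact 3'-terminal base: last primer base for "+", first for "-"
    ti <- if (ori == "+") m else 1L
    exact3 <- tmpl_chars[ti:(npos + ti - 1L)] == pc[ti]
    hit <- which(mm <= max_mismatch & exact3)
    if (length(hit)) {
      out[[length(out) + 1L]] <-
        data.frame(start = hit, end = hit + m - 1L, mismatches = mm[hit],
                   orientation = ori, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0), orientation = character(0)))
  }
  do.call(rbind, out)
}

#' Predict a PCR product in silico
#'
#' Finds binding sites of both primers (in either orientation) with an
#' exactly matching 3'-terminal base and at most `max_mismatch` total
#' mismatches, and returns the smallest convergent product of at most
#' `max_product` bp. On circular templates the product may span the
#' origin. Primer bases, including deliberate mismatches, are incorporated
#' into the product sequence, which is what a dCAPS assay relies on. The
#' product is always reported on the template's top strand, whichever
#' primer binds it.
#'
#' @param fwd,rev primer sequences 5'-to-3'.
#' @param template a [plastome()] or plain sequence string.
#' @param max_mismatch tolerated mismatches per primer (besides the exact
#'   3' base).
#' @param max_product largest product considered (default 5000 bp).
#' @param circular overrides the template's own circularity flag.
#' @return object of class `amplicon`: `amplified` (logical), and when
#'   amplified `product` (sequence), `size`, `start`, `end` (top-strand,
#'   `end` may exceed the template length when the product wraps the
#'   origin), `fwd_mismatches`, `rev_mismatches`. A failed reaction has
#'   `amplified = FALSE` and a `reason`; an ambiguous one (several distinct
#'   smallest products) is an error.
#' @export
insilico_pcr <- function(fwd, rev, template, max_mismatch = 2L,
                         max_product = 5000L, circular = NULL) {
  if (inherits(template, "plastome")) {
    s <- template$sequence
    circ <- circular %||% template$circular
    tid <- template$id
  } else {
    s <- normalize_dna(template)
    circ <- circular %||% FALSE
    tid <- NA_character_
  }
  fwd <- normalize_dna(fwd, "fwd primer")
  rev <- normalize_dna(rev, "rev primer")
  n <- nchar(s)
  search_s <- if (circ) paste0(s, s) else s
  tc <- seq_chars(search_s)
  sites_f <- primer_sites(fwd, tc, max_mismatch)
  sites_r <- primer_sites(rev, tc, max_mismatch)
  if (circ) {                            # each physical site once
    sites_f <- sites_f[sites_f$start <= n, , drop = FALSE]
    sites_r <- sites_r[sites_r$start <= n, , drop = FALSE]
  }
  no_site <- function(which) {
    structure(list(amplified = FALSE,
                   reason = sprintf("no binding site for %s primer", which),
                   template_id = tid), class = "amplicon")
  }
  if (!nrow(sites_f)) return(no_site("forward"))
  if (!nrow(sites_r)) return(no_site("reverse"))

  ## convergent pairs: one primer on "+" upstream, the other on "-" downstream
  cands <- list()
  combos <- list(list(a = sites_f, b = sites_r, af = "fwd"),
                 list(a = sites_r, b = sites_f, af = "rev"))
  for (cb in combos) {
    a <- cb$a[cb$a$orientation == "+", , drop = FALSE]
    b <- cb$b[cb$b$orientation == "-", , drop = FALSE]
    if (!nrow(a) || !nrow(b)) next
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      st <- a$start[i]; en <- b$end[j]
      if (circ) {
        if (en < st) en <- en + n
        if (en - st + 1L > n) next
      } else if (en < st) next
      size <- en - st + 1L
      if (size < a$end[i] - a$start[i] + 1L + b$end[j] - b$start[j] + 1L) next
      if (size > max_product) next
      cands[[length(cands) + 1L]] <-
        list(start = st, end = en, size = size,
             a_len = a$end[i] - a$start[i] + 1L,
             b_len = b$end[j] - b$start[j] + 1L,
             a_is_fwd = cb$af == "fwd",
             mm_a = a$mismatches[i], mm_b = b$mismatches[j])
    }
  }
  if (!length(cands)) {
    return(structure(list(amplified = FALSE,
                          reason = "no convergent primer pair",
                          template_id = tid), class = "amplicon"))
  }
  sizes <- vapply(cands, `[[`, integer(1), "size")
  best <- cands[sizes == min(sizes)]
  keys <- unique(vapply(best, function(x)
    paste((x$start - 1L) %% n + 1L, x$size), character(1)))
  if (length(keys) > 1L)
    stop(sprintf("ambiguous amplification: %d distinct products of %d bp",
                 length(keys), min(sizes)))
  x <- best[[1L]]
  core <- substr(search_s, x$start, x$end)
  up <- if (x$a_is_fwd) fwd else rev
  dn <- if (x$a_is_fwd) rev else fwd
  product <- paste0(up,
                    substr(core, x$a_len + 1L, x$size - x$b_len),
                    revcomp(dn))
  structure(list(amplified = TRUE, product = product, size = x$size,
                 start = (x$start - 1L) %% n + 1L, end = x$end,
                 template_id = tid,
                 fwd_mismatches = if (x$a_is_fwd) x$mm_a else x$mm_b,
                 rev_mismatches = if (x$a_is_fwd) x$mm_b else x$mm_a),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  if (x$amplified) {
    cat(sprintf("amplicon: %d bp [%d..%d]%s\n", x$size, x$start, x$end,
                if (!is.na(x$template_id)) paste0(" on ", x$template_id) else ""))
  } else cat(sprintf("no amplification: %s\n", x$reason))
  invisible(x)
}

#' Digest a PCR product with a restriction enzyme
#'
#' Cuts at every occurrence of the recognition site on either strand, at
#' the enzyme's top-strand offset. Zero cuts return the whole product as
#' one fragment. Fragment sizes always sum to the product size, and
#' digesting the reverse complement yields the reversed fragment list.
#'
#' @param product an `amplicon` from [insilico_pcr()] or a sequence string.
#' @param enzyme an [enzyme_spec()] or panel name (`"TaqI"`, `"XbaI"`).
#' @return integer vector of fragment sizes, ordered along the product.
#' @export
digest <- function(product, enzyme) {
  enzyme <- get_enzyme(enzyme)
  s <- if (inherits(product, "amplicon")) {
    if (!product$amplified) stop("cannot digest a failed amplification")
    product$product
  } else normalize_dna(product)
  n <- nchar(s)
  k <- nchar(enzyme$site)
  hits_top <- find_all(s, enzyme$site)
  rc_site <- revcomp(enzyme$site)
  hits_bot <- find_all(s, rc_site)
  ## one cut per physical site: a palindromic site appears in both scans at
  ## the same position and is cut once, at the top-strand offset; a
  ## bottom-strand-only site is cut at the mirrored offset
  hits_bot <- setdiff(hits_bot, hits_top)
  cuts <- sort(unique(c(hits_top + enzyme$cut_offset - 1L,
                        hits_bot + k - enzyme$cut_offset - 1L)))
  cuts <- cuts[cuts >= 1L & cuts < n]
  if (!length(cuts)) return(n)
  diff(c(0L, cuts, n))
}

## all (possibly overlapping) occurrences of `pat` in `s`
#' @noRd
find_all <- function(s, pat) {
  hits <- gregexpr(sprintf("(?=%s)", pat), s, perl = TRUE)[[1L]]
  hits <- as.integer(hits)
  hits[hits > 0L]
}
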