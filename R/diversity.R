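#' Sliding-window configuration for nucleotide diversity
#'
#' Defaults are the classic DnaSP plastome settings: 500 bp windows
#' advanced by 250 bp over alignment coordinates, with complete deletion of
#' gap/N columns inside each window.
#'
#' @param window window size in alignment columns.
#' @param step stride in alignment columns (must not exceed `window`).
#' @param gap_handling `"complete"` (drop a column when any sequence has a
#'   gap or N there, DnaSP's default) or `"pairwise"` (drop per pair).
#' @return list of class `pi_config`.
#' @export
pi_config <- function(window = 500L, step = 250L,
                      gap_handling = c("complete", "pairwise")) {
  gap_handling <- match.arg(gap_handling)
  stopifnot(window > 0L, step > 0L, step <= window)
  structure(list(window = as.integer(window), step = as.integer(step),
                 gap_handling = gap_handling), class = "pi_config")
}

#' Sliding-window nucleotide diversity (Pi)
#'
#' Pi in a window is the average over all sequence pairs of the proportion
#' of differing sites among compared sites. Under complete deletion the
#' compared sites of a window are its columns where no sequence has a gap
#' or N; under pairwise deletion each pair uses its own ungapped columns.
#'
#' @param aln a `plast_alignment` with at least 2 sequences.
#' @param config a [pi_config()].
#' @return object of class `pi_profile`: `windows` data.frame (`start`,
#'   `end`, `midpoint` in alignment coordinates, `n_sites` compared, `pi`)
#'   plus the `config` and overall `pi_total` computed on the whole
#'   alignment as one window.
#' @export
sliding_pi <- function(aln, config = pi_config()) {
  m <- alignment_matrix(aln)
  if (nrow(m) < 2L) stop("sliding_pi requires >= 2 sequences")
  C <- ncol(m)
  if (config$window > C) {
    warning("window larger than alignment; computing a single whole-alignment window")
    starts <- 1L
    ends <- C
  } else {
    starts <- seq.int(1L, C - config$window + 1L, by = config$step)
    ends <- pmin(starts + config$window - 1L, C)
    ## make sure the tail of the alignment is covered
    if (ends[length(ends)] < C) {
      starts <- c(starts, C - config$window + 1L)
      ends <- c(ends, C)
    }
  }
  wins <- data.frame(start = starts, end = ends,
                     midpoint = as.integer(floor((starts + ends) / 2)))
  res <- t(vapply(seq_len(nrow(wins)), function(i)
    window_pi(m, wins$start[i], wins$end[i], config$gap_handling),
    numeric(2)))
  wins$n_sites <- as.integer(res[, 2L])
  wins$pi <- res[, 1L]
  total <- window_pi(m, 1L, C, config$gap_handling)
  structure(list(windows = wins, config = config, pi_total = total[1L]),
            class = "pi_profile")
}

#' @export
print.pi_profile <- function(x, ...) {
  cat(sprintf("pi_profile: %d windows (window %d, step %d), overall Pi = %.6f\n",
              nrow(x$windows), x$config$window, x$config$step, x$pi_total))
  invisible(x)
}

## Pi for one window of an alignment matrix; returns c(pi, n_sites)
#' @noRd
window_pi <- function(m, from, to, gap_handling = "complete") {
  sub <- m[, from:to, drop = FALSE]
  n <- nrow(sub)
  pairs <- utils::combn(n, 2L)
  if (gap_handling == "complete") {
    valid <- colSums(sub == "-" | sub == "N") == 0L
    nv <- sum(valid)
    if (nv == 0L) return(c(0, 0))
    sub <- sub[, valid, drop = FALSE]
    d <- apply(pairs, 2L, function(pr) sum(sub[pr[1L], ] != sub[pr[2L], ]) / nv)
    c(mean(d), nv)
  } else {
    d <- apply(pairs, 2L, function(pr) {
      a <- sub[pr[1L], ]; b <- sub[pr[2L], ]
      ok <- a != "-" & a != "N" & b != "-" & b != "N"
      if (!any(ok)) return(NA_real_)
      sum(a[ok] != b[ok]) / sum(ok)
    })
    c(mean(d, na.rm = TRUE), sum(colSums(sub == "-" | sub == "N") == 0L))
  }
}

#' Summarise a Pi profile by region, by group, and list hotspots
#'
#' Windows are assigned to LSC/IRb/SSC/IRa by the reference coordinate of
#' their midpoint. Per-group Pi is recomputed on each group's subset of
#' rows over the whole alignment. Hotspots are windows whose Pi exceeds the
#' threshold; when annotations are given they are labelled with the gene or
#' flanking-gene spacer of the window midpoint.
#'
#' @param profile a `pi_profile` from [sliding_pi()].
#' @param aln the alignment it was computed from.
#' @param structure the reference's [detect_quadripartite()] structure, or
#'   `NULL` to skip region summaries.
#' @param groups optional [group_map()] for per-group Pi.
#' @param annotations optional reference `gene_features` for hotspot
#'   labels.
#' @param hotspot_threshold windows with Pi above this value are reported
#'   (default 0.01).
#' @return list with `by_region` (per region: window count, mean/min/max of
#'   window Pi, and `pi_sites`, the exact Pi over the region's own
#'   alignment columns -- window means can bleed across junctions because a
#'   window is assigned by its midpoint), `by_group` (overall Pi per
#'   group), and `hotspots` (windows above threshold, with labels).
#' @export
summarize_pi <- function(profile, aln, structure = NULL, groups = NULL,
                         annotations = NULL, hotspot_threshold = 0.01) {
  w <- profile$windows
  mid_ref <- pmax(aln$col_to_ref[w$midpoint], 1L)
  out <- list()
  if (!is.null(structure)) {
    w$region <- region_of_position(mid_ref, structure)
    m <- alignment_matrix(aln)
    col_region <- region_of_position(pmax(aln$col_to_ref, 1L), structure)
    ## the two IR copies are one evolutionary unit
    regions <- c("LSC", "IRb", "SSC", "IRa", "IR")
    tab <- lapply(regions, function(rg) {
      rset <- if (rg == "IR") c("IRb", "IRa") else rg
      sel <- w$region %in% rset
      ## pi_sites restricts the computation to the region's own columns:
      ## unlike window means it cannot pick up variation from a
      ## junction-straddling window, so it is exactly 0 for invariant IRs
      cols <- which(col_region %in% rset)
      pi_sites <- if (length(cols)) {
        sub <- m[, cols, drop = FALSE]
        window_pi(sub, 1L, ncol(sub), profile$config$gap_handling)[1L]
      } else NA_real_
      if (!any(sel, na.rm = TRUE)) {
        return(data.frame(region = rg, n_windows = 0L, mean_pi = NA_real_,
                          min_pi = NA_real_, max_pi = NA_real_,
                          pi_sites = pi_sites))
      }
      data.frame(region = rg, n_windows = sum(sel, na.rm = TRUE),
                 mean_pi = mean(w$pi[sel], na.rm = TRUE),
                 min_pi = min(w$pi[sel], na.rm = TRUE),
                 max_pi = max(w$pi[sel], na.rm = TRUE),
                 pi_sites = pi_sites)
    })
    out$by_region <- do.call(rbind, tab)
  }
  if (!is.null(groups)) {
    m <- alignment_matrix(aln)
    check_group_map(groups, rownames(m))
    gm <- stats::setNames(groups$group, groups$sample)[rownames(m)]
    out$by_group <- do.call(rbind, lapply(unique(gm), function(g) {
      rows <- which(gm == g)
      pi_g <- if (length(rows) < 2L) NA_real_ else
        window_pi(m[rows, , drop = FALSE], 1L, ncol(m),
                  profile$config$gap_handling)[1L]
      data.frame(group = g, n_samples = length(rows), pi = pi_g)
    }))
  }
  hot <- w[w$pi > hotspot_threshold, , drop = FALSE]
  if (nrow(hot) && !is.null(annotations)) {
    hm <- pmax(aln$col_to_ref[hot$midpoint], 1L)
    cls <- classify_positions(hm, annotations)
    hot$locus <- cls$locus
    hot$region_class <- cls$region
  }
  rownames(hot) <- NULL
  out$hotspots <- hot
  out
}
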