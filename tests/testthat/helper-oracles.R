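## shared fixtures and independent brute-force oracles

rnd_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
unchars <- function(x) paste(x, collapse = "")
comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## construct a quadripartite toy genome with junction blockers so that
## maximal exact extension reproduces the nominal segment lengths
make_quadripartite <- function(lsc_len, ir_len, ssc_len) {
  lsc <- chars(rnd_seq(lsc_len))
  irb <- chars(rnd_seq(ir_len))
  ssc <- chars(rnd_seq(ssc_len))
  if (lsc[lsc_len] == comp_map[[lsc[1]]])
    lsc[lsc_len] <- setdiff(c("A", "C", "G", "T"), comp_map[[lsc[1]]])[1]
  if (ssc[1] == comp_map[[ssc[ssc_len]]])
    ssc[1] <- setdiff(c("A", "C", "G", "T"), comp_map[[ssc[ssc_len]]])[1]
  unchars(c(lsc, irb, ssc, rev(unname(comp_map[irb]))))
}

## O(n^2) oracle: longest exact inverted repeat on the circle, by comparing
## the doubled sequence with its reverse complement at every offset
bf_longest_inverted_repeat <- function(s) {
  n <- nchar(s)
  d <- chars(paste0(s, s))
  rc <- rev(unname(comp_map[d]))
  nd <- length(d)
  best <- 0L
  for (off in (-(nd - 1L)):(nd - 1L)) {
    i1 <- max(1L, 1L + off); i2 <- min(nd, nd + off)
    if (i2 < i1) next
    x <- i1:i2
    eq <- d[x] == rc[x - off]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (k in which(r$values)) {
      len <- r$lengths[k]
      if (len <= best || len > n %/% 2) next
      ## exclude self-overlapping (palindromic) runs: map to circle coords
      xs <- x[ends[k] - len + 1L]
      a <- ((xs - 1L) %% n) + 1L
      y_hi <- nd - (xs - off) + 1L
      b <- ((y_hi - len + 1L - 1L) %% n) + 1L
      sep1 <- (b - (a + len)) %% n
      sep2 <- (a - (b + len)) %% n
      overlap <- ((b - a) %% n) < len || ((a - b) %% n) < len
      if (!overlap && (sep1 > 0L || sep2 > 0L)) best <- max(best, len)
    }
  }
  best
}

## regex oracle for perfect SSR scanning (MISA semantics)
bf_ssr_scan <- function(s, min_copies = c(10L, 5L, 5L, 4L, 3L, 3L)) {
  out <- list()
  for (p in 1:6) {
    k <- min_copies[p]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", p, k - 1L)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (i in seq_along(m)) {
      st <- as.integer(m[i])
      len <- attr(m, "match.length")[i]
      motif <- substr(s, st, st + p - 1L)
      ## primitivity
      prim <- TRUE
      for (q in seq_len(p - 1L)) {
        if (p %% q == 0L && strrep(substr(motif, 1, q), p %/% q) == motif) {
          prim <- FALSE; break
        }
      }
      if (!prim) next
      ## maximality on both sides (regex is greedy but left-anchored)
      copies <- len %/% p
      en <- st + copies * p - 1L
      if (st > 1L && substr(s, st - 1L, st - 1L) ==
          substr(s, st + p - 1L, st + p - 1L)) next  # left-extendable: not maximal
      out[[length(out) + 1L]] <- data.frame(motif = motif, motif_len = p,
                                            copies = copies, start = st,
                                            end = en, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(motif = character(0), motif_len = integer(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$motif_len), ]
}

## all-pairs Pi oracle for one window, complete deletion
bf_window_pi <- function(rows, from, to) {
  sub <- lapply(rows, function(r) chars(r)[from:to])
  keep <- Reduce(`&`, lapply(sub, function(x) x != "-" & x != "N"))
  nv <- sum(keep)
  if (nv == 0) return(0)
  tot <- 0; np <- 0
  for (i in seq_along(sub)[-length(sub)]) for (j in (i + 1):length(sub)) {
    tot <- tot + sum(sub[[i]][keep] != sub[[j]][keep]) / nv
    np <- np + 1
  }
  tot / np
}

## brute-force Saitou-Nei neighbor joining on a distance matrix, returning
## an ape tree; ties broken by smallest pair index
bf_nj <- function(d) {
  d <- as.matrix(d)
  labs <- rownames(d)
  nodes <- as.list(labs)
  lens <- as.list(rep(NA_real_, length(labs)))
  while (length(nodes) > 2) {
    n <- nrow(d)
    r <- rowSums(d)
    best <- NULL; bq <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      q <- (n - 2) * d[i, j] - r[i] - r[j]
      if (q < bq - 1e-12) { bq <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    newick_i <- if (is.na(lens[[i]])) nodes[[i]] else nodes[[i]]
    merged <- sprintf("(%s:%g,%s:%g)", nodes[[i]], bi, nodes[[j]], bj)
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(1:n, c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], merged)
    d <- d2
    rownames(d) <- colnames(d) <- NULL
  }
  tr <- sprintf("(%s:%g,%s:%g);", nodes[[1]], d[1, 2] / 2, nodes[[2]], d[1, 2] / 2)
  ape::read.tree(text = tr)
}

## memoized quarter-scale simulation fixture shared across test files:
## full per-species budgets on a 35 kb genome (scaled so the suite runs in
## minutes; the acceptance file also exercises one full-size genome set)
.fixture_env <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (!is.null(.fixture_env$fix)) return(.fixture_env$fix)
  cfg <- sim_config(lsc_len = 20750L, ssc_len = 3125L, ir_len = 5700L)
  sim <- simulate_plastome_set(cfg, seed = 3)
  al <- align_plastomes(sim$genomes, "reference", band = 200L)
  v <- call_variants(al)
  dv <- diagnostic_variants(v, sim$groups)
  .fixture_env$fix <- list(cfg = cfg, sim = sim, al = al, v = v, dv = dv)
  .fixture_env$fix
}

## truth-vs-called comparison used by recovery tests: per-sample sets of
## normalized records
called_set <- function(v, sample) {
  calls <- attr(v, "calls")
  alt <- calls[, sample]
  has <- !is.na(alt) & alt != v$ref
  paste(v$kind[has], v$pos[has], v$ref[has], alt[has])
}

truth_set <- function(truth, sample) {
  tt <- truth[truth$sample == sample, ]
  paste(tt$kind, tt$pos, tt$ref, tt$alt)
}
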