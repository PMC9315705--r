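#' Extract protein-coding genes shared single-copy across taxa
#'
#' A gene qualifies when every annotated genome carries exactly one feature
#' with that name (IR-duplicated genes have two features sharing a name and
#' are therefore excluded). CDS sequences are extracted on the coding
#' strand, with multi-part (intron-containing or trans-spliced) genes
#' spliced in part order.
#'
#' @param genomes list of annotated [plastome()] objects.
#' @param kind feature class to extract (default `"CDS"`).
#' @return named list (gene -> named character vector of per-taxon
#'   sequences).
#' @export
extract_shared_genes <- function(genomes, kind = "CDS") {
  ids <- vapply(genomes, function(g) g$id, character(1))
  names(genomes) <- ids
  for (g in genomes) {
    if (is.null(g$annotations) || nrow(g$annotations) == 0L)
      stop(sprintf("taxon '%s' lacks annotations", g$id))
  }
  per_taxon <- lapply(genomes, function(g) {
    feat <- g$annotations[g$annotations$kind == kind, , drop = FALSE]
    copies <- vapply(split(feat$feature_id, feat$gene),
                     function(x) length(unique(x)), integer(1))
    names(copies)[copies == 1L]
  })
  shared <- Reduce(intersect, per_taxon)
  out <- lapply(shared, function(gene) {
    vapply(genomes, function(g) splice_gene(g, gene), character(1))
  })
  names(out) <- shared
  out
}

## splice one gene copy out of a genome, on the coding strand
#' @noRd
splice_gene <- function(genome, gene) {
  feat <- genome$annotations
  f <- feat[feat$gene == gene, , drop = FALSE]
  f <- f[f$feature_id == f$feature_id[1L], , drop = FALSE]
  f <- f[order(f$part), , drop = FALSE]
  parts <- vapply(seq_len(nrow(f)), function(i) {
    s <- substr(genome$sequence, f$start[i], f$end[i])
    if (f$strand[i] == "-") revcomp(s) else s
  }, character(1))
  ## minus-strand multi-exon genes splice 3'-most part first
  if (all(f$strand == "-")) parts <- rev(parts)
  paste(parts, collapse = "")
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes are aligned one by one (banded global alignment against the first
#' taxon, merged center-star) unless already equal-length, then
#' concatenated with recorded partition boundaries. Taxa are ordered
#' canonically (sorted ids) so the matrix is invariant to input order. A
#' spliced gene with an internal stop codon is kept, with a warning:
#' annotation noise must not silently drop signal.
#'
#' @param gene_sets output of [extract_shared_genes()].
#' @param band pairwise band width for per-gene alignment.
#' @return object of class `supermatrix`: `taxa`, `seqs` (aligned,
#'   concatenated), `partitions` (data.frame gene/start/end, 1-based
#'   closed).
#' @export
build_supermatrix <- function(gene_sets, band = 50L) {
  stopifnot(length(gene_sets) > 0L)
  taxa <- sort(names(gene_sets[[1L]]))
  aligned <- lapply(names(gene_sets), function(gene) {
    seqs <- gene_sets[[gene]][taxa]
    if (any(is.na(seqs))) stop(sprintf("taxon missing from gene '%s'", gene))
    if (has_internal_stop(seqs[[1L]]))
      warning(sprintf("gene '%s' has an internal stop after splicing; retained", gene))
    if (length(unique(nchar(seqs))) > 1L) {
      gl <- lapply(taxa, function(t) plastome(t, seqs[[t]], circular = FALSE))
      al <- align_plastomes(gl, taxa[1L], band = band, max_len_diff = Inf)
      seqs <- al$seqs[taxa]
    }
    seqs
  })
  lens <- vapply(aligned, function(s) nchar(s[[1L]]), integer(1))
  ends <- cumsum(lens)
  partitions <- data.frame(gene = names(gene_sets),
                           start = c(1L, utils::head(ends, -1L) + 1L),
                           end = ends)
  seqs <- vapply(taxa, function(t)
    paste(vapply(aligned, `[[`, character(1), t), collapse = ""), character(1))
  structure(list(taxa = taxa, seqs = seqs, partitions = partitions),
            class = "supermatrix")
}

#' @noRd
has_internal_stop <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 6L) return(FALSE)
  codons <- substring(seq, seq.int(1L, n - 3L, 3L), seq.int(3L, n - 3L, 3L))
  any(codons %in% c("TAA", "TAG", "TGA"))
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %s sites, %d gene partitions\n",
              length(x$taxa), format(nchar(x$seqs[[1L]]), big.mark = ","),
              nrow(x$partitions)))
  invisible(x)
}

#' Write a supermatrix as aligned FASTA plus RAxML-style partition lines
#' @param sm a `supermatrix`.
#' @param fasta,partitions output paths.
#' @return invisibly, the two paths.
#' @export
write_supermatrix <- function(sm, fasta, partitions) {
  write_sequences(sm$seqs, fasta)
  writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$gene,
                     sm$partitions$start, sm$partitions$end), partitions)
  invisible(c(fasta, partitions))
}

#' Bootstrap neighbor-joining tree from a supermatrix
#'
#' Saitou--Nei neighbor joining (via [ape::nj()]) on p-distances or JC69
#' distances with pairwise deletion of gap/N sites, plus nonparametric
#' bootstrap by resampling matrix columns with a fixed seed. Support values
#' are bipartition frequencies in percent, attached as node labels. This is
#' a deliberate desk-scale stand-in for full ML inference: for
#' near-identical plastomes the topology is driven by shared SNPs, which
#' distance methods recover.
#'
#' @param sm a `supermatrix` (or any named character vector of aligned
#'   sequences).
#' @param model `"p-distance"` or `"JC69"`.
#' @param bootstrap_n bootstrap replicates (default 1000).
#' @param seed RNG seed for resampling (mandatory: runs are reproducible).
#' @param outgroup taxon to root on, or `NULL` for an unrooted tree.
#' @return an [ape::phylo] tree with `node.label` bootstrap percentages.
#' @export
nj_tree <- function(sm, model = c("p-distance", "JC69"), bootstrap_n = 1000L,
                    seed = 1L, outgroup = NULL) {
  model <- match.arg(model)
  seqs <- if (inherits(sm, "supermatrix")) sm$seqs else sm
  if (length(seqs) < 3L) stop("nj_tree requires >= 3 taxa")
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  ## site-pattern compression: distances and bootstraps only depend on the
  ## multiset of column patterns, so resampling becomes a multinomial draw
  ## over distinct patterns (the same device alignment packages use)
  pats <- do.call(paste0, lapply(seq_len(nrow(m)), function(r) m[r, ]))
  up <- unique(pats)
  idx <- match(pats, up)
  w <- tabulate(idx, length(up))
  pm <- do.call(rbind, strsplit(up, "", fixed = TRUE))  # P x taxa
  taxa <- rownames(m)
  nt <- length(taxa)
  pair_i <- pair_j <- integer(0)
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    pair_i <- c(pair_i, i); pair_j <- c(pair_j, j)
  }
  base <- c("A", "C", "G", "T")
  D <- O <- matrix(0, nrow(pm), length(pair_i))
  for (k in seq_along(pair_i)) {
    a <- pm[, pair_i[k]]; b <- pm[, pair_j[k]]
    ok <- a %in% base & b %in% base
    O[, k] <- as.numeric(ok)
    D[, k] <- as.numeric(ok & a != b)
  }
  dist_from_weights <- function(wt) {
    num <- as.numeric(wt %*% D)
    den <- as.numeric(wt %*% O)
    p <- ifelse(den > 0, num / den, 0)
    if (model == "JC69") {
      bad <- which(p >= 0.75)
      if (length(bad))
        stop(sprintf("JC69 distance undefined for pair %s/%s (p = %.3f)",
                     taxa[pair_i[bad[1L]]], taxa[pair_j[bad[1L]]], p[bad[1L]]))
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    dm <- matrix(0, nt, nt, dimnames = list(taxa, taxa))
    dm[cbind(pair_i, pair_j)] <- p
    dm[cbind(pair_j, pair_i)] <- p
    stats::as.dist(dm)
  }
  tree <- ape::nj(dist_from_weights(w))
  if (bootstrap_n > 0L) {
    set.seed(seed)
    C <- ncol(m)
    W <- stats::rmultinom(bootstrap_n, C, w / C)
    boots <- vector("list", bootstrap_n)
    for (b in seq_len(bootstrap_n)) {
      boots[[b]] <- tryCatch(ape::nj(dist_from_weights(W[, b])),
                             error = function(e) NULL)
    }
    boots <- boots[!vapply(boots, is.null, logical(1))]
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    support <- round(100 * counts / length(boots))
    tree$node.label <- as.character(support)
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label)
      stop(sprintf("outgroup '%s' not among taxa", outgroup))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  }
  tree
}

## pairwise p-distance / JC69 with pairwise deletion of gap/N sites
#' @noRd
pairwise_distances <- function(m, model = "p-distance") {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- m[i, ]; b <- m[j, ]
    ok <- a != "-" & a != "N" & b != "-" & b != "N"
    p <- if (!any(ok)) 0 else sum(a[ok] != b[ok]) / sum(ok)
    if (model == "JC69") {
      if (p >= 0.75)
        stop(sprintf("JC69 distance undefined for pair %s/%s (p = %.3f)",
                     rownames(m)[i], rownames(m)[j], p))
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- p
  }
  stats::as.dist(d)
}
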