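#' Plastome objects
#'
#' A `plastome` is the package's container for one circular chloroplast
#' genome: an identifier, a species (group) label, the sequence on the
#' stored forward strand, and optionally gene annotations and the detected
#' quadripartite structure.
#'
#' All coordinates inside the package are 1-based and closed, the IRanges
#' convention; conversions to 0-based half-open happen only at the BED
#' boundary and parsing of GFF3/GenBank converts into this convention.
#'
#' @param id single character identifier, unique within a collection.
#' @param sequence DNA string over `{A,C,G,T,N}`; `U` is mapped to `T` and
#'   lowercase is uppercased.
#' @param species species/group label (may be `NA` until a group map is
#'   attached).
#' @param circular logical; plastomes are circular molecules.
#' @param annotations a `gene_features` data.frame (see
#'   [gene_features()]) or `NULL`.
#' @param structure a `quadripartite` object (see
#'   [detect_quadripartite()]) or `NULL`.
#' @return an object of class `plastome`.
#' @export
plastome <- function(id, sequence, species = NA_character_, circular = TRUE,
                     annotations = NULL, structure = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_dna(sequence, id)
  if (nchar(sequence) == 0L) stop(sprintf("plastome '%s' has empty sequence", id))
  if (!is.null(annotations)) validate_features(annotations, nchar(sequence))
  structure(list(id = id, species = species, sequence = sequence,
                 circular = isTRUE(circular), annotations = annotations,
                 structure = structure),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("plastome '%s' (%s): %s bp, %s\n", x$id,
              ifelse(is.na(x$species), "ungrouped", x$species),
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear"))
  if (!is.null(x$annotations))
    cat(sprintf("  %d gene features\n", length(unique(x$annotations$feature_id))))
  if (!is.null(x$structure))
    cat(sprintf("  quadripartite: LSC %d / IRb %d / SSC %d / IRa %d bp\n",
                x$structure$lsc_len, x$structure$ir_len,
                x$structure$ssc_len, x$structure$ir_len))
  invisible(x)
}

#' @export
length.plastome <- function(x) nchar(x$sequence)

#' Gene feature tables
#'
#' Gene annotations are stored as a flat data.frame with one row per
#' feature *part* (exon); multi-part rows sharing a `feature_id` encode
#' introns and the trans-spliced \emph{rps12}. IR-duplicated genes appear
#' as two `feature_id`s sharing a `gene` name.
#'
#' @param gene gene symbol (e.g. `rps19`, `ndhF`).
#' @param kind one of `"CDS"`, `"tRNA"`, `"rRNA"`.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based closed part coordinates (parallel vectors; one
#'   element per part, in splicing order).
#' @param feature_id identifier unique per feature copy; defaults to the
#'   gene name.
#' @return data.frame of class `gene_features` with columns
#'   `feature_id, gene, kind, strand, start, end, part`.
#' @export
gene_features <- function(gene, kind, strand, start, end,
                          feature_id = gene) {
  n <- length(start)
  stopifnot(length(end) == n)
  df <- data.frame(feature_id = rep_len(feature_id, n),
                   gene = rep_len(gene, n),
                   kind = rep_len(kind, n),
                   strand = rep_len(strand, n),
                   start = as.integer(start), end = as.integer(end),
                   part = seq_len(n),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_features", "data.frame")
  df
}

#' Combine feature tables
#' @param ... `gene_features` tables.
#' @return a single `gene_features` table.
#' @export
bind_features <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("gene_features", "data.frame")
  df
}

#' @noRd
validate_features <- function(feat, genome_len) {
  stopifnot(is.data.frame(feat))
  need <- c("feature_id", "gene", "kind", "strand", "start", "end")
  if (!all(need %in% names(feat))) stop("feature table lacks required columns")
  if (nrow(feat) == 0L) return(invisible(feat))
  if (any(feat$start < 1L | feat$start > feat$end))
    stop("malformed feature interval")
  bad <- feat$end > genome_len
  if (any(bad))
    stop(sprintf("feature '%s' exceeds sequence length %d",
                 feat$gene[which(bad)[1L]], genome_len))
  if (!all(feat$kind %in% c("CDS", "tRNA", "rRNA")))
    stop("feature kind must be CDS, tRNA or rRNA")
  invisible(feat)
}

#' Sample-to-group maps
#'
#' A `group_map` records which species group each sample belongs to, as
#' used by diagnostic-variant detection and marker validation.
#'
#' @param sample character vector of plastome ids.
#' @param group parallel character vector of group (species) labels.
#' @return data.frame of class `group_map`.
#' @export
group_map <- function(sample, group) {
  stopifnot(length(sample) == length(group))
  if (anyDuplicated(sample))
    stop(sprintf("duplicate sample id in group map: %s",
                 sample[duplicated(sample)][1L]))
  df <- data.frame(sample = as.character(sample), group = as.character(group),
                   stringsAsFactors = FALSE)
  attr(df, "groups") <- unique(df$group)
  class(df) <- c("group_map", "data.frame")
  df
}

#' @noRd
groups_of <- function(gm) attr(gm, "groups") %||% unique(gm$group)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
check_group_map <- function(gm, ids) {
  missing <- setdiff(ids, gm$sample)
  if (length(missing))
    stop(sprintf("samples absent from group map: %s",
                 paste(missing, collapse = ", ")))
  tab <- table(gm$group[gm$sample %in% ids])
  if (any(tab == 0L)) stop("group with zero samples")
  invisible(gm)
}
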