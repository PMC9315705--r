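#' Attach gene annotations from a GenBank flat file or GFF3
#'
#' Both conventions are converted to the package's internal 1-based closed
#' coordinates on the stored forward strand. Joined (multi-exon or
#' trans-spliced) locations are preserved as multi-part features;
#' IR-duplicated genes appear as two features sharing a gene name.
#'
#' @param genome a [plastome()].
#' @param path GenBank flat file (`.gb`, `.gbk`, `.genbank`) or GFF3.
#' @param format `"auto"` (by extension), `"genbank"` or `"gff3"`.
#' @return the plastome with `$annotations` filled in.
#' @export
read_annotations <- function(genome, path, format = c("auto", "genbank", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|gbf|genbank)$", path, ignore.case = TRUE))
      "genbank" else "gff3"
  }
  feat <- switch(format,
                 genbank = parse_genbank_features(path),
                 gff3 = parse_gff3_features(path))
  validate_features(feat, nchar(genome$sequence))
  genome$annotations <- feat
  genome
}

## ---- GenBank flat file -----------------------------------------------------
## Minimal parser for the FEATURES table: CDS / tRNA / rRNA keys, location
## strings with complement()/join()/order(), and the /gene qualifier.
## No installed R package parses GenBank flat files offline, hence this one.

#' @noRd
parse_genbank_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) stop("no FEATURES table in GenBank file")
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1L]]) - 1L else length(lines)
  flines <- lines[(fstart[1L] + 1L):fend]

  ## a new feature starts at column 6 with a non-blank key
  is_key <- grepl("^ {5}\\S", flines)
  idx <- cumsum(is_key)
  recs <- split(flines, idx)
  recs <- recs[names(recs) != "0"]

  rows <- list()
  counters <- new.env(parent = emptyenv())
  for (rec in recs) {
    key <- sub("^ {5}(\\S+).*", "\\1", rec[1L])
    if (!key %in% c("CDS", "tRNA", "rRNA")) next
    body <- paste(sub("^ +", "", sub("^ {5}\\S+ +", "", rec)), collapse = "\n")
    ## location = everything up to the first qualifier line
    parts_txt <- strsplit(body, "\n/", fixed = TRUE)[[1L]]
    loc <- gsub("[\n ]", "", parts_txt[1L])
    quals <- if (length(parts_txt) > 1L) parts_txt[-1L] else character(0)
    gene <- NA_character_
    g <- grep("^gene=", quals, value = TRUE)
    if (length(g)) gene <- gsub("\"|\n.*", "", sub("^gene=", "", g[1L]))
    if (is.na(gene)) {
      g <- grep("^locus_tag=", quals, value = TRUE)
      if (length(g)) gene <- gsub("\"|\n.*", "", sub("^locus_tag=", "", g[1L]))
    }
    if (is.na(gene)) gene <- key
    loc_parsed <- parse_gb_location(loc)
    k <- sprintf("%s|%s", gene, key)
    n_prev <- if (exists(k, envir = counters)) get(k, envir = counters) else 0L
    assign(k, n_prev + 1L, envir = counters)
    fid <- if (n_prev == 0L) gene else sprintf("%s.%d", gene, n_prev + 1L)
    rows[[length(rows) + 1L]] <-
      gene_features(gene, key, loc_parsed$strand,
                    loc_parsed$start, loc_parsed$end, feature_id = fid)
  }
  if (!length(rows)) {
    return(gene_features(character(0), character(0), character(0),
                         integer(0), integer(0)))
  }
  do.call(bind_features, rows)
}

## parse a GenBank location string into parts + overall strand
#' @noRd
parse_gb_location <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  st <- en <- integer(length(parts)); ps <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[i]; s <- strand
    if (grepl("^complement\\(", p)) {
      s <- if (strand == "+") "-" else "+"
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    p <- gsub("[<>]", "", p)
    if (grepl("\\.\\.", p)) {
      nums <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    } else nums <- rep(as.integer(p), 2L)
    if (anyNA(nums)) stop(sprintf("unparseable GenBank location: %s", parts[i]))
    st[i] <- nums[1L]; en[i] <- nums[2L]; ps[i] <- s
  }
  list(start = st, end = en, strand = ps)
}

## ---- GFF3 ------------------------------------------------------------------

#' @noRd
parse_gff3_features <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(gr$type) %in% c("CDS", "tRNA", "rRNA")]
  if (length(gr) == 0L) {
    return(gene_features(character(0), character(0), character(0),
                         integer(0), integer(0)))
  }
  meta <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(meta)) as.character(meta$ID) else
    sprintf("feat%04d", seq_along(gr))
  ids[is.na(ids)] <- sprintf("feat%04d", which(is.na(ids)))
  genes <- if ("gene" %in% names(meta)) as.character(meta$gene) else
    if ("Name" %in% names(meta)) as.character(meta$Name) else ids
  genes[is.na(genes)] <- ids[is.na(genes)]
  rows <- lapply(split(seq_along(gr), ids), function(ii) {
    ii <- ii[order(GenomicRanges::start(gr)[ii])]
    gene_features(genes[ii[1L]], as.character(gr$type)[ii[1L]],
                  as.character(GenomicRanges::strand(gr))[ii[1L]],
                  GenomicRanges::start(gr)[ii], GenomicRanges::end(gr)[ii],
                  feature_id = ids[ii[1L]])
  })
  do.call(bind_features, rows)
}

#' Write gene annotations as GFF3
#'
#' Multi-part features are written as discontinuous GFF3 features sharing an
#' `ID`, the convention [read_annotations()] parses back.
#'
#' @param genome an annotated [plastome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations_gff3 <- function(genome, path) {
  feat <- genome$annotations
  if (is.null(feat)) stop("plastome has no annotations")
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$id,
                     nchar(genome$sequence)))
  if (nrow(feat)) {
    lines <- c(lines, sprintf(
      "%s\tplastmarker\t%s\t%d\t%d\t.\t%s\t.\tID=%s;gene=%s",
      genome$id, feat$kind, feat$start, feat$end, feat$strand,
      feat$feature_id, feat$gene))
  }
  writeLines(lines, path)
  invisible(path)
}
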