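#' Write variant calls as VCF 4.2
#'
#' Positions are written 1-based; InDel records carry the anchor base so
#' REF/ALT follow VCF conventions (the caller already left-aligns events).
#' Per-sample calls are haploid GT fields.
#'
#' @param variants a `variant_table` from [call_variants()].
#' @param path output file.
#' @param reference_id contig name for the header (defaults to the table's
#'   reference attribute).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, reference_id = attr(variants, "reference")) {
  calls <- attr(variants, "calls")
  samples <- colnames(calls)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=plastmarker",
           sprintf("##contig=<ID=%s>", reference_id %||% "ref"),
           "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"SNP or InDel\">",
           "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Region class\">",
           "##INFO=<ID=LOCUS,Number=1,Type=String,Description=\"Gene or flanking-gene pair\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- character(0)
  if (nrow(variants)) {
    info <- sprintf("TYPE=%s", variants$kind)
    if (!is.null(variants$region))
      info <- paste0(info, ";REGION=", variants$region,
                     ";LOCUS=", variants$locus)
    gt <- vapply(seq_len(nrow(variants)), function(i) {
      alleles <- c(variants$ref[i], strsplit(variants$alt[i], ",")[[1L]])
      idx <- match(calls[i, ], alleles) - 1L
      paste(ifelse(is.na(idx), ".", idx), collapse = "\t")
    }, character(1))
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s\tGT\t%s",
                    reference_id %||% "ref", variants$pos,
                    sprintf("var%04d", seq_len(nrow(variants))),
                    variants$ref, variants$alt, info, gt)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a plastmarker VCF back into a variant table
#'
#' Companion reader to [write_vcf()]; supports the subset of VCF 4.2 that
#' writer emits (haploid GT, TYPE/REGION/LOCUS INFO keys).
#'
#' @param path VCF file.
#' @return a `variant_table` (see [call_variants()]).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  if (!length(hdr_i)) stop("no #CHROM header line in VCF")
  cols <- strsplit(lines[hdr_i], "\t")[[1L]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  parse_info <- function(info, key) {
    m <- regmatches(info, regexpr(sprintf("%s=[^;]+", key), info))
    if (length(m) == 0L) NA_character_ else sub(sprintf("^%s=", key), "", m)
  }
  if (!length(body)) {
    vt <- data.frame(kind = character(0), pos = integer(0),
                     ref = character(0), alt = character(0),
                     stringsAsFactors = FALSE)
    attr(vt, "calls") <- matrix(character(0), 0, length(samples),
                                dimnames = list(NULL, samples))
  } else {
    f <- do.call(rbind, strsplit(body, "\t"))
    vt <- data.frame(kind = vapply(f[, 8], parse_info, "", key = "TYPE"),
                     pos = as.integer(f[, 2]), ref = f[, 4], alt = f[, 5],
                     stringsAsFactors = FALSE)
    region <- vapply(f[, 8], parse_info, "", key = "REGION")
    if (!all(is.na(region))) {
      vt$region <- region
      vt$locus <- vapply(f[, 8], parse_info, "", key = "LOCUS")
    }
    calls <- matrix(NA_character_, nrow(vt), length(samples),
                    dimnames = list(NULL, samples))
    for (i in seq_len(nrow(vt))) {
      alleles <- c(vt$ref[i], strsplit(vt$alt[i], ",")[[1L]])
      idx <- suppressWarnings(as.integer(f[i, -(1:9)])) + 1L
      calls[i, ] <- alleles[idx]
    }
    attr(vt, "calls") <- calls
  }
  rownames(vt) <- NULL
  attr(vt, "reference") <- sub("^##contig=<ID=([^,>]+).*", "\\1",
                               grep("^##contig", lines, value = TRUE)[1L])
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Write a sliding-window Pi profile as BED
#'
#' BED intervals are 0-based half-open; the score column carries Pi.
#'
#' @param profile a `pi_profile` from [sliding_pi()].
#' @param path output file.
#' @param chrom contig name.
#' @return `path`, invisibly.
#' @export
write_pi_bed <- function(profile, path, chrom = "alignment") {
  w <- profile$windows
  lines <- sprintf("%s\t%d\t%d\t%s\t%.6f", chrom, w$start - 1L, w$end,
                   sprintf("window%04d", seq_len(nrow(w))), w$pi)
  writeLines(lines, path)
  invisible(path)
}

#' Write any marker/SSR/junction table as TSV
#'
#' Column layout is the data.frame's own; list columns are flattened with
#' comma separators so tables stay greppable.
#'
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]]))
      df[[j]] <- vapply(df[[j]], function(v) paste(v, collapse = ","), character(1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
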