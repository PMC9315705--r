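#' Read plastome sequences from a FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any character outside
#' `{A,C,G,T,N}` is rejected. Record ids are the first whitespace-delimited
#' token of the header and must be unique.
#'
#' @param path FASTA file (may contain multiple records).
#' @param circular logical, applied to every record.
#' @return list of [plastome()] objects, named by id.
#' @export
read_sequences <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop(sprintf("duplicate sequence id: %s", dup[1L]))
  out <- lapply(seq_along(ss), function(i)
    plastome(ids[i], as.character(ss[[i]]), circular = circular))
  names(out) <- ids
  out
}

#' Write plastomes (or any named sequences) as FASTA
#'
#' @param x list of [plastome()] objects, or a named character vector of
#'   sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path) {
  if (is.list(x) && length(x) && inherits(x[[1L]], "plastome")) {
    seqs <- vapply(x, function(p) p$sequence, character(1))
    names(seqs) <- vapply(x, function(p) p$id, character(1))
  } else seqs <- x
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a sample-to-group map from TSV
#'
#' Expects two columns, `sample` and `group` (a header line is detected and
#' honoured; otherwise the first two columns are used in that order).
#'
#' @param path TSV file.
#' @return a [group_map()].
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  header <- grepl("^sample\\t", first)
  df <- if (header) {
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE,
                      col.names = c("sample", "group"))
  }
  group_map(df[[1L]], df[[2L]])
}

#' Write a group map as TSV
#' @param gm a [group_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(gm, path) {
  utils::write.table(as.data.frame(gm)[, c("sample", "group")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
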