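#' Write and read tab-separated tables
#'
#' Plain TSV round trip for the pipeline's tabular objects (catalogs, read
#' counts, expression tables, cell measurements).
#'
#' @param x a data frame; list columns are dropped with a message.
#' @param path file path.
#' @return `write_tsv_table()` returns `path` invisibly; `read_tsv_table()`
#'   returns a tibble.
#' @export
write_tsv_table <- function(x, path) {
  is_list <- vapply(x, is.list, logical(1))
  if (any(is_list)) {
    message(sprintf("dropping list columns: %s",
                    paste(names(x)[is_list], collapse = ", ")))
    x <- x[, !is_list, drop = FALSE]
  }
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Write catalog protein sequences as FASTA
#'
#' @param catalog a [generate_catalog()] result.
#' @param path output FASTA path.
#' @return `path` invisibly.
#' @export
write_protein_fasta <- function(catalog, path) {
  rows <- catalog[!is.na(catalog$protein_sequence), ]
  if (nrow(rows) == 0L) stop("catalog has no protein sequences", call. = FALSE)
  aa <- Biostrings::AAStringSet(setNames(rows$protein_sequence, rows$id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return tibble (`id`, `protein_sequence`).
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble::tibble(id = names(aa),
                 protein_sequence = unname(as.character(aa)))
}
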