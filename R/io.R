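#' Read a barcode set from a FASTA file
#'
#' Reads candidate barcodes (or an existing index set) from a standard FASTA
#' file and validates them into a [barcode_pool()]: equal lengths, A/C/G/T
#' alphabet, unique identifiers. Line-wrapped sequences are supported and
#' blank lines ignored; lower-case bases are normalized to upper case.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A [barcode_pool()] with records kept in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">b1", "AACACATC", ">b2", "AGAGTGCG"), f)
#' read_barcode_fasta(f)
#' @export
read_barcode_fasta <- function(path) {
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("cannot read FASTA: ", conditionMessage(e)))
  if (length(ss) == 0L) stop("no records: FASTA input is empty")
  ids <- sub("\\s.*$", "", names(ss))  # FASTA description after first word dropped
  barcode_pool(as.character(ss), ids)
}

#' Write a barcode set to a FASTA file
#'
#' @param pool A [barcode_pool()] (or anything [barcode_pool()] accepts).
#' @param path Output file path, or `""` to print to the console.
#' @return Invisibly, the FASTA text as a character vector.
#' @details Writing then re-reading a valid pool reproduces it exactly
#'   (identifiers, order, upper-case sequences).
#' @export
write_barcode_fasta <- function(pool, path) {
  if (is.null(pool) || (is.character(pool) && length(pool) == 0L)) {
    stop("nothing to write: empty barcode collection")
  }
  pool <- as_pool(pool)
  txt <- as.vector(rbind(paste0(">", pool$id), pool$seq))
  writeLines(txt, path)
  invisible(txt)
}
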