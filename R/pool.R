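#' Construct a barcode pool
#'
#' A barcode pool is an ordered collection of equal-length DNA barcodes
#' (sample indexes) over the alphabet A/C/G/T, each with a unique identifier.
#' It is the common input container for distance screening, balance
#' diagnostics and subset selection.
#'
#' @param seq Character vector of barcode sequences. Lower case is accepted
#'   and normalized to upper case.
#' @param id Character vector of unique identifiers, one per sequence.
#'   Defaults to `bc1`, `bc2`, ... or to `names(seq)` when present.
#' @return An object of class `barcode_pool`: a list with elements
#'   `id`, `seq`, `L` (common barcode length in nucleotides) and
#'   `M` (number of barcodes).
#' @details Sequences containing IUPAC ambiguity codes (N, R, Y, ...) are
#'   rejected: the balance cost and the laser-group balance are defined only
#'   over the four unambiguous nucleotides. Duplicate sequences under
#'   distinct identifiers are accepted with a warning; any minimum-distance
#'   threshold of at least 1 later excludes them from appearing together in
#'   a selected set.
#' @examples
#' barcode_pool(c("AACACATC", "AGAGTGCG"))
#' @seealso [read_barcode_fasta()], [select_barcodes()]
#' @export
barcode_pool <- function(seq, id = NULL) {
  if (length(seq) == 0L) stop("no records: a barcode pool needs at least one sequence")
  if (is.null(id)) {
    id <- if (!is.null(names(seq))) names(seq) else paste0("bc", seq_along(seq))
  }
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq must have equal length")
  if (any(!nzchar(id)) || anyNA(id)) stop("barcode identifiers must be non-empty")
  dup <- id[duplicated(id)]
  if (length(dup)) {
    stop("duplicate identifier: ", paste(unique(dup), collapse = ", "))
  }
  bad <- gregexpr("[^ACGT]", seq)
  for (i in seq_along(seq)) {
    pos <- bad[[i]]
    if (pos[1] != -1L) {
      stop(sprintf("invalid alphabet: record '%s' has character '%s' at position %d (only A,C,G,T allowed)",
                   id[i], substr(seq[i], pos[1], pos[1]), pos[1]))
    }
  }
  L <- nchar(seq)
  if (length(unique(L)) != 1L) {
    off <- which(L != L[1])[1]
    stop(sprintf("length mismatch: record '%s' has length %d, expected %d",
                 id[off], L[off], L[1]))
  }
  if (anyDuplicated(seq)) {
    warning("duplicate sequences present under distinct identifiers; ",
            "they can never be selected together when min_distance >= 1")
  }
  structure(list(id = id, seq = seq, L = L[1], M = length(seq)),
            class = "barcode_pool")
}

#' @export
print.barcode_pool <- function(x, ...) {
  cat(sprintf("Barcode pool: %d barcodes of length %d nt\n", x$M, x$L))
  show <- utils::head(seq_len(x$M), 10L)
  for (i in show) cat(sprintf("  %-12s %s\n", x$id[i], x$seq[i]))
  if (x$M > 10L) cat(sprintf("  ... and %d more\n", x$M - 10L))
  invisible(x)
}

#' @export
as.data.frame.barcode_pool <- function(x, ...) {
  data.frame(id = x$id, seq = x$seq, stringsAsFactors = FALSE)
}

#' @export
length.barcode_pool <- function(x) x$M

#' Extract a subset of a barcode pool
#'
#' @param x A `barcode_pool`.
#' @param i Index vector (positions, logicals, or identifiers).
#' @param ... Ignored.
#' @return A `barcode_pool` with the selected barcodes, in the given order.
#' @export
`[.barcode_pool` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  barcode_pool(x$seq[i], x$id[i])
}

# Internal: coerce path / pool / character vector to barcode_pool
as_pool <- function(x) {
  if (inherits(x, "barcode_pool")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(read_barcode_fasta(x))
  }
  barcode_pool(x)
}

# Internal: pool -> L x M character matrix (rows = positions)
pool_matrix <- function(pool) {
  m <- vapply(strsplit(pool$seq, "", fixed = TRUE), identity,
              character(pool$L))
  if (pool$L == 1L) m <- matrix(m, nrow = 1L)
  m
}
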