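#' Distance specification for barcode compatibility
#'
#' Bundles the sequence-distance metric and the minimum pairwise distance two
#' barcodes must satisfy to be used together. With Hamming distance, a
#' minimum distance of 2m+1 guarantees that up to m substitution errors per
#' read can be corrected during demultiplexing; the default of 3 tolerates
#' one sequencing error.
#'
#' @param metric `"hamming"` (substitutions only, equal lengths) or
#'   `"levenshtein"` (substitutions, insertions and deletions).
#' @param min_distance Non-negative integer; pairs closer than this are
#'   forbidden from co-occurring in a selected set. Default 3.
#' @return An object of class `distance_spec` with fields `metric`,
#'   `min_distance` and `tolerated_mismatches` (`floor((d-1)/2)`, reported
#'   for the Hamming metric; with indels the error-correction guarantee does
#'   not transfer directly, so it is `NA` for Levenshtein).
#' @export
distance_spec <- function(metric = c("hamming", "levenshtein"), min_distance = 3L) {
  metric <- match.arg(metric)
  min_distance <- as.integer(min_distance)
  if (is.na(min_distance) || min_distance < 0L) {
    stop("min_distance must be a non-negative integer")
  }
  structure(list(metric = metric,
                 min_distance = min_distance,
                 tolerated_mismatches = if (metric == "hamming")
                   max(0L, (min_distance - 1L) %/% 2L) else NA_integer_),
            class = "distance_spec")
}

#' @export
print.distance_spec <- function(x, ...) {
  cat(sprintf("Distance spec: %s, min pairwise distance %d", x$metric, x$min_distance))
  if (!is.na(x$tolerated_mismatches)) {
    cat(sprintf(" (corrects up to %d substitution error%s)",
        x$tolerated_mismatches, if (x$tolerated_mismatches == 1L) "" else "s"))
  }
  cat("\n")
  invisible(x)
}

#' Hamming distance between two sequences
#'
#' Number of mismatching positions in the gapless alignment of two
#' equal-length sequences.
#'
#' @param a,b Character scalars of equal length.
#' @return Integer in `[0, nchar(a)]`.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop(sprintf("length mismatch: %d vs %d nt", nchar(a), nchar(b)))
  }
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Levenshtein (edit) distance between two sequences
#'
#' Minimum number of substitutions, insertions and deletions converting one
#' sequence into the other (plain global edit distance; no free end gaps).
#' Note that demultiplexing with fixed-length index reads cannot exploit
#' indels freely, so Levenshtein distances can be optimistic about real
#' error tolerance.
#'
#' @param a,b Character scalars; lengths may differ.
#' @return Non-negative integer.
#' @export
levenshtein_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

# Internal: full symmetric distance matrix for a pool
pairwise_distance_matrix <- function(pool, metric = c("hamming", "levenshtein")) {
  metric <- match.arg(metric)
  M <- pool$M
  if (metric == "levenshtein") {
    d <- utils::adist(pool$seq)
  } else {
    chars <- pool_matrix(pool)              # L x M
    d <- matrix(0L, M, M)
    for (j in seq_len(M - 1L)) {
      rest <- (j + 1L):M
      dj <- colSums(chars[, rest, drop = FALSE] != chars[, j])
      d[j, rest] <- dj
      d[rest, j] <- dj
    }
  }
  dimnames(d) <- list(pool$id, pool$id)
  d
}

#' Enumerate barcode pairs violating the minimum distance
#'
#' Computes all pairwise distances in a pool and returns exactly the pairs
#' whose distance falls below the threshold; these pairs must not co-occur
#' in a selected set.
#'
#' @param pool A [barcode_pool()] (or path / character vector).
#' @param spec A [distance_spec()].
#' @return A data frame with columns `j`, `k` (1-based indexes, `j < k`),
#'   `id_j`, `id_k` and `distance`; zero rows when all pairs meet the
#'   threshold.
#' @examples
#' forbidden_pairs(barcode_pool(c("AAAA", "AAAT", "TTTT")), distance_spec("hamming", 3))
#' @export
forbidden_pairs <- function(pool, spec = distance_spec()) {
  pool <- as_pool(pool)
  stopifnot(inherits(spec, "distance_spec"))
  empty <- data.frame(j = integer(), k = integer(),
                      id_j = character(), id_k = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  if (pool$M < 2L || spec$min_distance == 0L) return(empty)
  d <- pairwise_distance_matrix(pool, spec$metric)
  idx <- which(upper.tri(d) & d < spec$min_distance, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(j = idx[, 1L], k = idx[, 2L],
             id_j = pool$id[idx[, 1L]], id_k = pool$id[idx[, 2L]],
             distance = d[idx], stringsAsFactors = FALSE)
}

#' Minimum pairwise distance within a pool
#'
#' Diagnostic used by the check mode: the smallest distance over all
#' unordered barcode pairs.
#'
#' @inheritParams forbidden_pairs
#' @param metric `"hamming"` or `"levenshtein"`.
#' @return Integer scalar.
#' @export
min_pairwise_distance <- function(pool, metric = c("hamming", "levenshtein")) {
  pool <- as_pool(pool)
  if (pool$M < 2L) stop("need at least two barcodes")
  d <- pairwise_distance_matrix(pool, match.arg(metric))
  min(d[upper.tri(d)])
}
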