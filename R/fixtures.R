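#' Bundled example sets of optimal 8-nt barcodes
#'
#' Four published example index sets of 8, 12, 16 and 24 barcodes, each
#' 8 nt long. Within every set all pairwise Hamming distances are at least
#' 3 (one sequencing error per index read can be corrected) and the four
#' nucleotides appear equally often at every barcode position, so the
#' balance cost of each whole set is exactly 0.
#'
#' @return Named list of four [barcode_pool()]s: `A` (8), `B` (12),
#'   `C` (16), `D` (24).
#' @examples
#' sets <- example_barcode_sets()
#' balance_cost(sets$A)$total  # 0
#' @export
example_barcode_sets <- function() {
  sets <- list(
    A = c("AACACATC", "AGAGTGCG", "CCGTATAT", "CTTGGTTG",
          "GAGATAAC", "GTACAGGA", "TCTCGCCT", "TGCTCCGA"),
    B = c("AGTTGCTG", "ATAGAGTC", "ATCATTGC", "CAGTTCCA",
          "CATGGAAT", "CGCAAGCT", "GAGATAAC", "GCAGATAA",
          "GGCTCTTG", "TCGCCAGA", "TCTCGCCT", "TTACCGGG"),
    C = c("ACACAGGC", "ACTGTTAG", "ATAGAGTC", "ATTAGCTG",
          "CAGTTCCA", "CCGTATAT", "CGCAAGCT", "CTGGCACA",
          "GACACTAA", "GGAGTAGA", "GGCTCTTG", "GGGAGATC",
          "TACTGCAG", "TATCCAGT", "TCTCGCCT", "TTACTGGC"),
    D = c("ACACAGGC", "AGCCTACT", "AGTTCCGC", "ATACGGAT",
          "ATGACGAA", "ATGGTCTC", "CAGTTCCA", "CATGTTGA",
          "CCTGAACC", "CGAACTTC", "CTCCGGTT", "CTGAATCA",
          "GAAAGAAG", "GAGATTGT", "GCATCACG", "GCCGAATG",
          "GCTGAAGA", "GGCTCTTG", "TACTGCAG", "TATCTGTG",
          "TCTCGCCT", "TGAGAGAT", "TGCTCCGA", "TTGAGTAC"))
  stats::setNames(lapply(names(sets), function(nm) {
    barcode_pool(sets[[nm]], paste0(tolower(nm), seq_along(sets[[nm]])))
  }), names(sets))
}

#' Generate a synthetic candidate pool with a planted optimal subset
#'
#' Builds a reproducible candidate pool for testing and benchmarking. When
#' `planted_n` is given (a multiple of 4), the pool contains a planted
#' subset of that size with balance cost exactly 0: each of its positions
#' is an independent random permutation of the balanced multiset
#' A,C,G,T repeated `planted_n/4` times, rejection-sampled until all
#' pairwise Hamming distances reach `min_distance`. The remaining
#' `M - planted_n` decoys are drawn with a skewed nucleotide composition so
#' that including them worsens the balance. The planted subset is verified
#' post hoc (cost 0, distances) before the pool is returned; construction
#' never relies on the sampling being correct by itself.
#'
#' @param M Pool size.
#' @param L Barcode length in nucleotides.
#' @param planted_n Size of the planted cost-zero subset (multiple of 4,
#'   at most `M`), or `NULL` for a pool of decoys only.
#' @param min_distance Minimum pairwise Hamming distance the planted subset
#'   must satisfy (default 3).
#' @param decoy_bias Skew of the decoy nucleotide composition in `[0, 1)`:
#'   0 gives uniform decoys, larger values push decoys further from balance.
#' @param seed RNG seed; the pool is a deterministic function of the
#'   arguments. The caller's RNG state is left untouched.
#' @param max_tries Rejection-sampling retry cap before giving up.
#' @return List with `pool` (a [barcode_pool()], order shuffled) and
#'   `planted_ids` (identifiers of the planted subset; `character(0)` if
#'   none).
#' @examples
#' fx <- generate_candidate_pool(M = 32, L = 8, planted_n = 8, seed = 1)
#' balance_cost(fx$pool[fx$planted_ids])$total  # 0
#' @export
generate_candidate_pool <- function(M, L, planted_n = NULL, min_distance = 3L,
                                    decoy_bias = 0.5, seed = 1L,
                                    max_tries = 1000L) {
  stopifnot(M >= 1L, L >= 1L, decoy_bias >= 0, decoy_bias < 1)
  if (!is.null(planted_n)) {
    if (planted_n %% 4L != 0L) stop("planted_n must be a multiple of 4")
    if (planted_n > M) stop("planted_n cannot exceed M")
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  planted <- character()
  if (!is.null(planted_n) && planted_n > 0L) {
    for (try in seq_len(max_tries)) {
      cols <- replicate(L, sample(rep(NUC, planted_n / 4L)))
      cand <- apply(matrix(cols, ncol = L), 1L, paste, collapse = "")
      if (anyDuplicated(cand)) next
      if (planted_n >= 2L &&
          min_pairwise_distance(barcode_pool(cand), "hamming") < min_distance) next
      planted <- cand
      break
    }
    if (!length(planted)) {
      stop(sprintf(paste0(
        "cannot plant subset: no %d balanced %d-mers at pairwise Hamming ",
        "distance >= %d found in %d tries; lengthen the barcodes, shrink the ",
        "subset or lower the distance threshold"),
        planted_n, L, min_distance, max_tries))
    }
  }

  probs <- (1 - decoy_bias) * rep(0.25, 4L) + decoy_bias * c(0.55, 0.25, 0.12, 0.08)
  seqs <- planted
  tries <- 0L
  while (length(seqs) < M) {
    s <- paste(sample(NUC, L, replace = TRUE, prob = probs), collapse = "")
    if (s %in% seqs) {
      tries <- tries + 1L
      if (tries > max_tries) stop("cannot generate ", M, " distinct decoys; increase L")
      next
    }
    seqs <- c(seqs, s)
  }

  ord <- sample.int(M)
  ids <- paste0("cand", seq_len(M))
  pool <- barcode_pool(seqs[ord], ids)
  planted_ids <- ids[match(seq_along(planted), ord)]

  if (length(planted)) {   # post-hoc verification, never trust construction
    sub <- pool[planted_ids]
    stopifnot(balance_cost(sub)$total == 0,
              planted_n < 2L ||
                min_pairwise_distance(sub, "hamming") >= min_distance)
  }
  list(pool = pool, planted_ids = planted_ids)
}
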