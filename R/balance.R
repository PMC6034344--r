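NUC <- c("A", "C", "G", "T")

#' Per-position and global nucleotide counts of a barcode set
#'
#' For a set of n equal-length barcodes, counts how many barcodes carry each
#' nucleotide at each position, plus the four global totals over all
#' positions. These counts are the raw material of the balance cost: on
#' two-laser Illumina chemistry the A/C and G/T groups should each cover
#' about half the barcodes at every cycle, and ideally each single
#' nucleotide covers n/4.
#'
#' @param subset A [barcode_pool()], character vector of sequences, or FASTA
#'   path; all sequences equal length.
#' @return Object of class `balance_profile`: list with `position_counts`
#'   (L x 4 integer matrix, columns A,C,G,T), `global_counts` (length-4
#'   integer vector), `n` (subset size) and `L` (barcode length).
#' @examples
#' balance_profile(c("ACGT", "CAGT"))
#' @export
balance_profile <- function(subset) {
  pool <- as_pool(subset)
  if (pool$M < 1L) stop("empty set")
  chars <- pool_matrix(pool)   # L x n
  counts <- vapply(NUC, function(b) rowSums(chars == b), numeric(pool$L))
  counts <- matrix(as.integer(counts), nrow = pool$L,
                   dimnames = list(paste0("pos", seq_len(pool$L)), NUC))
  structure(list(position_counts = counts,
                 global_counts = colSums(counts),
                 n = pool$M, L = pool$L),
            class = "balance_profile")
}

#' @export
print.balance_profile <- function(x, ...) {
  cat(sprintf("Nucleotide balance profile: n = %d barcodes, L = %d nt\n", x$n, x$L))
  print(rbind(x$position_counts, total = x$global_counts))
  invisible(x)
}

#' Nucleotide-balance cost of a barcode set
#'
#' Evaluates the balance objective that the selection ILP minimizes, as a
#' plain unweighted sum of absolute deviations:
#' for every position l, the two laser-group terms
#' `|n_l^A + n_l^C - n/2| + |n_l^G + n_l^T - n/2|` and the four
#' single-nucleotide terms `|n_l^X - n/4|`; plus four global terms
#' `|N^X - nL/4|` over all positions. A cost of 0 is attainable exactly when
#' n is a multiple of four and every position carries each nucleotide n/4
#' times.
#'
#' All arithmetic is done in scaled integers (quarter counts), so the parts
#' and total are exact even when n is not divisible by 2 or 4; values are
#' integer multiples of 0.25.
#'
#' @inheritParams balance_profile
#' @return Object of class `cost_breakdown`: list with
#'   `positional_group_cost`, `positional_single_cost`, `global_cost` and
#'   `total` (their sum).
#' @examples
#' balance_cost(c("AACACATC", "AGAGTGCG", "CCGTATAT", "CTTGGTTG",
#'                "GAGATAAC", "GTACAGGA", "TCTCGCCT", "TGCTCCGA"))$total  # 0
#' @export
balance_cost <- function(subset) {
  prof <- if (inherits(subset, "balance_profile")) subset else balance_profile(subset)
  n <- prof$n
  pc <- prof$position_counts
  # quarter-count units: |g - n/2| -> 2|2g - n|, |c - n/4| -> |4c - n|,
  # |N - nL/4| -> |4N - nL|
  grp_q <- 2L * (abs(2L * (pc[, "A"] + pc[, "C"]) - n) +
                 abs(2L * (pc[, "G"] + pc[, "T"]) - n))
  sng_q <- rowSums(abs(4L * pc - n))
  glb_q <- sum(abs(4L * prof$global_counts - n * prof$L))
  structure(list(positional_group_cost = sum(grp_q) / 4,
                 positional_single_cost = sum(sng_q) / 4,
                 global_cost = glb_q / 4,
                 total = (sum(grp_q) + sum(sng_q) + glb_q) / 4),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("Nucleotide-balance cost\n")
  cat(sprintf("  positional laser-group (A/C vs G/T): %g\n", x$positional_group_cost))
  cat(sprintf("  positional single-nucleotide:        %g\n", x$positional_single_cost))
  cat(sprintf("  global nucleotide balance:           %g\n", x$global_cost))
  cat(sprintf("  total:                               %g\n", x$total))
  invisible(x)
}

#' Tabular (and optional graphical) balance report
#'
#' One row per barcode position plus a `total` row, each with the four
#' nucleotide counts and fractions. Fractions in every row sum to 1. The
#' table is the canonical output; set `plot_file` to additionally draw the
#' stacked per-position composition chart.
#'
#' @inheritParams balance_profile
#' @param file Optional path for a TSV copy of the table.
#' @param plot_file Optional image path (`.png` or `.pdf` by extension).
#' @return The report as a data frame, invisibly when `file` is given.
#' @export
balance_report <- function(subset, file = NULL, plot_file = NULL) {
  prof <- if (inherits(subset, "balance_profile")) subset else balance_profile(subset)
  counts <- rbind(prof$position_counts, total = prof$global_counts)
  denom <- c(rep(prof$n, prof$L), prof$n * prof$L)
  frac <- counts / denom
  rep_df <- data.frame(position = c(as.character(seq_len(prof$L)), "total"),
                       counts, frac, check.names = FALSE, row.names = NULL,
                       stringsAsFactors = FALSE)
  names(rep_df) <- c("position", paste0("count_", NUC), paste0("frac_", NUC))
  if (!is.null(plot_file)) {
    ext <- tolower(sub(".*\\.", "", plot_file))
    switch(ext,
           png = grDevices::png(plot_file, width = 800, height = 500),
           pdf = grDevices::pdf(plot_file, width = 8, height = 5),
           stop("unsupported plot format: ", ext))
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_balance(prof)
  }
  if (!is.null(file)) {
    utils::write.table(rep_df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep_df))
  }
  rep_df
}

#' Stacked per-position nucleotide composition plot
#'
#' Draws one stacked bar per barcode position showing the fraction of
#' barcodes carrying A, C, G and T there, plus a `total` column for the
#' global composition. A perfectly balanced set shows four equal bands of
#' 0.25 everywhere.
#'
#' @inheritParams balance_profile
#' @param main Plot title.
#' @return Invisibly, the fraction matrix that was drawn.
#' @export
plot_balance <- function(subset, main = "Nucleotide balance") {
  prof <- if (inherits(subset, "balance_profile")) subset else balance_profile(subset)
  frac <- t(rbind(prof$position_counts / prof$n,
                  total = prof$global_counts / (prof$n * prof$L)))
  cols <- c(A = "#E41A1C", C = "#FF7F00", G = "#4DAF4A", T = "#377EB8")
  graphics::barplot(frac, col = cols[NUC], border = NA,
                    names.arg = c(seq_len(prof$L), "total"),
                    xlab = "barcode position", ylab = "fraction of barcodes",
                    main = main, legend.text = NUC,
                    args.legend = list(x = "topright", inset = c(-0.08, 0),
                                       xpd = TRUE, bty = "n"))
  graphics::abline(h = c(0.25, 0.5, 0.75), lty = 3, col = "grey40")
  invisible(frac)
}
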