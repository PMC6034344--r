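#' Select an optimal barcode subset from candidates
#'
#' The main entry point: picks `n` barcodes out of a candidate pool so that
#' the nucleotide-balance cost is minimal among all subsets whose pairwise
#' sequence distances all reach the threshold. The search is exact
#' branch-and-bound on the selection ILP; if the time limit stops it, the
#' best subset found so far is returned with status
#' `"feasible_time_limited"`.
#'
#' @param candidates A [barcode_pool()], FASTA path, or character vector of
#'   candidate sequences.
#' @param n Number of barcodes to select.
#' @param metric `"hamming"` or `"levenshtein"`.
#' @param min_distance Minimum pairwise distance (default 3, tolerating one
#'   sequencing error under Hamming distance).
#' @param time_limit Solver wall-clock limit in seconds (default 10).
#' @param branch_depth_limit Passed to [solver_options()].
#' @param seed Backend initialization hint, see [solver_options()].
#' @param fixed Candidates forced into the solution (indexes or ids);
#'   used by [augment_barcodes()].
#' @param allow_fixed_conflicts See [selection_problem()].
#' @param out_fasta Optional path: write the selected barcodes as FASTA.
#' @param report_file Optional path: write the balance table as TSV.
#' @param plot_file Optional path: write the balance plot (png/pdf).
#' @return A `selection_result`; see [solve_ilp()].
#' @examples
#' \donttest{
#' pools <- example_barcode_sets()
#' res <- select_barcodes(pools$A, n = 8)
#' res$objective_value  # 0: the whole set is perfectly balanced
#' }
#' @export
select_barcodes <- function(candidates, n,
                            metric = c("hamming", "levenshtein"),
                            min_distance = 3L,
                            time_limit = 10, branch_depth_limit = 0L,
                            seed = NULL, fixed = integer(),
                            allow_fixed_conflicts = FALSE,
                            out_fasta = NULL, report_file = NULL,
                            plot_file = NULL) {
  pool <- as_pool(candidates)
  spec <- distance_spec(match.arg(metric), min_distance)
  opts <- solver_options(time_limit, branch_depth_limit, seed)
  prob <- selection_problem(pool, n, spec, fixed = fixed, options = opts,
                            allow_fixed_conflicts = allow_fixed_conflicts)
  structure_ <- build_selection_ilp(prob)
  res <- solve_ilp(structure_)
  if (res$status == "infeasible") {
    message(sprintf(
      "no subset of size %d meets distance >= %d: %d forbidden pair(s) among %d candidates",
      n, spec$min_distance, structure_$n_pair_constraints, pool$M))
    return(res)
  }
  write_selection_outputs(res, out_fasta, report_file, plot_file)
  res
}

# Internal: shared report writing for select/augment
write_selection_outputs <- function(res, out_fasta, report_file, plot_file) {
  if (!is.null(out_fasta)) write_barcode_fasta(res$selected, out_fasta)
  if (!is.null(report_file) || !is.null(plot_file)) {
    balance_report(res$selected, file = report_file, plot_file = plot_file)
  }
  invisible(res)
}

#' Check an existing barcode set for compatibility and balance
#'
#' Diagnostics only, no optimization: reports the minimum pairwise distance,
#' every pair below the threshold, the balance cost breakdown and the full
#' balance table for the set exactly as given. Typical use: deciding whether
#' two libraries with already-assigned indexes can be pooled in one
#' sequencing run (check the union of their barcode sets).
#'
#' @inheritParams select_barcodes
#' @param barcodes The barcode set to check (pool, FASTA path or character
#'   vector).
#' @param report_file,plot_file Optional output paths as in
#'   [select_barcodes()].
#' @return Object of class `barcode_check`: `pool`, `spec`, `compatible`
#'   (TRUE iff no violating pairs), `violations` (data frame from
#'   [forbidden_pairs()]), `min_distance_observed`, `breakdown`, `profile`,
#'   `report`.
#' @examples
#' chk <- check_barcodes(c("AAAA", "AAAT"), min_distance = 3)
#' chk$compatible  # FALSE: the pair is only 1 mismatch apart
#' @export
check_barcodes <- function(barcodes, metric = c("hamming", "levenshtein"),
                           min_distance = 3L,
                           report_file = NULL, plot_file = NULL) {
  pool <- as_pool(barcodes)
  spec <- distance_spec(match.arg(metric), min_distance)
  viol <- forbidden_pairs(pool, spec)
  prof <- balance_profile(pool)
  rep_df <- balance_report(prof, file = report_file, plot_file = plot_file)
  structure(list(pool = pool, spec = spec,
                 compatible = nrow(viol) == 0L,
                 violations = viol,
                 min_distance_observed =
                   if (pool$M >= 2L) min_pairwise_distance(pool, spec$metric) else NA_integer_,
                 breakdown = balance_cost(prof),
                 profile = prof, report = rep_df),
            class = "barcode_check")
}

#' @export
print.barcode_check <- function(x, ...) {
  cat(sprintf("Barcode set check: %d barcodes of %d nt, %s distance >= %d required\n",
              x$pool$M, x$pool$L, x$spec$metric, x$spec$min_distance))
  cat(sprintf("  verdict: %s\n", if (x$compatible) "compatible" else "NOT compatible"))
  if (!is.na(x$min_distance_observed)) {
    cat(sprintf("  min pairwise distance: %d\n", x$min_distance_observed))
  }
  if (nrow(x$violations)) {
    cat("  violating pairs:\n")
    for (r in seq_len(nrow(x$violations))) {
      cat(sprintf("    %s vs %s: distance %d\n", x$violations$id_j[r],
                  x$violations$id_k[r], x$violations$distance[r]))
    }
  }
  cat(sprintf("  balance cost: %g (positional group %g + single %g + global %g)\n",
              x$breakdown$total, x$breakdown$positional_group_cost,
              x$breakdown$positional_single_cost, x$breakdown$global_cost))
  invisible(x)
}

#' Augment an existing barcode set with new compatible barcodes
#'
#' Expands an already-committed index set: the initial barcodes are forced
#' into the solution (appended to the candidate pool if not already in it)
#' and `n_new` additional barcodes are chosen from the candidates so that
#' the combined set of size `|initial| + n_new` minimizes the balance cost
#' under the distance constraints.
#'
#' @inheritParams select_barcodes
#' @param initial The committed barcode set (pool, FASTA path or character
#'   vector); may be `NULL` or empty, in which case this is plain
#'   [select_barcodes()].
#' @param n_new Number of new barcodes to add (>= 0).
#' @return A `selection_result`; `new_idx` indexes the newly added barcodes
#'   within the (possibly extended) candidate pool, and
#'   `result$selected$id` marks nothing — use `result$new_idx` /
#'   `result$problem$fixed` to distinguish kept from added.
#' @export
augment_barcodes <- function(candidates, initial, n_new,
                             metric = c("hamming", "levenshtein"),
                             min_distance = 3L,
                             time_limit = 10, branch_depth_limit = 0L,
                             seed = NULL, allow_fixed_conflicts = FALSE,
                             out_fasta = NULL, report_file = NULL,
                             plot_file = NULL) {
  metric <- match.arg(metric)
  pool <- as_pool(candidates)
  n_new <- as.integer(n_new)
  if (is.na(n_new) || n_new < 0L) stop("n_new must be a non-negative integer")
  if (is.null(initial) || (is.character(initial) && length(initial) == 0L)) {
    return(select_barcodes(pool, n_new, metric, min_distance, time_limit,
                           branch_depth_limit, seed,
                           out_fasta = out_fasta, report_file = report_file,
                           plot_file = plot_file))
  }
  init <- as_pool(initial)
  if (init$L != pool$L) {
    stop(sprintf("length mismatch: initial barcodes are %d nt, candidates %d nt",
                 init$L, pool$L))
  }
  # initial barcodes already in the pool (by sequence) become fixed there;
  # the rest are appended
  fixed <- match(init$seq, pool$seq)
  absent <- which(is.na(fixed))
  if (length(absent)) {
    add_id <- make.unique(c(pool$id, init$id[absent]),
                          sep = "_")[pool$M + seq_along(absent)]
    pool <- barcode_pool(c(pool$seq, init$seq[absent]), c(pool$id, add_id))
    fixed[absent] <- pool$M - length(absent) + seq_along(absent)
  }
  fixed <- unique(fixed)
  n <- length(fixed) + n_new
  if (n > pool$M) {
    stop(sprintf("not enough candidates: need %d (= %d fixed + %d new) from a pool of %d",
                 n, length(fixed), n_new, pool$M))
  }
  # fail fast if the committed set itself violates the threshold
  spec <- distance_spec(metric, min_distance)
  if (!allow_fixed_conflicts && length(fixed) >= 2L) {
    fp0 <- forbidden_pairs(pool[fixed], spec)
    if (nrow(fp0)) {
      stop(sprintf("initial set violates the distance threshold: '%s' vs '%s' at distance %d < %d",
                   fp0$id_j[1], fp0$id_k[1], fp0$distance[1], min_distance))
    }
  }
  if (n_new == 0L) {
    sel <- pool[fixed]
    bd <- balance_cost(sel)
    prob <- selection_problem(pool, n, spec, fixed = fixed,
                              options = solver_options(time_limit,
                                                       branch_depth_limit, seed),
                              allow_fixed_conflicts = allow_fixed_conflicts)
    res <- structure(list(selected = sel, selected_idx = fixed,
                          objective_value = bd$total, breakdown = bd,
                          status = "optimal", solver_objective = bd$total,
                          new_idx = integer(), problem = prob),
                     class = "selection_result")
    write_selection_outputs(res, out_fasta, report_file, plot_file)
    return(res)
  }
  select_barcodes(pool, n, metric, min_distance, time_limit,
                  branch_depth_limit, seed, fixed = fixed,
                  allow_fixed_conflicts = allow_fixed_conflicts,
                  out_fasta = out_fasta, report_file = report_file,
                  plot_file = plot_file)
}
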