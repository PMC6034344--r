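#' Solver options for the selection ILP
#'
#' @param time_limit Wall-clock limit in seconds for the branch-and-bound
#'   search (default 10). When it is hit, the best feasible solution found so
#'   far (the incumbent) is returned and flagged.
#' @param branch_depth_limit Integer; 0 means unrestricted. Honored only if
#'   the backend supports depth limiting, otherwise a warning is emitted.
#' @param seed Opaque initialization hint passed through to the backend so
#'   runs can be made repeatable per backend; the bundled HiGHS backend is
#'   deterministic on its own and ignores it.
#' @param backend_options Named list passed verbatim to the backend.
#' @return Object of class `solver_options`.
#' @export
solver_options <- function(time_limit = 10, branch_depth_limit = 0L,
                           seed = NULL, backend_options = list()) {
  stopifnot(is.numeric(time_limit), time_limit > 0)
  structure(list(time_limit = time_limit,
                 branch_depth_limit = as.integer(branch_depth_limit),
                 seed = seed, backend_options = backend_options),
            class = "solver_options")
}

#' Define a barcode selection problem
#'
#' Couples a candidate pool with the required subset size, the pairwise
#' distance requirement, and any barcodes forced into the solution
#' (augment mode).
#'
#' @param pool A [barcode_pool()] of M candidates.
#' @param n Required subset size, `1 <= n <= M`.
#' @param spec A [distance_spec()].
#' @param fixed Indexes (1-based) or identifiers of candidates that must be
#'   part of the solution; at most `n` of them.
#' @param options A [solver_options()].
#' @param allow_fixed_conflicts If `TRUE`, a forbidden pair entirely inside
#'   the fixed set does not abort model building (its pair constraint is
#'   dropped, since both members are mandated anyway); by default such a
#'   pair is an error naming the offending barcodes.
#' @return Object of class `selection_problem`.
#' @export
selection_problem <- function(pool, n, spec = distance_spec(),
                              fixed = integer(), options = solver_options(),
                              allow_fixed_conflicts = FALSE) {
  pool <- as_pool(pool)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("subset size n must be a positive integer")
  if (n > pool$M) {
    stop(sprintf("not enough candidates: requested n = %d from a pool of M = %d", n, pool$M))
  }
  if (is.character(fixed)) {
    idx <- match(fixed, pool$id)
    if (anyNA(idx)) stop("unknown fixed barcode: ", paste(fixed[is.na(idx)], collapse = ", "))
    fixed <- idx
  }
  fixed <- sort(unique(as.integer(fixed)))
  if (length(fixed) && (min(fixed) < 1L || max(fixed) > pool$M)) {
    stop("unknown fixed barcode: index out of range")
  }
  if (length(fixed) > n) stop("more fixed barcodes than the requested subset size")
  stopifnot(inherits(spec, "distance_spec"), inherits(options, "solver_options"))
  structure(list(pool = pool, n = n, spec = spec, fixed = fixed,
                 options = options,
                 allow_fixed_conflicts = isTRUE(allow_fixed_conflicts)),
            class = "selection_problem")
}

# Internal: append one "t >= e, t >= -e" linearization.
# e = sum(coef * x) - target; t is aux column `tcol`.
# Encoded as two rows:  coef.x - t <= target   and   -coef.x - t <= -target
add_abs_pair <- function(tr, xcols, coef, tcol, target, family) {
  for (sgn in c(1, -1)) {
    tr$i <- c(tr$i, rep(tr$nrow + 1L, length(xcols) + 1L))
    tr$j <- c(tr$j, xcols, tcol)
    tr$v <- c(tr$v, sgn * coef, -1)
    tr$ub <- c(tr$ub, sgn * target)
    tr$lb <- c(tr$lb, -Inf)
    tr$family <- c(tr$family, family)
    tr$nrow <- tr$nrow + 1L
  }
  tr
}

#' Build the selection ILP
#'
#' Translates a [selection_problem()] into a mixed-integer linear program:
#' one binary indicator per candidate; continuous auxiliary variables
#' linearizing each absolute-value term of the balance cost (`min |e|`
#' becomes `min t` with `t >= e` and `t >= -e`); two inequality constraints
#' per auxiliary; one `x_j + x_k <= 1` constraint per forbidden pair; the
#' cardinality constraint `sum(x) = n`; and `x_i = 1` for each fixed
#' candidate. Per position there are 6 auxiliaries (two laser-group terms,
#' four single-nucleotide terms), so a pool of L-nt barcodes yields `6L`
#' positional auxiliaries with `12L` constraints plus 4 global-balance
#' auxiliaries with 8 constraints — counts that depend on L only, never on
#' the pool size.
#'
#' @param problem A [selection_problem()].
#' @return Object of class `selection_ilp` carrying the variable and
#'   constraint matrices (triplet form) plus bookkeeping counts
#'   (`n_binary`, `n_aux_positional`, `n_aux_global`,
#'   `n_balance_constraints_positional`, `n_balance_constraints_global`,
#'   `n_pair_constraints`, ...).
#' @export
build_selection_ilp <- function(problem) {
  stopifnot(inherits(problem, "selection_problem"))
  pool <- problem$pool
  M <- pool$M; L <- pool$L; n <- problem$n

  fp <- forbidden_pairs(pool, problem$spec)
  fixed <- problem$fixed
  if (length(fixed) >= 2L && nrow(fp)) {
    inside <- fp$j %in% fixed & fp$k %in% fixed
    if (any(inside)) {
      if (!problem$allow_fixed_conflicts) {
        w <- which(inside)[1]
        stop(sprintf(
          "fixed barcodes '%s' and '%s' are only %d apart (< %d); the fixed set itself violates the distance threshold",
          fp$id_j[w], fp$id_k[w], fp$distance[w], problem$spec$min_distance))
      }
      fp <- fp[!inside, , drop = FALSE]
    }
  }

  n_aux_pos <- 6L * L
  n_aux_glob <- 4L
  nvar <- M + n_aux_pos + n_aux_glob
  chars <- pool_matrix(pool)   # L x M

  tr <- list(i = integer(), j = integer(), v = numeric(),
             lb = numeric(), ub = numeric(), family = character(), nrow = 0L)

  # positional balance: per position, aux order (AC-group, GT-group, A, C, G, T)
  tcol <- M
  for (l in seq_len(L)) {
    is_nuc <- lapply(NUC, function(b) which(chars[l, ] == b))
    names(is_nuc) <- NUC
    groups <- list(c(is_nuc$A, is_nuc$C), c(is_nuc$G, is_nuc$T))
    for (g in groups) {
      tcol <- tcol + 1L
      tr <- add_abs_pair(tr, g, rep(1, length(g)), tcol, n / 2, "balance_positional")
    }
    for (b in NUC) {
      tcol <- tcol + 1L
      idx <- is_nuc[[b]]
      tr <- add_abs_pair(tr, idx, rep(1, length(idx)), tcol, n / 4, "balance_positional")
    }
  }
  # global balance: coefficient of x_i is the count of that nucleotide in seq_i
  for (b in NUC) {
    tcol <- tcol + 1L
    cnt <- colSums(chars == b)
    nz <- which(cnt > 0)
    tr <- add_abs_pair(tr, nz, cnt[nz], tcol, n * L / 4, "balance_global")
  }

  # pair exclusion
  if (nrow(fp)) {
    for (r in seq_len(nrow(fp))) {
      tr$i <- c(tr$i, rep(tr$nrow + 1L, 2L)); tr$j <- c(tr$j, fp$j[r], fp$k[r])
      tr$v <- c(tr$v, 1, 1); tr$lb <- c(tr$lb, -Inf); tr$ub <- c(tr$ub, 1)
      tr$family <- c(tr$family, "pair"); tr$nrow <- tr$nrow + 1L
    }
  }
  # cardinality
  tr$i <- c(tr$i, rep(tr$nrow + 1L, M)); tr$j <- c(tr$j, seq_len(M))
  tr$v <- c(tr$v, rep(1, M)); tr$lb <- c(tr$lb, n); tr$ub <- c(tr$ub, n)
  tr$family <- c(tr$family, "cardinality"); tr$nrow <- tr$nrow + 1L
  # fixing
  for (f in fixed) {
    tr$i <- c(tr$i, tr$nrow + 1L); tr$j <- c(tr$j, f); tr$v <- c(tr$v, 1)
    tr$lb <- c(tr$lb, 1); tr$ub <- c(tr$ub, 1)
    tr$family <- c(tr$family, "fixing"); tr$nrow <- tr$nrow + 1L
  }

  obj <- c(rep(0, M), rep(1, n_aux_pos + n_aux_glob))
  varnames <- c(paste0("x_", seq_len(M)),
                paste0("t_pos", rep(seq_len(L), each = 6L), "_",
                       rep(c("AC", "GT", NUC), L)),
                paste0("t_glob_", NUC))

  structure(list(
    problem = problem, forbidden = fp,
    nvar = nvar, objective = obj, varnames = varnames,
    integrality = c(rep(1L, M), rep(0L, n_aux_pos + n_aux_glob)),
    var_lb = rep(0, nvar),
    var_ub = c(rep(1, M), rep(Inf, n_aux_pos + n_aux_glob)),
    con_i = tr$i, con_j = tr$j, con_v = tr$v,
    con_lb = tr$lb, con_ub = tr$ub, con_family = tr$family,
    ncon = tr$nrow,
    n_binary = M,
    n_aux_positional = n_aux_pos,
    n_aux_global = n_aux_glob,
    n_balance_constraints_positional = 2L * n_aux_pos,
    n_balance_constraints_global = 2L * n_aux_glob,
    n_pair_constraints = nrow(fp),
    n_cardinality_constraints = 1L,
    n_fixing_constraints = length(fixed)),
    class = "selection_ilp")
}

#' @export
print.selection_ilp <- function(x, ...) {
  cat("Barcode selection ILP\n")
  cat(sprintf("  binaries: %d   auxiliaries: %d positional + %d global\n",
              x$n_binary, x$n_aux_positional, x$n_aux_global))
  cat(sprintf("  constraints: %d + %d balance, %d pair, 1 cardinality, %d fixing\n",
              x$n_balance_constraints_positional, x$n_balance_constraints_global,
              x$n_pair_constraints, x$n_fixing_constraints))
  invisible(x)
}

#' Export the model in CPLEX LP text format
#'
#' Debugging aid: writes the full model (objective, constraints, bounds,
#' binaries) in the plain-text LP format most solvers read.
#'
#' @param structure A `selection_ilp` from [build_selection_ilp()].
#' @param path Output path (or `""` for the console).
#' @return Invisibly, the LP text lines.
#' @export
write_lp <- function(structure, path) {
  s <- structure
  term <- function(v, j) sprintf("%+g %s", v, s$varnames[j])
  lines <- c("Minimize",
             paste(" obj:", paste(term(s$objective[s$objective != 0],
                                       which(s$objective != 0)), collapse = " ")),
             "Subject To")
  for (r in seq_len(s$ncon)) {
    sel <- s$con_i == r
    lhs <- paste(term(s$con_v[sel], s$con_j[sel]), collapse = " ")
    lb <- s$con_lb[r]; ub <- s$con_ub[r]
    rel <- if (is.finite(lb) && is.finite(ub) && lb == ub) {
      sprintf("= %g", ub)
    } else if (is.finite(ub)) sprintf("<= %g", ub) else sprintf(">= %g", lb)
    lines <- c(lines, sprintf(" c%d_%s: %s %s", r, s$con_family[r], lhs, rel))
  }
  lines <- c(lines, "Bounds",
             sprintf(" 0 <= %s <= 1", s$varnames[seq_len(s$n_binary)]),
             sprintf(" %s >= 0", s$varnames[-seq_len(s$n_binary)]),
             "Binaries",
             paste("", paste(s$varnames[seq_len(s$n_binary)], collapse = " ")),
             "End")
  writeLines(lines, path)
  invisible(lines)
}

#' Solve a selection ILP
#'
#' Sends the model to the mixed-integer solver backend and converts the
#' answer into a `selection_result`. The objective value reported is the
#' balance cost recomputed exactly from the returned subset (the float
#' objective from the solver is kept as `solver_objective` and
#' cross-checked); the result is always re-verified against subset size,
#' distance constraints and fixed-barcode inclusion before being returned.
#'
#' @param structure A `selection_ilp`.
#' @param options A [solver_options()]; defaults to those of the problem.
#' @return Object of class `selection_result`: `selected` (barcode pool),
#'   `selected_idx`, `objective_value`, `breakdown` (a `cost_breakdown`),
#'   `status` (`"optimal"`, `"feasible_time_limited"` or `"infeasible"`),
#'   `solver_objective`, `new_idx` (selected barcodes that were not fixed).
#' @export
solve_ilp <- function(structure, options = NULL) {
  stopifnot(inherits(structure, "selection_ilp"))
  if (is.null(options)) options <- structure$problem$options
  if (options$branch_depth_limit != 0L) {
    warning("the HiGHS backend does not support branch-depth limiting; option ignored")
  }
  raw <- milp_backend(list(ilp_to_model(structure)), options)[[1]]
  as_selection_result(raw, structure)
}

# Internal: selection_ilp -> plain model list for the backend
ilp_to_model <- function(s) {
  list(nvar = s$nvar, obj = s$objective, integrality = s$integrality,
       lb = s$var_lb, ub = s$var_ub,
       con_i = s$con_i, con_j = s$con_j, con_v = s$con_v,
       con_lb = s$con_lb, con_ub = s$con_ub)
}

# Internal: backend answer -> selection_result (with defensive verification)
as_selection_result <- function(raw, structure) {
  problem <- structure$problem
  if (raw$status == "infeasible") {
    res <- structure(list(selected = NULL, selected_idx = integer(),
                          objective_value = NA_real_, breakdown = NULL,
                          status = "infeasible",
                          solver_objective = NA_real_,
                          new_idx = integer(), problem = problem),
                     class = "selection_result")
    return(res)
  }
  if (raw$status == "error") stop("solver error: ", raw$message)
  idx <- which(round(raw$x[seq_len(structure$n_binary)]) == 1)
  selected <- problem$pool[idx]
  bd <- balance_cost(selected)
  res <- structure(list(selected = selected, selected_idx = idx,
                        objective_value = bd$total, breakdown = bd,
                        status = raw$status,
                        solver_objective = raw$objective,
                        new_idx = setdiff(idx, problem$fixed),
                        problem = problem),
                   class = "selection_result")
  v <- verify_selection(res, problem)
  if (!v$ok) {
    stop("solver returned an invalid solution: ",
         paste(v$violations$family, v$violations$detail, collapse = "; "))
  }
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Barcode selection: status %s\n", x$status))
  if (x$status == "infeasible") {
    cat("  no subset satisfies the distance and cardinality constraints\n")
    return(invisible(x))
  }
  cat(sprintf("  %d barcodes selected, balance cost %g\n",
              x$selected$M, x$objective_value))
  if (length(x$new_idx) && length(x$problem$fixed)) {
    cat(sprintf("  (%d kept fixed, %d newly added)\n",
                length(x$problem$fixed), length(x$new_idx)))
  }
  print(x$selected)
  invisible(x)
}

#' @export
summary.selection_result <- function(object, ...) {
  print(object)
  if (object$status != "infeasible") {
    print(object$breakdown)
    if (object$selected$M >= 2L) {
      cat(sprintf("  min pairwise %s distance: %d\n",
                  object$problem$spec$metric,
                  min_pairwise_distance(object$selected, object$problem$spec$metric)))
    }
  }
  invisible(object)
}

#' @export
plot.selection_result <- function(x, ...) {
  if (x$status == "infeasible") stop("nothing to plot: infeasible problem")
  plot_balance(x$selected, ...)
}

#' Re-verify a selection result against its problem
#'
#' Defensive re-check of solver output: subset size, all pairwise distances
#' against the threshold, inclusion of every fixed barcode, and agreement of
#' the reported objective with an independent cost recomputation.
#'
#' @param result A `selection_result` with status other than `"infeasible"`.
#' @param problem The originating [selection_problem()].
#' @return List with `ok` (logical) and `violations` (data frame with
#'   columns `family` and `detail`; zero rows when `ok`).
#' @export
verify_selection <- function(result, problem) {
  stopifnot(inherits(result, "selection_result"))
  viol <- data.frame(family = character(), detail = character(),
                     stringsAsFactors = FALSE)
  add <- function(family, detail) rbind(viol, data.frame(family = family,
                                                         detail = detail,
                                                         stringsAsFactors = FALSE))
  if (result$selected$M != problem$n) {
    viol <- add("cardinality constraint",
                sprintf("size %d != n = %d", result$selected$M, problem$n))
  }
  if (problem$spec$min_distance > 0L && result$selected$M >= 2L) {
    fp <- forbidden_pairs(result$selected, problem$spec)
    if (length(problem$fixed) >= 2L && problem$allow_fixed_conflicts && nrow(fp)) {
      fixed_ids <- problem$pool$id[problem$fixed]
      fp <- fp[!(fp$id_j %in% fixed_ids & fp$id_k %in% fixed_ids), , drop = FALSE]
    }
    for (r in seq_len(nrow(fp))) {
      viol <- add("distance constraint",
                  sprintf("%s vs %s at distance %d < %d", fp$id_j[r], fp$id_k[r],
                          fp$distance[r], problem$spec$min_distance))
    }
  }
  missing_fixed <- setdiff(problem$fixed, result$selected_idx)
  for (f in missing_fixed) {
    viol <- add("fixing constraint",
                sprintf("fixed barcode '%s' absent from solution", problem$pool$id[f]))
  }
  if (!is.na(result$objective_value) && result$selected$M >= 1L) {
    recomputed <- balance_cost(result$selected)$total
    if (abs(recomputed - result$objective_value) > 1e-9) {
      viol <- add("objective", sprintf("reported %g, recomputed %g",
                                       result$objective_value, recomputed))
    }
  }
  list(ok = nrow(viol) == 0L, violations = viol)
}
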