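# Independent oracles used across the suite. These deliberately re-derive
# everything from first principles (naive loops, full DP tables, exhaustive
# subset enumeration) and share no code with the package internals.

NUCS <- c("A", "C", "G", "T")

naive_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sum(av != bv)
}

# Full Wagner-Fischer dynamic-programming table
naive_levenshtein <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  d <- matrix(0L, na + 1L, nb + 1L)
  d[, 1L] <- 0:na; d[1L, ] <- 0:nb
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                             d[i, j] + (av[i] != bv[j]))
  }
  d[na + 1L, nb + 1L]
}

naive_dist <- function(a, b, metric) {
  if (metric == "hamming") naive_hamming(a, b) else naive_levenshtein(a, b)
}

# Double loop over all pairs; returns j < k index pairs below the threshold
naive_forbidden <- function(seqs, metric, dmin) {
  out <- NULL
  M <- length(seqs)
  if (M >= 2L) for (j in 1:(M - 1L)) for (k in (j + 1L):M) {
    if (naive_dist(seqs[j], seqs[k], metric) < dmin) out <- rbind(out, c(j, k))
  }
  out
}

# Direct float evaluation of the balance objective for a set of sequences
naive_cost <- function(seqs) {
  n <- length(seqs); L <- nchar(seqs[1])
  chars <- do.call(rbind, strsplit(seqs, ""))  # n x L
  total <- 0
  glob <- setNames(numeric(4), NUCS)
  for (l in seq_len(L)) {
    cnt <- sapply(NUCS, function(b) sum(chars[, l] == b))
    glob <- glob + cnt
    total <- total + abs(cnt["A"] + cnt["C"] - n / 2) +
      abs(cnt["G"] + cnt["T"] - n / 2) + sum(abs(cnt - n / 4))
  }
  total + sum(abs(glob - n * L / 4))
}

# Exhaustive enumeration over all C(M, n) subsets that contain `fixed` and
# whose pairwise distances all reach dmin; returns feasibility and optimum.
enumerate_optimum <- function(seqs, n, metric = "hamming", dmin = 3,
                              fixed = integer()) {
  M <- length(seqs)
  dm <- matrix(0L, M, M)
  if (M >= 2L) for (j in 1:(M - 1L)) for (k in (j + 1L):M) {
    dm[j, k] <- dm[k, j] <- naive_dist(seqs[j], seqs[k], metric)
  }
  best <- Inf; feasible <- FALSE
  subsets <- utils::combn(M, n)
  for (s in seq_len(ncol(subsets))) {
    idx <- subsets[, s]
    if (!all(fixed %in% idx)) next
    if (dmin > 0 && n >= 2L) {
      sub <- dm[idx, idx]
      if (min(sub[upper.tri(sub)]) < dmin) next
    }
    feasible <- TRUE
    best <- min(best, naive_cost(seqs[idx]))
  }
  list(feasible = feasible, objective = if (feasible) best else NA_real_)
}

# Objective value the built ILP assigns to an indicator vector: for each
# auxiliary t (objective coefficient 1), its two rows encode t >= e and
# t >= -e, so at the optimum for fixed x, t = |e|. e is reconstructed from
# the "+" row: sum(v * x) - ub.
eval_ilp_objective <- function(structure, idx) {
  x <- numeric(structure$n_binary)
  x[idx] <- 1
  total <- 0
  aux_cols <- which(structure$objective != 0)
  for (tc in aux_cols) {
    rows <- unique(structure$con_i[structure$con_j == tc &
                                   structure$con_v == -1])
    r <- rows[1]   # the first of the pair carries the +coefficients
    sel <- structure$con_i == r & structure$con_j != tc
    e <- sum(structure$con_v[sel] * x[structure$con_j[sel]]) - structure$con_ub[r]
    total <- total + abs(e)
  }
  total
}

# Random equal-length pool without duplicate sequences
random_seqs <- function(M, L) {
  seqs <- character()
  while (length(seqs) < M) {
    s <- paste(sample(NUCS, L, replace = TRUE), collapse = "")
    if (!s %in% seqs) seqs <- c(seqs, s)
  }
  seqs
}

# Batched solve of many selection problems through one backend call;
# returns a list of selection_result objects.
solve_batch <- function(problems, time_limit = 10) {
  structures <- lapply(problems, build_selection_ilp)
  models <- lapply(structures, indexsel:::ilp_to_model)
  raws <- indexsel:::milp_backend(models, solver_options(time_limit))
  mapply(indexsel:::as_selection_result, raws, structures, SIMPLIFY = FALSE)
}

write_fasta_tmp <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
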