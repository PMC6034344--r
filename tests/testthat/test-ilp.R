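test_that("auxiliary-variable and constraint counts depend on L only", {
  # 8-nt barcodes: 6 aux per position -> 48, two constraints each -> 96,
  # plus 4 global auxiliaries with 8 constraints
  for (pool in list(example_barcode_sets()$A,
                    generate_candidate_pool(40, 8, seed = 5)$pool)) {
    s <- build_selection_ilp(selection_problem(pool, 4))
    expect_equal(s$n_aux_positional, 48L)
    expect_equal(s$n_balance_constraints_positional, 96L)
    expect_equal(s$n_aux_global, 4L)
    expect_equal(s$n_balance_constraints_global, 8L)
  }
  # closed forms 6L + 4 and 12L + 8 for other lengths, including L = 1
  for (L in c(1L, 2L, 5L, 12L)) {
    pool <- barcode_pool(random_seqs(4, L))
    s <- build_selection_ilp(selection_problem(pool, 2, distance_spec("hamming", 0)))
    expect_equal(s$n_aux_positional + s$n_aux_global, 6L * L + 4L)
    expect_equal(s$n_balance_constraints_positional +
                   s$n_balance_constraints_global, 12L * L + 8L)
    expect_equal(s$n_binary, 4L)
    expect_equal(s$n_cardinality_constraints, 1L)
  }
})

test_that("problem validation rejects impossible requests", {
  pool <- example_barcode_sets()$A
  expect_error(selection_problem(pool, 9), "not enough candidates")
  expect_error(selection_problem(pool, 0), "positive")
  expect_error(selection_problem(pool, 4, fixed = 12), "unknown fixed barcode")
  expect_error(selection_problem(pool, 4, fixed = "nope"), "unknown fixed barcode")
  expect_error(selection_problem(pool, 2, fixed = c(1, 2, 3)), "more fixed barcodes")
})

test_that("a forbidden pair inside the fixed set fails fast unless overridden", {
  pool <- barcode_pool(c("AAAA", "AAAT", "TTTT", "CCGG"),
                       c("b1", "b2", "b3", "b4"))
  prob <- selection_problem(pool, 3, distance_spec("hamming", 3), fixed = c(1, 2))
  expect_error(build_selection_ilp(prob), "b1.*b2.*violates the distance threshold")
  prob2 <- selection_problem(pool, 3, distance_spec("hamming", 3), fixed = c(1, 2),
                             allow_fixed_conflicts = TRUE)
  s <- build_selection_ilp(prob2)
  # the fixed-fixed pair constraint is dropped, others stay
  expect_false(any(s$forbidden$j == 1 & s$forbidden$k == 2))
})

test_that("the ILP objective of an indicator vector equals the balance cost", {
  set.seed(13)
  for (rep in 1:10) {
    M <- sample(4:9, 1); L <- sample(2:6, 1); n <- sample(2:min(4, M), 1)
    pool <- barcode_pool(random_seqs(M, L))
    s <- build_selection_ilp(selection_problem(pool, n, distance_spec("hamming", 0)))
    idx <- sort(sample(M, n))
    expect_equal(eval_ilp_objective(s, idx), balance_cost(pool[idx])$total)
  }
})

test_that("solve finds the zero-cost optimum and detects infeasibility", {
  res <- select_barcodes(example_barcode_sets()$A, 8)
  expect_equal(res$status, "optimal")
  expect_identical(res$objective_value, 0)
  expect_equal(res$selected$M, 8L)
  expect_equal(abs(res$solver_objective), 0, tolerance = 1e-6)

  expect_message(res2 <- select_barcodes(c("AAAA", "AAAT"), 2),
                 "no subset of size 2")
  expect_equal(res2$status, "infeasible")
  expect_true(is.na(res2$objective_value))
})

test_that("solve matches exhaustive enumeration on random instances", {
  set.seed(99)
  problems <- list(); oracles <- list()
  for (rep in 1:30) {
    M <- sample(4:10, 1); L <- sample(2:6, 1)
    n <- sample(2:min(5, M), 1); d <- sample(0:3, 1)
    metric <- sample(c("hamming", "levenshtein"), 1)
    seqs <- random_seqs(M, L)
    problems[[rep]] <- selection_problem(barcode_pool(seqs), n,
                                         distance_spec(metric, d))
    oracles[[rep]] <- enumerate_optimum(seqs, n, metric, d)
  }
  results <- solve_batch(problems)
  for (rep in seq_along(problems)) {
    if (oracles[[rep]]$feasible) {
      expect_equal(results[[rep]]$status, "optimal")
      expect_equal(results[[rep]]$objective_value, oracles[[rep]]$objective)
      # objective consistency between solver and exact recomputation
      expect_equal(results[[rep]]$solver_objective,
                   results[[rep]]$objective_value, tolerance = 1e-6)
    } else {
      expect_equal(results[[rep]]$status, "infeasible")
    }
  }
})

test_that("relaxing the distance threshold never worsens the optimum", {
  set.seed(55)
  seqs <- random_seqs(10, 4)
  probs <- lapply(c(3, 2, 1, 0), function(d)
    selection_problem(barcode_pool(seqs), 4, distance_spec("hamming", d)))
  objs <- vapply(solve_batch(probs), function(r)
    if (r$status == "infeasible") 1e9 else r$objective_value, numeric(1))
  expect_true(all(diff(objs) <= 1e-9))  # d decreasing -> feasible set grows
})

test_that("fixed barcodes are honored and cost at least the free optimum", {
  set.seed(77)
  seqs <- random_seqs(9, 5)
  pool <- barcode_pool(seqs)
  free <- selection_problem(pool, 4, distance_spec("hamming", 1))
  fixed <- selection_problem(pool, 4, distance_spec("hamming", 1), fixed = c(2, 5))
  res <- solve_batch(list(free, fixed))
  expect_true(all(c(2, 5) %in% res[[2]]$selected_idx))
  expect_gte(res[[2]]$objective_value, res[[1]]$objective_value)
  oracle <- enumerate_optimum(seqs, 4, "hamming", 1, fixed = c(2, 5))
  expect_equal(res[[2]]$objective_value, oracle$objective)
})

test_that("verify_selection flags hand-built violations by constraint family", {
  pool <- barcode_pool(c("AAAA", "AAAT", "TTTT", "CCGG", "GGCC"))
  prob <- selection_problem(pool, 2, distance_spec("hamming", 3), fixed = 4)
  good <- structure(list(selected = pool[c(4, 3)], selected_idx = c(4L, 3L),
                         objective_value = balance_cost(pool[c(4, 3)])$total,
                         status = "optimal"), class = "selection_result")
  expect_true(verify_selection(good, prob)$ok)

  bad_fix <- structure(list(selected = pool[c(1, 3)], selected_idx = c(1L, 3L),
                            objective_value = balance_cost(pool[c(1, 3)])$total,
                            status = "optimal"), class = "selection_result")
  v <- verify_selection(bad_fix, prob)
  expect_false(v$ok)
  expect_true("fixing constraint" %in% v$violations$family)

  bad_dist <- structure(list(selected = pool[c(1, 2)], selected_idx = c(1L, 2L),
                             objective_value = balance_cost(pool[c(1, 2)])$total,
                             status = "optimal"), class = "selection_result")
  v2 <- verify_selection(bad_dist, selection_problem(pool, 2, distance_spec("hamming", 3)))
  expect_false(v2$ok)
  expect_true("distance constraint" %in% v2$violations$family)

  bad_size <- structure(list(selected = pool[1], selected_idx = 1L,
                             objective_value = balance_cost(pool[1])$total,
                             status = "optimal"), class = "selection_result")
  v3 <- verify_selection(bad_size, selection_problem(pool, 2, distance_spec("hamming", 0)))
  expect_false(v3$ok)
  expect_true("cardinality constraint" %in% v3$violations$family)
})

test_that("the model exports as LP text", {
  s <- build_selection_ilp(selection_problem(example_barcode_sets()$A, 4))
  f <- tempfile(fileext = ".lp")
  write_lp(s, f)
  txt <- readLines(f)
  expect_true(any(txt == "Minimize"))
  expect_true(any(txt == "Subject To"))
  expect_true(any(grepl("x_1", txt)))
  expect_equal(sum(grepl("^ c[0-9]+_balance", txt)), 104L)  # 96 + 8 for L = 8
})

test_that("an unsupported branch-depth limit warns but still solves", {
  expect_warning(
    res <- select_barcodes(example_barcode_sets()$A, 4, branch_depth_limit = 5),
    "branch-depth")
  expect_equal(res$status, "optimal")
})
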