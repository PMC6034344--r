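test_that("select recovers a planted perfectly balanced subset", {
  fx <- generate_candidate_pool(M = 32, L = 8, planted_n = 8, min_distance = 3,
                                seed = 1)
  out <- tempfile(fileext = ".fasta")
  rep_f <- tempfile(fileext = ".tsv")
  res <- select_barcodes(fx$pool, 8, out_fasta = out, report_file = rep_f)
  expect_equal(res$status, "optimal")
  expect_identical(res$objective_value, 0)  # the planted subset proves 0 attainable
  expect_true(file.exists(out) && file.exists(rep_f))
  # pipeline self-consistency: the written set always re-checks as compatible
  chk <- check_barcodes(out, "hamming", 3)
  expect_true(chk$compatible)
  expect_identical(chk$breakdown$total, res$objective_value)
})

test_that("select propagates input errors", {
  expect_error(select_barcodes(example_barcode_sets()$A, 20),
               "not enough candidates")
})

test_that("check reports distances, violations and balance without optimizing", {
  chk <- check_barcodes(example_barcode_sets()$D, "hamming", 3)
  expect_true(chk$compatible)
  expect_identical(chk$breakdown$total, 0)
  expect_gte(chk$min_distance_observed, 3L)
  expect_equal(nrow(chk$violations), 0L)

  chk2 <- check_barcodes(c("AAAA", "AAAT"), min_distance = 3)
  expect_false(chk2$compatible)
  expect_equal(chk2$violations$distance, 1L)
  expect_equal(chk2$min_distance_observed, 1L)
  expect_output(print(chk2), "NOT compatible")
})

test_that("check answers whether two libraries can be pooled together", {
  sets <- example_barcode_sets()
  lib1 <- tempfile(fileext = ".fasta"); lib2 <- tempfile(fileext = ".fasta")
  write_barcode_fasta(sets$A, lib1)
  write_barcode_fasta(sets$B[1:4], lib2)
  combined <- barcode_pool(c(read_barcode_fasta(lib1)$seq,
                             read_barcode_fasta(lib2)$seq))
  chk <- check_barcodes(combined, "hamming", 3)
  # the verdict is exactly "no cross-library pair below the threshold"
  expect_equal(chk$compatible,
               is.null(naive_forbidden(combined$seq, "hamming", 3)))
})

test_that("augment keeps the committed set and adds optimal new barcodes", {
  sets <- example_barcode_sets()
  # candidates: 16-set C (which does not contain all of A) plus A appended
  res <- augment_barcodes(sets$C, sets$A, n_new = 8)
  expect_equal(res$status, "optimal")
  expect_equal(res$selected$M, 16L)
  expect_true(all(sets$A$seq %in% res$selected$seq))
  expect_equal(length(res$new_idx), 8L)

  # requesting nothing returns the committed set unchanged, with its cost
  res0 <- augment_barcodes(sets$C, sets$A, n_new = 0)
  expect_equal(sort(res0$selected$seq), sort(sets$A$seq))
  expect_identical(res0$objective_value, balance_cost(sets$A)$total)
  expect_equal(res0$status, "optimal")
})

test_that("augment with an empty initial set is exactly select", {
  fx <- generate_candidate_pool(M = 16, L = 6, planted_n = 4, seed = 9)
  a <- augment_barcodes(fx$pool, NULL, n_new = 4)
  s <- select_barcodes(fx$pool, 4)
  expect_identical(a$objective_value, s$objective_value)
  expect_equal(a$status, s$status)
})

test_that("augment matches enumeration restricted to supersets of the initial set", {
  set.seed(17)
  seqs <- random_seqs(8, 5)
  init <- seqs[c(2, 6)]
  res <- augment_barcodes(barcode_pool(seqs), init, n_new = 2,
                          min_distance = 1)
  oracle <- enumerate_optimum(seqs, 4, "hamming", 1, fixed = c(2, 6))
  if (oracle$feasible) {
    expect_equal(res$objective_value, oracle$objective)
    expect_true(all(init %in% res$selected$seq))
  } else {
    expect_equal(res$status, "infeasible")
  }
})

test_that("augment validates the initial set before solving", {
  expect_error(augment_barcodes(example_barcode_sets()$A,
                                c("AAAAAAAA", "AAAAAAAT"), n_new = 2),
               "initial set violates the distance threshold")
  expect_error(augment_barcodes(example_barcode_sets()$A, "ACGT", n_new = 1),
               "length mismatch")
  expect_error(augment_barcodes(example_barcode_sets()$A, example_barcode_sets()$B,
                                n_new = 20), "not enough candidates")
})

test_that("the command-line interface runs end to end with scriptable exit codes", {
  cli <- system.file("cli", "indexsel.R", package = "indexsel")
  rscript <- file.path(R.home("bin"), "Rscript")
  fasta <- tempfile(fileext = ".fasta")
  write_barcode_fasta(example_barcode_sets()$A, fasta)
  out <- tempfile(fileext = ".fasta")

  st <- system2(rscript, c(cli, "select", "--candidates", fasta, "--n", "4",
                           "--out", out, "--quiet"),
                stdout = TRUE, stderr = TRUE)
  expect_true(is.null(attr(st, "status")))      # exit 0: optimal
  expect_equal(read_barcode_fasta(out)$M, 4L)

  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">b1", "AAAA", ">b2", "AAAT"), bad)
  st2 <- suppressWarnings(
    system2(rscript, c(cli, "check", "--candidates", bad, "--quiet"),
            stdout = TRUE, stderr = TRUE))
  expect_equal(attr(st2, "status"), 1L)         # exit 1: incompatible
  st3 <- suppressWarnings(
    system2(rscript, c(cli, "select", "--candidates", bad, "--n", "2",
                       "--quiet"), stdout = TRUE, stderr = TRUE))
  expect_equal(attr(st3, "status"), 2L)         # exit 2: infeasible
  st4 <- suppressWarnings(
    system2(rscript, c(cli, "select", "--candidates", "/nonexistent.fa",
                       "--n", "2"), stdout = TRUE, stderr = TRUE))
  expect_equal(attr(st4, "status"), 3L)         # exit 3: input error
})
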