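test_that("association TSV loads, validates, and rejects non-binary cells", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "assoc.tsv")
  writeLines(c("\tOM1\tOM2", "DB1\t1\t0", "DB2\t0\t1"), f)
  net <- load_association_network(f)
  expect_identical(unname(net$Y), diag(2))
  expect_identical(net$drug_ids, c("DB1", "DB2"))
  expect_identical(net$disease_ids, c("OM1", "OM2"))

  writeLines(c("\tOM1\tOM2", "DB1\t1\t0.5", "DB2\t0\t1"), f)
  expect_error(load_association_network(f), class = "cmaf_value_error")
  expect_error(load_association_network(f), "binary")

  writeLines(c("\tOM1\tOM1", "DB1\t1\t0", "DB2\t0\t1"), f)
  expect_error(load_association_network(f), class = "cmaf_identifier_error")

  writeLines(c("\tOM1\tOM2", "DB1\t1\tx", "DB2\t0\t1"), f)
  expect_error(load_association_network(f), class = "cmaf_value_error")
})

test_that("write -> load roundtrips all three matrix roles exactly", {
  dir <- withr::local_tempdir()
  inst <- rand_instance(42, m = 5L, n = 4L)

  f <- file.path(dir, "net.tsv")
  write_matrix(inst$net, f)
  back <- load_association_network(f)
  expect_identical(back$drug_ids, inst$net$drug_ids)
  expect_identical(back$disease_ids, inst$net$disease_ids)
  expect_equal(back$Y, inst$net$Y, tolerance = 1e-15)

  f <- file.path(dir, "sim.tsv")
  write_matrix(inst$S_r, f)
  back <- load_similarity_matrix(f, inst$S_r$ids)
  expect_equal(back$S, inst$S_r$S, tolerance = 1e-15)

  sc <- score_matrix(matrix(c(0.875, 1 / 3, 1e-9, 0.2), 2, 2,
                            dimnames = list(c("a", "b"), c("c", "d"))))
  f <- file.path(dir, "score.tsv")
  write_matrix(sc, f)
  back <- load_score_matrix(f)
  expect_identical(back$R, sc$R)  # %.17g preserves doubles bit-exactly

  comp <- dd_network(matrix(c(1, 0.25, 1 / 3, 0), 2, 2,
                            dimnames = list(c("a", "b"), c("c", "d"))),
                     completed = TRUE)
  f <- file.path(dir, "comp.tsv")
  write_matrix(comp, f)
  expect_identical(load_association_network(f, completed = TRUE)$Y, comp$Y)
})

test_that("a single-cell score matrix is written verbatim", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "one.tsv")
  write_matrix(score_matrix(matrix(0.875, dimnames = list("d", "s"))), f)
  expect_identical(readLines(f)[2L], "d\t0.875")
})

test_that("similarity loading aligns to expected ids and symmetrizes small asymmetry", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "sim.tsv")
  writeLines(c("\tB\tA\tC",
               "B\t1\t0.3\t0.5",
               "A\t0.300000001\t1\t0.2",
               "C\t0.5\t0.2\t1"), f)
  S <- load_similarity_matrix(f, c("A", "B"))
  expect_identical(S$ids, c("A", "B"))
  expect_equal(S$S[1L, 2L], 0.3000000005, tolerance = 1e-12)
  expect_identical(S$S, t(S$S))
  expect_identical(unname(diag(S$S)), c(1, 1))

  # permuting file rows/columns together yields the identical object
  writeLines(c("\tA\tB\tC",
               "A\t1\t0.300000001\t0.2",
               "B\t0.3\t1\t0.5",
               "C\t0.2\t0.5\t1"), f)
  expect_equal(load_similarity_matrix(f, c("A", "B"))$S, S$S)

  writeLines(c("\tA\tB", "A\t1\t1.5", "B\t1.5\t1"), f)
  expect_error(load_similarity_matrix(f, c("A", "B")),
               class = "cmaf_value_error")
  writeLines(c("\tA\tB", "A\t1\t0.9", "B\t0.2\t1"), f)
  expect_error(load_similarity_matrix(f, c("A", "B")), "asymmetric")
  writeLines(c("\tA\tB", "A\t1\t0.2", "B\t0.2\t1"), f)
  expect_error(load_similarity_matrix(f, c("A", "B", "Z")),
               class = "cmaf_identifier_error")
})

test_that("constructors enforce the container invariants", {
  expect_error(dd_network(matrix(2, 1, 1, dimnames = list("a", "b"))),
               class = "cmaf_value_error")
  expect_error(dd_network(matrix(1, 2, 2,
                                 dimnames = list(c("a", "a"), c("b", "c")))),
               class = "cmaf_identifier_error")
  expect_error(sim_matrix(matrix(c(1, 0.1, 0.1, 1), 2, 2,
                                 dimnames = list(c("a", "b"), c("a", "b"))),
                          kind = "linear_neighborhood"),
               class = "cmaf_value_error")  # nonzero diagonal, bad row sums
  ok <- sim_matrix(matrix(c(0, 1, 1, 0), 2, 2),
                   ids = c("a", "b"), kind = "linear_neighborhood")
  expect_identical(unname(rowSums(ok$S)), c(1, 1))
  expect_error(score_matrix(matrix(1.2, dimnames = list("a", "b")),
                            source = "CMAF"),
               class = "cmaf_value_error")
  expect_silent(score_matrix(matrix(1.2, dimnames = list("a", "b")),
                             source = "NMFRIA"))
  expect_error(write_matrix(matrix(numeric(0), 0, 0), tempfile()),
               class = "cmaf_format_error")
  expect_error(write_matrix(dd_network(matrix(1, 1, 1,
                                              dimnames = list("a", "b"))),
                            file.path(withr::local_tempdir(), "no", "x.tsv")),
               class = "cmaf_io_error")
})
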