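test_that("SDF reading returns one molecule per record with coordinates", {
  path <- write_sdf_text(sdf_record("methane",
                                    make_methane()$xyz,
                                    make_methane()$elements,
                                    make_methane()$bonds))
  mols <- load_structures(path)
  expect_length(mols, 1L)
  expect_equal(n_atoms(mols[[1]]), 5L)
  expect_equal(mols[[1]]$id, "methane")
  expect_equal(mols[[1]]$elements, c("C", "H", "H", "H", "H"))
  expect_equal(mols[[1]]$xyz, make_methane()$xyz,
               ignore_attr = TRUE, tolerance = 1e-4)
  expect_equal(nrow(mols[[1]]$bonds), 4L)
})

test_that("write/read round trip preserves coordinates, charges and weights", {
  set.seed(4)
  m <- make_ethanol()
  m <- assign_charges(m)
  m$weights <- matrix(runif(9 * 5), 9, 5,
                      dimnames = list(NULL, PROPERTY_KINDS))
  path <- tempfile(fileext = ".sdf")
  write_structures(list(m), path)
  back <- load_structures(path)[[1]]
  expect_equal(back$xyz, m$xyz, ignore_attr = TRUE, tolerance = 1e-4)
  expect_equal(back$charges, m$charges, tolerance = 1e-5)
  expect_equal(back$weights, m$weights, ignore_attr = TRUE,
               tolerance = 1e-5)
})

test_that("empty records are skipped and reported, not fatal", {
  me <- make_methane()
  lines <- c(sdf_record("mol_a", me$xyz, me$elements, me$bonds),
             c("mol_empty", "  test", "",
               "  0  0  0  0  0  0  0  0  0  0999 V2000", "M  END", "$$$$"),
             sdf_record("mol_b", matrix(c(0.5, 0.2, 0.1), 1, 3), "O"))
  mols <- load_structures(write_sdf_text(lines))
  expect_length(mols, 2L)
  expect_equal(vapply(mols, `[[`, "", "id"), c("mol_a", "mol_b"))
  errs <- attr(mols, "errors")
  expect_length(errs, 1L)
  expect_match(errs, "mol_empty")
})

test_that("MOL2 files are read with partial charges from the charge column", {
  path <- tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "etoh_frag", " 3 2 0 0 0",
               "SMALL", "GASTEIGER", "",
               "@<TRIPOS>ATOM",
               "1 C1  -0.888  0.168 -0.010 C.3 1 LIG -0.0418",
               "2 C2   0.468 -0.447 -0.296 C.3 1 LIG  0.0402",
               "3 O1   1.434  0.600 -0.231 O.3 1 LIG -0.3967",
               "@<TRIPOS>BOND",
               "1 1 2 1",
               "2 2 3 1"), path)
  mols <- load_structures(path)
  expect_length(mols, 1L)
  m <- mols[[1]]
  expect_equal(m$elements, c("C", "C", "O"))
  expect_equal(m$charges, c(-0.0418, 0.0402, -0.3967))
  expect_equal(m$xyz[2, ], c(0.468, -0.447, -0.296), ignore_attr = TRUE)
  expect_equal(nrow(m$bonds), 2L)
})

test_that("pKi conversion matches printed and closed-form values", {
  expect_equal(ki_to_pki(10.8), 7.96, tolerance = 0.01)
  expect_equal(ki_to_pki(1), 9)
  expect_equal(ki_to_pki(0.3), 9.523, tolerance = 5e-4)
  expect_error(ki_to_pki(0), "positive")
  expect_error(ki_to_pki(-2), "positive")
})

test_that("pKi conversion is a strictly decreasing bijection", {
  set.seed(1)
  ki <- sort(10^runif(50, -2, 3))
  pki <- ki_to_pki(ki)
  expect_true(all(diff(pki) < 0))
  expect_equal(pki_to_ki(pki), ki, tolerance = 1e-9)
})

test_that("activity files require unique ids and an id,ki_nM header", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id,ki_nM", "a,10", "b,20", "a,30"), path)
  expect_error(read_activities(path), "duplicate")
  writeLines(c("compound,affinity", "a,10"), path)
  expect_error(read_activities(path), "id, ki_nM")
  writeLines(c("# comment", "id,ki_nM", "a,10", "b,1"), path)
  act <- read_activities(path)
  expect_equal(act$pki, c(8, 9))
})

test_that("train/test split has the documented sizes and stratification", {
  set.seed(2)
  act <- data.frame(id = sprintf("c%03d", 1:103),
                    pki = runif(103, 6, 9.6))
  sp <- split_train_test(act, 81, seed = 3)
  expect_equal(sum(sp$subset == "train"), 81L)
  expect_equal(sum(sp$subset == "test"), 22L)

  # one test compound per activity quartile on a constructed input
  act20 <- data.frame(id = sprintf("c%02d", 1:20), pki = 1:20)
  sp20 <- split_train_test(act20, 16, seed = 1)
  test_pki <- sp20$pki[sp20$subset == "test"]
  expect_length(test_pki, 4L)
  expect_equal(findInterval(test_pki, c(1, 6, 11, 16), rightmost.closed = FALSE),
               1:4)

  # boundary: no test set
  sp_all <- split_train_test(act20, 20, seed = 1)
  expect_equal(sum(sp_all$subset == "test"), 0L)
  expect_error(split_train_test(act20, 21, seed = 1), "n_train")
})

test_that("split is a deterministic partition bounded by the pooled range", {
  set.seed(6)
  act <- data.frame(id = sprintf("c%03d", 1:60), pki = rnorm(60, 7.8, 0.8))
  a <- split_train_test(act, 48, seed = 11)
  b <- split_train_test(act, 48, seed = 11)
  expect_identical(a, b)
  expect_equal(sort(c(which(a$subset == "train"), which(a$subset == "test"))),
               1:60)
  for (s in c("train", "test")) {
    expect_gte(min(a$pki[a$subset == s]), min(act$pki))
    expect_lte(max(a$pki[a$subset == s]), max(act$pki))
  }
  c_ <- split_train_test(act, 48, seed = 12)
  expect_false(identical(a$subset, c_$subset))
})
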