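test_that("grid construction follows the documented encompassment rule", {
  g <- build_grid(matrix(0, 1, 3), spacing = 2, margin = 4)
  expect_equal(g$origin, c(-4, -4, -4))
  expect_equal(g$dims, c(5L, 5L, 5L))
  expect_equal(nrow(grid_points(g)), 125L)
  expect_equal(range(grid_points(g)), c(-4, 4))
  # spacing defaults to 2 A
  expect_equal(build_grid(matrix(0, 1, 3))$spacing, 2)
  expect_error(build_grid(list()), "empty")
})

test_that("grid always clears the atoms by at least the margin", {
  set.seed(31)
  for (k in 1:5) {
    xyz <- matrix(rnorm(30, sd = 5), 10, 3)
    g <- build_grid(xyz, spacing = 1.7, margin = 3.2)
    pts <- grid_points(g)
    for (ax in 1:3) {
      expect_lte(min(pts[, ax]), min(xyz[, ax]) - 3.2)
      expect_gte(max(pts[, ax]), max(xyz[, ax]) + 3.2)
    }
  }
})

test_that("lattice points enumerate x fastest, then y, then z", {
  g <- build_grid(matrix(0, 1, 3), spacing = 1, margin = 1)
  pts <- grid_points(g)
  expect_equal(pts[1:3, "x"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(pts[1:3, "y"], rep(-1, 3), ignore_attr = TRUE)
  expect_equal(pts[4, "y"], 0, ignore_attr = TRUE)
  expect_equal(pts[10, "z"], 0, ignore_attr = TRUE)
})

one_atom_mol <- function(w = 1, at = c(0, 0, 0)) {
  molecule("a1", "C", matrix(at, 1, 3), charges = 0,
           weights = matrix(w, 1, 5,
                            dimnames = list(NULL, PROPERTY_KINDS)))
}

point_grid <- function(xyz) {
  structure(list(origin = as.numeric(xyz), spacing = 1,
                 dims = c(1L, 1L, 1L)), class = "field_grid")
}

test_that("CoMSIA similarity index matches its closed form", {
  m <- one_atom_mol()
  expect_equal(comsia_field(m, point_grid(c(0, 0, 0)), "steric"), -1)
  expect_equal(comsia_field(m, point_grid(c(1, 0, 0)), "steric"),
               -exp(-0.3), tolerance = 1e-12)
  expect_equal(comsia_field(m, point_grid(c(0, 2, 0)), "steric",
                            alpha = 0.5), -exp(-2), tolerance = 1e-12)
  # null property weights give a null field
  m0 <- one_atom_mol(w = 0)
  g <- build_grid(matrix(0, 1, 3), margin = 2)
  expect_equal(comsia_field(m0, g, "hydrophobic"),
               rep(0, n_grid_points(g)))
  expect_error(comsia_field(molecule("x", "C", matrix(0, 1, 3)),
                            g, "steric"), "weights")
})

test_that("CoMSIA fields are translation-equivariant, bounded and linear", {
  set.seed(13)
  m <- molecule("m", rep("C", 6), matrix(rnorm(18, sd = 2), 6, 3),
                charges = rnorm(6, sd = 0.2),
                weights = matrix(runif(30), 6, 5,
                                 dimnames = list(NULL, PROPERTY_KINDS)))
  g <- build_grid(m$xyz, spacing = 2, margin = 3)
  f <- comsia_field(m, g, "steric")
  # moving molecule and grid together changes nothing
  shift <- c(3.3, -1.7, 0.4)
  m2 <- m; m2$xyz <- sweep(m$xyz, 2, shift, `+`)
  g2 <- g; g2$origin <- g$origin + shift
  expect_equal(comsia_field(m2, g2, "steric"), f, tolerance = 1e-10)
  # bound: |field| <= sum of |weights|
  expect_lte(max(abs(f)), sum(abs(m$weights[, "steric"])))
  # linearity in atomic weights
  m3 <- m; m3$weights <- 2 * m$weights
  expect_equal(comsia_field(m3, g, "steric"), 2 * f, tolerance = 1e-12)
  # additivity of an overlay
  mA <- m; mB <- m2
  overlay <- molecule("ab", c(mA$elements, mB$elements),
                      rbind(mA$xyz, mB$xyz),
                      charges = c(mA$charges, mB$charges),
                      weights = rbind(mA$weights, mB$weights))
  expect_equal(comsia_field(overlay, g, "steric"),
               comsia_field(mA, g, "steric") +
                 comsia_field(mB, g, "steric"), tolerance = 1e-12)
})

test_that("CoMFA steric field follows the Lennard-Jones closed form", {
  # one carbon atom; probe also carbon: rmin = 1.7 + 1.7, eps = 0.107
  m <- molecule("c1", "C", matrix(0, 1, 3), charges = 0)
  rmin <- 3.4
  f <- comfa_fields(m, point_grid(c(rmin, 0, 0)))
  expect_equal(f$steric, -0.107, tolerance = 1e-10)
  # far atom: both fields negligible
  far <- comfa_fields(m, point_grid(c(50, 0, 0)))
  expect_lt(abs(far$steric), 1e-3)
  expect_lt(abs(far$electrostatic), 1e-3)
  # on top of an atom: clamped to +cutoff
  ontop <- comfa_fields(m, point_grid(c(0, 0, 0)))
  expect_equal(ontop$steric, 30)
  expect_true(ontop$steric_at_cutoff)
  expect_error(comfa_fields(molecule("u", "U", matrix(0, 1, 3),
                                     charges = 0),
                            point_grid(c(1, 0, 0))), "U")
})

test_that("CoMFA electrostatics use 332*q/D(r)r and respect the clamp", {
  m <- molecule("q1", "C", matrix(0, 1, 3), charges = 0.5)
  g4 <- point_grid(c(4, 0, 0))
  expect_equal(comfa_fields(m, g4)$electrostatic, 332 * 0.5 / 16,
               tolerance = 1e-10)
  g8 <- point_grid(c(8, 0, 0))
  expect_equal(comfa_fields(m, g8, dielectric = "constant")$electrostatic,
               332 * 0.5 / 8, tolerance = 1e-10)
  near <- comfa_fields(m, point_grid(c(0.5, 0, 0)))
  expect_equal(near$electrostatic, 30)   # clamped
  expect_lte(max(abs(comfa_fields(m, point_grid(c(1, 0, 0)))$steric)), 30)
})

test_that("in-core electrostatic values are replaced by the column mean", {
  mk <- function(id, x) molecule(id, "C", matrix(c(x, 0, 0), 1, 3),
                                 charges = 0.3)
  mols <- list(mk("hit", 0), mk("far1", 6), mk("far2", 8))
  g <- point_grid(c(0, 0, 0))
  fb <- field_block(mols, g, "comfa_electrostatic")
  raw_far <- c(332 * 0.3 / 36, 332 * 0.3 / 64)
  expect_equal(unname(fb$values["hit", 1]), mean(raw_far), tolerance = 1e-10)
  expect_equal(unname(fb$values["far1", 1]), raw_far[1], tolerance = 1e-10)
})

test_that("descriptor assembly filters columns and equalises block variance", {
  set.seed(7)
  b1 <- stub_block(12, 30, "comsia_steric", sd_scale = 1)
  b2 <- stub_block(12, 30, "comsia_hydrophobic", sd_scale = 8)
  b1$values[, 5] <- 3.14   # constant column
  dm <- assemble_descriptor_matrix(list(b1, b2))
  expect_equal(ncol(dm$x), 59L)
  expect_equal(dm$dropped$comsia_steric, 5L, ignore_attr = TRUE)
  v1 <- sum(apply(dm$x[, dm$col_map$kind == "comsia_steric"], 2, var))
  v2 <- sum(apply(dm$x[, dm$col_map$kind == "comsia_hydrophobic"], 2, var))
  expect_equal(v1 / v2, 1, tolerance = 1e-10)
  # single block: ordering preserved
  dm1 <- assemble_descriptor_matrix(list(b1))
  expect_equal(dm1$col_map$point, setdiff(1:30, 5))
  # min_sigma filter on CoMFA blocks
  b3 <- stub_block(12, 30, "comfa_steric", sd_scale = 1)
  b3$values[, 2] <- b3$values[, 2] * 50
  dm3 <- assemble_descriptor_matrix(list(b3),
                                    min_sigma = c(comfa = 2, comsia = 0))
  expect_true(all(apply(b3$values[, dm3$col_map$point, drop = FALSE], 2, sd) >= 2))
  # mismatched molecule counts are an error
  b4 <- stub_block(11, 30, "comsia_donor")
  expect_error(assemble_descriptor_matrix(list(b1, b4)), "mismatch")
})
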