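test_that("a noise-free one-latent-variable system is fit exactly", {
  set.seed(3)
  t_ <- rnorm(15)
  p_ <- rnorm(8)
  X <- outer(t_, p_)             # rank 1
  w <- rnorm(8)
  y <- as.numeric(X %*% w) + 2
  fit <- pls_fit(X, y, 1)
  st <- fit_statistics(fit, X, y)
  expect_equal(st$r2_ncv, 1, tolerance = 1e-10)
  expect_equal(st$see, 0, tolerance = 1e-6)
  expect_equal(predict(fit, X), y, tolerance = 1e-8)
})

test_that("coefficients match a brute-force NIPALS oracle", {
  set.seed(11)
  for (dims in list(c(10L, 20L, 3L), c(30L, 200L, 5L))) {
    X <- matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2])
    y <- rnorm(dims[1])
    fit <- pls_fit(X, y, dims[3])
    ref <- nipals_reference(X, y, dims[3])
    expect_equal(fit$coefficients, ref$coefficients, tolerance = 1e-8)
    expect_equal(predict(fit, X),
                 as.numeric(X %*% ref$coefficients) + ref$intercept,
                 tolerance = 1e-8)
  }
})

test_that("fitted values equal the Krylov-subspace projection of y", {
  set.seed(19)
  X <- matrix(rnorm(25 * 12), 25, 12)
  y <- rnorm(25)
  for (a in c(1, 2, 4)) {
    fit <- pls_fit(X, y, a)
    expect_equal(predict(fit, X), krylov_fitted(X, y, a),
                 tolerance = 1e-8)
  }
})

test_that("zero components predict the training mean; rank excess errors", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  fit0 <- pls_fit(X, y, 0)
  expect_equal(predict(fit0, X), rep(mean(y), 10))
  expect_error(pls_fit(X, y, 5), "rank")
  expect_error(pls_fit(X, rep(1, 10), 2), "constant")
  expect_error(pls_fit(X, y, 9), "observations")
})

test_that("score vectors are mutually orthogonal", {
  set.seed(8)
  X <- matrix(rnorm(20 * 30), 20, 30)
  y <- rnorm(20)
  fit <- pls_fit(X, y, 5)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
})

test_that("multi-component LOO equals an explicit loop of full refits", {
  set.seed(21)
  X <- matrix(rnorm(18 * 25), 18, 25)
  y <- rnorm(18)
  multi <- loo_q2(X, y, 1:4)
  for (a in 1:4) {
    single <- loo_q2(X, y, a)
    expect_identical(single$q2, multi$q2[multi$ncomp == a])
    # definitional check: naive n-refit loop, recomputed here
    preds <- vapply(seq_len(18), function(i) {
      f <- pls_fit(X[-i, ], y[-i], a)
      predict(f, X[i, , drop = FALSE])
    }, numeric(1))
    expect_identical(single$predictions, preds)
    expect_identical(single$q2,
                     1 - sum((y - preds)^2) / sum((y - mean(y))^2))
  }
})

test_that("LOO Q2 is high for clean latent data and low under the null", {
  set.seed(33)
  t_ <- rnorm(30); p_ <- rnorm(40)
  X <- outer(t_, p_)
  y <- 3 * t_ + 7
  expect_gt(loo_q2(X, y, 1)$q2, 0.99)
  # pure noise: Q2 small at a single draw, median <= 0 over seeds
  q2s <- vapply(1:20, function(s) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(50 * 10), 50, 10)
    yn <- rnorm(50)
    loo_q2(Xn, yn, 2)$q2
  }, numeric(1))
  expect_lte(median(q2s), 0)
  expect_lte(min(q2s), 0.2)
})

test_that("fit statistics equal direct evaluation of their formulas", {
  set.seed(14)
  X <- matrix(rnorm(20 * 15), 20, 15)
  y <- rnorm(20)
  fit <- pls_fit(X, y, 3)
  st <- fit_statistics(fit, X, y)
  res <- y - predict(fit, X)
  rss <- sum(res^2); sd_ <- sum((y - mean(y))^2)
  expect_equal(st$r2_ncv, 1 - rss / sd_, tolerance = 1e-10)
  expect_equal(st$see, sqrt(rss / (20 - 3 - 1)), tolerance = 1e-10)
  expect_equal(st$f, (st$r2_ncv / 3) / ((1 - st$r2_ncv) / 16),
               tolerance = 1e-10)
  expect_equal(st$f_ratio, st$r2_ncv / (1 - st$r2_ncv), tolerance = 1e-10)
  expect_gte(st$r2_ncv, 0)
  expect_lte(st$r2_ncv, 1)
  fit3 <- pls_fit(X[1:6, ], y[1:6], 3)
  expect_error(fit_statistics(fit3, X[1:4, ], y[1:4]), "n >")
})

test_that("training R2 is non-decreasing in the component count", {
  set.seed(26)
  X <- matrix(rnorm(15 * 30), 15, 30)
  y <- rnorm(15)
  r2 <- vapply(1:8, function(a)
    fit_statistics(pls_fit(X, y, a), X, y)$r2_ncv, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("external predictivity statistic reproduces worked examples", {
  expect_equal(r2_pred(c(7, 8, 9), c(7, 8, 9), 8), 1.0)
  expect_equal(r2_pred(c(7, 8, 9), c(8, 8, 8), 8), 0.0)
  expect_equal(r2_pred(c(7, 8, 9), c(7.5, 8, 8.5), 8), 0.75)
  expect_error(r2_pred(c(8, 8), c(7, 9), 8), "undefined")
  expect_error(r2_pred(c(7, 8), 7.5, 8), "equal length")
})

test_that("field contributions are normalised |b|*sd sums", {
  set.seed(44)
  b1 <- stub_block(14, 10, "comsia_steric")
  dm1 <- assemble_descriptor_matrix(list(b1))
  y <- rnorm(14)
  fit1 <- pls_fit(dm1, y, 2)
  expect_equal(unname(field_contributions(fit1)), 1)
  # two identical blocks split evenly by symmetry
  b2 <- b1; b2$kind <- "comsia_hydrophobic"
  dm2 <- assemble_descriptor_matrix(list(b1, b2))
  fit2 <- pls_fit(dm2, y, 2)
  contr <- field_contributions(fit2)
  expect_equal(unname(contr), c(0.5, 0.5), tolerance = 1e-10)
  # random two-block case matches the direct formula
  b3 <- stub_block(14, 7, "comsia_donor")
  dm3 <- assemble_descriptor_matrix(list(b1, b3))
  fit3 <- pls_fit(dm3, y, 3)
  raw <- abs(fit3$coefficients) * apply(dm3$x, 2, sd)
  direct <- tapply(raw, dm3$col_map$kind, sum)
  direct <- direct / sum(direct)
  expect_equal(sort(unname(field_contributions(fit3))),
               sort(as.numeric(direct)), tolerance = 1e-10)
  expect_equal(sum(field_contributions(fit3)), 1, tolerance = 1e-9)
})

test_that("predictions are invariant to a consistent column permutation", {
  set.seed(55)
  X <- matrix(rnorm(16 * 12), 16, 12)
  y <- rnorm(16)
  perm <- sample(12)
  f1 <- pls_fit(X, y, 3)
  f2 <- pls_fit(X[, perm], y, 3)
  expect_equal(predict(f2, X[, perm]), predict(f1, X), tolerance = 1e-10)
  expect_equal(f2$coefficients[order(perm)], f1$coefficients,
               tolerance = 1e-10)
})

test_that("adding pure-noise columns does not systematically raise Q2", {
  deltas <- vapply(1:50, function(s) {
    set.seed(200 + s)
    X <- matrix(rnorm(30 * 8), 30, 8)
    y <- as.numeric(X[, 1:3] %*% c(1, -0.5, 0.8)) + rnorm(30, sd = 0.5)
    base <- loo_q2(X, y, 3)$q2
    noisy <- loo_q2(cbind(X, matrix(rnorm(30 * 6), 30, 6)), y, 3)$q2
    noisy - base
  }, numeric(1))
  expect_lte(median(deltas), 0)
})

test_that("model search enumerates subsets and finds planted signal", {
  set.seed(66)
  kinds <- paste0("comsia_", PROPERTY_KINDS)
  blocks <- lapply(kinds, function(k) stub_block(24, 12, k))
  # activity driven by the steric block only
  y <- as.numeric(blocks[[1]]$values %*% rnorm(12, sd = 0.6))
  ms <- model_search(blocks, y, max_components = 4)
  expect_equal(nrow(ms$table), 31L)
  expect_match(ms$table$model[1], "steric")
  expect_true(all(diff(ms$table$q2) <= 1e-12))
  # single block: one combination
  ms1 <- model_search(blocks[1], y, max_components = 3)
  expect_equal(nrow(ms1$table), 1L)
  # the CoMFA pair adds exactly one combined model
  cblocks <- list(stub_block(24, 12, "comfa_steric"),
                  stub_block(24, 12, "comfa_electrostatic"))
  ms2 <- model_search(c(blocks[1:2], cblocks), y, max_components = 3,
                      min_sigma = c(comfa = 0, comsia = 0))
  expect_equal(nrow(ms2$table), 4L)   # 3 CoMSIA subsets + CoMFA pair
  expect_true("comfa.steric+comfa.electrostatic" %in% ms2$table$model)
})

test_that("model search output is deterministic", {
  set.seed(77)
  blocks <- lapply(c("comsia_steric", "comsia_donor"),
                   function(k) stub_block(20, 9, k))
  y <- rnorm(20)
  t1 <- model_search(blocks, y, max_components = 3)$table
  t2 <- model_search(blocks, y, max_components = 3)$table
  expect_identical(t1, t2)
})
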