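as_x_matrix <- function(x) {
  if (inherits(x, "descriptor_matrix")) x$x else as.matrix(x)
}

#' Fit a PLS regression model (NIPALS, single response)
#'
#' Sequential NIPALS latent components on column-centred X and centred y:
#' for each component, the weight vector is the (normalised) covariance
#' `X'y`, scores `t = Xw`, X-loadings `p = X't/t't`, y-loading
#' `q = y't/t't`, followed by deflation of X and y. The regression
#' coefficient vector on the original (centred) columns is
#' `B = W (P'W)^-1 q`. The response is never rescaled; X columns are only
#' centred (block scaling is handled upstream by
#' [assemble_descriptor_matrix()]), matching CoMFA-standard practice.
#'
#' @param x A `descriptor_matrix` or numeric matrix (n x p).
#' @param y Numeric response vector (pKi), length n.
#' @param ncomp Number of latent components (0 gives the training-mean
#'   model). Must not exceed the effective rank of centred X.
#' @return Object of class `pls_model`: `ncomp`, `x_mean`, `y_mean`,
#'   `weights` (p x ncomp), `loadings` (p x ncomp), `y_loadings`,
#'   `scores` (n x ncomp), `coefficients` (p), plus `col_map` and
#'   `x_sd` when fitted from a `descriptor_matrix`.
#' @export
pls_fit <- function(x, y, ncomp) {
  xm <- as_x_matrix(x)
  y <- as.numeric(y)
  n <- nrow(xm); p <- ncol(xm)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (stats::sd(y) == 0) stop("constant response: zero variance in y")
  if (ncomp < 0) stop("ncomp must be >= 0")
  if (n < ncomp + 2L) stop("need at least ncomp + 2 observations")
  x_mean <- colMeans(xm)
  y_mean <- mean(y)
  E <- sweep(xm, 2L, x_mean)
  f <- y - y_mean
  W <- P <- matrix(0, p, ncomp)
  TT <- matrix(0, n, ncomp)
  qv <- numeric(ncomp)
  tol <- 1e-12 * max(1, sum(E^2))
  a <- 0L
  while (a < ncomp) {
    w <- crossprod(E, f)
    wn <- sqrt(sum(w^2))
    if (wn^2 < tol * max(1, sum(f^2)) || sum(f^2) < 1e-30)
      stop("ncomp = ", ncomp, " exceeds the rank of X (stopped at ", a, ")")
    w <- w / wn
    t_ <- E %*% w
    tt <- sum(t_^2)
    if (tt < tol)
      stop("ncomp = ", ncomp, " exceeds the rank of X (stopped at ", a, ")")
    p_ <- crossprod(E, t_) / tt
    q_ <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - q_ * t_
    a <- a + 1L
    W[, a] <- w; P[, a] <- p_; TT[, a] <- t_; qv[a] <- q_
  }
  coefficients <- if (ncomp == 0L) numeric(p) else
    as.numeric(W %*% solve(crossprod(P, W), qv))
  out <- structure(list(ncomp = ncomp, x_mean = x_mean, y_mean = y_mean,
                        weights = W, loadings = P, y_loadings = qv,
                        scores = TT, coefficients = coefficients),
                   class = "pls_model")
  if (inherits(x, "descriptor_matrix")) {
    out$col_map <- x$col_map
    out$x_sd <- apply(xm, 2L, stats::sd)
    out$grid <- x$grid
    out$dropped <- x$dropped
  }
  out
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d descriptor column(s)\n",
              x$ncomp, length(x$coefficients)))
  invisible(x)
}

#' Predict activities from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata A `descriptor_matrix` or matrix with the same columns the
#'   model was fitted on.
#' @param ncomp Optional smaller component count to truncate the model to.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ncomp = NULL, ...) {
  xm <- as_x_matrix(newdata)
  b <- if (is.null(ncomp) || ncomp == object$ncomp) object$coefficients
       else coef_at(object, ncomp)
  as.numeric(sweep(xm, 2L, object$x_mean) %*% b + object$y_mean)
}

# coefficient vector truncated to the first `a` components
coef_at <- function(model, a) {
  stopifnot(a >= 0, a <= model$ncomp)
  if (a == 0L) return(numeric(length(model$coefficients)))
  W <- model$weights[, seq_len(a), drop = FALSE]
  P <- model$loadings[, seq_len(a), drop = FALSE]
  as.numeric(W %*% solve(crossprod(P, W), model$y_loadings[seq_len(a)]))
}

#' Leave-one-out cross-validation Q2
#'
#' Refits the PLS model n times, each time leaving one compound out
#' (centering recomputed per fold), and predicts it from the reduced model.
#' \deqn{Q^2 = 1 - PRESS/SD}, with \eqn{PRESS = \sum_i (y_i -
#' \hat{y}_{(-i)})^2} and \eqn{SD = \sum_i (y_i - \bar{y})^2} about the
#' full training mean. When `ncomp` is a vector, predictions for every
#' component count are extracted from a single sequential fit per fold
#' (NIPALS components are nested, so this equals refitting at each count).
#'
#' @param x A `descriptor_matrix` or matrix.
#' @param y Numeric response vector.
#' @param ncomp Component count, or vector of counts to evaluate.
#' @return For scalar `ncomp`: list with `q2`, `press`, `sd`, `sep`
#'   (`sqrt(PRESS/(n - ncomp - 1))`), `predictions`. For a vector: a
#'   data.frame with one row per component count.
#' @export
loo_q2 <- function(x, y, ncomp) {
  xm <- as_x_matrix(x)
  y <- as.numeric(y)
  n <- nrow(xm)
  if (n < 3L) stop("leave-one-out requires n >= 3")
  cmax <- max(ncomp)
  preds <- matrix(NA_real_, n, cmax)
  for (i in seq_len(n)) {
    fit <- pls_fit(xm[-i, , drop = FALSE], y[-i], cmax)
    for (a in ncomp)
      preds[i, a] <- predict(fit, xm[i, , drop = FALSE], ncomp = a)
  }
  sd_tot <- sum((y - mean(y))^2)
  stats_at <- function(a) {
    press <- sum((y - preds[, a])^2)
    list(q2 = 1 - press / sd_tot, press = press, sd = sd_tot,
         sep = sqrt(press / (n - a - 1)), predictions = preds[, a])
  }
  if (length(ncomp) == 1L) return(stats_at(ncomp))
  do.call(rbind, lapply(ncomp, function(a) {
    s <- stats_at(a)
    data.frame(ncomp = a, q2 = s$q2, press = s$press, sep = s$sep)
  }))
}

#' Non-cross-validated fit statistics
#'
#' Computes, from training residuals, the squared correlation-type fit
#' coefficient `r2_ncv = 1 - RSS/SD`, the standard error of estimate
#' `SEE = sqrt(RSS/(n - c - 1))`, and the F statistic in its
#' degrees-of-freedom form `F = (r2/c) / ((1 - r2)/(n - c - 1))` with
#' `c = ncomp`. The dimensionless ratio `r2/(1 - r2)` is also reported as
#' `f_ratio` for comparability with tables that print it.
#'
#' @param model A `pls_model`.
#' @param x Training descriptors (matrix or `descriptor_matrix`).
#' @param y Training response.
#' @return List with `r2_ncv`, `see`, `f`, `f_ratio`, `rss`, `sd`.
#' @export
fit_statistics <- function(model, x, y) {
  y <- as.numeric(y)
  n <- length(y)
  cc <- model$ncomp
  if (n <= cc + 1L) stop("need n > ncomp + 1 for fit statistics")
  yhat <- predict(model, x)
  rss <- sum((y - yhat)^2)
  sd_tot <- sum((y - mean(y))^2)
  r2 <- 1 - rss / sd_tot
  see <- sqrt(rss / (n - cc - 1))
  f <- if (cc > 0L) (r2 / cc) / ((1 - r2) / (n - cc - 1)) else NA_real_
  list(r2_ncv = r2, see = see, f = f,
       f_ratio = if (r2 < 1) r2 / (1 - r2) else Inf,
       rss = rss, sd = sd_tot)
}

#' External predictivity statistic
#'
#' \deqn{R^2_{pred} = (SD - PRESS)/SD} where SD is the sum of squared
#' deviations of the test activities from the **training-set** mean and
#' PRESS the sum of squared test prediction errors.
#'
#' @param y_test Observed test activities.
#' @param y_hat Predicted test activities.
#' @param train_mean Mean activity of the training set.
#' @return Scalar R2_pred.
#' @examples
#' r2_pred(c(7, 8, 9), c(7.5, 8, 8.5), 8)  # 0.75
#' @export
r2_pred <- function(y_test, y_hat, train_mean) {
  y_test <- as.numeric(y_test); y_hat <- as.numeric(y_hat)
  if (length(y_test) != length(y_hat) || !length(y_test))
    stop("y_test and y_hat must be non-empty and of equal length")
  sd_tot <- sum((y_test - train_mean)^2)
  if (sd_tot == 0)
    stop("undefined statistic: test activities all equal the training mean")
  (sd_tot - sum((y_test - y_hat)^2)) / sd_tot
}

#' Per-field contribution fractions
#'
#' The contribution of field kind k is
#' \eqn{\sum_{j \in k} |b_j|\, sd(x_j)} over the model's retained columns,
#' normalised to sum to 1 across kinds.
#'
#' @param model A `pls_model` fitted from a `descriptor_matrix` (or supply
#'   `x` and `col_map`).
#' @param x Optional training descriptors to recompute column sds from.
#' @param col_map Optional data.frame with a `kind` column per descriptor
#'   column.
#' @return Named numeric vector of fractions summing to 1.
#' @export
field_contributions <- function(model, x = NULL, col_map = NULL) {
  if (is.null(col_map)) col_map <- model$col_map
  if (is.null(col_map)) stop("no column-to-field mapping available")
  sds <- if (!is.null(x)) apply(as_x_matrix(x), 2L, stats::sd) else model$x_sd
  if (is.null(sds)) stop("no column standard deviations available")
  raw <- abs(model$coefficients) * sds
  contr <- tapply(raw, factor(col_map$kind, levels = unique(col_map$kind)), sum)
  contr <- stats::setNames(as.numeric(contr), names(contr))
  total <- sum(contr)
  if (total == 0) return(contr)
  contr / total
}

#' Exhaustive field-combination model search
#'
#' Evaluates a PLS model for every non-empty subset of the supplied CoMSIA
#' field blocks (31 combinations for all five kinds) plus, when both CoMFA
#' blocks are supplied, the CoMFA steric+electrostatic pair as one
#' additional model. For each combination the component count maximising
#' the leave-one-out Q2 over `1..max_components` is selected (ties broken
#' toward fewer components) and the full fit statistics are reported.
#'
#' @param blocks Named list of `field_block` objects (see
#'   [compute_field_blocks()]).
#' @param y Response vector (pKi), aligned with the block rows.
#' @param max_components Upper bound on PLS components (default 10; also
#'   capped at n - 2).
#' @param min_sigma Column filter thresholds, see
#'   [assemble_descriptor_matrix()].
#' @return Object of class `model_search`: list with `table` (data.frame
#'   ranked by Q2: `model`, `fields`, `ncomp`, `q2`, `sep`, `r2_ncv`,
#'   `see`, `f`, contribution columns) and `models` (named list with the
#'   fitted `pls_model` and `descriptor_matrix` per combination).
#' @export
model_search <- function(blocks, y, max_components = 10,
                         min_sigma = c(comfa = 2.0, comsia = 0)) {
  if (!length(blocks)) stop("need at least one field block")
  kinds <- vapply(blocks, `[[`, character(1L), "kind")
  names(blocks) <- kinds
  comsia <- kinds[startsWith(kinds, "comsia_")]
  combos <- list()
  if (length(comsia)) {
    for (sz in seq_along(comsia))
      combos <- c(combos, utils::combn(comsia, sz, simplify = FALSE))
  }
  if (all(c("comfa_steric", "comfa_electrostatic") %in% kinds))
    combos <- c(combos, list(c("comfa_steric", "comfa_electrostatic")))
  if (!length(combos)) combos <- list(kinds)
  n <- nrow(blocks[[1L]]$values)
  cmax <- max(1L, min(max_components, n - 2L))
  rows <- list(); models <- list()
  for (combo in combos) {
    name <- paste(sub("^comsia_", "", sub("^comfa_", "comfa.", combo)),
                  collapse = "+")
    dm <- assemble_descriptor_matrix(blocks[combo], min_sigma = min_sigma)
    loo_table <- function(comps) {
      r <- loo_q2(dm, y, comps)
      if (is.data.frame(r)) r
      else data.frame(ncomp = comps, q2 = r$q2, press = r$press,
                      sep = r$sep)
    }
    cv <- tryCatch(loo_table(seq_len(cmax)), error = function(e) e)
    if (inherits(cv, "error")) {
      # rank-limited: retry with the largest feasible component count
      feas <- max_feasible_ncomp(dm, y, cmax)
      cv <- loo_table(seq_len(feas))
    }
    best <- cv$ncomp[which.max(cv$q2)]
    fit <- pls_fit(dm, y, best)
    st <- fit_statistics(fit, dm, y)
    contr <- field_contributions(fit)
    row <- data.frame(model = name,
                      fields = paste(combo, collapse = ","),
                      ncomp = best,
                      q2 = cv$q2[cv$ncomp == best],
                      sep = cv$sep[cv$ncomp == best],
                      r2_ncv = st$r2_ncv, see = st$see, f = st$f,
                      stringsAsFactors = FALSE)
    for (k in names(blocks))
      row[[paste0("contrib_", sub("^comsia_", "", sub("^comfa_", "comfa.", k)))]] <-
        if (k %in% combo) unname(contr[k]) else NA_real_
    rows[[name]] <- row
    models[[name]] <- list(model = fit, descriptors = dm, cv = cv)
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$q2, tab$ncomp, tab$model)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, models = models), class = "model_search")
}

max_feasible_ncomp <- function(dm, y, cmax) {
  for (a in rev(seq_len(cmax))) {
    ok <- TRUE
    n <- nrow(as_x_matrix(dm))
    for (i in seq_len(n)) {
      f <- tryCatch(pls_fit(as_x_matrix(dm)[-i, , drop = FALSE], y[-i], a),
                    error = function(e) NULL)
      if (is.null(f)) { ok <- FALSE; break }
    }
    if (ok) return(a)
  }
  stop("no feasible PLS component count")
}

#' @export
print.model_search <- function(x, ...) {
  cat("<model_search> ", nrow(x$table), " field combination(s), best by Q2:\n",
      sep = "")
  print(utils::head(x$table[, c("model", "ncomp", "q2", "r2_ncv", "see", "f")],
                    5L))
  invisible(x)
}
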