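# independent reference implementations used as oracles

# reference PEOE charges for the helper fixtures, computed with RDKit's
# ComputeGasteigerCharges (12 iterations); atom order as in make_ethanol()
rdkit_ethanol_charges <- c(-0.04184, 0.04022, -0.39666,
                           0.02537, 0.02537, 0.02537,
                           0.05607, 0.05607, 0.21002)
rdkit_methane_charges <- c(-0.07756, 0.01939, 0.01939, 0.01939, 0.01939)

# brute-force NIPALS written with explicit scalar loops (deliberately
# different code path from the package implementation)
nipals_reference <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  xm <- numeric(p)
  for (j in 1:p) xm[j] <- mean(X[, j])
  E <- X
  for (j in 1:p) E[, j] <- X[, j] - xm[j]
  f <- y - mean(y)
  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  for (a in 1:ncomp) {
    w <- numeric(p)
    for (j in 1:p) w[j] <- sum(E[, j] * f)
    w <- w / sqrt(sum(w * w))
    t_ <- numeric(n)
    for (i in 1:n) t_[i] <- sum(E[i, ] * w)
    tt <- sum(t_ * t_)
    pv <- numeric(p)
    for (j in 1:p) pv[j] <- sum(E[, j] * t_) / tt
    qa <- sum(f * t_) / tt
    for (j in 1:p) E[, j] <- E[, j] - t_ * pv[j]
    f <- f - qa * t_
    W[, a] <- w; P[, a] <- pv; q[a] <- qa
  }
  b <- W %*% solve(t(P) %*% W) %*% q
  list(coefficients = as.numeric(b),
       intercept = mean(y) - sum(xm * b))
}

# closed-form check: PLS1 fitted values equal the least-squares projection
# of centred y onto the Krylov space span{s, As, A^2 s, ...} of the centred
# data (A = X'X, s = X'y) — a mathematically independent characterisation
krylov_fitted <- function(X, y, ncomp) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  s <- crossprod(Xc, yc)
  A <- crossprod(Xc)
  K <- matrix(0, ncol(X), ncomp)
  v <- s
  for (a in 1:ncomp) {
    K[, a] <- v
    v <- A %*% v
  }
  Q <- qr.Q(qr(K))
  Z <- Xc %*% Q
  as.numeric(Z %*% solve(crossprod(Z), crossprod(Z, yc))) + mean(y)
}
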