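# independent oracles, deliberately computed on a different path than the
# implementations they check

# PLS1 regression vector via Helland's Krylov-subspace closed form:
# b = Q (Q' S Q)^-1 Q' s with S = Xc'Xc, s = Xc'yc and Q an orthonormal basis
# of span{s, S s, ..., S^(A-1) s}. Equivalent to A-component PLS1 but shares
# no code with the NIPALS engine.
krylov_pls1 <- function(X, y, a) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  S <- crossprod(Xc)
  s <- drop(crossprod(Xc, yc))
  K <- matrix(0, ncol(X), a)
  v <- s
  for (j in seq_len(a)) {
    K[, j] <- v / sqrt(sum(v^2))
    v <- drop(S %*% K[, j])
  }
  Q <- qr.Q(qr(K))
  b <- Q %*% solve(crossprod(Q, S %*% Q), crossprod(Q, s))
  list(b = drop(b), x_mean = xm, y_mean = ym)
}

krylov_predict <- function(oracle, X) {
  drop(sweep(X, 2, oracle$x_mean) %*% oracle$b) + oracle$y_mean
}

# brute-force leave-one-out RMSECV at 1 LV using the closed-form
# single-component model (w ~ Xc'yc)
brute_loo_rmsecv_1lv <- function(X, y) {
  errs <- vapply(seq_len(nrow(X)), function(i) {
    Xt <- X[-i, , drop = FALSE]; yt <- y[-i]
    xm <- colMeans(Xt); ym <- mean(yt)
    Xc <- sweep(Xt, 2, xm); yc <- yt - ym
    w <- drop(crossprod(Xc, yc)); w <- w / sqrt(sum(w^2))
    t_ <- drop(Xc %*% w)
    q <- sum(yc * t_) / sum(t_^2)
    (ym + q * sum((X[i, ] - xm) * w)) - y[i]
  }, numeric(1))
  sqrt(mean(errs^2))
}
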