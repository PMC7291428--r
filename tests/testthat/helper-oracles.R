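# Independent oracles used to verify the package's solvers. These
# deliberately use different algorithms from the implementation.

# Projected-gradient NNLS (FISTA with monotone restart), run to tight
# KKT tolerance. Independent of the active-set solver in the package.
pg_nnls <- function(X, y, tol = 1e-11, max_iter = 2e5) {
  X <- as.matrix(X)
  cs <- sqrt(colSums(X^2)); cs[cs == 0] <- 1
  Xs <- sweep(X, 2, cs, "/")
  XtX <- crossprod(Xs)
  Xty <- drop(crossprod(Xs, y))
  L <- max(eigen(XtX, symmetric = TRUE, only.values = TRUE)$values)
  p <- ncol(Xs)
  x <- numeric(p); z <- x; t_k <- 1
  obj <- function(v) sum((y - Xs %*% v)^2)
  f_prev <- obj(x)
  for (it in seq_len(max_iter)) {
    grad <- drop(XtX %*% z) - Xty
    x_new <- pmax(z - grad / L, 0)
    f_new <- obj(x_new)
    if (f_new > f_prev) {        # monotone restart
      z <- x; t_k <- 1
      grad <- drop(XtX %*% z) - Xty
      x_new <- pmax(z - grad / L, 0)
      f_new <- obj(x_new)
    }
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- x_new + (t_k - 1) / t_new * (x_new - x)
    # KKT: gradient ~ 0 on the support, >= 0 off it
    g2 <- drop(XtX %*% x_new) - Xty
    kkt <- max(abs(g2[x_new > 0]), 0, -min(g2[x_new <= 0], 0))
    x <- x_new; t_k <- t_new; f_prev <- f_new
    if (kkt < tol * max(1, max(abs(Xty)))) break
  }
  b <- x / cs
  list(coefficients = b, rss = sum((y - X %*% b)^2))
}

# Closed-form OLS via solve of the normal equations (textbook route).
ols_oracle <- function(X, y) {
  b <- solve(crossprod(X), crossprod(X, y))
  r <- y - X %*% b
  rss <- sum(r^2)
  df <- nrow(X) - ncol(X)
  se <- sqrt(diag(solve(crossprod(X))) * rss / df)
  t <- drop(b) / se
  list(coefficients = drop(b), se = se,
       p = 2 * stats::pt(abs(t), df, lower.tail = FALSE), rss = rss)
}

# Brute-force TMM factor for one sample against a reference: enumerate the
# trimmed gene set by explicit sorting, then take the weighted mean M-value.
tmm_oracle <- function(obs, ref, trim_m = 0.3, trim_a = 0.05) {
  lo_ <- sum(obs); lr_ <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / lo_) / (ref / lr_))
  a <- 0.5 * log2((obs / lo_) * (ref / lr_))
  w <- (lo_ - obs) / (lo_ * obs) + (lr_ - ref) / (lr_ * ref)
  if (max(abs(m)) < 1e-10) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  ok_m <- rank(m) >= lo_m & rank(m) <= hi_m
  ok_a <- rank(a) >= lo_a & rank(a) <= hi_a
  sel <- ok_m & ok_a
  if (!any(sel)) return(1)
  2^(sum(m[sel] / w[sel]) / sum(1 / w[sel]))
}

# Step-up Benjamini-Hochberg computed by direct enumeration.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
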