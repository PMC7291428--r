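#' Non-negative least squares
#'
#' Solves min ||y - X b||^2 subject to b >= 0 by the Lawson-Hanson active-set
#' algorithm, operating on the normal equations with column equilibration for
#' numerical stability. The active-set method terminates at the exact KKT
#' point (up to the tolerance), which is what the deconvolution model needs:
#' residual sums of squares of nested models must be comparable at 1e-9.
#'
#' @param X numeric design matrix (n x p), no intercept added.
#' @param y numeric response of length n.
#' @param tol dual-feasibility tolerance, scaled by the problem magnitude.
#' @return list with `coefficients` (length p, >= 0) and `rss`.
#' @export
nnls_solve <- function(X, y, tol = 1e-10) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  cs <- sqrt(colSums(X^2))
  cs[cs == 0] <- 1
  Xs <- sweep(X, 2, cs, "/")
  fit <- nnls_normal(crossprod(Xs), drop(crossprod(Xs, y)), sum(y^2),
                     tol = tol)
  b <- fit$x
  # polish the passive set with a QR least-squares solve on the actual
  # columns and recompute the rss from residuals: the normal-equations rss
  # formula cancels catastrophically when rss << ||y||^2, and nested-model
  # comparisons need absolute 1e-9 agreement
  act <- which(b > 0)
  if (length(act)) {
    bp <- qr.solve(Xs[, act, drop = FALSE], y)
    if (all(bp >= 0)) b[act] <- bp
  }
  rss <- sum((y - drop(Xs %*% b))^2)
  b <- b / cs
  names(b) <- colnames(X)
  list(coefficients = b, rss = rss)
}

# Lawson-Hanson active-set NNLS on a precomputed Gram system.
# XtX: p x p crossproduct, Xty: length-p, yty: sum(y^2).
nnls_normal <- function(XtX, Xty, yty, tol = 1e-10) {
  p <- length(Xty)
  x <- numeric(p)
  passive <- rep(FALSE, p)
  scale <- max(abs(Xty), diag(XtX), 1)
  ls_on <- function(idx) {
    z <- numeric(p)
    sol <- tryCatch(solve(XtX[idx, idx, drop = FALSE], Xty[idx]),
                    error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    z[idx] <- sol
    z
  }
  for (outer in seq_len(10 * p + 30)) {
    w <- Xty - drop(XtX %*% x)
    w[passive] <- -Inf
    j <- which.max(w)
    if (!any(!passive) || w[j] <= tol * scale) break
    passive[j] <- TRUE
    for (inner in seq_len(10 * p + 30)) {
      idx <- which(passive)
      z <- ls_on(idx)
      if (is.null(z)) {            # singular subsystem: reject the new entry
        passive[j] <- FALSE
        z <- x
        break
      }
      if (all(z[idx] > 0)) break
      neg <- idx[z[idx] <= 0]
      ratio <- x[neg] / (x[neg] - z[neg])
      alpha <- min(ratio)
      x <- x + alpha * (z - x)
      movers <- neg[ratio <= alpha * (1 + 1e-12) + 1e-300]
      x[movers] <- 0
      passive[movers] <- FALSE
      x[!passive] <- 0
    }
    x <- z
    x[!passive] <- 0
  }
  rss <- yty - 2 * sum(x * Xty) + drop(t(x) %*% XtX %*% x)
  list(x = x, rss = max(rss, 0))
}
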