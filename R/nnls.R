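# Fast nonnegative least squares on the normal equations (Bro & De Jong
# 1997 variant of Lawson-Hanson). Operates on the cross-products ZtZ = A'A
# and Ztx = A'b, which keeps the 2D inversion tractable: the Kronecker
# structure of the compressed kernel makes A'A cheap to form once and reuse
# across records, while the raw augmented matrix would not fit the same
# budget. Cross-checked against pracma::lsqnonneg in the test suite.
#
# Solves min ||A x - b||^2 s.t. x >= 0. ZtZ must be positive definite on
# the passive set (guaranteed when a Tikhonov term alpha^2 I is folded in).
fnnls <- function(ZtZ, Ztx, tol = NULL, max_iter = NULL) {
  n <- length(Ztx)
  if (is.null(tol)) tol <- 1e-10 * max(abs(Ztx), .Machine$double.xmin)
  if (is.null(max_iter)) max_iter <- 30 * n
  x <- numeric(n)
  passive <- logical(n)
  w <- Ztx                      # gradient of -0.5 * objective at x = 0
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol) {
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        stop("fnnls failed to converge (", iter, " iterations)",
             call. = FALSE)
      P <- which(passive)
      s <- numeric(n)
      sol <- tryCatch(
        chol2inv(chol(ZtZ[P, P, drop = FALSE])) %*% Ztx[P],
        error = function(e)
          qr.solve(ZtZ[P, P, drop = FALSE], Ztx[P], tol = 1e-14))
      s[P] <- sol
      if (all(s[P] > 0)) { x <- s; break }
      bad <- P[s[P] <= 0]
      step <- min(x[bad] / (x[bad] - s[bad]))
      x <- x + step * (s - x)
      passive[x <= tol * max(1, max(abs(x)))] <- FALSE
      x[!passive] <- 0
    }
    w <- Ztx - ZtZ %*% x
  }
  x
}
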