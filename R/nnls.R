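## Non-negative least squares (Lawson-Hanson active set), shared by the
## indirect Fourier transform and the c(s) fitter. Operates on the normal
## equations; callers are expected to regularize ill-conditioned systems
## by stacking Tikhonov rows before the call.

nnls_solve <- function(A, b, tol = NULL, max_outer = NULL) {
  A <- as.matrix(A)
  n <- ncol(A)
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  if (is.null(tol)) tol <- 1e-10 * max(abs(Atb), 1)
  if (is.null(max_outer)) max_outer <- 5L * n
  x <- numeric(n)
  passive <- logical(n)
  outer <- 0L
  repeat {
    w <- Atb - drop(AtA %*% x)
    cand <- which(!passive)
    if (length(cand) == 0L || max(w[cand]) <= tol || outer >= max_outer) break
    outer <- outer + 1L
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      p <- which(passive)
      s <- numeric(n)
      sp <- tryCatch(
        solve(AtA[p, p, drop = FALSE], Atb[p]),
        error = function(e) qr.solve(AtA[p, p, drop = FALSE] +
                                       diag(1e-12, length(p)), Atb[p]))
      s[p] <- sp
      if (min(s[p]) > 0) { x <- s; break }
      q <- p[s[p] <= 0]
      alpha <- min(x[q] / (x[q] - s[q]))
      x <- x + alpha * (s - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) { x[] <- 0; break }
    }
  }
  x[x < 0] <- 0
  x
}
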