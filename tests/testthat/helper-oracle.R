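# Independent brute-force oracle for the marginal-polytope optimization.
#
# Everything here is deliberately separate from the package's solution path:
# plain dense linear algebra (svd), closed-form interval arithmetic and
# one-dimensional golden-section minimization (stats::optimize), and direct
# entropy sums.  The feasible set is parametrized by an orthonormal basis of
# the null space of the marginal-constraint matrix restricted to the support
# grid; the input distribution itself is a feasible starting point.  Only
# null-space dimensions 0, 1 and 2 are supported, which covers the gate
# benchmarks that need brute force (And, XorAnd: k = 1) and full-support
# 2x2x2 distributions (k = 2).

okey <- function(...) paste(..., sep = "\r")

oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

## support grid and dense marginal-constraint system of a joint_pmf-like
## data.frame with columns x, y, z, p
oracle_system <- function(pmf) {
  pxy <- tapply(pmf$p, okey(pmf$x, pmf$y), sum)
  pxz <- tapply(pmf$p, okey(pmf$x, pmf$z), sum)
  grid <- expand.grid(x = sort(unique(as.character(pmf$x))),
                      y = sort(unique(as.character(pmf$y))),
                      z = sort(unique(as.character(pmf$z))),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- okey(grid$x, grid$y) %in% names(pxy) &
          okey(grid$x, grid$z) %in% names(pxz)
  tri <- grid[keep, , drop = FALSE]
  fxy <- factor(okey(tri$x, tri$y)); fxz <- factor(okey(tri$x, tri$z))
  n <- nrow(tri)
  B <- matrix(0, nlevels(fxy) + nlevels(fxz), n)
  B[cbind(as.integer(fxy), seq_len(n))] <- 1
  B[cbind(nlevels(fxy) + as.integer(fxz), seq_len(n))] <- 1
  q0 <- numeric(n)
  q0[match(okey(pmf$x, pmf$y, pmf$z), okey(tri$x, tri$y, tri$z))] <- pmf$p
  list(tri = tri, B = B, b = c(pxy[levels(fxy)], pxz[levels(fxz)]), q0 = q0)
}

## objective of the underlying convex program at q >= 0 (0 ln 0 = 0)
oracle_objective <- function(q, blk) {
  q <- pmax(q, 0)
  V <- tapply(q, blk, sum)
  s <- q * log(q / as.numeric(V[blk]))
  sum(s[q > 0])
}

## feasible interval of t for q + t * dir >= 0
oracle_interval <- function(q, dir, eps = 0) {
  lo <- -Inf; hi <- Inf
  pos <- dir > 1e-14; neg <- dir < -1e-14
  if (any(pos)) lo <- max(-q[pos] / dir[pos])
  if (any(neg)) hi <- min(-q[neg] / dir[neg])
  c(lo + eps, hi - eps)
}

## minimize a univariate convex function over [iv[1], iv[2]], tolerating
## empty or degenerate (single-point) intervals
oracle_min1d <- function(fn, iv) {
  if (!all(is.finite(iv)) || iv[1] > iv[2] + 1e-12) return(Inf)
  if (iv[2] - iv[1] < 1e-12) return(fn(mean(iv)))
  op <- stats::optimize(fn, iv, tol = 1e-14)
  min(op$objective, fn(iv[1]), fn(iv[2]))
}

## as oracle_min1d but returning the minimizing argument
oracle_argmin1d <- function(fn, iv) {
  if (iv[2] - iv[1] < 1e-12) return(mean(iv))
  op <- stats::optimize(fn, iv, tol = 1e-14)
  cand <- c(op$minimum, iv)
  cand[which.min(vapply(cand, fn, 0))]
}

## minimize the convex objective over the marginal polytope by exhaustive
## search over the (<= 2 dimensional) null space
oracle_min_cp <- function(pmf) {
  sys <- oracle_system(pmf)
  n <- nrow(sys$tri)
  blk <- as.integer(factor(okey(sys$tri$y, sys$tri$z)))
  sv <- svd(sys$B, nu = 0, nv = n)
  rk <- sum(sv$d > 1e-11 * max(sv$d))
  k <- n - rk
  if (k == 0) {
    q <- sys$q0
  } else if (k == 1) {
    dirn <- sv$v[, n, drop = TRUE]
    iv <- oracle_interval(sys$q0, dirn)
    t_best <- oracle_argmin1d(function(t)
      oracle_objective(sys$q0 + t * dirn, blk), iv)
    q <- sys$q0 + t_best * dirn
  } else if (k == 2) {
    N <- sv$v[, c(n - 1, n), drop = FALSE]
    fixed <- abs(N[, 2]) <= 1e-14
    inner <- function(t1) {
      base <- sys$q0 + t1 * N[, 1]
      if (any(base[fixed] < -1e-12)) return(Inf)
      oracle_min1d(function(t2) oracle_objective(base + t2 * N[, 2], blk),
                   oracle_interval(base, N[, 2]))
    }
    ## outer: scan t1 over a ball certain to contain the polytope (any two
    ## probability vectors are at L2 distance <= sqrt(2) and N is
    ## orthonormal), then refine around the best grid point
    span <- seq(-1.5, 1.5, length.out = 601)
    vals <- vapply(span, inner, 0)
    i0 <- which.min(vals)
    lo <- span[max(1, i0 - 1)]; hi <- span[min(length(span), i0 + 1)]
    op1 <- stats::optimize(inner, c(lo, hi), tol = 1e-12)
    best_t1 <- if (op1$objective <= min(vals)) op1$minimum else span[i0]
    base <- sys$q0 + best_t1 * N[, 1]
    t2_best <- oracle_argmin1d(function(t2)
      oracle_objective(base + t2 * N[, 2], blk),
      oracle_interval(base, N[, 2]))
    q <- base + t2_best * N[, 2]
  } else {
    stop("oracle supports null-space dimension <= 2, got ", k)
  }
  q <- pmax(q, 0)
  list(fmin = oracle_objective(q, blk), q = q, tri = sys$tri)
}

## mutual information (nats) from a weighted atom table; atoms are first
## aggregated into (a, b) cells, then zero cells dropped
oracle_mi <- function(ka, kb, w) {
  key <- okey(ka, kb)
  wab <- tapply(w, key, sum)
  cell_a <- tapply(ka, key, function(v) v[1])
  cell_b <- tapply(kb, key, function(v) v[1])
  wa <- tapply(w, ka, sum); wb <- tapply(w, kb, sum)
  w2 <- as.numeric(wab); keep <- w2 > 0
  sum(w2[keep] * log(w2[keep] /
        (as.numeric(wa[cell_a])[keep] * as.numeric(wb[cell_b])[keep])))
}

oracle_cmi <- function(kac, kbc, kc, w) {
  key <- okey(kac, kbc)
  wj <- tapply(w, key, sum)
  cell_ac <- tapply(kac, key, function(v) v[1])
  cell_bc <- tapply(kbc, key, function(v) v[1])
  cell_c <- tapply(kc, key, function(v) v[1])
  wac <- tapply(w, kac, sum); wbc <- tapply(w, kbc, sum)
  wc <- tapply(w, kc, sum)
  w2 <- as.numeric(wj); keep <- w2 > 0
  sum(w2[keep] * log(w2[keep] * as.numeric(wc[cell_c])[keep] /
        (as.numeric(wac[cell_ac])[keep] * as.numeric(wbc[cell_bc])[keep])))
}

## the full decomposition (bits) from the brute-force optimum
oracle_pid <- function(pmf) {
  opt <- oracle_min_cp(pmf)
  tri <- opt$tri; q <- opt$q
  mi_p_xyz <- oracle_mi(as.character(pmf$x), okey(pmf$y, pmf$z), pmf$p)
  mi_p_xy <- oracle_mi(as.character(pmf$x), as.character(pmf$y), pmf$p)
  mi_q_xyz <- oracle_mi(tri$x, okey(tri$y, tri$z), q)
  ui_y <- oracle_cmi(okey(tri$x, tri$z), okey(tri$y, tri$z), tri$z, q)
  ui_z <- oracle_cmi(okey(tri$x, tri$y), okey(tri$z, tri$y), tri$y, q)
  list(si = (mi_p_xy - ui_y) / log(2),
       ui_y = ui_y / log(2), ui_z = ui_z / log(2),
       ci = (mi_p_xyz - mi_q_xyz) / log(2),
       fmin = opt$fmin)
}
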