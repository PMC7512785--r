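## ---- support restriction -------------------------------------------------

key_join <- function(...) paste(..., sep = "\r")

#' Support index of the marginal polytope
#'
#' Enumerates the triplets over which the optimization variables live: all
#' `(x, y, z)` with both pair marginals positive, `p[x,y,*] > 0` and
#' `p[x,*,z] > 0`.  Every other coordinate of a feasible `q` is identically
#' zero, so restricting the program to this support is exact; it is also what
#' keeps large instances (notably the Copy gate, whose unrestricted size
#' scales as `|Y|^2 |Z|^2`) tractable.  Ordering is lexicographic on the
#' stringified symbols, so the index is deterministic.
#'
#' @param p a [joint_pmf()].
#' @return an object of class `support_index`: a list with
#'   * `triplets`: `data.frame(x, y, z)`, one row per supported triplet;
#'   * `xy_row`, `xz_row`: integer row index of each triplet's `(x,y)` and
#'     `(x,z)` marginal equation;
#'   * `yz_block`: integer id of each triplet's `(y,z)` cell (the coupling
#'     aggregation group);
#'   * `xy_keys`, `xz_keys`: the marginal-row keys, and `pxy`, `pxz`, `px`
#'     the corresponding positive marginals of `p`.
#' @export
build_support <- function(p) {
  stopifnot(inherits(p, "joint_pmf"))
  pxy <- marginal_vec(p, c("x", "y"))
  pxz <- marginal_vec(p, c("x", "z"))
  px  <- marginal_vec(p, "x")
  xs <- sort(unique(p$x)); ys <- sort(unique(p$y)); zs <- sort(unique(p$z))
  grid <- expand.grid(x = xs, y = ys, z = zs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  kxy <- key_join(grid$x, grid$y)
  kxz <- key_join(grid$x, grid$z)
  keep <- kxy %in% names(pxy) & kxz %in% names(pxz)
  tri <- grid[keep, , drop = FALSE]
  ord <- order(tri$x, tri$y, tri$z)
  tri <- tri[ord, , drop = FALSE]
  rownames(tri) <- NULL
  kxy <- key_join(tri$x, tri$y); kxz <- key_join(tri$x, tri$z)
  kyz <- key_join(tri$y, tri$z)
  fxy <- factor(kxy); fxz <- factor(kxz); fyz <- factor(kyz)
  structure(list(
    triplets = tri,
    xy_row = as.integer(fxy), xz_row = as.integer(fxz),
    yz_block = as.integer(fyz),
    xy_keys = levels(fxy), xz_keys = levels(fxz), yz_keys = levels(fyz),
    pxy = as.numeric(pxy[levels(fxy)]), pxz = as.numeric(pxz[levels(fxz)]),
    px = px), class = "support_index")
}

#' @export
print.support_index <- function(x, ...) {
  cat(sprintf("support index: %d triplets, %d (x,y) rows, %d (x,z) rows, %d (y,z) cells\n",
              nrow(x$triplets), length(x$xy_keys), length(x$xz_keys),
              length(x$yz_keys)))
  invisible(x)
}

## ---- exponential cone membership ----------------------------------------

#' Exponential cone membership margin
#'
#' For points `(r, t, q)` returns the margin `t - q * exp(r / q)` when
#' `q > 0`; a point is in the closed exponential cone iff the margin is
#' nonnegative (or `q = 0`, `r <= 0`, `t >= 0`), and strictly interior iff
#' the margin is positive with `q > 0`.
#'
#' @param r,t,q numeric vectors of equal length.
#' @return numeric vector of margins (`-Inf` where `q <= 0` and the
#'   boundary-ray condition fails, `+Inf` margin is never produced).
#' @export
exp_cone_margin <- function(r, t, q) {
  m <- ifelse(q > 0, t - q * exp(r / q),
              ifelse(r <= 0 & t >= 0, pmin(t, -r), -Inf))
  as.numeric(m)
}

## ---- bivariate program ---------------------------------------------------

#' Assemble the bivariate exponential cone program
#'
#' Builds the conic problem data of the shared/unique/synergy optimization:
#' minimize `-sum r[x,y,z]` subject to the marginal equations
#' `q[x,y,*] = p[x,y,*]`, `q[x,*,z] = p[x,*,z]`, the coupling equations
#' `q[*,y,z] - t[x,y,z] = 0`, and one generalized inequality
#' `(-r, -t, -q) <=_Kexp 0` per supported triplet.  Variables are laid out
#' triplet-major as `(r, t, q)` blocks; rows are the `(x,y)` marginal
#' equations, then the `(x,z)` ones, then one coupling row per triplet.
#'
#' @param p a [joint_pmf()].
#' @param support the [build_support()] index of `p` (rebuilt when omitted).
#' @return an object of class `cone_problem`: a list with the conic data
#'   `c`, `A`, `b`, `G`, `h` (sparse `Matrix` classes), the cone layout
#'   (`n_exp` cones, `exp_vars` an `n x 3` matrix of each cone's
#'   `(r, t, q)` column indices, `n_nonneg` extra nonnegative scalar cones),
#'   `var_layout`, a `rows` description, and the reduced solver form used by
#'   [solve_cone_program()].
#' @export
build_exp_program <- function(p, support = build_support(p)) {
  tri <- support$triplets
  n <- nrow(tri)
  if (n == 0) stop("empty support", call. = FALSE)
  m1 <- length(support$xy_keys); m2 <- length(support$xz_keys)
  r_col <- 3L * seq_len(n) - 2L
  t_col <- r_col + 1L
  q_col <- r_col + 2L
  nv <- 3L * n
  ## equality block: marginal rows on q, coupling rows q[*,y,z] - t = 0
  blk <- support$yz_block
  ## for each triplet i (row m1+m2+i) the q-columns of its (y,z) cell:
  cell_members <- split(seq_len(n), blk)
  coup_cols <- unlist(cell_members[blk], use.names = FALSE)
  coup_rows <- rep(seq_len(n), times = lengths(cell_members)[blk])
  A <- Matrix::sparseMatrix(
    i = c(support$xy_row, m1 + support$xz_row,
          m1 + m2 + coup_rows, m1 + m2 + seq_len(n)),
    j = c(q_col, q_col, q_col[coup_cols], t_col),
    x = c(rep(1, 2L * n), rep(1, length(coup_cols)), rep(-1, n)),
    dims = c(m1 + m2 + n, nv))
  b <- c(support$pxy, support$pxz, rep(0, n))
  cvec <- numeric(nv); cvec[r_col] <- -1
  G <- -Matrix::Diagonal(nv)
  h <- numeric(nv)
  rows <- data.frame(
    type = rep(c("marg_xy", "marg_xz", "coupling"), c(m1, m2, n)),
    key = c(support$xy_keys, support$xz_keys,
            key_join(tri$x, tri$y, tri$z)),
    stringsAsFactors = FALSE)
  structure(list(
    c = cvec, A = A, b = b, G = G, h = h,
    n_exp = n, exp_vars = cbind(r = r_col, t = t_col, q = q_col),
    n_nonneg = 0L, nonneg_vars = integer(0),
    var_layout = data.frame(tri, r = r_col, t = t_col, q = q_col),
    rows = rows,
    family = "bivariate", pmf = p, support = support,
    reduced = reduce_bivariate(p, support)), class = "cone_problem")
}

## the equivalent smooth form the interior-point backend operates on:
## variables q over the support, entropy blocks = (y,z) cells,
## equality rows = marginal equations only (coupling rows eliminate t)
reduce_bivariate <- function(p, support) {
  tri <- support$triplets
  n <- nrow(tri)
  m1 <- length(support$xy_keys); m2 <- length(support$xz_keys)
  B <- Matrix::sparseMatrix(
    i = c(support$xy_row, m1 + support$xz_row),
    j = c(seq_len(n), seq_len(n)), x = 1, dims = c(m1 + m2, n))
  kxy <- key_join(tri$x, tri$y); kxz <- key_join(tri$x, tri$z)
  v0 <- as.numeric(support$pxy[match(kxy, support$xy_keys)] *
                   support$pxz[match(kxz, support$xz_keys)] /
                   support$px[tri$x])
  list(nvar = n, B = B, b = c(support$pxy, support$pxz),
       ent = rep(TRUE, n), blk = support$yz_block, v0 = v0,
       lambda_split = list(xy = seq_len(m1), xz = m1 + seq_len(m2)),
       row_keys = c(support$xy_keys, support$xz_keys))
}

#' Strictly feasible interior point of the bivariate program
#'
#' Constructs the analytic interior point that certifies strong duality:
#' `q~ = p[x,y,*] p[x,*,z] / p[x,*,*]` (the conditional-independence
#' coupling), `t~ = q~[*,y,z]`, and `r~ = q~ ln(t~ / q~) - 100`.  The offset
#' makes the cone inequality strict, `q~ exp(r~/q~) = t~ exp(-100/q~) < t~`,
#' while `q~` reproduces the pair marginals of `p` exactly on the support.
#'
#' @inheritParams build_exp_program
#' @return a `data.frame` with the triplet columns and `r`, `t`, `q`:
#'   one strictly interior exponential-cone point per supported triplet.
#' @export
interior_point <- function(p, support = build_support(p)) {
  red <- reduce_bivariate(p, support)
  if (any(!is.finite(red$v0)) || any(red$v0 <= 0))
    stop("zero pair marginal on the support", call. = FALSE)
  q <- red$v0
  tt <- as.numeric(tapply(q, support$yz_block, sum))[support$yz_block]
  r <- q * log(tt / q) - 100
  data.frame(support$triplets, r = r, t = tt, q = q)
}

## ---- trivariate programs -------------------------------------------------

#' Support index for a four-coordinate pmf
#'
#' The quadruples `(s, x, y, z)` whose three (target, source) pair marginals
#' `p[s,x,*,*]`, `p[s,*,y,*]`, `p[s,*,*,z]` are all positive; every other
#' variable vanishes at any feasible point of the trivariate programs.
#'
#' @param p4 a [joint_pmf4()].
#' @return a list analogous to [build_support()], with marginal families
#'   `sx`, `sy`, `sz` and aggregation cells `xyz` (sources) and `syz`.
#' @export
build_support4 <- function(p4) {
  stopifnot(inherits(p4, "joint_pmf4"))
  psx <- marginal_vec(p4, c("s", "x"))
  psy <- marginal_vec(p4, c("s", "y"))
  psz <- marginal_vec(p4, c("s", "z"))
  ps  <- marginal_vec(p4, "s")
  ss <- sort(unique(p4$s)); xs <- sort(unique(p4$x))
  ys <- sort(unique(p4$y)); zs <- sort(unique(p4$z))
  grid <- expand.grid(s = ss, x = xs, y = ys, z = zs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- key_join(grid$s, grid$x) %in% names(psx) &
          key_join(grid$s, grid$y) %in% names(psy) &
          key_join(grid$s, grid$z) %in% names(psz)
  quad <- grid[keep, , drop = FALSE]
  quad <- quad[order(quad$s, quad$x, quad$y, quad$z), , drop = FALSE]
  rownames(quad) <- NULL
  fsx <- factor(key_join(quad$s, quad$x))
  fsy <- factor(key_join(quad$s, quad$y))
  fsz <- factor(key_join(quad$s, quad$z))
  fxyz <- factor(key_join(quad$x, quad$y, quad$z))
  fsyz <- factor(key_join(quad$s, quad$y, quad$z))
  structure(list(
    quadruples = quad,
    sx_row = as.integer(fsx), sy_row = as.integer(fsy),
    sz_row = as.integer(fsz),
    xyz_block = as.integer(fxyz), syz_cell = as.integer(fsyz),
    sx_keys = levels(fsx), sy_keys = levels(fsy), sz_keys = levels(fsz),
    xyz_keys = levels(fxyz), syz_keys = levels(fsyz),
    psx = as.numeric(psx[levels(fsx)]), psy = as.numeric(psy[levels(fsy)]),
    psz = as.numeric(psz[levels(fsz)]), ps = ps), class = "support_index4")
}

tri_marginal_matrix <- function(sup) {
  n <- length(sup$sx_row)
  m1 <- length(sup$sx_keys); m2 <- length(sup$sy_keys)
  m3 <- length(sup$sz_keys)
  B <- Matrix::sparseMatrix(
    i = c(sup$sx_row, m1 + sup$sy_row, m1 + m2 + sup$sz_row),
    j = rep(seq_len(n), 3L), x = 1, dims = c(m1 + m2 + m3, n))
  list(B = B, b = c(sup$psx, sup$psy, sup$psz),
       lambda_split = list(sx = seq_len(m1), sy = m1 + seq_len(m2),
                           sz = m1 + m2 + seq_len(m3)),
       row_keys = c(sup$sx_keys, sup$sy_keys, sup$sz_keys))
}

## product-form strictly feasible start over the quadruple support
tri_interior_q <- function(sup) {
  quad <- sup$quadruples
  as.numeric(sup$psx[sup$sx_row] * sup$psy[sup$sy_row] *
             sup$psz[sup$sz_row] / sup$ps[quad$s]^2)
}

#' Assemble the trivariate synergy cone program
#'
#' The program whose optimum is `min MI(S'; X', Y', Z')` over all
#' distributions sharing the three (target, source) pair marginals of `p4`:
#' minimize `-sum r[s,x,y,z]` subject to `q[s,x,*,*] = p[s,x,*,*]`,
#' `q[s,*,y,*] = p[s,*,y,*]`, `q[s,*,*,z] = p[s,*,*,z]`, coupling
#' `q[*,x,y,z] - t[s,x,y,z] = 0` and one exponential cone per supported
#' quadruple.  Structurally it is [build_exp_program()] with the target in
#' the role of X and the source triple in the role of (Y, Z).
#'
#' @param p4 a [joint_pmf4()].
#' @param support the [build_support4()] index of `p4`.
#' @return a `cone_problem`; the optimum value of the reduced objective is
#'   `-H(S | X, Y, Z)` at the optimal `q`.
#' @export
build_tri_synergy_program <- function(p4, support = build_support4(p4)) {
  quad <- support$quadruples
  n <- nrow(quad)
  if (n == 0) stop("empty support", call. = FALSE)
  mm <- tri_marginal_matrix(support)
  m <- nrow(mm$B)
  r_col <- 3L * seq_len(n) - 2L; t_col <- r_col + 1L; q_col <- r_col + 2L
  nv <- 3L * n
  blk <- support$xyz_block
  cell_members <- split(seq_len(n), blk)
  coup_cols <- unlist(cell_members[blk], use.names = FALSE)
  coup_rows <- rep(seq_len(n), times = lengths(cell_members)[blk])
  Bq <- mm$B
  Bq_cols <- rep(seq_len(ncol(Bq)), diff(Bq@p))
  A <- Matrix::sparseMatrix(
    i = c(Bq@i + 1L, m + coup_rows, m + seq_len(n)),
    j = c(q_col[Bq_cols], q_col[coup_cols], t_col),
    x = c(Bq@x, rep(1, length(coup_cols)), rep(-1, n)),
    dims = c(m + n, nv))
  cvec <- numeric(nv); cvec[r_col] <- -1
  rows <- data.frame(
    type = c(rep(c("marg_sx", "marg_sy", "marg_sz"),
                 c(length(support$sx_keys), length(support$sy_keys),
                   length(support$sz_keys))), rep("coupling", n)),
    key = c(mm$row_keys, key_join(quad$s, quad$x, quad$y, quad$z)),
    stringsAsFactors = FALSE)
  structure(list(
    c = cvec, A = A, b = c(mm$b, rep(0, n)),
    G = -Matrix::Diagonal(nv), h = numeric(nv),
    n_exp = n, exp_vars = cbind(r = r_col, t = t_col, q = q_col),
    n_nonneg = 0L, nonneg_vars = integer(0),
    var_layout = data.frame(quad, r = r_col, t = t_col, q = q_col),
    rows = rows, family = "tri_synergy", pmf = p4, support = support,
    reduced = list(nvar = n, B = mm$B, b = mm$b, ent = rep(TRUE, n),
                   blk = blk, v0 = tri_interior_q(support),
                   lambda_split = mm$lambda_split,
                   row_keys = mm$row_keys)), class = "cone_problem")
}

#' Assemble the trivariate conditional-marginal cone program
#'
#' The program whose optimum is `min MI(S'; Y', Z')` over the same
#' three-pair-marginal polytope: the objective
#' `sum q[s,*,y,z] ln( q[s,*,y,z] / q[*,*,y,z] )` depends on `q` only
#' through the aggregates over the X coordinate, so the program keeps the
#' full `q` over the quadruple support (as nonnegative scalar variables),
#' introduces aggregate variables `u[s,y,z] = q[s,*,y,z]` with coupling
#' `t[s,y,z] = u[*,y,z]`, and places one exponential cone on each
#' `(-r[s,y,z], -t[s,y,z], -u[s,y,z])`.
#'
#' @inheritParams build_tri_synergy_program
#' @return a `cone_problem` with `n_exp` cones (one per `(s, y, z)` cell)
#'   and `n_nonneg` scalar nonnegativity cones (one per quadruple).
#' @export
build_tri_condmarg_program <- function(p4, support = build_support4(p4)) {
  quad <- support$quadruples
  n <- nrow(quad)
  if (n == 0) stop("empty support", call. = FALSE)
  mm <- tri_marginal_matrix(support)
  m <- nrow(mm$B)
  ncell <- length(support$syz_keys)
  cell <- support$syz_cell
  ## (y,z) block of each (s,y,z) cell: two cells share a block iff their
  ## (y,z) parts agree
  cell_first <- match(seq_len(ncell), cell)
  yz_of_cell <- as.integer(factor(key_join(quad$y, quad$z)[cell_first]))
  ## variable layout: q (quadruples), then (r, t, u) per (s,y,z) cell
  q_col <- seq_len(n)
  r_col <- n + 3L * seq_len(ncell) - 2L
  t_col <- r_col + 1L
  u_col <- r_col + 2L
  nv <- n + 3L * ncell
  ## equality rows: marginal families on q; aggregation u - q[s,*,y,z] = 0;
  ## coupling t[s,y,z] - u[*,y,z] = 0
  yz_members <- split(seq_len(ncell), yz_of_cell)
  coup_cols <- unlist(yz_members[yz_of_cell], use.names = FALSE)
  coup_rows <- rep(seq_len(ncell), times = lengths(yz_members)[yz_of_cell])
  Bq_cols <- rep(seq_len(ncol(mm$B)), diff(mm$B@p))
  A <- Matrix::sparseMatrix(
    i = c(mm$B@i + 1L,
          m + cell, m + seq_len(ncell),
          m + ncell + coup_rows, m + ncell + seq_len(ncell)),
    j = c(q_col[Bq_cols],
          q_col, u_col,
          u_col[coup_cols], t_col),
    x = c(mm$B@x, rep(-1, n), rep(1, ncell),
          rep(1, length(coup_cols)), rep(-1, ncell)),
    dims = c(m + 2L * ncell, nv))
  b <- c(mm$b, rep(0, 2L * ncell))
  cvec <- numeric(nv); cvec[r_col] <- -1
  cells <- quad[cell_first, c("s", "y", "z")]
  rownames(cells) <- NULL
  rows <- data.frame(
    type = c(rep(c("marg_sx", "marg_sy", "marg_sz"),
                 c(length(support$sx_keys), length(support$sy_keys),
                   length(support$sz_keys))),
             rep("aggregation", ncell), rep("coupling", ncell)),
    key = c(mm$row_keys, support$syz_keys, support$syz_keys),
    stringsAsFactors = FALSE)
  q0 <- tri_interior_q(support)
  u0 <- as.numeric(tapply(q0, cell, sum))
  structure(list(
    c = cvec, A = A, b = b, G = -Matrix::Diagonal(nv), h = numeric(nv),
    n_exp = ncell, exp_vars = cbind(r = r_col, t = t_col, q = u_col),
    n_nonneg = n, nonneg_vars = q_col,
    var_layout = list(q = data.frame(quad, q = q_col),
                      cells = data.frame(cells, r = r_col, t = t_col,
                                         u = u_col)),
    rows = rows, family = "tri_condmarg", pmf = p4, support = support,
    reduced = list(
      nvar = n + ncell,
      B = rbind(
        cbind(mm$B, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0),
                                         dims = c(m, ncell))),
        cbind(Matrix::sparseMatrix(i = cell, j = seq_len(n), x = -1,
                                   dims = c(ncell, n)),
              Matrix::Diagonal(ncell))),
      b = c(mm$b, rep(0, ncell)),
      ent = c(rep(FALSE, n), rep(TRUE, ncell)),
      blk = c(rep(NA_integer_, n), yz_of_cell),
      v0 = c(q0, u0),
      lambda_split = c(mm$lambda_split,
                       list(aggregation = m + seq_len(ncell))),
      row_keys = c(mm$row_keys, support$syz_keys))),
    class = "cone_problem")
}

#' @export
print.cone_problem <- function(x, ...) {
  cat(sprintf(
    "cone problem (%s): %d variables, %d equality rows, %d exponential cones%s\n",
    x$family, length(x$c), nrow(x$A), x$n_exp,
    if (x$n_nonneg > 0) sprintf(", %d nonnegative vars", x$n_nonneg) else ""))
  invisible(x)
}
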