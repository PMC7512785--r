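#' Partial information decomposition from an optimal solution
#'
#' Turns a solved bivariate cone program into the four decomposition
#' quantities.  With `q+` the positive part of the optimal `q` (nonpositive
#' entries dropped, no renormalization applied):
#' \itemize{
#'   \item `CI = MI_p(X;Y,Z) - MI_q+(X;Y,Z)` (synergy),
#'   \item `UI_Y = MI_q+(X;Y|Z)`, `UI_Z = MI_q+(X;Z|Y)` (unique),
#'   \item `SI = MI_p(X;Y) - UI_Y` (shared),
#' }
#' all converted from nats to bits.  The three numerical-quality metrics
#' accompany the values: the primal feasibility violation, the dual
#' feasibility violation and the duality-gap violation (see
#' [num_err_primal()], [num_err_dual()], [num_err_gap()]).  Values are
#' reported as computed — numerical noise can make them slightly negative;
#' quality is judged from `num_err`, not by clipping.
#'
#' @param p the input [joint_pmf()].
#' @param sol a [solve_cone_program()] solution of the program built from
#'   `p`; its status must not be `"failed"`.
#' @return an object of class `pid_result`: a list with `si`, `ui_y`,
#'   `ui_z`, `ci` (bits), `num_err = c(primal, dual, gap)` and `solver`.
#' @export
decompose <- function(p, sol) {
  stopifnot(inherits(p, "joint_pmf"), inherits(sol, "pid_solution"))
  if (sol$status == "failed")
    solver_failure("cannot decompose: solver status is 'failed'")
  prof <- info_profile(p)
  q <- sol$primal
  keep <- q$q > 0
  w <- q$q[keep]
  kx <- q$x[keep]; ky <- q$y[keep]; kz <- q$z[keep]
  mi_q_xyz <- mi_pair_nats(kx, key_join(ky, kz), w)
  ui_y <- cmi_nats(key_join(kx, kz), key_join(ky, kz), kz, w)
  ui_z <- cmi_nats(key_join(kx, ky), key_join(kz, ky), ky, w)
  ci <- prof$mi_x_yz - mi_q_xyz
  si <- prof$mi_x_y - ui_y
  num_err <- c(primal = num_err_primal(p, sol),
               dual = num_err_dual(sol),
               gap = num_err_gap(p, sol))
  structure(list(si = si / log(2), ui_y = ui_y / log(2),
                 ui_z = ui_z / log(2), ci = ci / log(2),
                 num_err = num_err, solver = sol$solver,
                 status = sol$status), class = "pid_result")
}

#' @export
print.pid_result <- function(x, ...) {
  cat("partial information decomposition (bits):\n")
  cat(sprintf("  SI  %.9f\n  UIY %.9f\n  UIZ %.9f\n  CI  %.9f\n",
              x$si, x$ui_y, x$ui_z, x$ci))
  cat(sprintf("  Num_err: primal %.3e, dual %.3e, gap %.3e  [%s, %s]\n",
              x$num_err[1], x$num_err[2], x$num_err[3], x$solver, x$status))
  invisible(x)
}

#' Primal feasibility violation
#'
#' `max( |q'[x,y,*] - p[x,y,*]|, |q'[x,*,z] - p[x,*,z]|, -q[x,y,z] )` where
#' `q'` is the returned `q` with nonpositive entries zeroed; the marginal
#' deviations are measured with `q'`, the nonnegativity term with the raw
#' `q`.  Always nonnegative.
#'
#' @inheritParams decompose
#' @return a single nonnegative number.
#' @export
num_err_primal <- function(p, sol) {
  q <- sol$primal
  qpos <- pmax(q$q, 0)
  pxy <- marginal_vec(p, c("x", "y"))
  pxz <- marginal_vec(p, c("x", "z"))
  qxy <- tapply(qpos, key_join(q$x, q$y), sum)
  qxz <- tapply(qpos, key_join(q$x, q$z), sum)
  ## every (x,y) key of p appears among the support triplets, so the
  ## deviations below cover all marginal equations
  dev_xy <- abs(as.numeric(qxy[names(pxy)]) - as.numeric(pxy))
  dev_xz <- abs(as.numeric(qxz[names(pxz)]) - as.numeric(pxz))
  max(c(dev_xy, dev_xz, -q$q))
}

#' Dual feasibility violation
#'
#' The minimum of the per-cone dual residuals and zero:
#' `min_x,y,z( lambda[x,y] + lambda[x,z] + mu[*,y,z] + 1 + ln(-mu[x,y,z]), 0 )`.
#' Always nonpositive; zero exactly when the returned dual point is
#' feasible.
#'
#' @param sol a [solve_cone_program()] solution.
#' @return a single nonpositive number.
#' @export
num_err_dual <- function(sol) {
  min(c(sol$dual_resid, 0))
}

#' Duality-gap violation
#'
#' `max( -H_q(X|Y,Z) + lambda' b, 0 )` where `-H_q(X|Y,Z)` is the primal
#' objective evaluated from the returned `q` (its positive part) and
#' `lambda' b = sum lambda[x,y] p[x,y,*] + sum lambda[x,z] p[x,*,z]`.  Weak
#' duality makes the expression nonnegative for a feasible pair; its
#' magnitude bounds the suboptimality of the returned solution.
#'
#' @inheritParams decompose
#' @return a single nonnegative number.
#' @export
num_err_gap <- function(p, sol) {
  q <- sol$primal
  keep <- q$q > 0
  w <- q$q[keep]
  kyz <- key_join(q$y, q$z)[keep]
  wyz <- tapply(w, kyz, sum)
  minus_h <- sum(w * log(w / as.numeric(wyz[kyz])))
  pxy <- marginal_vec(p, c("x", "y"))
  pxz <- marginal_vec(p, c("x", "z"))
  lb <- sum(sol$lambda$xy[gsub("\r", ",", names(pxy), fixed = TRUE)] *
              as.numeric(pxy)) +
        sum(sol$lambda$xz[gsub("\r", ",", names(pxz), fixed = TRUE)] *
              as.numeric(pxz))
  max(minus_h + lb, 0)
}

#' Assemble the flat result record
#'
#' Packs a [decompose()] result into the six-key record the estimator
#' returns: `SI`, `UIY`, `UIZ`, `CI` (bits), `Num_err` (the ordered triple
#' primal/dual/gap violation) and `Solver`.
#'
#' @param result a `pid_result`.
#' @return a named list with exactly those six keys.
#' @export
assemble_returndata <- function(result) {
  stopifnot(inherits(result, "pid_result"))
  list(SI = result$si, UIY = result$ui_y, UIZ = result$ui_z,
       CI = result$ci, Num_err = unname(result$num_err),
       Solver = result$solver)
}

#' Compute the bivariate partial information decomposition
#'
#' The main entry point: builds the exponential cone program of the input
#' distribution, solves it, and returns the shared / unique / synergistic
#' decomposition with numerical-quality certificates.
#'
#' @param p a [joint_pmf()], or anything [joint_pmf()] accepts.
#' @param params a [solver_params()]; individual parameters can also be
#'   passed through `...`.
#' @param ... parameters forwarded to [solver_params()] when `params` is
#'   not supplied.
#' @return the record of [assemble_returndata()], with the full
#'   [decompose()] result attached as attribute `"result"` and the solver
#'   solution as attribute `"solution"`.
#' @examples
#' andgate <- gate("and")
#' pid(andgate)
#' @export
pid <- function(p, params = solver_params(...), ...) {
  if (!inherits(p, "joint_pmf")) p <- joint_pmf(p)
  solver_message(params, 1, "preparing the exponential cone program")
  problem <- build_exp_program(p)
  sol <- solve_cone_program(problem, params)
  res <- decompose(p, sol)
  out <- assemble_returndata(res)
  attr(out, "result") <- res
  attr(out, "solution") <- sol
  class(out) <- "pid_returndata"
  out
}

#' @export
print.pid_returndata <- function(x, ...) {
  cat(sprintf(
    "SI  = %.9f bits\nUIY = %.9f bits\nUIZ = %.9f bits\nCI  = %.9f bits\n",
    x$SI, x$UIY, x$UIZ, x$CI))
  cat(sprintf("Num_err = (%.3e, %.3e, %.3e)\nSolver  = %s\n",
              x$Num_err[1], x$Num_err[2], x$Num_err[3], x$Solver))
  invisible(x)
}
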