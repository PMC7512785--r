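#' Solver parameters
#'
#' Tolerances and controls of the exponential-cone interior-point backend.
#' The defaults are the recommended values for this problem family:
#' `feastol` bounds the primal and dual feasibility violations of a
#' solution reported as optimal, `abstol`/`reltol` bound its absolute and
#' relative duality gap, and the `*_inacc` counterparts are the relaxed
#' thresholds at which a solution is still surfaced, flagged `inaccurate`,
#' rather than discarded.
#'
#' @param feastol primal/dual feasibility tolerance (default `1e-7`).
#' @param abstol absolute tolerance on the duality gap (default `1e-6`).
#' @param reltol relative tolerance on the duality gap (default `1e-6`).
#' @param feastol_inacc,abstol_inacc,reltol_inacc relaxed tolerances
#'   (defaults `1e-3`, `1e-4`, `1e-4`).
#' @param max_iter maximum number of Newton iterations (default 100).
#' @param output_level printing mode, an integer in 0:2 — 0: result only;
#'   1: also flag the model-build and solver-call stages; 2: also relay
#'   per-stage solver output.
#' @param backend_name identifier of the backend implementation.
#' @param ... advanced engine controls overriding the internal defaults
#'   (`tau_start`, `tau_end`, `tau_shrink`, `center_tol_path`,
#'   `center_tol_cert`, `cert_tau`, `max_inner`, `kkt_reg`,
#'   `dense_cutoff`).
#' @return an object of class `solver_params`.
#' @export
solver_params <- function(feastol = 1e-7, abstol = 1e-6, reltol = 1e-6,
                          feastol_inacc = 1e-3, abstol_inacc = 1e-4,
                          reltol_inacc = 1e-4, max_iter = 100L,
                          output_level = 0L,
                          backend_name = "pidcone-ipm", ...) {
  tol <- c(feastol = feastol, abstol = abstol, reltol = reltol,
           feastol_inacc = feastol_inacc, abstol_inacc = abstol_inacc,
           reltol_inacc = reltol_inacc)
  if (any(tol <= 0)) stop("all tolerances must be positive", call. = FALSE)
  if (max_iter < 1) stop("`max_iter` must be at least 1", call. = FALSE)
  if (!output_level %in% 0:2)
    stop("`output_level` must be 0, 1 or 2", call. = FALSE)
  extra <- list(...)
  eng <- ipm_defaults()
  unknown <- setdiff(names(extra), names(eng))
  if (length(unknown))
    stop("unknown solver parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  eng[names(extra)] <- extra
  structure(c(list(feastol = feastol, abstol = abstol, reltol = reltol,
                   feastol_inacc = feastol_inacc,
                   abstol_inacc = abstol_inacc,
                   reltol_inacc = reltol_inacc,
                   max_iter = as.integer(max_iter),
                   output_level = as.integer(output_level),
                   backend_name = backend_name), eng),
            class = "solver_params")
}

solver_message <- function(params, level, ...) {
  if (!is.null(params$output_level) && params$output_level >= level)
    message(...)
}

#' Condition raised when the backend returns no usable solution
#'
#' @param message description of the failure.
#' @keywords internal
solver_failure <- function(message) {
  stop(structure(class = c("pidcone_solver_failure", "error", "condition"),
                 list(message = message, call = NULL)))
}

#' Solve an exponential cone program of the decomposition family
#'
#' Runs the interior-point backend on a [build_exp_program()],
#' [build_tri_synergy_program()] or [build_tri_condmarg_program()] problem
#' and maps the solver's vectors back to the problem's own naming: the
#' primal point `w = (r, t, q)` per cone, the equality multipliers `eta`
#' split into marginal multipliers `lambda` (one per marginal row) and
#' coupling multipliers `mu` (one per cone), and the dual-cone multipliers
#' `theta = nu = (nu1, nu2, nu3)` per cone.  Sign conventions are fixed so
#' that the reduced dual constraint
#' `lambda[x,y] + lambda[x,z] + mu[*,y,z] + 1 + ln(-mu[x,y,z]) >= 0`
#' holds at optimality (so `mu < 0` and `nu2 = -mu`).
#'
#' The status is `"optimal"` when the three certificates meet the strict
#' tolerances of [solver_params()], `"inaccurate"` when only the relaxed
#' ones are met, and `"failed"` otherwise; in all three cases the vectors
#' are returned.  An error of class `pidcone_solver_failure` is raised only
#' when the backend cannot produce any iterate.
#'
#' @param problem a `cone_problem`.
#' @param params a [solver_params()].
#' @return an object of class `pid_solution`: a list with `status`,
#'   per-cone `primal` data frame (`r`, `t`, `q` and the cone margin),
#'   `lambda` (named list per marginal family), `mu`, `nu` (matrix),
#'   `objective` (primal, nats), `dual_objective`, `iterations`,
#'   certificate fields `pviol`, `dviol`, `gapviol`, and the full primal
#'   vector `w` in problem column order.
#' @export
solve_cone_program <- function(problem, params = solver_params()) {
  stopifnot(inherits(problem, "cone_problem"))
  red <- problem$reduced
  solver_message(params, 1, "calling the cone solver backend")
  res <- tryCatch(ipm_entropy(red, params), error = function(e) e)
  if (inherits(res, "error") || any(!is.finite(res$v)))
    solver_failure(paste("backend returned no solution:",
                         if (inherits(res, "error")) conditionMessage(res)
                         else "non-finite iterate"))
  solver_message(params, 2, sprintf(
    "backend: %d Newton iterations, final barrier %.2e, note '%s'",
    res$iterations, res$tau, res$note))
  sol <- extract_solution(problem, res, params)
  class(sol) <- "pid_solution"
  sol
}

## map engine output back to the cone program's naming and classify status
extract_solution <- function(problem, res, params) {
  red <- problem$reduced
  fam <- problem$family
  lam <- res$lambda
  lambda <- lapply(red$lambda_split, function(ix) {
    out <- lam[ix]
    names(out) <- gsub("\r", ",", red$row_keys[ix], fixed = TRUE)
    out
  })
  if (fam %in% c("bivariate", "tri_synergy")) {
    q <- res$v
    blk <- red$blk
    Vb <- res$Vb
    tt <- Vb[blk]
    r <- q * log(tt / q)
    mu <- -q / tt
    w <- numeric(length(problem$c))
    w[problem$exp_vars[, "r"]] <- r
    w[problem$exp_vars[, "t"]] <- tt
    w[problem$exp_vars[, "q"]] <- q
    cone_df <- data.frame(problem$var_layout[pmf_coords(problem$pmf)],
                          r = r, t = tt, q = q)
    dual_obj <- -sum(lam * red$b)
    fval <- res$f
    mu_star <- as.numeric(tapply(mu, blk, sum))[blk]
    lam_sum <- as.numeric(Matrix::t(red$B) %*% lam)
    dresid <- lam_sum + mu_star + 1 + log(-mu)
  } else { # tri_condmarg: cones live on the (s,y,z) aggregates
    nq <- problem$n_nonneg
    ncell <- problem$n_exp
    q <- res$v[seq_len(nq)]
    u <- res$v[nq + seq_len(ncell)]
    blk <- red$blk[nq + seq_len(ncell)]
    Vb <- res$Vb
    tt <- Vb[blk]
    r <- u * log(tt / u)
    mu <- -u / tt
    w <- numeric(length(problem$c))
    w[problem$var_layout$q$q] <- q
    w[problem$exp_vars[, "r"]] <- r
    w[problem$exp_vars[, "t"]] <- tt
    w[problem$exp_vars[, "q"]] <- u
    cone_df <- data.frame(problem$var_layout$cells[c("s", "y", "z")],
                          r = r, t = tt, q = u)
    ## the aggregation multipliers play the role of the per-cone linear
    ## part in the dual residual of this program
    kappa <- lam[red$lambda_split$aggregation]
    mu_star <- as.numeric(tapply(mu, blk, sum))[blk]
    dresid <- kappa + mu_star + 1 + log(-mu)
    dual_obj <- -sum(lam * red$b)   # aggregation rows have b = 0
    fval <- res$f
  }
  nu <- cbind(nu1 = rep(-1, length(mu)), nu2 = -mu,
              nu3 = if (fam == "tri_condmarg")
                      lam[red$lambda_split$aggregation] + mu_star
                    else lam_sum + mu_star)
  ## certificates
  pviol <- primal_violation(problem, q_pos = pmax(res$v, 0), res = res)
  dviol <- min(c(dresid, 0))
  gap <- max(fval - dual_obj, 0)   # fval + lambda' b
  relgap <- gap / max(abs(fval), 1e-10)
  strict <- pviol <= params$feastol && dviol >= -params$feastol &&
    (gap <= params$abstol || relgap <= params$reltol)
  relaxed <- pviol <= params$feastol_inacc &&
    dviol >= -params$feastol_inacc &&
    (gap <= params$abstol_inacc || relgap <= params$reltol_inacc)
  status <- if (strict) "optimal" else if (relaxed) "inaccurate" else "failed"
  list(status = status, primal = cone_df, w = w,
       lambda = lambda, mu = mu, nu = nu,
       objective = fval, dual_objective = dual_obj,
       dual_resid = dresid,
       pviol = pviol, dviol = dviol, gapviol = gap,
       iterations = res$iterations, note = res$note,
       solver = params$backend_name, family = fam,
       q = if (fam == "tri_condmarg") q else res$v,
       u = if (fam == "tri_condmarg") u else NULL,
       barrier_final = res$tau)
}

## max over marginal-equation violations at the positive part of q and -q
primal_violation <- function(problem, q_pos, res) {
  red <- problem$reduced
  marg <- setdiff(names(red$lambda_split), "aggregation")
  ix <- unlist(red$lambda_split[marg], use.names = FALSE)
  Bq <- as.numeric(red$B[ix, , drop = FALSE] %*% q_pos)
  max(c(abs(Bq - red$b[ix]), -res$v))
}

#' Per-cone dual feasibility residuals
#'
#' Evaluates, for every supported triplet, the reduced dual constraint
#' `lambda[x,y] + lambda[x,z] + mu[*,y,z] + 1 + ln(-mu[x,y,z])`; nonnegative
#' residuals certify dual feasibility.  Where `mu >= 0` the logarithm is
#' undefined and the residual is recorded as `-Inf` (a violation), not an
#' error.
#'
#' @param problem the `cone_problem` that was solved.
#' @param sol the [solve_cone_program()] solution.
#' @return numeric vector of residuals, one per cone, in cone order.
#' @export
dual_feasibility_residuals <- function(problem, sol) {
  stopifnot(inherits(sol, "pid_solution"))
  mu <- sol$mu
  red <- problem$reduced
  if (problem$family == "tri_condmarg") {
    blk <- red$blk[!is.na(red$blk)]
    lam_lin <- unname(sol$lambda$aggregation)
  } else {
    blk <- red$blk
    lam_all <- unlist(sol$lambda, use.names = FALSE)
    lam_lin <- as.numeric(Matrix::t(red$B) %*% lam_all)
  }
  mu_star <- as.numeric(tapply(mu, blk, sum))[blk]
  out <- rep(-Inf, length(mu))
  okmu <- mu < 0
  out[okmu] <- lam_lin[okmu] + mu_star[okmu] + 1 + log(-mu[okmu])
  out
}

#' @export
print.pid_solution <- function(x, ...) {
  cat(sprintf(
    "cone program solution (%s): status %s, %d iterations\n",
    x$family, x$status, x$iterations))
  cat(sprintf("  primal objective %.9f nats, dual %.9f nats\n",
              x$objective, -x$dual_objective))
  cat(sprintf("  certificates: pviol %.3e, dviol %.3e, gap %.3e\n",
              x$pviol, x$dviol, x$gapviol))
  invisible(x)
}
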