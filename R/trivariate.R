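#' Trivariate synergistic information
#'
#' Synergy of three sources about a target:
#' `CI(S; X, Y, Z) = MI_p(S; X, Y, Z) - min MI(S'; X', Y', Z')`, the
#' minimum over all distributions with the same `(s,x)`, `(s,y)` and
#' `(s,z)` pair marginals, computed by solving
#' [build_tri_synergy_program()].
#'
#' @param p4 a [joint_pmf4()].
#' @param params a [solver_params()].
#' @return a list with `ci` (nats), `ci_bits`, the minimized mutual
#'   information `min_mi` (nats), the solver `status` and the
#'   certificate triple `num_err`.
#' @export
tri_synergy <- function(p4, params = solver_params()) {
  stopifnot(inherits(p4, "joint_pmf4"))
  problem <- build_tri_synergy_program(p4)
  sol <- solve_cone_program(problem, params)
  if (sol$status == "failed")
    solver_failure("trivariate synergy program not solved")
  hs <- entropy_nats(marginal_vec(p4, "s"))
  ## MI at the optimal q: H(S) is pinned by the (s,x) marginals, so
  ## MI_q(S;X,Y,Z) = H(S) + sum q ln(q / q[*,x,y,z])
  min_mi <- hs + sol$objective
  mi_p <- hs - (entropy_nats(p4$p) -
                  entropy_nats(marginal_vec(p4, c("x", "y", "z"))))
  ci <- mi_p - min_mi
  list(ci = ci, ci_bits = ci / log(2), min_mi = min_mi,
       mi_p = mi_p, status = sol$status,
       num_err = c(primal = sol$pviol, dual = sol$dviol, gap = sol$gapviol),
       solution = sol)
}

#' Trivariate unique information of one source
#'
#' Unique information of source X about the target S, given the other two
#' sources:
#' `UI(S; X \\ Y, Z) = min MI(S'; X', Y', Z') - min MI(S'; Y', Z')`,
#' both minima over the polytope of distributions sharing the three
#' (target, source) pair marginals — the first is the optimum of
#' [build_tri_synergy_program()], the second of
#' [build_tri_condmarg_program()].  Each optimum is recovered as the
#' corresponding mutual information evaluated at the optimal `q`; up to
#' numerical tolerance the difference is nonnegative.
#'
#' @inheritParams tri_synergy
#' @return a list with `ui` (nats), `ui_bits`, the two program optima
#'   `min_mi_sxyz` and `min_mi_syz` (nats), the two statuses, and the
#'   worst certificate triple `num_err`.
#' @export
tri_unique <- function(p4, params = solver_params()) {
  stopifnot(inherits(p4, "joint_pmf4"))
  support <- build_support4(p4)
  hs <- entropy_nats(marginal_vec(p4, "s"))
  p1 <- build_tri_synergy_program(p4, support)
  s1 <- solve_cone_program(p1, params)
  p2 <- build_tri_condmarg_program(p4, support)
  s2 <- solve_cone_program(p2, params)
  if (s1$status == "failed" || s2$status == "failed")
    solver_failure("trivariate unique-information programs not solved")
  min_mi_sxyz <- hs + s1$objective
  min_mi_syz <- hs + s2$objective
  ui <- min_mi_sxyz - min_mi_syz
  list(ui = ui, ui_bits = ui / log(2),
       min_mi_sxyz = min_mi_sxyz, min_mi_syz = min_mi_syz,
       status = c(sxyz = s1$status, syz = s2$status),
       num_err = c(primal = max(s1$pviol, s2$pviol),
                   dual = min(s1$dviol, s2$dviol),
                   gap = max(s1$gapviol, s2$gapviol)),
       solutions = list(sxyz = s1, syz = s2))
}
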