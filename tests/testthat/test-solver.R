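test_that("degenerate single-atom program solves exactly", {
  p <- joint_pmf(data.frame(x = "a", y = "b", z = "c", p = 1))
  sol <- solve_cone_program(build_exp_program(p), solver_params())
  expect_equal(sol$status, "optimal")
  expect_equal(sol$primal$q, 1, tolerance = 1e-9)
  expect_equal(sol$objective, 0, tolerance = 1e-9)
})

test_that("the And program solves to optimality with a certified pair", {
  p <- gate("and")
  pr <- build_exp_program(p)
  params <- solver_params()
  sol <- solve_cone_program(pr, params)
  expect_equal(sol$status, "optimal")
  ## cross-check the optimum against the brute-force polytope minimum
  o <- oracle_min_cp(p)
  expect_equal(sol$objective, o$fmin, tolerance = 1e-9)
  ## duality gap of the returned pair within abstol
  expect_lte(sol$gapviol, params$abstol)
  ## weak duality: primal >= dual objective up to tolerance
  expect_gte(sol$objective - sol$dual_objective, -1e-9)
})

test_that("iteration starvation is surfaced, not silently accepted", {
  r <- tryCatch(
    solve_cone_program(build_exp_program(gate("and")),
                       solver_params(max_iter = 1)),
    pidcone_solver_failure = function(e) "exception")
  if (!identical(r, "exception"))
    expect_true(r$status %in% c("inaccurate", "failed"))
})

test_that("dual feasibility residuals match the closed-form algebra", {
  ## hand-built dual point lambda = 0, mu = -1/e on the uniform pmf:
  ## residual = 1 + mu[*,y,z] + ln(1/e) = mu[*,y,z] at every triplet
  u <- joint_pmf(transform(expand.grid(x = 0:1, y = 0:1, z = 0:1), p = 1 / 8))
  pr <- build_exp_program(u)
  sol <- solve_cone_program(pr, solver_params())
  n <- pr$n_exp
  hand <- sol
  hand$mu <- rep(-exp(-1), n)
  hand$lambda <- lapply(sol$lambda, function(v) v * 0)
  res <- dual_feasibility_residuals(pr, hand)
  mu_star <- -2 * exp(-1)   # two x-values per (y,z) cell
  expect_equal(res, rep(mu_star, n), tolerance = 1e-12)

  ## lowering one lambda[x,y] by delta lowers exactly the residuals of the
  ## triplets containing that (x,y) by delta
  delta <- 0.3
  pert <- sol
  pert$lambda$xy[1] <- pert$lambda$xy[1] - delta
  r0 <- dual_feasibility_residuals(pr, sol)
  r1 <- dual_feasibility_residuals(pr, pert)
  touched <- pr$support$xy_row == 1
  expect_equal(r1[touched], r0[touched] - delta, tolerance = 1e-9)
  expect_equal(r1[!touched], r0[!touched], tolerance = 1e-12)

  ## mu >= 0 is recorded as -Inf violation, not an error
  bad <- sol
  bad$mu[2] <- 0.5
  rb <- dual_feasibility_residuals(pr, bad)
  expect_identical(rb[2], -Inf)

  ## at the optimum all residuals clear -feastol
  expect_true(all(dual_feasibility_residuals(pr, sol) >= -1e-7))
})

test_that("solution round-trips through the problem data", {
  p <- random_pmf(c(2, 3, 2), seed = 31)
  pr <- build_exp_program(p)
  sol <- solve_cone_program(pr, solver_params())
  ## re-evaluated equality residuals agree with the reported violation
  w <- sol$w
  resid <- as.numeric(pr$A %*% w) - pr$b
  expect_lt(max(abs(resid)), 1e-7)
  ## the reported violation is the q+-marginal form of the same residuals
  expect_lt(sol$pviol, 1e-7)
})

test_that("solver is deterministic", {
  p <- random_pmf(c(2, 2, 4), seed = 55)
  pr <- build_exp_program(p)
  a <- solve_cone_program(pr, solver_params())
  b <- solve_cone_program(pr, solver_params())
  expect_identical(a$status, b$status)
  expect_identical(a$objective, b$objective)
  expect_identical(a$primal$q, b$primal$q)
})

test_that("weak duality holds on every solved random instance", {
  for (i in 1:25) {
    p <- random_pmf(c(2, 2, 2 + i %% 4), seed = 4000 + i)
    sol <- solve_cone_program(build_exp_program(p), solver_params())
    if (sol$status != "failed")
      expect_gte(sol$objective - sol$dual_objective, -1e-7)
  }
})
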