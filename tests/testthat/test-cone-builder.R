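test_that("support restriction keeps exactly the marginally compatible triplets", {
  ## And gate: supported (x,y) pairs {(0,0),(0,1),(1,1)} and likewise for
  ## (x,z); their compatible products give 5 triplets
  sup <- build_support(gate("and"))
  expect_equal(nrow(sup$triplets), 5)
  expect_equal(length(sup$xy_keys), 3)
  expect_equal(length(sup$xz_keys), 3)

  ## every input atom appears among the triplets
  p <- random_pmf(c(3, 2, 2), seed = 5)
  sup2 <- build_support(p)
  k_atoms <- paste(p$x, p$y, p$z)
  k_tri <- paste(sup2$triplets$x, sup2$triplets$y, sup2$triplets$z)
  expect_true(all(k_atoms %in% k_tri))

  ## copy gate: each x = (y,z) is compatible only with its own pair
  expect_equal(nrow(build_support(copy_gate(4, 3))$triplets), 12)

  ## full-support product pmf: all |X||Y||Z| triplets
  u <- joint_pmf(transform(expand.grid(x = 0:1, y = 0:1, z = 0:2), p = 1 / 12))
  expect_equal(nrow(build_support(u)$triplets), 12)
})

test_that("program shapes follow the support", {
  pr <- build_exp_program(gate("and"))
  expect_equal(length(pr$c), 15)              # 3 variables per triplet
  expect_equal(nrow(pr$A), 3 + 3 + 5)         # marginal + coupling rows
  expect_equal(pr$n_exp, 5)
  expect_equal(sum(pr$c == -1), 5)            # -1 on every r variable
  expect_equal(unname(pr$c[pr$exp_vars[, "r"]]), rep(-1, 5))
  ## G is minus identity against h = 0
  expect_equal(as.matrix(pr$G), diag(-1, 15), ignore_attr = TRUE)
  expect_equal(pr$h, rep(0, 15))

  pc <- build_exp_program(copy_gate(2, 2))
  expect_equal(length(pc$c), 12)
  expect_equal(nrow(pc$A), 4 + 4 + 4)
  expect_equal(pc$n_exp, 4)

  p1 <- build_exp_program(joint_pmf(data.frame(x = 0, y = 0, z = 0, p = 1)))
  expect_equal(length(p1$c), 3)
  expect_equal(nrow(p1$A), 2 + 1)

  ## marginal rows carry the pair marginals, coupling rows carry zero
  m <- sum(pr$rows$type != "coupling")
  expect_equal(sum(pr$b[seq_len(m)]), 2)      # each family sums to 1
  expect_equal(pr$b[pr$rows$type == "coupling"], rep(0, 5))
})

test_that("builders are deterministic", {
  a <- build_exp_program(random_pmf(c(2, 3, 2), seed = 9))
  b <- build_exp_program(random_pmf(c(2, 3, 2), seed = 9))
  expect_identical(a$c, b$c)
  expect_identical(as.matrix(a$A), as.matrix(b$A))
  expect_identical(a$b, b$b)
})

test_that("a feasible (r,t,q) satisfies A w = b and the cone inequalities", {
  p <- random_pmf(c(2, 2, 3), seed = 21)
  pr <- build_exp_program(p)
  ip <- interior_point(p, pr$support)
  w <- numeric(length(pr$c))
  w[pr$exp_vars[, "r"]] <- ip$r
  w[pr$exp_vars[, "t"]] <- ip$t
  w[pr$exp_vars[, "q"]] <- ip$q
  resid <- as.numeric(pr$A %*% w) - pr$b
  expect_lt(max(abs(resid)), 1e-12)
  expect_true(all(exp_cone_margin(ip$r, ip$t, ip$q) > 0))
})

test_that("interior point is strictly feasible with positive cone margin", {
  ## the analytic point has q~ = p[x,y,*] p[x,*,z] / p[x,*,*]; its own pair
  ## marginals reproduce p's, and the -100 offset makes the cone inequality
  ## strict on every triplet
  for (i in 1:100) {
    dims <- 1 + (c(i, i * 3, i * 7) %% 4)
    p <- random_pmf(dims, seed = 3000 + i)
    sup <- build_support(p)
    ip <- interior_point(p, sup)
    margins <- exp_cone_margin(ip$r, ip$t, ip$q)
    expect_true(all(ip$q > 0))
    expect_true(all(margins > 0))
    ## marginal equations hold at q~
    qxy <- tapply(ip$q, paste(ip$x, ip$y), sum)
    pxy <- marginal(p, c("x", "y"))
    expect_equal(as.numeric(qxy[paste(pxy$x, pxy$y)]), pxy$p,
                 tolerance = 1e-12)
    qxz <- tapply(ip$q, paste(ip$x, ip$z), sum)
    pxz <- marginal(p, c("x", "z"))
    expect_equal(as.numeric(qxz[paste(pxz$x, pxz$z)]), pxz$p,
                 tolerance = 1e-12)
  }
})

test_that("product pmfs make the interior point equal to the pmf itself", {
  u <- joint_pmf(transform(expand.grid(x = 0:1, y = 0:1, z = 0:1), p = 1 / 8))
  ip <- interior_point(u)
  expect_equal(ip$q, u$p, tolerance = 1e-14)
})

test_that("the conic objective at the embedded optimum equals the smooth objective", {
  ## Proposition-style equivalence: feeding the solver's q through the
  ## embedding map (r,t,q) = (q ln(t/q), q[*,y,z], q) reproduces
  ## sum q ln(q / q[*,y,z]) as c'w
  for (s in c(1, 2, 3)) {
    p <- random_pmf(c(2, 2, 2), seed = 600 + s)
    pr <- build_exp_program(p)
    sol <- solve_cone_program(pr, solver_params())
    cw <- sum(pr$c * sol$w)
    expect_equal(cw, sol$objective, tolerance = 1e-9)
    ## and the returned w is cone-feasible (boundary: margin >= 0)
    expect_true(all(exp_cone_margin(sol$primal$r, sol$primal$t,
                                    sol$primal$q) >= -1e-12))
  }
})

test_that("trivariate builders lay out three marginal families and cells", {
  p4 <- xor3_gate()
  pr <- build_tri_synergy_program(p4)
  ## 16 supported quadruples (all (s,x),(s,y),(s,z) pairs occur)
  expect_equal(pr$n_exp, 16)
  expect_equal(length(pr$c), 48)
  expect_equal(nrow(pr$A), 4 + 4 + 4 + 16)

  pc <- build_tri_condmarg_program(p4)
  ## q over 16 quadruples + (r,t,u) per (s,y,z) cell (8 cells)
  expect_equal(pc$n_nonneg, 16)
  expect_equal(pc$n_exp, 8)
  expect_equal(length(pc$c), 16 + 24)
  expect_equal(nrow(pc$A), 12 + 8 + 8)
})
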