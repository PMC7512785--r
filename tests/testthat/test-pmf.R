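and_df <- data.frame(x = c(0, 0, 0, 1), y = c(0, 0, 1, 1),
                     z = c(0, 1, 0, 1), p = 0.25)

test_that("construction validates, discards zero atoms and normalizes", {
  p <- joint_pmf(and_df)
  expect_s3_class(p, "joint_pmf")
  expect_equal(nrow(p), 4)
  expect_equal(sum(p$p), 1)

  ## zero atoms are dropped
  p2 <- joint_pmf(data.frame(x = c(0, 0, 1), y = c(0, 0, 1),
                             z = c(0, 1, 1), p = c(0.5, 0, 0.5)))
  expect_equal(nrow(p2), 2)
  expect_false(any(p2$p == 0))

  ## normalization
  p3 <- joint_pmf(data.frame(x = c(0, 1), y = c(0, 1), z = c(0, 1),
                             p = c(2, 2)), normalize = TRUE)
  expect_equal(p3$p, c(0.5, 0.5))

  ## rejections
  expect_error(joint_pmf(data.frame(x = 0, y = 0, z = 0, p = -0.1)),
               "negative")
  expect_error(joint_pmf(data.frame(x = 0, y = 0, z = 0, p = 0)),
               "empty support")
  expect_error(joint_pmf(data.frame(x = c(0, 1), y = c(0, 1), z = c(0, 1),
                                    p = c(0.5, 0.6))),
               "sum")

  ## duplicate triples are aggregated
  p4 <- joint_pmf(data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 0),
                             p = c(0.4, 0.6)))
  expect_equal(nrow(p4), 1)
  expect_equal(p4$p, 1)

  ## dictionary-style input: named vector with comma-separated triples
  p5 <- joint_pmf(c("0,0,0" = 0.25, "0,0,1" = 0.25, "0,1,0" = 0.25,
                    "1,1,1" = 0.25))
  expect_equal(p5, joint_pmf(and_df))
  expect_error(joint_pmf(c("0,0" = 1)), "comma-separated")
})

test_that("marginals sum out the right coordinates and preserve mass", {
  p <- joint_pmf(and_df)
  mxy <- marginal(p, c("x", "y"))
  ## hand-derived from the four atoms: p[0,0,*]=0.5, p[0,1,*]=0.25,
  ## p[1,1,*]=0.25
  expect_equal(mxy$p[mxy$x == "0" & mxy$y == "0"], 0.5)
  expect_equal(mxy$p[mxy$x == "0" & mxy$y == "1"], 0.25)
  expect_equal(mxy$p[mxy$x == "1" & mxy$y == "1"], 0.25)
  expect_equal(sum(mxy$p), 1, tolerance = 1e-14)

  ## keeping all coordinates returns the pmf itself
  mall <- marginal(p, 1:3)
  expect_equal(mall$p, p$p)

  ## uniform on {0,1}^3: any pair marginal is four cells of 1/4
  u <- joint_pmf(expand.grid(x = 0:1, y = 0:1, z = 0:1) |>
                   transform(p = 1 / 8))
  myz <- marginal(u, c("y", "z"))
  expect_equal(myz$p, rep(0.25, 4))

  ## integer coords and validation
  expect_equal(marginal(p, c(1, 2)), mxy)
  expect_error(marginal(p, character(0)), "nonempty")
})

test_that("marginalization keeps each marginal summing to 1 on random pmfs", {
  for (i in 1:20) {
    p <- random_pmf(c(3, 2, 4), seed = 400 + i)
    for (co in list("x", "y", "z", c("x", "y"), c("x", "z"), c("y", "z")))
      expect_equal(sum(marginal(p, co)$p), 1, tolerance = 1e-12)
  }
})

test_that("info_profile matches direct enumeration and the chain rule", {
  ## product (uniform) pmf: all pairwise mutual informations vanish
  pr <- joint_pmf(transform(expand.grid(x = 0:1, y = 0:2, z = 0:1),
                            p = 1 / 12))
  ip <- info_profile(pr)
  expect_equal(ip$mi_x_y, 0, tolerance = 1e-12)
  expect_equal(ip$mi_x_z, 0, tolerance = 1e-12)
  expect_equal(ip$mi_y_z, 0, tolerance = 1e-12)

  ## xor: MI(X;Y,Z) = ln 2 nats, pairwise zero
  px <- gate("xor")
  ipx <- info_profile(px)
  expect_equal(ipx$mi_x_yz, log(2), tolerance = 1e-12)
  expect_equal(ipx$mi_x_y, 0, tolerance = 1e-12)
  expect_equal(ipx$mi_x_z, 0, tolerance = 1e-12)

  ## and: MI(X;Y,Z)/ln2 = H(X) = 2 - (3/4) log2(3), by direct summation
  ipa <- info_profile(joint_pmf(and_df))
  expect_equal(ipa$mi_x_yz / log(2), 2 - 0.75 * log2(3), tolerance = 1e-12)

  ## chain rule MI(X;Y,Z) = MI(X;Y) + MI(X;Z|Y) on random pmfs, and
  ## permutation covariance under symbol relabeling
  for (i in 1:10) {
    p <- random_pmf(c(2, 3, 2), seed = 900 + i)
    ip <- info_profile(p)
    ## MI(X;Z|Y) via H-terms computed from marginals
    hfun <- function(co) {
      w <- marginal(p, co)$p
      -sum(w * log(w))
    }
    mi_x_z_given_y <- hfun(c("x", "y")) + hfun(c("y", "z")) -
      hfun("y") - hfun(c("x", "y", "z"))
    expect_equal(ip$mi_x_yz, ip$mi_x_y + mi_x_z_given_y, tolerance = 1e-12)
    expect_true(ip$mi_x_yz >= -1e-12 && ip$h_x_given_yz >= -1e-12)

    relab <- joint_pmf(data.frame(x = paste0("sym", p$x), y = paste0("w", p$y),
                                  z = paste0("v", p$z), p = p$p))
    ipr <- info_profile(relab)
    expect_equal(unclass(ipr), unclass(ip), tolerance = 1e-12)
  }
})

test_that("gate distributions have the expected atoms", {
  expect_equal(nrow(gate("and")), 4)
  expect_equal(sort(gate("and")$p), rep(0.25, 4))
  gx <- gate("xor")
  expect_equal(nrow(gx), 4)
  expect_true(all(gx$x == as.character(bitwXor(as.integer(gx$y),
                                               as.integer(gx$z)))))
  gr <- gate("rdn")
  expect_equal(nrow(gr), 2)
  expect_equal(gr$p, c(0.5, 0.5))
  expect_true(all(gr$x == gr$y & gr$y == gr$z))
  expect_equal(nrow(gate("rdnxor")), 8)
  expect_equal(nrow(gate("rdnunqxor")), 32)
  expect_error(gate("nand"))
})

test_that("copy gate is uniform on m*n pairs with x = (y,z)", {
  p <- copy_gate(2, 2)
  expect_equal(nrow(p), 4)
  expect_equal(p$p, rep(0.25, 4))
  expect_equal(sort(p$x), sort(paste(p$y, p$z, sep = ".")))

  expect_equal(nrow(copy_gate(3, 2)), 6)
  expect_equal(copy_gate(3, 2)$p, rep(1 / 6, 6))

  p1 <- copy_gate(1, 1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$p, 1)

  expect_error(copy_gate(0, 2), "positive")
})

test_that("random_pmf is seed-reproducible and flat on the simplex", {
  a <- random_pmf(c(2, 2, 2), seed = 11)
  b <- random_pmf(c(2, 2, 2), seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, random_pmf(c(2, 2, 2), seed = 12)))

  ## the caller's RNG stream is not consumed
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(random_pmf(c(2, 2, 2), seed = 5)); x2 <- runif(1)
  expect_identical(x1, x2)

  ## degenerate simplex
  expect_equal(random_pmf(c(1, 1, 1), seed = 1)$p, 1)

  ## flat Dirichlet moments: each atom has mean 1/56 over (2,2,14) draws
  nrep <- 500
  ps <- vapply(seq_len(nrep),
               function(i) random_pmf(c(2, 2, 14), seed = 2000 + i)$p,
               numeric(56))
  m <- rowMeans(ps)
  se <- apply(ps, 1, stats::sd) / sqrt(nrep)
  expect_true(all(abs(m - 1 / 56) <= 3 * se + 1e-12))
})
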