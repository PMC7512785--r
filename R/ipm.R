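## Primal path-following interior-point engine for the entropy-block family
##
## All programs in this package reduce, after eliminating the r- and
## t-variables of the conic form, to
##
##     minimize   f(v) = sum_{i in E} v_i ln( v_i / V_{blk(i)} )
##     subject to B v = b,  v >= 0,
##
## where E is the set of "entropy" variables, blk partitions E into
## aggregation cells and V_b = sum_{i in b} v_i.  Variables outside E enter
## the constraints linearly and carry no objective.  The engine minimizes
## the barrier-augmented objective  f(v) - tau * sum_i ln v_i  along a
## decreasing schedule of tau by feasible-start equality-constrained Newton
## steps.  Key structural facts exploited:
##
##  * the Hessian of f is block-diagonal: diag(1/v) - (1/V_b) 1 1' on each
##    cell, so (H + barrier)^{-1} is available in closed form by a
##    Sherman-Morrison update per cell; the update factor is computed in a
##    cancellation-free form, and the Newton system is polished by
##    iterative refinement against the exact Hessian;
##  * at an exactly centered point the equality multipliers lambda satisfy
##    ln(v_i/V_b) + (B' lambda)_i = tau / v_i > 0, so the dual point is
##    feasible with positive margin and the duality gap equals
##    (number of variables) * tau -- which is what makes the final
##    certificates small by construction rather than by accident.
##
## Instances whose optimum lies on a face where whole aggregation cells
## vanish (V_b -> 0) become severely ill-conditioned once tau approaches
## the floor; the engine therefore snapshots the deepest iterate whose
## certificates already meet the strict tolerances and falls back to it
## when a later stage stalls, instead of returning the damaged iterate.
##
## The engine is deterministic: no randomization, ordering fixed by the
## caller's problem data.

ipm_entropy <- function(red, params) {
  B <- red$B; b <- red$b; v <- red$v0
  ent <- red$ent; blk <- red$blk
  n <- red$nvar
  m <- nrow(B)
  stopifnot(length(v) == n, all(v > 0))
  ent_idx <- which(ent)
  nb <- if (length(ent_idx)) max(blk[ent_idx]) else 0L
  Ablk <- Matrix::sparseMatrix(i = ent_idx, j = blk[ent_idx], x = 1,
                               dims = c(n, nb))
  Bt <- Matrix::t(B)
  dense <- m <= params$dense_cutoff
  Bd <- if (dense) as.matrix(B) else NULL
  blocksum <- function(x) as.numeric(Matrix::crossprod(Ablk, x))
  fof <- function(v) {
    Vb <- blocksum(v)
    ve <- v[ent_idx]
    sum(ve * log(ve / Vb[blk[ent_idx]]))
  }
  ## certificate score: <= 1 iff the iterate meets the strict tolerances;
  ## the worst violation ratio otherwise
  cert_score <- function(cert) {
    max(cert$pviol / params$feastol, -cert$dviol / params$feastol,
        min(cert$gap / params$abstol,
            cert$gap / max(abs(cert$f), 1e-10) / params$reltol),
        cert$wdneg / (0.5 * params$feastol))
  }
  certify <- function(v, lam) {
    Vb <- blocksum(v)
    gf <- numeric(n)
    gf[ent_idx] <- log(v[ent_idx] / Vb[blk[ent_idx]])
    f <- sum(v[ent_idx] * gf[ent_idx])
    dresid <- gf + as.numeric(Bt %*% lam)
    margin <- f + sum(lam * b)   # primal minus dual objective
    list(pviol = max(abs(as.numeric(B %*% v) - b)),
         dviol = min(c(dresid, 0)),
         gap = max(margin, 0), wdneg = max(-margin, 0), f = f)
  }
  ## Newton's equality multipliers inherit noise along the near-null
  ## directions of B'; at a centered point the centrality equations
  ## B'lam = tau/v - grad f are consistent, so a rank-revealing
  ## least-squares refit recovers lam far more accurately
  polish_lambda <- function(v, tau) {
    Vb <- blocksum(v)
    gf <- numeric(n)
    gf[ent_idx] <- log(v[ent_idx] / Vb[blk[ent_idx]])
    lam_ls <- tryCatch(
      qr.coef(qr(as.matrix(Bt), LAPACK = TRUE), tau / v - gf),
      error = function(e) NULL)
    if (is.null(lam_ls)) return(NULL)
    lam_ls[!is.finite(lam_ls)] <- 0
    lam_ls
  }
  tau <- params$tau_start
  tau_end <- params$tau_end
  iters <- 0L
  lam <- numeric(m)
  status_note <- "ok"
  best_any <- NULL      # iterate with the best certificate score overall
  repeat {
    last_stage <- tau <= tau_end * (1 + 1e-9)
    ## certificates are harvested from every stage past the crossover;
    ## a dual residual of order feastol needs the Newton decrement driven
    ## to the numerical floor there (the allowed decrement scales like
    ## feastol^2 * v for the large coordinates, far below c * tau), so
    ## those stages iterate until the stall detector fires
    thresh <- if (last_stage || tau <= params$cert_tau)
      params$center_tol_cert else params$center_tol_path * tau
    stage_end <- "centered"
    prev_dec2 <- Inf
    stalls <- 0L
    for (inner in seq_len(params$max_inner)) {
      if (iters >= params$max_iter) {
        status_note <- "max_iter"; stage_end <- "max_iter"; break
      }
      Vb <- blocksum(v)
      gf <- numeric(n)
      gf[ent_idx] <- log(v[ent_idx] / Vb[blk[ent_idx]])
      g <- gf - tau / v
      d <- tau / v^2
      d[ent_idx] <- d[ent_idx] + 1 / v[ent_idx]
      beta <- 1 / Vb
      ## Sherman-Morrison factor gam = beta / (1 - beta * sum v^2/(v+tau)),
      ## computed cancellation-free: 1 - beta*sb = sum tau*v/(v+tau) / V_b
      gam <- 1 / blocksum(tau * v / (v + tau))
      Hinv <- function(x) {
        y <- x / d
        if (nb) {
          bs <- blocksum(y)
          y[ent_idx] <- y[ent_idx] +
            (gam[blk[ent_idx]] * bs[blk[ent_idx]]) / d[ent_idx]
        }
        y
      }
      ## exact Hessian apply (no cancellation), for iterative refinement
      Hmul <- function(x) {
        y <- d * x
        if (nb) {
          bs <- blocksum(x)
          y[ent_idx] <- y[ent_idx] - beta[blk[ent_idx]] * bs[blk[ent_idx]]
        }
        y
      }
      r <- b - as.numeric(B %*% v)
      ## Schur complement S = B H^{-1} B' and a reusable solver for it
      solve_S <- NULL
      if (dense) {
        BD <- Bd * rep(1 / d, each = m)
        S <- tcrossprod(BD, Bd)
        if (nb) {
          M <- as.matrix(B %*% (Ablk / d))
          S <- S + tcrossprod(M * rep(gam, each = m), M)
        }
        del <- params$kkt_reg * max(diag(S))
        R <- tryCatch(chol(S + diag(del, m)), error = function(e) NULL)
        if (is.null(R))
          R <- tryCatch(chol(S + diag(1e6 * del, m)),
                        error = function(e) NULL)
        if (!is.null(R))
          solve_S <- function(x) backsolve(R, backsolve(R, x, transpose = TRUE))
      } else {
        S <- B %*% (Bt / d)
        if (nb) {
          M <- B %*% (Ablk / d)
          S <- S + M %*% Matrix::Diagonal(x = gam) %*% Matrix::t(M)
        }
        S <- Matrix::forceSymmetric(S)
        del <- params$kkt_reg * max(Matrix::diag(S))
        ch <- tryCatch(Matrix::Cholesky(S + Matrix::Diagonal(m, del),
                                        LDL = FALSE),
                       error = function(e) NULL)
        if (is.null(ch))
          ch <- tryCatch(Matrix::Cholesky(S + Matrix::Diagonal(m, 1e6 * del),
                                          LDL = FALSE),
                         error = function(e) NULL)
        if (!is.null(ch))
          solve_S <- function(x) as.numeric(Matrix::solve(ch, x))
      }
      if (is.null(solve_S)) {
        status_note <- "kkt_failure"; stage_end <- "kkt_failure"; break
      }
      ## KKT solve with iterative refinement against the exact Hessian
      kkt_solve <- function(rhs1, rhs2) {
        lam_k <- solve_S(as.numeric(B %*% Hinv(rhs1)) - rhs2)
        dv_k <- Hinv(rhs1 - as.numeric(Bt %*% lam_k))
        list(dv = dv_k, lam = lam_k)
      }
      st <- kkt_solve(-g, r)
      gscale <- max(1, max(abs(g)))
      prev_res <- Inf
      for (ref in 1:6) {
        res1 <- (-g) - as.numeric(Bt %*% st$lam) - Hmul(st$dv)
        res2 <- r - as.numeric(B %*% st$dv)
        resn <- max(max(abs(res1)) / gscale, max(abs(res2)))
        if (resn < 1e-14 || resn > 0.5 * prev_res) break
        prev_res <- resn
        co <- kkt_solve(res1, res2)
        st$dv <- st$dv + co$dv
        st$lam <- st$lam + co$lam
      }
      dv <- st$dv
      lam <- st$lam
      dec2 <- -sum(g * dv) - sum(lam * r)
      if (!is.finite(dec2)) {
        status_note <- "kkt_failure"; stage_end <- "kkt_failure"; break
      }
      if (dec2 <= thresh) break
      neg <- dv < 0
      amax <- if (any(neg)) min(1, 0.995 * min(-v[neg] / dv[neg])) else 1
      phi0 <- fof(v) - tau * sum(log(v))
      gd <- sum(g * dv)
      a <- amax
      ok <- FALSE
      for (ls in 1:50) {
        vn <- v + a * dv
        if (all(vn > 0)) {
          phin <- fof(vn) - tau * sum(log(vn))
          if (is.finite(phin) &&
              phin <= phi0 + 0.01 * a * gd + 1e-14 * abs(phi0)) {
            ok <- TRUE; break
          }
        }
        a <- a / 2
      }
      if (!ok) { stage_end <- "linesearch"; break }
      v <- v + a * dv
      iters <- iters + 1L
      ## noise-floor detection: steps this small make no real progress
      ## unless the decrement is also collapsing (superlinear tail)
      if (a < 1e-4 && dec2 >= prev_dec2 * (1 - 1e-3)) stalls <- stalls + 1L
      else stalls <- 0L
      if (stalls >= 3L) { stage_end <- "stalled"; break }
      prev_dec2 <- min(prev_dec2, dec2)
    }
    cert <- certify(v, lam)
    score <- cert_score(cert)
    if ((tau <= params$cert_tau || last_stage) && dense) {
      lam_ls <- polish_lambda(v, tau)
      if (!is.null(lam_ls)) {
        cert_ls <- certify(v, lam_ls)
        if (cert_score(cert_ls) < score) {
          lam <- lam_ls; cert <- cert_ls; score <- cert_score(cert)
        }
      }
    }
    if (!is.null(params$output_level) && params$output_level >= 2)
      message(sprintf(
        "  stage tau %.2e: %s after %d total iters; pviol %.2e dviol %.2e gap %.2e score %.2g",
        tau, stage_end, iters, cert$pviol, cert$dviol, cert$gap, score))
    if (tau <= params$cert_tau || last_stage) {
      if (is.null(best_any) || score < best_any$score)
        best_any <- list(v = v, lam = lam, tau = tau, cert = cert,
                         score = score)
    }
    hard_stop <- stage_end %in% c("stalled", "linesearch", "kkt_failure") &&
      !is.null(best_any) && best_any$score <= 1 && score > 1
    if (status_note == "max_iter" || last_stage || hard_stop) {
      ## conditioning can quietly eat the certificates near the barrier
      ## floor; among all harvested stage-end iterates (the floor iterate
      ## included) return the one with the best certificate score -- on
      ## clean instances that IS the floor iterate, which has the most
      ## accurate decomposition
      if (!is.null(best_any) && best_any$score < score) {
        v <- best_any$v; lam <- best_any$lam; tau <- best_any$tau
        if (status_note == "ok") status_note <- "early_stop"
      }
      break
    }
    tau <- max(tau * params$tau_shrink, tau_end)
  }
  ## final quantities at the returned point
  Vb <- blocksum(v)
  gf <- numeric(n)
  gf[ent_idx] <- log(v[ent_idx] / Vb[blk[ent_idx]])
  dual_resid <- gf + as.numeric(Bt %*% lam)
  list(v = v, lambda = lam, f = sum(v[ent_idx] * gf[ent_idx]), tau = tau,
       iterations = iters,
       dual_resid = dual_resid,
       primal_resid = as.numeric(B %*% v - b),
       note = status_note, Vb = Vb, blocksum = blocksum)
}

## default engine controls; exposed through solver_params()
ipm_defaults <- function() {
  list(tau_start = 0.1, tau_end = 1e-11, tau_shrink = 0.02,
       center_tol_path = 0.25, center_tol_cert = 1e-15, cert_tau = 1e-6,
       max_inner = 20L, kkt_reg = 1e-12, dense_cutoff = 320L)
}
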