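#' Reference decompositions of the benchmark gates
#'
#' Closed-form partial information decompositions of the seven benchmark
#' gates, in bits.  Each value follows from the marginal-polytope
#' definition by exhibiting a feasible distribution attaining a matching
#' information-theoretic lower bound (e.g. for `rdn`, `MI(X';Y',Z') >=
#' MI(X;Y) = 1` bit for every feasible distribution, and the coupling
#' concentrated on `y = z` attains it), except for `and` and `xorand`
#' whose shared terms are the optimum of a one-parameter family:
#' `SI(and) = 3/2 - (3/4) log2(3)` (about 0.311278 bits, attained where
#' the optimal coupling touches the boundary of the polytope) and
#' `SI(xorand) = 1/2`.
#'
#' @return a `data.frame` with columns `gate`, `si`, `ui_y`, `ui_z`, `ci`
#'   (bits).
#' @export
gate_reference_pid <- function() {
  data.frame(
    gate = c("rdn", "unq", "xor", "and", "rdnxor", "rdnunqxor", "xorand"),
    si   = c(1, 0, 0, 1.5 - 0.75 * log2(3), 1, 1, 0.5),
    ui_y = c(0, 1, 0, 0, 0, 1, 0),
    ui_z = c(0, 1, 0, 0, 0, 1, 0),
    ci   = c(0, 0, 1, 0.5, 1, 1, 1))
}

## per-instance quality record shared by the experiment harnesses:
## certificate triple, weak-duality margin, and the worst deviation of the
## three additivity identities SI+UIY = MI(X;Y), SI+UIZ = MI(X;Z),
## SI+UIY+UIZ+CI = MI(X;Y,Z) (bits)
instance_quality <- function(p, r) {
  sol <- attr(r, "solution")
  ip <- info_profile(p)
  id_dev <- max(abs(c(r$SI + r$UIY - ip$mi_x_y / log(2),
                      r$SI + r$UIZ - ip$mi_x_z / log(2),
                      r$SI + r$UIY + r$UIZ + r$CI - ip$mi_x_yz / log(2))))
  data.frame(ne_primal = r$Num_err[1], ne_dual = r$Num_err[2],
             ne_gap = r$Num_err[3],
             id_dev = id_dev,
             wd_margin = sol$objective - sol$dual_objective,
             status = sol$status)
}

#' Run the gate validation suite
#'
#' Computes the decomposition of all seven benchmark gates and compares it
#' with the closed-form values of [gate_reference_pid()].
#'
#' @param params a [solver_params()].
#' @return a `data.frame` with one row per gate: the computed `si`, `ui_y`,
#'   `ui_z`, `ci` (bits), the deviation from the reference (`max_dev`,
#'   bits), the worst certificate `max_num_err` and the solver `status`;
#'   the largest deviation over the suite is attached as attribute
#'   `"max_deviation"`.
#' @export
run_gate_suite <- function(params = solver_params()) {
  ref <- gate_reference_pid()
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    g <- ref$gate[i]
    p <- gate(g)
    r <- pid(p, params = params)
    data.frame(gate = g, si = r$SI, ui_y = r$UIY, ui_z = r$UIZ, ci = r$CI,
               max_dev = max(abs(c(r$SI - ref$si[i], r$UIY - ref$ui_y[i],
                                   r$UIZ - ref$ui_z[i], r$CI - ref$ci[i]))),
               max_num_err = max(abs(r$Num_err)),
               instance_quality(p, r))
  })
  out <- do.call(rbind, rows)
  attr(out, "max_deviation") <- max(out$max_dev)
  out
}

#' Run the Copy-gate grid
#'
#' For every `(m, n)` in the given ranges, decomposes the Copy gate and
#' records the relative deviation of `UIY` from `log2(m)` and of `UIZ`
#' from `log2(n)` (absolute deviation where the reference is 0, i.e.
#' `m = 1` or `n = 1`), together with `|SI|` and `|CI|`, which are exactly
#' zero for the Copy gate.
#'
#' @param m_range,n_range integer vectors of Y and Z alphabet sizes.
#' @param params a [solver_params()].
#' @return a `data.frame` with one row per pair; the worst relative
#'   deviation and worst `|SI|`/`|CI|` over the grid are attached as
#'   attributes `"worst_rel_dev"` and `"worst_si_ci"`.
#' @export
run_copy_grid <- function(m_range = 2:30, n_range = 2:30,
                          params = solver_params()) {
  stopifnot(all(m_range >= 1), all(n_range >= 1))
  grid <- expand.grid(m = m_range, n = n_range)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- grid$m[i]; n <- grid$n[i]
    p <- copy_gate(m, n)
    r <- pid(p, params = params)
    rel <- function(v, ref) if (ref > 0) abs(v - ref) / ref else abs(v)
    data.frame(m = m, n = n,
               ui_y = r$UIY, ui_z = r$UIZ, si = r$SI, ci = r$CI,
               rel_dev_y = rel(r$UIY, log2(m)),
               rel_dev_z = rel(r$UIZ, log2(n)),
               max_num_err = max(abs(r$Num_err)),
               instance_quality(p, r))
  })
  out <- do.call(rbind, rows)
  attr(out, "worst_rel_dev") <- max(out$rel_dev_y, out$rel_dev_z)
  attr(out, "worst_si_ci") <- max(abs(out$si), abs(out$ci))
  out
}

#' Run a random-distribution robustness set
#'
#' Reproduces the random-simplex experiment design: joint distributions of
#' (X, Y, Z) drawn uniformly from the probability simplex, grouped by the
#' varying alphabet size —
#' \itemize{
#'   \item Set 1: `|X| = |Y| = 2`, `|Z|` varies;
#'   \item Set 2: `|X| = |Z| = 2`, `|Y|` varies;
#'   \item Set 3: `|X| = |Y| = |Z| = s`, `s` varies.
#' }
#' Each group draws `reps` distributions and solves them at the given
#' parameters.  Failures are counted, never averaged over.
#'
#' @param set_id 1, 2 or 3.
#' @param reps draws per group.
#' @param seed integer seed; the whole experiment is reproducible from it.
#' @param sizes the varying sizes (defaults: `2:8` for Sets 1 and 2,
#'   `2:10` for Set 3).
#' @param params a [solver_params()].
#' @return a list of class `experiment_report`: `per_instance` (one row
#'   per draw: group, status, SI/UIY/UIZ/CI, max `Num_err`) and `groups`
#'   (per group: the fraction of instances solved to optimality at strict
#'   tolerances, mean values over non-failed instances, worst `Num_err`),
#'   plus the `seed`.
#' @export
run_random_sets <- function(set_id, reps = 100, seed = 1,
                            sizes = NULL, params = solver_params()) {
  stopifnot(set_id %in% 1:3, reps >= 1)
  if (is.null(sizes)) sizes <- if (set_id == 3) 2:10 else 2:8
  dims <- switch(set_id,
                 lapply(sizes, function(k) c(2, 2, k)),
                 lapply(sizes, function(k) c(2, k, 2)),
                 lapply(sizes, function(k) c(k, k, k)))
  inst_seeds <- with_seed(seed, function()
    matrix(sample.int(.Machine$integer.max - 1, length(sizes) * reps),
           nrow = reps))
  rows <- list()
  for (gi in seq_along(sizes)) {
    for (k in seq_len(reps)) {
      p <- random_pmf(dims[[gi]], seed = inst_seeds[k, gi])
      rec <- tryCatch({
        r <- pid(p, params = params)
        data.frame(group = sizes[gi], rep = k,
                   si = r$SI, ui_y = r$UIY, ui_z = r$UIZ, ci = r$CI,
                   max_num_err = max(abs(r$Num_err)),
                   instance_quality(p, r))
      }, pidcone_solver_failure = function(e)
        data.frame(group = sizes[gi], rep = k,
                   si = NA_real_, ui_y = NA_real_, ui_z = NA_real_,
                   ci = NA_real_, max_num_err = NA_real_,
                   ne_primal = NA_real_, ne_dual = NA_real_,
                   ne_gap = NA_real_, id_dev = NA_real_,
                   wd_margin = NA_real_, status = "failed"))
      rows[[length(rows) + 1L]] <- rec
    }
  }
  per_instance <- do.call(rbind, rows)
  groups <- do.call(rbind, lapply(split(per_instance, per_instance$group),
    function(d) {
      ok <- d$status != "failed"
      data.frame(group = d$group[1], n = nrow(d),
                 frac_optimal = mean(d$status == "optimal"),
                 mean_si = mean(d$si[ok]), mean_ui_y = mean(d$ui_y[ok]),
                 mean_ui_z = mean(d$ui_z[ok]), mean_ci = mean(d$ci[ok]),
                 max_num_err = if (any(ok)) max(d$max_num_err[ok]) else NA_real_)
    }))
  groups <- groups[order(groups$group), ]
  rownames(groups) <- NULL
  structure(list(set_id = set_id, per_instance = per_instance,
                 groups = groups, seed = seed, reps = reps),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("random-distribution set %d: %d draws per group, seed %d\n",
              x$set_id, x$reps, x$seed))
  print.data.frame(x$groups, row.names = FALSE, digits = 4)
  invisible(x)
}
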