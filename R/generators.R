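#' Benchmark logic-gate distributions
#'
#' Builds the canonical gate distributions used to validate partial
#' information decompositions.  Each gate maps independent uniform input
#' bits through a deterministic function, so every distribution is a
#' uniform mixture over its input alphabet:
#'
#' * `rdn` - a single uniform bit copied to all of x, y, z;
#' * `unq` - y, z independent uniform bits, x = (y, z) as an ordered pair;
#' * `xor` - x = y XOR z;
#' * `and` - x = y AND z;
#' * `rdnxor` - y = (y1, r), z = (z1, r), x = (y1 XOR z1, r) on iid bits;
#' * `rdnunqxor` - the concatenation of independent Rdn, Unq and Xor
#'   components: y = (r, u, a), z = (r, v, b), x = (r, (u, v), a XOR b);
#' * `xorand` - x = (y XOR z, y AND z).
#'
#' Composite symbols are encoded as period-joined labels, e.g. `"0.1"`.
#'
#' @param name one of `"rdn"`, `"unq"`, `"xor"`, `"and"`, `"rdnxor"`,
#'   `"rdnunqxor"`, `"xorand"`.
#' @return a [joint_pmf()].
#' @examples
#' gate("and")
#' @export
gate <- function(name) {
  name <- match.arg(name,
    c("rdn", "unq", "xor", "and", "rdnxor", "rdnunqxor", "xorand"))
  lab <- function(...) paste(..., sep = ".")
  bits <- c(0L, 1L)
  df <- switch(name,
    rdn = {
      w <- expand.grid(b = bits)
      data.frame(x = w$b, y = w$b, z = w$b)
    },
    unq = {
      w <- expand.grid(y = bits, z = bits)
      data.frame(x = lab(w$y, w$z), y = w$y, z = w$z)
    },
    xor = {
      w <- expand.grid(y = bits, z = bits)
      data.frame(x = bitwXor(w$y, w$z), y = w$y, z = w$z)
    },
    and = {
      w <- expand.grid(y = bits, z = bits)
      data.frame(x = bitwAnd(w$y, w$z), y = w$y, z = w$z)
    },
    rdnxor = {
      w <- expand.grid(y1 = bits, z1 = bits, r = bits)
      data.frame(x = lab(bitwXor(w$y1, w$z1), w$r),
                 y = lab(w$y1, w$r), z = lab(w$z1, w$r))
    },
    rdnunqxor = {
      w <- expand.grid(r = bits, u = bits, v = bits, a = bits, b = bits)
      data.frame(x = lab(w$r, w$u, w$v, bitwXor(w$a, w$b)),
                 y = lab(w$r, w$u, w$a), z = lab(w$r, w$v, w$b))
    },
    xorand = {
      w <- expand.grid(y = bits, z = bits)
      data.frame(x = lab(bitwXor(w$y, w$z), bitwAnd(w$y, w$z)),
                 y = w$y, z = w$z)
    })
  df$p <- 1 / nrow(df)
  joint_pmf(df)   # duplicate (x,y,z) rows are summed
}

#' Copy-gate distribution
#'
#' The Copy gate maps a pair (y, z), drawn uniformly from
#' \{1..m\} x \{1..n\}, to the triple (x, y, z) with x = (y, z).  Its
#' decomposition is known in closed form: with Y and Z independent,
#' UI(X;Y\\Z) = H(Y) = log2(m) bits, UI(X;Z\\Y) = H(Z) = log2(n) bits,
#' SI(X;Y,Z) = MI(Y;Z) = 0 and CI(X;Y,Z) = 0, which makes the gate a
#' closed-form benchmark that scales to large systems.
#'
#' @param m,n alphabet sizes of Y and Z (positive integers).
#' @return a [joint_pmf()] with exactly `m * n` atoms of probability
#'   `1 / (m * n)`.
#' @export
copy_gate <- function(m, n) {
  if (m < 1 || n < 1) stop("`m` and `n` must be positive integers",
                           call. = FALSE)
  w <- expand.grid(y = seq_len(m), z = seq_len(n))
  joint_pmf(data.frame(x = paste(w$y, w$z, sep = "."), y = w$y, z = w$z,
                       p = 1 / (m * n)))
}

#' Three-source XOR distribution
#'
#' The parity target: s = x XOR y XOR z with x, y, z independent uniform
#' bits.  All pairwise (target, source) marginals are products, yet the
#' three sources jointly determine the target, so the trivariate synergy
#' CI(S; X, Y, Z) equals H(S) = 1 bit.
#'
#' @return a [joint_pmf4()] with 8 atoms of probability 1/8.
#' @export
xor3_gate <- function() {
  w <- expand.grid(x = c(0L, 1L), y = c(0L, 1L), z = c(0L, 1L))
  joint_pmf4(data.frame(s = bitwXor(bitwXor(w$x, w$y), w$z),
                        x = w$x, y = w$y, z = w$z, p = 1 / 8))
}

## evaluate fun() under a temporary RNG state seeded with `seed`;
## the caller's .Random.seed is restored afterwards
with_seed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

#' Random joint distribution from the uniform simplex
#'
#' Draws a joint pmf of (X, Y, Z) uniformly at random from the probability
#' simplex on the `prod(sizes)` outcome triples, i.e. a flat Dirichlet draw,
#' realized as i.i.d. standard-exponential weights divided by their sum.
#'
#' @param sizes integer vector `c(|X|, |Y|, |Z|)`, each at least 1.
#' @param seed optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return a [joint_pmf()]; symbols are `"1" ... "|X|"` and so on.
#' @export
random_pmf <- function(sizes, seed = NULL) {
  stopifnot(length(sizes) == 3, all(sizes >= 1))
  grid <- expand.grid(x = seq_len(sizes[1]), y = seq_len(sizes[2]),
                      z = seq_len(sizes[3]))
  w <- with_seed(seed, function() stats::rexp(nrow(grid)))
  joint_pmf(data.frame(grid, p = w / sum(w)))
}

#' Random four-coordinate joint distribution from the uniform simplex
#'
#' @param sizes integer vector `c(|S|, |X|, |Y|, |Z|)`, each at least 1.
#' @inheritParams random_pmf
#' @return a [joint_pmf4()].
#' @export
random_pmf4 <- function(sizes, seed = NULL) {
  stopifnot(length(sizes) == 4, all(sizes >= 1))
  grid <- expand.grid(s = seq_len(sizes[1]), x = seq_len(sizes[2]),
                      y = seq_len(sizes[3]), z = seq_len(sizes[4]))
  w <- with_seed(seed, function() stats::rexp(nrow(grid)))
  joint_pmf4(data.frame(grid, p = w / sum(w)))
}
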