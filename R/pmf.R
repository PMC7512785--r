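#' Discrete joint distributions of (X, Y, Z)
#'
#' A `joint_pmf` stores a finite joint probability mass function of three
#' discrete random variables as a table of atoms: one row per outcome triple
#' `(x, y, z)` with strictly positive probability.  Symbols are opaque labels
#' (stored as character strings); no ordering or 0/1 coding is assumed.
#' Zero-probability atoms are always discarded on construction, and rows are
#' sorted lexicographically on the stringified symbols so that identical
#' distributions have identical representations.
#'
#' @param atoms a `data.frame` with columns `x`, `y`, `z` and `p`, or a named
#'   numeric vector / list whose names are comma-separated triples.
#'   Duplicate triples are summed.
#' @param normalize if `TRUE`, probabilities are divided by their sum;
#'   otherwise the sum must already be 1 within `tol`.
#' @param tol tolerance on the total mass when `normalize = FALSE`.
#' @return an object of class `joint_pmf`: a `data.frame` with columns
#'   `x`, `y`, `z` (character) and `p` (double), all `p > 0`.
#' @examples
#' andgate <- joint_pmf(data.frame(
#'   x = c(0, 0, 0, 1), y = c(0, 0, 1, 1), z = c(0, 1, 0, 1), p = 0.25))
#' marginal(andgate, c("x", "y"))
#' @export
joint_pmf <- function(atoms, normalize = FALSE, tol = 1e-10) {
  if (!is.data.frame(atoms) && (is.numeric(atoms) || is.list(atoms)))
    atoms <- named_atoms_to_df(atoms, c("x", "y", "z"))
  atoms <- as.data.frame(atoms)
  need <- c("x", "y", "z", "p")
  if (!all(need %in% names(atoms)))
    stop("`atoms` must have columns x, y, z, p", call. = FALSE)
  new_pmf(atoms[need], coords = c("x", "y", "z"), normalize = normalize,
          tol = tol, class = "joint_pmf")
}

#' Four-coordinate joint distributions of (S, X, Y, Z)
#'
#' The variant of [joint_pmf()] used by the trivariate programs: a target
#' variable `S` together with three sources `X`, `Y`, `Z`.
#'
#' @param atoms a `data.frame` with columns `s`, `x`, `y`, `z` and `p`.
#' @inheritParams joint_pmf
#' @return an object of class `joint_pmf4`.
#' @export
joint_pmf4 <- function(atoms, normalize = FALSE, tol = 1e-10) {
  if (!is.data.frame(atoms) && (is.numeric(atoms) || is.list(atoms)))
    atoms <- named_atoms_to_df(atoms, c("s", "x", "y", "z"))
  atoms <- as.data.frame(atoms)
  need <- c("s", "x", "y", "z", "p")
  if (!all(need %in% names(atoms)))
    stop("`atoms` must have columns s, x, y, z, p", call. = FALSE)
  new_pmf(atoms[need], coords = c("s", "x", "y", "z"), normalize = normalize,
          tol = tol, class = "joint_pmf4")
}

## dictionary-style input: a named vector/list with comma-separated symbol
## tuples as names, e.g. c("0,0,0" = 0.25, "1,1,1" = 0.75)
named_atoms_to_df <- function(atoms, coords) {
  vals <- as.numeric(unlist(atoms, use.names = FALSE))
  keys <- names(atoms)
  if (is.null(keys) || any(!nzchar(keys)))
    stop("`atoms` given as a vector/list must have names of the form ",
         paste(coords, collapse = ","), call. = FALSE)
  parts <- strsplit(keys, ",", fixed = TRUE)
  if (any(lengths(parts) != length(coords)))
    stop("each name must have ", length(coords),
         " comma-separated symbols", call. = FALSE)
  tab <- do.call(rbind, parts)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- coords
  out[] <- lapply(out, trimws)
  out$p <- vals
  out
}

## shared constructor: validates, aggregates duplicates, drops zero atoms,
## sorts lexicographically on stringified symbols
new_pmf <- function(df, coords, normalize, tol, class) {
  p <- as.numeric(df$p)
  if (any(!is.finite(p))) stop("probabilities must be finite", call. = FALSE)
  if (any(p < 0)) stop("negative probability in `atoms`", call. = FALSE)
  for (cc in coords) df[[cc]] <- as.character(df[[cc]])
  df$p <- p
  key <- do.call(paste, c(df[coords], sep = "\r"))
  if (anyDuplicated(key)) {
    agg <- tapply(df$p, key, sum)
    df <- df[!duplicated(key), , drop = FALSE]
    df$p <- as.numeric(agg[key[!duplicated(key)]])
  }
  keep <- df$p > 0
  if (!any(keep)) stop("empty support: no atom has positive probability",
                       call. = FALSE)
  df <- df[keep, , drop = FALSE]
  s <- sum(df$p)
  if (normalize) {
    df$p <- df$p / s
  } else if (abs(s - 1) > tol) {
    stop(sprintf("probabilities sum to %.12g, not 1 (use normalize = TRUE)", s),
         call. = FALSE)
  }
  ord <- do.call(order, unname(df[coords]))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c(class, "data.frame"))
}

#' @export
print.joint_pmf <- function(x, ...) {
  cat(sprintf("joint pmf of (X, Y, Z): %d atoms, |X|=%d |Y|=%d |Z|=%d\n",
              nrow(x), length(unique(x$x)), length(unique(x$y)),
              length(unique(x$z))))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.joint_pmf4 <- function(x, ...) {
  cat(sprintf("joint pmf of (S, X, Y, Z): %d atoms, |S|=%d |X|=%d |Y|=%d |Z|=%d\n",
              nrow(x), length(unique(x$s)), length(unique(x$x)),
              length(unique(x$y)), length(unique(x$z))))
  print.data.frame(x, ...)
  invisible(x)
}

pmf_coords <- function(p) {
  if (inherits(p, "joint_pmf4")) c("s", "x", "y", "z") else c("x", "y", "z")
}

## internal: marginal as a fast named vector keyed by "\r"-joined symbols
marginal_vec <- function(p, coords) {
  key <- do.call(paste, c(unclass(p)[coords], sep = "\r"))
  tapply(p$p, key, sum)
}

#' Marginal distribution over a subset of coordinates
#'
#' Sums the joint pmf over the coordinates not in `coords`, following the
#' asterisk convention: `marginal(p, c("x", "y"))` is the table of
#' `p[x, y, *] = P(X = x, Y = y)`.
#'
#' @param p a [joint_pmf()] or [joint_pmf4()].
#' @param coords the coordinates to keep: a subset of `c("x","y","z")`
#'   (or of `c("s","x","y","z")` for four-coordinate pmfs), or the
#'   corresponding integer positions.
#' @return a `data.frame` with the kept coordinate columns and an aggregated
#'   `p` column, sorted lexicographically; the `p` column sums to 1.
#' @export
marginal <- function(p, coords) {
  all_coords <- pmf_coords(p)
  if (is.numeric(coords)) coords <- all_coords[coords]
  coords <- all_coords[all_coords %in% coords]   # canonical order
  if (length(coords) == 0 || anyNA(coords))
    stop("`coords` must be a nonempty subset of the pmf coordinates",
         call. = FALSE)
  key <- do.call(paste, c(unclass(p)[coords], sep = "\r"))
  agg <- tapply(p$p, key, sum)
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- as.data.frame(parts, stringsAsFactors = FALSE)
  names(out) <- coords
  out$p <- as.numeric(agg)
  ord <- do.call(order, unname(out[coords]))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Shannon entropy of a probability vector, in nats, with 0 ln 0 := 0.
## Entries are assumed nonnegative; zeros are skipped.
entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Information profile of a joint pmf
#'
#' Computes the basic Shannon quantities of a [joint_pmf()] in nats
#' (with the convention 0 ln 0 = 0): the conditional entropy H(X | Y, Z),
#' the mutual information MI(X; Y, Z), and the pairwise mutual informations
#' MI(X; Y), MI(X; Z) and MI(Y; Z).
#'
#' @param p a [joint_pmf()].
#' @return an object of class `info_profile`: a list with elements
#'   `h_x_given_yz`, `mi_x_yz`, `mi_x_y`, `mi_x_z`, `mi_y_z`, all in nats.
#' @export
info_profile <- function(p) {
  stopifnot(inherits(p, "joint_pmf"))
  hx  <- entropy_nats(marginal_vec(p, "x"))
  hy  <- entropy_nats(marginal_vec(p, "y"))
  hz  <- entropy_nats(marginal_vec(p, "z"))
  hxy <- entropy_nats(marginal_vec(p, c("x", "y")))
  hxz <- entropy_nats(marginal_vec(p, c("x", "z")))
  hyz <- entropy_nats(marginal_vec(p, c("y", "z")))
  hxyz <- entropy_nats(p$p)
  structure(list(
    h_x_given_yz = hxyz - hyz,
    mi_x_yz = hx + hyz - hxyz,
    mi_x_y  = hx + hy - hxy,
    mi_x_z  = hx + hz - hxz,
    mi_y_z  = hy + hz - hyz), class = "info_profile")
}

#' @export
print.info_profile <- function(x, ...) {
  cat("information profile (nats):\n")
  for (nm in names(x)) cat(sprintf("  %-12s %.9f\n", nm, x[[nm]]))
  invisible(x)
}

## mutual information (nats) of two key columns of an atom table with
## weights w, applied as written (no renormalization); zero rows skipped
mi_pair_nats <- function(key_a, key_b, w) {
  keep <- w > 0
  key_a <- key_a[keep]; key_b <- key_b[keep]; w <- w[keep]
  wa <- tapply(w, key_a, sum)
  wb <- tapply(w, key_b, sum)
  sum(w * log(w / (as.numeric(wa[key_a]) * as.numeric(wb[key_b]))))
}

## conditional mutual information MI(A; B | C) in nats from atom keys
cmi_nats <- function(key_ac, key_bc, key_c, w) {
  keep <- w > 0
  w <- w[keep]
  key_ac <- key_ac[keep]; key_bc <- key_bc[keep]; key_c <- key_c[keep]
  wac <- tapply(w, key_ac, sum)
  wbc <- tapply(w, key_bc, sum)
  wc  <- tapply(w, key_c, sum)
  sum(w * log(w * as.numeric(wc[key_c]) /
                (as.numeric(wac[key_ac]) * as.numeric(wbc[key_bc]))))
}
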