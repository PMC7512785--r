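#' Read a joint distribution from a plain-text table
#'
#' Parses a UTF-8 text file with one atom per line: four whitespace-separated
#' fields `x y z p` for a bivariate-decomposition input, or five fields
#' `s x y z p` for a trivariate one.  Lines that are empty or start with `#`
#' are ignored.  Probabilities are decimal floats; symbols are kept as
#' opaque strings.
#'
#' @param path file to read.
#' @param normalize,tol passed to [joint_pmf()] / [joint_pmf4()].
#' @return a [joint_pmf()] (4 columns) or [joint_pmf4()] (5 columns).
#' @export
read_pmf <- function(path, normalize = FALSE, tol = 1e-10) {
  lines <- readLines(path, encoding = "UTF-8")
  raw <- trimws(lines)
  keep <- nzchar(raw) & !startsWith(raw, "#")
  if (!any(keep)) stop(sprintf("%s: no data lines", path), call. = FALSE)
  fields <- strsplit(raw[keep], "[[:space:]]+")
  lineno <- which(keep)
  nf <- lengths(fields)
  width <- nf[1]
  if (!width %in% c(4L, 5L))
    stop(sprintf("%s:%d: expected 4 or 5 fields, found %d",
                 path, lineno[1], width), call. = FALSE)
  bad <- which(nf != width)
  if (length(bad))
    stop(sprintf("%s:%d: expected %d fields, found %d",
                 path, lineno[bad[1]], width, nf[bad[1]]), call. = FALSE)
  tab <- do.call(rbind, fields)
  prob <- suppressWarnings(as.numeric(tab[, width]))
  if (anyNA(prob))
    stop(sprintf("%s:%d: cannot parse probability '%s'",
                 path, lineno[which(is.na(prob))[1]],
                 tab[which(is.na(prob))[1], width]), call. = FALSE)
  neg <- which(prob < 0)
  if (length(neg))
    stop(sprintf("%s:%d: negative probability %g",
                 path, lineno[neg[1]], prob[neg[1]]), call. = FALSE)
  if (width == 4L) {
    joint_pmf(data.frame(x = tab[, 1], y = tab[, 2], z = tab[, 3], p = prob),
              normalize = normalize, tol = tol)
  } else {
    joint_pmf4(data.frame(s = tab[, 1], x = tab[, 2], y = tab[, 3],
                          z = tab[, 4], p = prob),
               normalize = normalize, tol = tol)
  }
}

#' Write a joint distribution to a plain-text table
#'
#' Inverse of [read_pmf()]: one atom per line, whitespace-separated, full
#' double precision.
#'
#' @param p a [joint_pmf()] or [joint_pmf4()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(p, path) {
  coords <- pmf_coords(p)
  lines <- do.call(paste, c(unclass(p)[coords],
                            list(formatC(p$p, format = "g", digits = 17))))
  writeLines(c(paste("#", paste(c(coords, "p"), collapse = " ")), lines),
             con = path, useBytes = TRUE)
  invisible(path)
}
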