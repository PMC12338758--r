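#' Round half away from zero
#'
#' Base R's [round()] uses banker's rounding (round-half-even); reported
#' percentages and length statistics in this package use the conventional
#' round-half-up instead, so that e.g. 2.55 -> 2.6 at one decimal.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  # small epsilon absorbs representation error just below a .5 boundary
  sign(x) * trunc(abs(x) * f + 0.5 + 1e-9) / f
}

#' Format a percentage the way result tables print it
#'
#' Integer percent unless the exact value terminates at one decimal
#' (e.g. 15/24 -> 62.5); rounding is half-up.
#'
#' @param count numerator count.
#' @param total denominator count (> 0).
#' @return a single numeric, e.g. `29` or `62.5`.
#' @export
fold_percent <- function(count, total) {
  stopifnot(total > 0, count >= 0, count <= total)
  p <- 100 * count / total
  p1 <- round_half_up(p, 1L)
  if (abs(p - p1) < 1e-9 && p1 != trunc(p1)) p1 else round_half_up(p, 0L)
}

# Minimal union-find over arbitrary string labels.
uf_new <- function() new.env(parent = emptyenv())

uf_find <- function(uf, x) {
  root <- x
  while (!is.null(p <- uf[[root]]) && p != root) root <- p
  # path compression
  while (!is.null(p <- uf[[x]]) && p != x) {
    uf[[x]] <- root
    x <- p
  }
  if (is.null(uf[[root]])) uf[[root]] <- root
  root
}

uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a)
  rb <- uf_find(uf, b)
  if (ra != rb) uf[[rb]] <- ra
  invisible(NULL)
}

uf_components <- function(uf, members) {
  if (length(members) == 0L) return(list())
  roots <- vapply(members, function(m) uf_find(uf, m), character(1))
  unname(split(members, roots))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
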