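#' Series truncation policies
#'
#' The CMP normalising constant is an infinite series; all computations in
#' this package replace it by a finite sum of `k + 1` terms.  Two policies
#' are supported:
#'
#' * `trunc_series(k)`: plain series truncation.  The distribution's support
#'   is conceptually unbounded and `k` is a numerical cut-off; the default
#'   `k = max(60, ceiling(2 * mu))` (about twice the largest mean of
#'   interest) makes the dropped tail negligible for the low-count,
#'   moderate-dispersion regimes this model targets.
#' * `trunc_bound(k)`: a hard support bound.  Counts genuinely cannot exceed
#'   `k` (for example, at most ten wickets can fall in a cricket innings),
#'   so the support is exactly `{0, ..., k}` and the series is finite by
#'   construction.
#'
#' @param k Positive integer: number of series terms beyond zero
#'   (`trunc_series`) or the maximum attainable count (`trunc_bound`).
#' @param mu Mean(s) the truncation must cover.
#' @return An object of class `cmp_trunc` with fields `mode` and `k`.
#' @examples
#' trunc_series(60)
#' trunc_bound(10)       # e.g. wickets in a cricket innings
#' default_trunc(mu = 40)
#' @export
trunc_series <- function(k = 60L) {
  k <- as.integer(k)
  stopifnot(length(k) == 1L, is.finite(k), k >= 1L)
  structure(list(mode = "series", k = k), class = "cmp_trunc")
}

#' @rdname trunc_series
#' @export
trunc_bound <- function(k) {
  k <- as.integer(k)
  stopifnot(length(k) == 1L, is.finite(k), k >= 1L)
  structure(list(mode = "bound", k = k), class = "cmp_trunc")
}

#' @rdname trunc_series
#' @export
default_trunc <- function(mu) {
  stopifnot(all(is.finite(mu)), all(mu > 0))
  trunc_series(max(60L, as.integer(ceiling(2 * max(mu)))))
}

#' @export
print.cmp_trunc <- function(x, ...) {
  what <- if (x$mode == "bound") "hard support bound" else "series truncation"
  cat(sprintf("<cmp_trunc> %s at k = %d\n", what, x$k))
  invisible(x)
}

as_trunc <- function(trunc, mu) {
  if (is.null(trunc)) return(default_trunc(mu))
  stopifnot(inherits(trunc, "cmp_trunc"))
  trunc
}
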