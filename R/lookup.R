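#' Grid specification for the rate look-up table
#'
#' The default grid follows the table used throughout the package: a step
#' of 0.01 for `mu` from 0.01 to 32 (over three times the largest count the
#' bundled scenarios can produce; `mu = 0` is excluded as a degenerate
#' point mass) and `nu` from 0 to 10.  The `nu` step defaults to 0.05,
#' which keeps the `nu`-direction interpolation error well below the
#' `mu`-direction error while keeping the table compact (643K nodes).
#' Nodes may alternatively be spaced uniformly in `log mu`
#' (`spacing = "log-mu"`); interpolation weights always use the `log mu`
#' transform regardless of node spacing.
#'
#' @param mu_min,mu_max,mu_step Mean-axis range and step (`mu_min > 0`).
#' @param nu_min,nu_max,nu_step Dispersion-axis range and step.
#' @param spacing `"linear-mu"` (default) or `"log-mu"` node spacing.
#' @return A `cmp_grid` object.
#' @export
lookup_grid <- function(mu_min = 0.01, mu_max = 32, mu_step = 0.01,
                        nu_min = 0, nu_max = 10, nu_step = 0.05,
                        spacing = c("linear-mu", "log-mu")) {
  spacing <- match.arg(spacing)
  stopifnot(mu_min > 0, mu_max > mu_min, mu_step > 0,
            nu_min >= 0, nu_max > nu_min, nu_step > 0)
  g <- structure(list(mu_min = mu_min, mu_max = mu_max, mu_step = mu_step,
                      nu_min = nu_min, nu_max = nu_max, nu_step = nu_step,
                      spacing = spacing), class = "cmp_grid")
  if (length(grid_mu_nodes(g)) < 2L || length(grid_nu_nodes(g)) < 2L)
    stop("grid must have at least 2 nodes per axis", call. = FALSE)
  g
}

grid_mu_nodes <- function(grid) {
  if (grid$spacing == "log-mu") {
    n <- floor((log(grid$mu_max) - log(grid$mu_min)) / grid$mu_step)
    exp(log(grid$mu_min) + grid$mu_step * (0:n))
  } else {
    n <- floor((grid$mu_max - grid$mu_min) / grid$mu_step + 1e-9)
    grid$mu_min + grid$mu_step * (0:n)
  }
}

grid_nu_nodes <- function(grid) {
  n <- floor((grid$nu_max - grid$nu_min) / grid$nu_step + 1e-9)
  grid$nu_min + grid$nu_step * (0:n)
}

#' Build the (mu, nu) -> log lambda look-up table
#'
#' Solves the mean constraint once per grid node and stores `log lambda`.
#' Nodes are independent, so the result is identical whatever the number
#' of workers; with `workers > 1` the `nu` columns are split across forked
#' processes (`parallel::mclapply`).
#'
#' @param grid A [lookup_grid()].
#' @param trunc_k Series truncation used at build time; defaults to
#'   `ceiling(2 * mu_max)` (about twice the largest tabulated mean).  The
#'   `nu = 0` row is finite by construction under this truncation, so the
#'   geometric-series divergence cannot arise during the build.
#' @param solver `"bisection"` (default) or `"polynomial"`.
#' @param workers Number of parallel workers for the build.
#' @return A `cmp_lookup` object: grid metadata, the dense node matrix
#'   (`mu` rows by `nu` columns), `trunc_k`, and build provenance.
#' @examples
#' tab <- build_lookup_table(lookup_grid(mu_max = 5, mu_step = 0.1,
#'                                       nu_max = 3, nu_step = 0.25))
#' lookup_log_lambda(tab, 2.5, 1)   # ~ log(2.5)
#' @export
build_lookup_table <- function(grid = lookup_grid(), trunc_k = NULL,
                               solver = c("bisection", "polynomial"),
                               workers = 1L) {
  solver <- match.arg(solver)
  stopifnot(inherits(grid, "cmp_grid"))
  mu_nodes <- grid_mu_nodes(grid)
  nu_nodes <- grid_nu_nodes(grid)
  if (is.null(trunc_k)) trunc_k <- as.integer(ceiling(2 * grid$mu_max))
  trunc_k <- as.integer(trunc_k)
  build_cols <- function(js) {
    if (solver == "bisection") {
      .cpp_build_table(mu_nodes, nu_nodes[js], trunc_k, 1e-10)
    } else {
      vapply(nu_nodes[js], function(nuj)
        solve_lambda_polynomial(mu_nodes, nuj, k = trunc_k,
                                trunc = trunc_series(trunc_k))$log_lambda,
        numeric(length(mu_nodes)))
    }
  }
  workers <- max(1L, as.integer(workers))
  if (workers > 1L) {
    chunks <- split(seq_along(nu_nodes),
                    cut(seq_along(nu_nodes), workers, labels = FALSE))
    vals <- parallel::mclapply(chunks, build_cols, mc.cores = workers)
    values <- do.call(cbind, vals)
  } else {
    values <- build_cols(seq_along(nu_nodes))
  }
  dimnames(values) <- NULL
  structure(list(grid = grid, mu_nodes = mu_nodes, nu_nodes = nu_nodes,
                 values = values, trunc_k = trunc_k,
                 build_metadata = list(
                   version = as.character(utils::packageVersion("bidisperse")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   solver = solver)),
            class = "cmp_lookup")
}

#' @export
print.cmp_lookup <- function(x, ...) {
  cat(sprintf(
    "<cmp_lookup> %d x %d nodes; mu in [%g, %g] (%s), nu in [%g, %g]; k = %d\n",
    length(x$mu_nodes), length(x$nu_nodes), x$grid$mu_min, x$grid$mu_max,
    x$grid$spacing, x$grid$nu_min, x$grid$nu_max, x$trunc_k))
  invisible(x)
}

#' Query the look-up table
#'
#' Bilinear interpolation of `log lambda` over the four nodes surrounding
#' `(mu, nu)`, with the `mu` weight computed on the `log mu` scale
#' (`dmu = (log mu - log mu1) / (log mu2 - log mu1)`) and the `nu` weight
#' on the linear `nu` scale.  Queries outside the grid hull reuse the
#' nearest boundary cell with weights outside `[0, 1]` (bilinear
#' extrapolation); when this happens a warning is emitted once per call
#' and the count of extrapolated queries is attached as attribute
#' `"n_extrapolated"`.
#'
#' @param table A `cmp_lookup` object.
#' @param mu,nu Query points (`nu` scalar or same length as `mu`).
#' @param warn Emit the extrapolation warning?  (Callers that track
#'   extrapolation themselves, e.g. the sampler, pass `FALSE`.)
#' @return Numeric vector of interpolated `log lambda` values.
#' @export
lookup_log_lambda <- function(table, mu, nu, warn = TRUE) {
  stopifnot(inherits(table, "cmp_lookup"), all(mu > 0), all(nu >= 0))
  res <- .cpp_lookup_loglambda(table$values, table$mu_nodes, table$nu_nodes,
                               table$grid$spacing == "log-mu",
                               as.numeric(mu), as.numeric(nu))
  if (warn && res$n_extrapolated > 0L)
    warning(sprintf("%d quer%s outside the look-up grid: bilinear extrapolation used",
                    res$n_extrapolated,
                    if (res$n_extrapolated == 1L) "y lies" else "ies lie"),
            call. = FALSE)
  structure(res$log_lambda, n_extrapolated = res$n_extrapolated)
}

#' Serialise a look-up table as plain text
#'
#' Format: `#`-prefixed `key=value` header lines (grid ranges and steps,
#' spacing, `trunc_k`, version), then one whitespace-delimited row of `nu`
#' nodes, then one row per `mu` node (the `mu` value followed by
#' `log lambda` at each `nu` node).  Values are written with full decimal
#' precision (17 significant digits) so the round trip is value-exact.
#'
#' @param table A `cmp_lookup` object.
#' @param path File path.
#' @return `write_lookup_table` returns `path` invisibly;
#'   `read_lookup_table` returns a `cmp_lookup`.
#' @export
write_lookup_table <- function(table, path) {
  stopifnot(inherits(table, "cmp_lookup"))
  g <- table$grid
  hdr <- c(
    sprintf("# mu_min=%.17g", g$mu_min), sprintf("# mu_max=%.17g", g$mu_max),
    sprintf("# mu_step=%.17g", g$mu_step), sprintf("# nu_min=%.17g", g$nu_min),
    sprintf("# nu_max=%.17g", g$nu_max), sprintf("# nu_step=%.17g", g$nu_step),
    sprintf("# spacing=%s", g$spacing), sprintf("# trunc_k=%d", table$trunc_k),
    sprintf("# version=%s", table$build_metadata$version))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(sprintf("%.17g", table$nu_nodes), collapse = " "), con)
  body <- vapply(seq_along(table$mu_nodes), function(i)
    paste(sprintf("%.17g", c(table$mu_nodes[i], table$values[i, ])),
          collapse = " "), character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_lookup_table
#' @export
read_lookup_table <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  need <- c("mu_min", "mu_max", "mu_step", "nu_min", "nu_max", "nu_step",
            "spacing", "trunc_k")
  if (!all(need %in% keys))
    stop("malformed look-up table header: missing ",
         paste(setdiff(need, keys), collapse = ", "), call. = FALSE)
  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]
  first_body_line <- which(!is_hdr & nzchar(trimws(lines)))[1L]
  nu_nodes <- as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]])
  rows <- lapply(body[-1], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  len <- lengths(rows)
  if (length(rows) && any(len != length(nu_nodes) + 1L)) {
    bad <- which(len != length(nu_nodes) + 1L)[1L]
    stop(sprintf("ragged look-up table row at line %d: expected %d values, got %d",
                 first_body_line + bad, length(nu_nodes) + 1L, len[bad]),
         call. = FALSE)
  }
  m <- do.call(rbind, rows)
  if (anyNA(m) || anyNA(nu_nodes))
    stop("non-numeric value in look-up table body", call. = FALSE)
  grid <- lookup_grid(mu_min = as.numeric(vals["mu_min"]),
                      mu_max = as.numeric(vals["mu_max"]),
                      mu_step = as.numeric(vals["mu_step"]),
                      nu_min = as.numeric(vals["nu_min"]),
                      nu_max = as.numeric(vals["nu_max"]),
                      nu_step = as.numeric(vals["nu_step"]),
                      spacing = vals[["spacing"]])
  structure(list(grid = grid, mu_nodes = m[, 1], nu_nodes = nu_nodes,
                 values = m[, -1, drop = FALSE],
                 trunc_k = as.integer(vals["trunc_k"]),
                 build_metadata = list(
                   version = if ("version" %in% keys) vals[["version"]] else NA_character_,
                   timestamp = NA_character_, solver = NA_character_)),
            class = "cmp_lookup")
}
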