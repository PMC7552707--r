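#' Piecewise linear interpolation
#'
#' Evaluates the piecewise linear interpolant through the knots
#' `(t_k, y_k)`: for `t_k <= t <= t_{k+1}`,
#' `y(t) = y_k + (y_{k+1} - y_k) / (t_{k+1} - t_k) * (t - t_k)`.
#' Exact at knots; no extrapolation outside the knot span.
#'
#' @param knots `data.frame` (or list) with strictly increasing `t` and
#'   values `y`, at least two rows.
#' @param t Query times, all inside `[t_1, t_n]`.
#' @return Interpolated values at `t`.
#' @export
piecewise_interpolate <- function(knots, t) {
  kt <- knots$t
  ky <- knots$y
  if (length(kt) < 2) stop("need at least two knots", call. = FALSE)
  if (any(diff(kt) <= 0)) stop("knot times must be strictly increasing", call. = FALSE)
  if (any(t < kt[1] - 1e-12) || any(t > kt[length(kt)] + 1e-12)) {
    stop("query time outside the knot span; no extrapolation", call. = FALSE)
  }
  k <- findInterval(t, kt, rightmost.closed = TRUE)
  k[k == length(kt)] <- length(kt) - 1
  ky[k] + (ky[k + 1] - ky[k]) / (kt[k + 1] - kt[k]) * (t - kt[k])
}

#' Resample a culture record onto a regular grid
#'
#' Builds the aligned hourly trajectory pair the identifier and controller
#' consume: cumulative lactate `y` interpolated from the record's sample
#' knots, and cumulative replaced medium `u` interpolated from the event
#' knots (post-event cumulative values). The step change of `u` at an
#' exchange can be represented either as a linear ramp between events
#' (`u_mode = "linear"`, the default) or as a right-continuous staircase
#' (`u_mode = "staircase"`).
#'
#' @param record A [culture_record()].
#' @param step Grid spacing in hours; must divide the replacement period.
#' @param include_initial_fill Include the seeding fill in `u`? Default
#'   `TRUE` (documented convention).
#' @param u_mode `"linear"` or `"staircase"` input representation.
#' @return An object of class `trajectory_pair`: list with `grid` (h), `y`
#'   (mM-equivalent), `u` (mL) and `source` (well id).
#' @export
resample_pair <- function(record, step = 1, include_initial_fill = TRUE,
                          u_mode = c("linear", "staircase")) {
  u_mode <- match.arg(u_mode)
  if (24 %% step != 0) stop("step must divide 24 h", call. = FALSE)
  span <- record$culture_span
  grid <- seq(0, span, by = step)

  y_knots <- data.frame(t = record$samples$time,
                        y = cumulative_lactate(record))
  y <- piecewise_interpolate(y_knots, grid)

  e <- record$events
  V <- record$working_volume
  fill <- if (include_initial_fill) V else 0
  u_t <- c(0, e$time, span)
  u_v <- c(fill, fill + cumsum(e$fraction * V))
  u_v <- c(u_v, u_v[length(u_v)])
  keep <- !duplicated(u_t)
  if (u_mode == "linear") {
    u <- piecewise_interpolate(data.frame(t = u_t[keep], y = u_v[keep]), grid)
  } else {
    u <- stats::approx(u_t[keep], u_v[keep], xout = grid,
                       method = "constant", f = 0, rule = 2)$y
  }

  structure(list(grid = grid, y = y, u = u, source = record$well_id),
            class = "trajectory_pair")
}

#' @export
print.trajectory_pair <- function(x, ...) {
  cat(sprintf("<trajectory_pair> %s: %d points over %g h; y in [%.3g, %.3g] mM-eq, u total %.3g mL\n",
              x$source, length(x$grid), max(x$grid), min(x$y), max(x$y),
              x$u[length(x$u)]))
  invisible(x)
}

#' Write / read a trajectory pair as CSV
#'
#' Columns `time_h,cum_lactate_mM,cum_medium_mL`.
#'
#' @param pair A `trajectory_pair`.
#' @param path File path.
#' @return `path` (write) or a `trajectory_pair` (read).
#' @export
write_trajectory_csv <- function(pair, path) {
  utils::write.csv(data.frame(time_h = pair$grid,
                              cum_lactate_mM = pair$y,
                              cum_medium_mL = pair$u),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param source Identifier to attach when reading.
#' @export
read_trajectory_csv <- function(path, source = basename(path)) {
  df <- utils::read.csv(path)
  structure(list(grid = df$time_h, y = df$cum_lactate_mM,
                 u = df$cum_medium_mL, source = source),
            class = "trajectory_pair")
}
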