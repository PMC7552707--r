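#' Normalised root mean square error goodness of fit
#'
#' `nrmse = 1 - ||y_ref - y_fit|| / ||y_ref - mean(y_ref)||` with the
#' Euclidean norm. Equals 1 for a perfect fit, 0 when the fit is no better
#' than the reference mean, and can be arbitrarily negative.
#'
#' @param y_ref Reference series.
#' @param y_fit Fitted/simulated series, same length.
#' @return Scalar in `(-Inf, 1]`.
#' @export
nrmse <- function(y_ref, y_fit) {
  if (length(y_ref) != length(y_fit)) stop("series lengths differ", call. = FALSE)
  if (length(y_ref) < 2) stop("need at least two points", call. = FALSE)
  denom <- sqrt(sum((y_ref - mean(y_ref))^2))
  if (denom == 0) stop("reference series is constant; NRMSE undefined", call. = FALSE)
  1 - sqrt(sum((y_ref - y_fit)^2)) / denom
}

#' Cross-fit NRMSE matrix
#'
#' Scores every identified model against every record: in `model_fit` mode,
#' each model is simulated on the record's input trajectory and its output
#' compared to the record's interpolated output; in `closed_loop` mode, a
#' receding-horizon controller built on each model is run against the
#' record's trajectory as reference (on a model of the record itself as
#' plant) and the realised output is scored. Diagonal cells are self-fits.
#'
#' @param pairs List of `trajectory_pair` objects (the records' hourly
#'   trajectories).
#' @param models List of `darx_model` objects, same length/order (model `j`
#'   identified from record `j`).
#' @param mode `"model_fit"` or `"closed_loop"`.
#' @param mpc A [mpc_config()] for closed-loop mode.
#' @return Matrix of NRMSE values in percent (rows = records, columns =
#'   models), class `fit_matrix`.
#' @export
cross_fit_matrix <- function(pairs, models, mode = c("model_fit", "closed_loop"),
                             mpc = mpc_config()) {
  mode <- match.arg(mode)
  nr <- length(pairs); nc <- length(models)
  out <- matrix(NA_real_, nr, nc,
                dimnames = list(vapply(pairs, `[[`, "", "source"),
                                vapply(seq_len(nc), function(j)
                                  sprintf("model_%02d", j), character(1))))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      p <- pairs[[i]]
      m <- models[[j]]
      if (length(m$grid) != length(p$grid)) {
        stop("trajectory and model grids are incompatible", call. = FALSE)
      }
      val <- if (mode == "model_fit") {
        nrmse(p$y, simulate_darx(m, p$u))
      } else {
        plant <- darx_model(models[[i]]$na, models[[i]]$nb, models[[i]]$delay,
                            a = models[[i]]$a, b = models[[i]]$b,
                            grid = models[[i]]$grid,
                            noise_variance = 0)
        tr <- receding_horizon_simulate(plant, reference = p$y, config = mpc,
                                        model = m, u0 = p$u[1])
        tr$output_nrmse
      }
      out[i, j] <- 100 * val
    }
  }
  class(out) <- c("fit_matrix", class(out))
  out
}

#' Summarise a fit matrix or control traces
#'
#' Mean and sample standard deviation, in percent, of the diagonal
#' (self-fit) cells, the off-diagonal cells and all cells.
#'
#' @param x A `fit_matrix` (percent NRMSE values).
#' @return `data.frame` with one row per cell set.
#' @export
summarize_fit <- function(x) {
  stopifnot(is.matrix(x))
  d <- diag(as.matrix(x))
  off <- as.matrix(x)[row(x) != col(x)]
  sets <- list(diagonal = d, off_diagonal = off, all = as.numeric(x))
  do.call(rbind, lapply(names(sets), function(nm) {
    v <- sets[[nm]]
    data.frame(cells = nm, n = length(v),
               mean_pct = mean(v),
               sd_pct = if (length(v) > 1) stats::sd(v) else 0)
  }))
}

#' Load a packaged benchmark reference table
#'
#' Printed summary tables of the benchmark hPDC expansion study, used as
#' reference values: `"harvest"` (1e5 cells), `"efficiency"` (1e4
#' cells/mL) and `"lactate_rate"` (1e-7 mM per cell per hour), each as
#' condition x donor means and SDs over triplicates.
#'
#' @param name One of `"harvest"`, `"efficiency"`, `"lactate_rate"`.
#' @return `data.frame` with columns `condition`, `donor`, `mean`, `sd`.
#' @export
benchmark_table <- function(name = c("harvest", "efficiency", "lactate_rate")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0("reference_", name, ".csv"),
                   package = "lactomc")
  utils::read.csv(f, comment.char = "#")
}

#' Medium-efficiency table from harvest counts and schedules
#'
#' Recomputes the benchmark efficiency table: harvested cells divided by
#' total medium used (seeding fill included) for each condition x donor
#' cell.
#'
#' @param harvest `data.frame` with `condition`, `donor`, `mean` harvest in
#'   1e5 cells (defaults to the packaged benchmark table).
#' @param schedules As returned by [benchmark_schedules()].
#' @return `data.frame` with `condition`, `donor`, `total_medium_mL` and
#'   `efficiency` in 1e4 cells/mL.
#' @export
efficiency_table <- function(harvest = benchmark_table("harvest"),
                             schedules = benchmark_schedules()) {
  totals <- vapply(schedules$schedules, function(s)
    cumulative_medium(s, schedules$working_volume)$total, numeric(1))
  tm <- totals[as.character(harvest$condition)]
  eff <- medium_efficiency(harvest$mean * 1e5, tm) / 1e4
  data.frame(condition = harvest$condition, donor = harvest$donor,
             total_medium_mL = unname(tm), efficiency = unname(eff))
}

#' Study-level report for a simulated dataset
#'
#' Generates the summary tables of a full expansion study from a dataset of
#' culture records: harvest counts, medium efficiency and endpoint
#' lactate-per-cell rates per condition x donor (means and SDs over
#' replicates), the self/cross model-fit NRMSE matrix per triplicate, and a
#' plain-text summary. Files are written as CSV into `out_dir`.
#'
#' @param dataset List of `culture_record`s (e.g. from
#'   [generate_dataset()]), with well ids of the form `d<donor>_c<cond>_r<rep>`.
#' @param out_dir Output directory, created if needed. `NULL` to skip
#'   writing.
#' @param config An [estimation_config()] for the per-record model fits.
#' @return Invisible list with `harvest`, `efficiency`, `lactate_rate`
#'   (data.frames), `fit_matrices` (per donor x condition triplicate) and
#'   `fit_summary`.
#' @export
study_report <- function(dataset, out_dir = NULL,
                         config = estimation_config()) {
  if (!length(dataset)) stop("empty dataset", call. = FALSE)
  meta <- do.call(rbind, lapply(dataset, function(r) {
    m <- regmatches(r$well_id,
                    regexec("^d(\\d+)_c(\\d+)_r(\\d+)$", r$well_id))[[1]]
    if (length(m) != 4) stop("well ids must look like d1_c2_r3", call. = FALSE)
    data.frame(donor = as.integer(m[2]), condition = as.integer(m[3]),
               replicate = as.integer(m[4]))
  }))
  sched <- benchmark_schedules()

  per_well <- cbind(meta, do.call(rbind, lapply(dataset, function(r) {
    y <- cumulative_lactate(r)
    total_medium <- cumulative_medium(
      sched$schedules[[as.character(sub(".*_c(\\d+)_.*", "\\1", r$well_id))]],
      r$working_volume)$total
    data.frame(harvest = r$harvested_cells,
               total_lactate = y[length(y)],
               total_medium = total_medium,
               efficiency = medium_efficiency(r$harvested_cells, total_medium),
               lactate_rate = lactate_per_cell_rate(
                 y[length(y)], r$harvested_cells, r$culture_span))
  })))

  agg <- function(col, scale) {
    m <- stats::aggregate(per_well[[col]] / scale,
                          by = list(condition = per_well$condition,
                                    donor = per_well$donor),
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
    data.frame(condition = m$condition, donor = m$donor,
               mean = m$x[, "mean"], sd = m$x[, "sd"])
  }
  harvest <- agg("harvest", 1e5)
  efficiency <- agg("efficiency", 1e4)
  lactate_rate <- agg("lactate_rate", 1e-7)

  groups <- split(seq_along(dataset),
                  interaction(meta$donor, meta$condition, drop = TRUE))
  fit_matrices <- lapply(groups, function(idx) {
    pairs <- lapply(dataset[idx], resample_pair)
    models <- lapply(pairs, function(p)
      estimate_darx_tv(p$y, p$u, c(1, 1), 0, config, grid = p$grid))
    cross_fit_matrix(pairs, models, "model_fit")
  })
  all_cells <- do.call(rbind, lapply(fit_matrices, unclass))
  diag_cells <- unlist(lapply(fit_matrices, function(m) diag(unclass(m))))
  off_cells <- unlist(lapply(fit_matrices, function(m) m[row(m) != col(m)]))
  msd <- function(v) {
    if (!length(v)) return(c(NA_real_, NA_real_))
    c(mean(v), if (length(v) > 1) stats::sd(v) else 0)
  }
  fit_summary <- data.frame(
    cells = c("diagonal", "off_diagonal"),
    n = c(length(diag_cells), length(off_cells)),
    mean_pct = c(msd(diag_cells)[1], msd(off_cells)[1]),
    sd_pct = c(msd(diag_cells)[2], msd(off_cells)[2]))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(harvest, file.path(out_dir, "harvest.csv"), row.names = FALSE)
    utils::write.csv(efficiency, file.path(out_dir, "efficiency.csv"), row.names = FALSE)
    utils::write.csv(lactate_rate, file.path(out_dir, "lactate_rate.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(all_cells), file.path(out_dir, "fit_matrix.csv"))
    summary_lines <- c(
      sprintf("wells: %d  donors: %d  conditions: %d", nrow(per_well),
              length(unique(meta$donor)), length(unique(meta$condition))),
      sprintf("self-fit NRMSE: %.2f%% +/- %.2f%%",
              fit_summary$mean_pct[1], fit_summary$sd_pct[1]),
      sprintf("cross-fit NRMSE: %.2f%% +/- %.2f%%",
              fit_summary$mean_pct[2], fit_summary$sd_pct[2]))
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  }

  invisible(list(harvest = harvest, efficiency = efficiency,
                 lactate_rate = lactate_rate, per_well = per_well,
                 fit_matrices = fit_matrices, fit_summary = fit_summary))
}
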