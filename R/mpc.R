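#' Receding-horizon controller configuration
#'
#' @param np_horizon Prediction horizon Np in samples (default 24: one day
#'   ahead on the hourly grid).
#' @param nc_horizon Control horizon Nc in samples (default 4); `Nc <= Np`.
#' @param output_weights Tracking weights `delta(j) >= 0`, recycled to Np.
#' @param move_weights Move-suppression weights `lambda(j) >= 0`, recycled
#'   to Nc (default 0.1).
#' @param u_min,u_max Per-step bounds on the medium increment `du` (mL).
#'   Default `[0, Inf)`: medium cannot be removed once added. Set
#'   `u_min = -Inf` for the unconstrained analysis case.
#' @param y_max Optional lactate *concentration* cap (mM); `NA` (default)
#'   disables the constraint, 20 mM is the documented toxicity threshold.
#' @param control_period Hours between control decisions (default 1).
#' @param adaptive Re-estimate the time-varying gain from closed-loop data
#'   at every decision (requires an estimator in the simulation call).
#' @param seed Optional RNG seed for the closed-loop simulation.
#' @return An object of class `mpc_config`.
#' @export
mpc_config <- function(np_horizon = 24, nc_horizon = 4,
                       output_weights = 1, move_weights = 0.1,
                       u_min = 0, u_max = Inf, y_max = NA_real_,
                       control_period = 1, adaptive = FALSE, seed = NULL) {
  if (nc_horizon > np_horizon) stop("Nc must not exceed Np", call. = FALSE)
  if (any(output_weights < 0) || any(move_weights < 0)) {
    stop("weights must be >= 0", call. = FALSE)
  }
  if (u_min > u_max) stop("u_min must not exceed u_max", call. = FALSE)
  structure(list(np_horizon = as.integer(np_horizon),
                 nc_horizon = as.integer(nc_horizon),
                 output_weights = output_weights,
                 move_weights = move_weights,
                 u_min = u_min, u_max = u_max, y_max = y_max,
                 control_period = as.numeric(control_period),
                 adaptive = isTRUE(adaptive), seed = seed),
            class = "mpc_config")
}

#' Load a controller configuration from YAML
#'
#' Keys `np`, `nc`, `delta_weights`, `lambda_weights`, `u_step_max_mL`,
#' `y_max_mM`, `control_period_h`, `adaptive`, `seed`.
#'
#' @param path YAML file.
#' @return An [mpc_config()].
#' @export
read_mpc_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  mpc_config(np_horizon = cfg$np %||% 24,
             nc_horizon = cfg$nc %||% 4,
             output_weights = unlist(cfg$delta_weights) %||% 1,
             move_weights = unlist(cfg$lambda_weights) %||% 0.1,
             u_min = cfg$u_step_min_mL %||% 0,
             u_max = cfg$u_step_max_mL %||% Inf,
             y_max = cfg$y_max_mM %||% NA_real_,
             control_period = cfg$control_period_h %||% 1,
             adaptive = cfg$adaptive %||% FALSE,
             seed = cfg$seed)
}

# Coefficients at grid index t, holding the last value beyond the grid end
# (no future-parameter look-ahead is possible).
coef_at <- function(model, t) {
  t <- min(max(t, 1L), nrow(model$b))
  list(a = model$a[t, ], b = model$b[t, ])
}

#' Predict outputs over the horizon
#'
#' Iterates the DARX recursion over `Np` future samples with the
#' coefficients held at their latest estimate. The candidate moves `du` are
#' increments of the cumulative medium input: the predicted input is
#' `u(k+j) = u(k) + sum_{i <= min(j, Nc)} du_i` (moves beyond the control
#' horizon are zero, so the cumulative input is held). The prediction is
#' affine in `du`.
#'
#' @param model A [darx_model()].
#' @param history List with numeric `y` and `u`, the realised trajectories
#'   up to the current sample (last element = time `k`). Must cover the
#'   model lags.
#' @param du Candidate moves (length Nc).
#' @param Np Prediction horizon in samples.
#' @return Predicted outputs `yhat(k+1) ... yhat(k+Np)`.
#' @export
predict_horizon <- function(model, history, du, Np) {
  k <- length(history$y)
  if (k < model$na || length(history$u) != k) {
    stop("history must cover the model lags and have aligned y/u", call. = FALSE)
  }
  Nc <- length(du)
  u_fut <- history$u[k] + cumsum(c(du, rep(0, Np - Nc)))[seq_len(Np)]
  y_ext <- c(history$y, numeric(Np))
  u_ext <- c(history$u, u_fut)
  for (j in seq_len(Np)) {
    t <- k + j
    cf <- coef_at(model, t)
    acc <- 0
    for (i in seq_len(model$na)) acc <- acc - cf$a[i] * y_ext[t - i]
    for (jj in seq_len(model$nb) - 1L) {
      s <- t - model$delay - jj
      if (s >= 1) acc <- acc + cf$b[jj + 1L] * u_ext[s]
    }
    y_ext[t] <- acc
  }
  y_ext[k + seq_len(Np)]
}

#' Quadratic tracking cost
#'
#' `J = sum_j delta(j) (yhat_j - r_j)^2 + sum_j lambda(j) du_j^2`.
#'
#' @param predicted Predicted outputs over Np.
#' @param reference Reference values over Np.
#' @param du Moves over Nc.
#' @param config An [mpc_config()] supplying the weights.
#' @return Non-negative scalar; zero iff perfect tracking with zero moves.
#' @export
cost_J <- function(predicted, reference, du, config) {
  Np <- length(predicted)
  if (length(reference) != Np) stop("reference length must match Np", call. = FALSE)
  delta <- rep_len(config$output_weights, Np)
  lambda <- rep_len(config$move_weights, length(du))
  sum(delta * (predicted - reference)^2) + sum(lambda * du^2)
}

# Predicted lactate concentration path given predicted cumulative lactate
# and the move sequence: exchange first (fraction du/V), production within
# the period afterwards.
predict_concentration <- function(yhat, du_full, C_now, C0, V, y_now) {
  Np <- length(yhat)
  C <- numeric(Np)
  Cpre <- numeric(Np)
  prev_y <- y_now
  Cc <- C_now
  for (j in seq_len(Np)) {
    U <- min(du_full[j] / V, 1)
    Cpre[j] <- Cc
    Cc <- Cc * (1 - U) + C0 * U
    Cc <- Cc + (yhat[j] - prev_y)
    prev_y <- yhat[j]
    C[j] <- Cc
  }
  list(post = C, pre = Cpre)
}

#' Solve one receding-horizon step
#'
#' Minimises [cost_J()] over the move sequence. The unconstrained problem
#' is solved in closed form from the stacked prediction equations
#' `yhat = f + G du`; box bounds on the moves are handled as a
#' box-constrained quadratic program; an optional lactate-concentration cap
#' is enforced by iteratively raising the move lower bounds until the
#' predicted concentration path (exchange first, production after) stays
#' below the cap.
#'
#' @inheritParams predict_horizon
#' @param reference_window Reference values `r(k+1) ... r(k+Np)`; shorter
#'   windows shrink the horizon near the record end.
#' @param config An [mpc_config()].
#' @param conc_state List with `C` (current concentration, mM), `C0`
#'   (baseline, mM) and `V` (working volume, mL); required when
#'   `config$y_max` is set.
#' @return List with `du` (optimal moves), `predicted`, `cost`, and the
#'   free response `free`.
#' @export
solve_step <- function(model, history, reference_window, config,
                       conc_state = NULL) {
  Np <- min(config$np_horizon, length(reference_window))
  Nc <- min(config$nc_horizon, Np)
  r <- reference_window[seq_len(Np)]
  delta <- rep_len(config$output_weights, Np)
  lambda <- rep_len(config$move_weights, Nc)

  free <- predict_horizon(model, history, rep(0, Nc), Np)
  G <- matrix(0, Np, Nc)
  for (i in seq_len(Nc)) {
    ei <- rep(0, Nc); ei[i] <- 1
    G[, i] <- predict_horizon(model, history, ei, Np) - free
  }

  Hmat <- t(G) %*% (delta * G) + diag(lambda, Nc)
  g <- t(G) %*% (delta * (r - free))
  ridge <- 1e-10 * max(1, sum(diag(Hmat)))
  du_free <- tryCatch(drop(solve(Hmat, g)),
                      error = function(e)
                        drop(solve(Hmat + diag(ridge, Nc), g)))

  lb <- rep(config$u_min, Nc)
  ub <- rep(config$u_max, Nc)

  clipq <- function(lb) {
    if (all(du_free >= lb) && all(du_free <= ub)) return(pmin(pmax(du_free, lb), ub))
    obj <- function(x) cost_J(free + drop(G %*% x), r, x, config)
    grad <- function(x) drop(2 * (Hmat %*% x - g))
    start <- pmin(pmax(du_free, lb), ub)
    res <- stats::optim(start, obj, grad, method = "L-BFGS-B",
                        lower = lb, upper = ub,
                        control = list(factr = 1e4, maxit = 500))
    res$par
  }

  du <- clipq(lb)

  if (is.finite(config$y_max)) {
    if (is.null(conc_state)) {
      stop("y_max constraint requires conc_state (C, C0, V)", call. = FALSE)
    }
    y_now <- history$y[length(history$y)]
    for (iter in 1:25) {
      du_full <- c(du, rep(0, Np - Nc))
      yhat <- free + drop(G %*% du)
      cp <- predict_concentration(yhat, du_full, conc_state$C, conc_state$C0,
                                  conc_state$V, y_now)
      viol <- which(cp$post > config$y_max + 1e-9)
      if (!length(viol)) break
      j <- viol[1]
      m <- min(j, Nc)
      head_room <- cp$pre[m] - conc_state$C0
      if (head_room <= 1e-9) {
        stop("lactate cap infeasible: no dilution head-room", call. = FALSE)
      }
      extra <- (cp$post[j] - config$y_max) / head_room * conc_state$V
      lb[m] <- max(lb[m], du[m] + extra * 1.0001)
      if (lb[m] > ub[m] + 1e-12) {
        stop("lactate cap infeasible under the move bounds", call. = FALSE)
      }
      du <- clipq(lb)
    }
  }

  predicted <- free + drop(G %*% du)
  list(du = du, predicted = predicted, free = free,
       cost = cost_J(predicted, r, du, config))
}

#' Closed-loop receding-horizon simulation
#'
#' At each control period the controller (optionally) re-estimates the
#' time-varying gain from the data observed so far, solves for the optimal
#' move sequence and applies the first move to the plant, which then
#' advances one sample. The plant is either a [darx_model()] (simulated on
#' its own recursion, optionally with relative output noise) or a
#' [virtual_plant()] culture.
#'
#' @param plant A `darx_model` or `virtual_plant`.
#' @param reference Reference cumulative-lactate trajectory: numeric vector
#'   on the hourly grid, or a `trajectory_pair` (whose `u` then also serves
#'   as the reference input for the input-fit NRMSE).
#' @param config An [mpc_config()].
#' @param estimator Optional [estimation_config()]; when given (and
#'   `config$adaptive`), the gain is re-identified from closed-loop data at
#'   every decision once `min_fit_samples` are available.
#' @param model Prediction model when not adaptive; defaults to the plant
#'   itself when the plant is a `darx_model` (perfect-model case).
#' @param noise Relative (multiplicative) output noise standard deviation
#'   applied to the realised output each sample (e.g. `0.01` for 1 %).
#' @param seed RNG seed for the noise draws.
#' @param u0 Initial cumulative medium (mL); defaults to the reference
#'   pair's initial value, else 0.
#' @param dilution List `(C0, V)` enabling concentration bookkeeping (and
#'   required when `config$y_max` is set and the plant is a `darx_model`).
#' @param min_fit_samples Samples required before adaptive re-estimation
#'   starts (default 12).
#' @return An object of class `control_trace`: list with `grid`,
#'   `reference`, `applied_u`, `du`, `realized_y`, `concentration` (or
#'   `NULL`), per-decision `cost`, `output_nrmse` and `input_nrmse` (or
#'   `NA`).
#' @export
receding_horizon_simulate <- function(plant, reference, config = mpc_config(),
                                      estimator = NULL, model = NULL,
                                      noise = 0, seed = NULL, u0 = NULL,
                                      dilution = NULL, min_fit_samples = 12) {
  if (inherits(reference, "trajectory_pair")) {
    r <- reference$y
    u_ref <- reference$u
    if (is.null(u0)) u0 <- reference$u[1]
  } else {
    r <- as.numeric(reference)
    u_ref <- NULL
    if (is.null(u0)) u0 <- 0
  }
  n <- length(r)
  is_darx_plant <- inherits(plant, "darx_model")
  if (is_darx_plant && length(plant$grid) < n) {
    stop("plant grid shorter than the reference", call. = FALSE)
  }
  if (is.null(model)) {
    if (!is.null(estimator)) {
      model <- NULL  # identified online
    } else if (is_darx_plant) {
      model <- plant
    } else {
      stop("a prediction model or an estimator is required for a mechanistic plant",
           call. = FALSE)
    }
  }
  adaptive <- !is.null(estimator)
  if (!is.null(seed)) set.seed(seed)

  y <- numeric(n); y[1] <- r[1]
  u <- numeric(n); u[1] <- u0
  du_tr <- numeric(n)
  cost <- rep(NA_real_, n)
  conc <- NULL
  if (!is.null(dilution)) {
    conc <- numeric(n)
    conc[1] <- dilution$C0 + y[1]
  }
  vp_state <- if (!is_darx_plant) plant_init(plant) else NULL
  if (!is_darx_plant) y[1] <- vp_state$cum_lactate

  period <- max(1L, as.integer(round(config$control_period)))
  cur_model <- model

  for (k in seq_len(n - 1)) {
    du1 <- 0
    if ((k - 1) %% period == 0) {
      if (adaptive && k >= max(min_fit_samples, 2 * 4 + 2)) {
        ords <- if (!is.null(model)) c(model$na, model$nb) else c(1, 1)
        dly <- if (!is.null(model)) model$delay else 0
        cur_model <- tryCatch(
          estimate_darx_tv(y[1:k], u[1:k], ords, dly, estimator),
          error = function(e) cur_model)
      }
      if (!is.null(cur_model)) {
        win <- r[(k + 1):min(n, k + config$np_horizon)]
        cs <- if (!is.null(conc)) {
          list(C = conc[k], C0 = dilution$C0, V = dilution$V)
        } else NULL
        sol <- solve_step(cur_model, list(y = y[1:k], u = u[1:k]), win,
                          config, conc_state = cs)
        du1 <- sol$du[1]
        cost[k] <- sol$cost
      }
    }
    du_tr[k + 1] <- du1
    u[k + 1] <- u[k] + du1

    if (is_darx_plant) {
      cf <- coef_at(plant, k + 1)
      acc <- 0
      for (i in seq_len(plant$na)) if (k + 1 - i >= 1) acc <- acc - cf$a[i] * y[k + 1 - i]
      for (jj in seq_len(plant$nb) - 1L) {
        s <- k + 1 - plant$delay - jj
        if (s >= 1) acc <- acc + cf$b[jj + 1L] * u[s]
      }
      if (noise > 0) acc <- acc * (1 + stats::rnorm(1, sd = noise))
      y[k + 1] <- acc
    } else {
      frac <- min(du1 / vp_state$params$working_volume, 1)
      if (frac > 0) vp_state <- apply_replacement(vp_state, frac)
      vp_state <- plant_run(vp_state, duration = 1)
      yk <- vp_state$cum_lactate
      if (noise > 0) yk <- yk * (1 + stats::rnorm(1, sd = noise))
      y[k + 1] <- yk
    }
    if (!is.finite(y[k + 1])) stop("plant diverged (non-finite output)", call. = FALSE)

    if (!is.null(conc)) {
      U <- min(du1 / dilution$V, 1)
      conc[k + 1] <- (conc[k] * (1 - U) + dilution$C0 * U) + (y[k + 1] - y[k])
    }
  }

  structure(list(grid = seq_len(n) - 1, reference = r, applied_u = u,
                 du = du_tr, realized_y = y, concentration = conc,
                 cost = cost,
                 output_nrmse = tryCatch(nrmse(r, y), error = function(e) NA_real_),
                 input_nrmse = if (!is.null(u_ref)) {
                   tryCatch(nrmse(u_ref, u), error = function(e) NA_real_)
                 } else NA_real_),
            class = "control_trace")
}

#' @export
print.control_trace <- function(x, ...) {
  cat(sprintf("<control_trace> %d samples; output NRMSE %.4f, input NRMSE %s, total medium %.3g mL\n",
              length(x$grid), x$output_nrmse,
              if (is.na(x$input_nrmse)) "NA" else sprintf("%.4f", x$input_nrmse),
              x$applied_u[length(x$applied_u)]))
  invisible(x)
}

#' Write a control trace to CSV
#'
#' @param trace A `control_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_h = trace$grid, reference = trace$reference,
                   applied_u_mL = trace$applied_u, du_mL = trace$du,
                   realized_y_mM = trace$realized_y)
  if (!is.null(trace$concentration)) df$concentration_mM <- trace$concentration
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
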