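#' Latent parameters of a virtual donor
#'
#' Parameters of the mechanistic virtual culture: logistic growth with
#' Monod limitation on a lumped substrate proxy (glucose plus growth
#' factors) and non-competitive lactate inhibition, plus growth-anchored
#' lactate production with the 2:1 lactate:substrate yield of anaerobic
#' glycolysis. Default means are calibrated so a five-day 12-well expansion
#' yields 1-2.4e5 cells and 10-16 mM-equivalent cumulative lactate under
#' the benchmark feeding strategies (see the packaged
#' `default_donor_params.yaml`).
#'
#' @param mu_max Maximum specific growth rate (1/h).
#' @param Ks Substrate half-saturation (mM-equivalent of the proxy).
#' @param q_lac Specific lactate production (mM per 1e5 cells per h).
#' @param K_inhib Lactate growth-inhibition constant (mM).
#' @param death_max Maximum specific death rate under full substrate
#'   starvation (1/h); cells die when the maintenance pathway is starved.
#' @param X0 Seeded cells (3300 cells/cm2 on 3.8 cm2 wells).
#' @param Xmax Confluence cap (cells).
#' @param baseline_S Substrate proxy concentration of fresh medium (mM-eq).
#' @param baseline_L Lactate concentration of fresh medium (mM).
#' @param working_volume Working volume (mL).
#' @return An object of class `donor_params`.
#' @export
donor_params <- function(mu_max = 0.10, Ks = 2.0, q_lac = 0.13,
                         K_inhib = 3, death_max = 0.08, X0 = 12500,
                         Xmax = 3.2e5, baseline_S = 5, baseline_L = 1,
                         working_volume = 1) {
  if (any(c(mu_max, Ks, q_lac, K_inhib, death_max) < 0)) {
    stop("rates must be >= 0", call. = FALSE)
  }
  if (X0 >= Xmax) stop("X0 must be below Xmax", call. = FALSE)
  structure(list(mu_max = mu_max, Ks = Ks, q_lac = q_lac,
                 K_inhib = K_inhib, death_max = death_max, X0 = X0,
                 Xmax = Xmax, baseline_S = baseline_S,
                 baseline_L = baseline_L, working_volume = working_volume),
            class = "donor_params")
}

#' Packaged default donor parameter distribution
#'
#' Means and coefficients of variation used by [generate_dataset()] to draw
#' virtual donors, from `inst/extdata/default_donor_params.yaml`.
#'
#' @return List with `means` (a [donor_params()]) and `cv` (named vector).
#' @export
default_donor_params <- function() {
  cfg <- yaml::read_yaml(system.file("extdata", "default_donor_params.yaml",
                                     package = "lactomc"))
  list(means = do.call(donor_params, cfg$means),
       cv = unlist(cfg$cv))
}

#' Initialise the virtual plant state
#'
#' @param params A [donor_params()] (or a `virtual_plant`, whose parameters
#'   are taken).
#' @return A `plant_state`: list with `t` (h), `X` (cells), `S`, `L` (mM),
#'   `cum_medium` (mL), `cum_lactate` (mM-equivalent) and `params`.
#' @export
plant_init <- function(params) {
  if (inherits(params, "virtual_plant")) params <- params$params
  structure(list(t = 0, X = params$X0, S = params$baseline_S,
                 L = params$baseline_L, cum_medium = params$working_volume,
                 cum_lactate = 0, params = params),
            class = "plant_state")
}

#' Wrap donor parameters as a closed-loop plant
#'
#' A thin wrapper marking a parameter set as a mechanistic plant for
#' [receding_horizon_simulate()].
#'
#' @param params A [donor_params()].
#' @return An object of class `virtual_plant`.
#' @export
virtual_plant <- function(params) {
  structure(list(params = params), class = "virtual_plant")
}

# Growth saturates at Ks; lactate production (maintenance glycolysis)
# saturates ten times lower, so starved cultures keep producing lactate
# after proliferation has stalled. Sustained starvation of the maintenance
# pathway kills cells (rate death_max at S = 0), which is what drives the
# high lactate-per-harvested-cell ratio of under-fed cultures.
plant_deriv <- function(x, p) {
  S <- max(x[2], 0)
  Ks_p <- p$Ks / 10
  mono_g <- S / (p$Ks + S)
  mono_p <- S / (Ks_p + S)
  inhib <- p$K_inhib / (p$K_inhib + max(x[3], 0))
  logi <- max(0, 1 - x[1] / p$Xmax)
  mu <- p$mu_max * mono_g * inhib * logi
  kd <- p$death_max * (1 - mono_p)
  prod <- p$q_lac * (x[1] / 1e5) * mono_p
  c((mu - kd) * x[1], -prod / 2, prod, prod)
}

#' Advance the plant one time step
#'
#' Classical fixed-step fourth-order Runge-Kutta update of the growth /
#' substrate / lactate system; local error is O(dt^5), so one step and two
#' half-steps agree to O(dt^4) globally.
#'
#' @param state A `plant_state`.
#' @param params Parameters (default: the state's own).
#' @param dt Step size (h), > 0.
#' @return Updated `plant_state`.
#' @export
step_plant <- function(state, params = state$params, dt = 0.1) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  x <- c(state$X, state$S, state$L, state$cum_lactate)
  k1 <- plant_deriv(x, params)
  k2 <- plant_deriv(x + dt / 2 * k1, params)
  k3 <- plant_deriv(x + dt / 2 * k2, params)
  k4 <- plant_deriv(x + dt * k3, params)
  x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  state$X <- x[1]
  state$S <- max(x[2], 0)
  state$L <- x[3]
  state$cum_lactate <- x[4]
  state$t <- state$t + dt
  state
}

#' Apply a medium replacement to the plant
#'
#' Dilutes substrate and lactate towards their fresh-medium baselines by
#' the exchanged fraction; cell number and the production bookkeeping
#' (`cum_lactate`) are unaffected; `cum_medium` increases by
#' `fraction * working_volume`.
#'
#' @param state A `plant_state`.
#' @param fraction Fraction of the working volume replaced, in `[0, 1]`.
#' @param baseline_S,baseline_L Fresh-medium concentrations (defaults: the
#'   plant's own baselines).
#' @return Updated `plant_state`.
#' @export
apply_replacement <- function(state, fraction,
                              baseline_S = state$params$baseline_S,
                              baseline_L = state$params$baseline_L) {
  state$S <- dilution_update(state$S, baseline_S, fraction)
  state$L <- dilution_update(state$L, baseline_L, fraction)
  state$cum_medium <- state$cum_medium + fraction * state$params$working_volume
  state
}

# Integrate for `duration` hours with fixed-step RK4.
plant_run <- function(state, duration, dt = 0.1) {
  nsteps <- round(duration / dt)
  if (abs(nsteps * dt - duration) > 1e-9) {
    stop("duration must be a multiple of dt", call. = FALSE)
  }
  for (i in seq_len(nsteps)) state <- step_plant(state, dt = dt)
  state
}

#' Simulate one well under a feeding schedule
#'
#' Runs the virtual culture for the five-day protocol: daily analytical
#' samples at 0, 24, ..., 120 h (drawn just *before* the exchange on
#' replacement days), medium exchanges at 24-96 h per the schedule, harvest
#' at 120 h. The time-zero sample is the fresh-medium calibration value;
#' later samples carry multiplicative log-normal measurement noise.
#'
#' @param params A [donor_params()].
#' @param schedule A [feeding_schedule()].
#' @param noise Relative measurement noise (log-normal sigma), default 0.03.
#' @param seed Optional RNG seed; identical seeds reproduce the record.
#' @param dt Integration step (h).
#' @return A [culture_record()] with the noiseless plant trajectory at
#'   sample times attached as attribute `"truth"`.
#' @export
run_condition <- function(params, schedule, noise = 0.03, seed = NULL,
                          dt = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  period <- schedule$replacement_period
  n_days <- length(schedule$daily_fractions) + 1
  state <- plant_init(params)
  times <- c(0, period * seq_len(n_days))
  conc <- numeric(length(times))
  truth <- data.frame(time = times, X = NA_real_, S = NA_real_, L = NA_real_,
                      cum_lactate = NA_real_)
  conc[1] <- params$baseline_L
  truth[1, -1] <- c(state$X, state$S, state$L, state$cum_lactate)

  events <- data.frame(time = numeric(0), fraction = numeric(0),
                       pre_concentration = numeric(0))
  for (d in seq_len(n_days)) {
    state <- plant_run(state, duration = period, dt = dt)
    state$t <- period * d  # exact clock at sample times
    meas <- state$L * exp(stats::rnorm(1, sd = noise))
    conc[d + 1] <- meas
    truth[d + 1, -1] <- c(state$X, state$S, state$L, state$cum_lactate)
    if (d <= length(schedule$daily_fractions)) {
      frac <- schedule$daily_fractions[d]
      events <- rbind(events,
                      data.frame(time = state$t, fraction = frac,
                                 pre_concentration = NA_real_))
      state <- apply_replacement(state, frac)
    }
  }
  harvested <- state$X * exp(stats::rnorm(1, sd = noise))
  rec <- culture_record(
    well_id = sprintf("c%d", schedule$condition_id),
    working_volume = params$working_volume,
    baseline_concentration = params$baseline_L,
    samples = data.frame(time = times, concentration = conc),
    events = events,
    harvested_cells = harvested,
    culture_span = times[length(times)])
  attr(rec, "truth") <- truth
  rec
}

#' Generate a full synthetic expansion study
#'
#' Emulates the benchmark study design: `n_donors` virtual donors drawn
#' from the packaged parameter distribution (log-normal around the default
#' means with the documented CVs), each cultured under every condition in
#' `conditions` with `n_replicates` replicate wells (5 % seeding-density
#' jitter between replicates). Fully reproducible from `master_seed`.
#'
#' @param n_donors,n_replicates Study dimensions (defaults 3 and 3).
#' @param conditions Condition ids from the benchmark schedule table.
#' @param master_seed Integer seed driving every draw.
#' @param noise Relative measurement noise passed to [run_condition()].
#' @return List of [culture_record()]s with well ids `d<donor>_c<cond>_r<rep>`
#'   and the drawn `donor_params` attached as attribute `"donors"`.
#' @export
generate_dataset <- function(n_donors = 3, n_replicates = 3,
                             conditions = 1:6, master_seed = 1,
                             noise = 0.03) {
  defaults <- default_donor_params()
  sched <- benchmark_schedules()
  set.seed(master_seed)
  donors <- lapply(seq_len(n_donors), function(d) {
    m <- defaults$means
    draw <- function(mean, cv) {
      if (cv <= 0) return(mean)
      stats::rlnorm(1, meanlog = log(mean) - 0.5 * log(1 + cv^2),
                    sdlog = sqrt(log(1 + cv^2)))
    }
    donor_params(
      mu_max = draw(m$mu_max, defaults$cv[["mu_max"]]),
      Ks = draw(m$Ks, defaults$cv[["Ks"]]),
      q_lac = draw(m$q_lac, defaults$cv[["q_lac"]]),
      K_inhib = draw(m$K_inhib, defaults$cv[["K_inhib"]]),
      death_max = draw(m$death_max, defaults$cv[["death_max"]]),
      X0 = m$X0, Xmax = draw(m$Xmax, defaults$cv[["Xmax"]]),
      baseline_S = m$baseline_S, baseline_L = m$baseline_L,
      working_volume = m$working_volume)
  })
  records <- list()
  for (d in seq_len(n_donors)) {
    for (cond in conditions) {
      for (r in seq_len(n_replicates)) {
        p <- donors[[d]]
        p$X0 <- p$X0 * exp(stats::rnorm(1, sd = 0.05))
        seed_r <- sample.int(.Machine$integer.max, 1)
        rec <- run_condition(p, sched$schedules[[as.character(cond)]],
                             noise = noise, seed = seed_r)
        rec$well_id <- sprintf("d%d_c%d_r%d", d, cond, r)
        records[[rec$well_id]] <- rec
      }
    }
  }
  attr(records, "donors") <- donors
  records
}

#' Write a generated dataset as culture CSV files
#'
#' One CSV per well plus a `manifest.csv` listing the files.
#'
#' @param records Output of [generate_dataset()].
#' @param out_dir Directory, created if needed.
#' @return Paths of the written files, invisibly.
#' @export
write_dataset <- function(records, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(records, function(r) {
    p <- file.path(out_dir, paste0(r$well_id, ".csv"))
    write_culture_csv(r, p)
    p
  }, character(1))
  manifest <- data.frame(well_id = names(paths), file = basename(paths))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}
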