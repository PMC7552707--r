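# Shared fixtures and independent oracles used across the test files.

# A small hand-checkable record: baseline 1 mM, one 50% exchange at 24 h.
simple_record <- function() {
  culture_record(
    well_id = "toy",
    working_volume = 1,
    baseline_concentration = 1,
    samples = data.frame(time = c(0, 24, 48),
                         concentration = c(1, 4, 3)),
    events = data.frame(time = 24, fraction = 0.5, pre_concentration = 4),
    culture_span = 48)
}

# Random valid record with explicit pre-event concentrations.
random_record <- function(n_days = 5, V = NULL, C0 = NULL) {
  V <- V %||% runif(1, 0.5, 2)
  C0 <- C0 %||% runif(1, 0.2, 2)
  times <- 0:n_days * 24
  conc <- C0 + c(0, cumsum(runif(n_days, 0, 3)))  # grows between samples
  ev_days <- sort(sample(seq_len(n_days - 1), sample(1:(n_days - 1), 1)))
  events <- data.frame(time = ev_days * 24,
                       fraction = runif(length(ev_days), 0, 1),
                       pre_concentration = NA_real_)
  # sample at event time is the pre-exchange measurement; dilute the
  # following samples accordingly so the record is self-consistent
  for (k in seq_len(nrow(events))) {
    i <- match(events$time[k], times)
    drop_ <- (conc[i] - dilution_update(conc[i], C0, events$fraction[k]))
    conc[(i + 1):length(conc)] <- conc[(i + 1):length(conc)] - drop_
  }
  conc <- pmax(conc, 0)
  culture_record(well_id = "rand", working_volume = V,
                 baseline_concentration = C0,
                 samples = data.frame(time = times, concentration = conc),
                 events = events, culture_span = max(times))
}

# Amount-bookkeeping oracle for produced lactate: walk the timeline
# tracking mmol in the well; produced = final amount - initial amount +
# removed amounts - supplied baseline amounts. Returns mM-equivalent.
oracle_cumulative_lactate <- function(record) {
  s <- record$samples
  e <- record$events
  V <- record$working_volume
  C0 <- record$baseline_concentration
  out <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    t <- s$time[i]
    amount_now <- V * s$concentration[i]
    removed <- supplied <- 0
    for (k in seq_len(nrow(e))) {
      if (nrow(e) == 0 || e$time[k] >= t) next
      C1 <- if (is.finite(e$pre_concentration[k])) e$pre_concentration[k] else {
        s$concentration[match(e$time[k], s$time)]
      }
      removed <- removed + e$fraction[k] * V * C1
      supplied <- supplied + e$fraction[k] * V * C0
    }
    out[i] <- (amount_now - V * C0 + removed - supplied) / V
  }
  out
}

# Brute-force per-segment linear interpolation oracle.
oracle_interp <- function(kt, ky, t) {
  vapply(t, function(tt) {
    for (k in seq_len(length(kt) - 1)) {
      if (tt >= kt[k] && tt <= kt[k + 1]) {
        w <- (tt - kt[k]) / (kt[k + 1] - kt[k])
        return((1 - w) * ky[k] + w * ky[k + 1])
      }
    }
    stop("outside span")
  }, numeric(1))
}

# Textbook re-implementation of the goodness-of-fit NRMSE.
oracle_nrmse <- function(ref, fit) {
  num <- 0
  den <- 0
  mr <- sum(ref) / length(ref)
  for (i in seq_along(ref)) {
    num <- num + (ref[i] - fit[i])^2
    den <- den + (ref[i] - mr)^2
  }
  1 - sqrt(num) / sqrt(den)
}

# Brute-force DARX difference-equation oracle (time-constant coefficients).
oracle_darx_sim <- function(a, b, delay, u) {
  n <- length(u)
  y <- numeric(n)
  na <- length(a); nb <- length(b)
  for (t in seq_len(n)) {
    acc <- 0
    for (i in seq_len(na)) if (t - i >= 1) acc <- acc - a[i] * y[t - i]
    for (j in seq_len(nb) - 1L) {
      s <- t - delay - j
      if (s >= 1) acc <- acc + b[j + 1L] * u[s]
    }
    y[t] <- acc
  }
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
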