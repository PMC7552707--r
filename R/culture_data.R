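#' Dilution mass balance for a medium replacement
#'
#' Concentration of a solute in the well immediately after a fraction
#' `fraction` of the working volume is exchanged for fresh medium:
#' `C2 = C1 * (1 - U) + C0 * U`.
#'
#' @param pre_concentration Concentration just before the exchange (mM).
#' @param baseline Concentration of fresh medium (mM).
#' @param fraction Fraction of the working volume replaced, in `[0, 1]`.
#' @return Post-replacement concentration (mM), always between
#'   `min(baseline, pre_concentration)` and `max(baseline, pre_concentration)`.
#' @examples
#' dilution_update(6, 2, 0.5) # 4
#' @export
dilution_update <- function(pre_concentration, baseline, fraction) {
  if (any(fraction < 0 | fraction > 1)) {
    stop("replacement fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(pre_concentration < 0) || any(baseline < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  pre_concentration * (1 - fraction) + baseline * fraction
}

#' Invert the dilution balance for the pre-replacement concentration
#'
#' Given the concentration just after an exchange, recover the concentration
#' just before it: `C1 = (C2 - C0 * U) / (1 - U)`. Undefined for a full
#' (100 %) exchange, which erases all pre-event information.
#'
#' @inheritParams dilution_update
#' @param post_concentration Concentration just after the exchange (mM).
#' @return Pre-replacement concentration (mM).
#' @export
invert_dilution <- function(post_concentration, baseline, fraction) {
  if (any(fraction < 0 | fraction > 1)) {
    stop("replacement fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(fraction >= 1)) {
    stop("pre-replacement concentration is unrecoverable after a 100% exchange",
         call. = FALSE)
  }
  (post_concentration - baseline * fraction) / (1 - fraction)
}

#' Construct a culture record
#'
#' One well's measurement history: daily lactate samples, the medium
#' replacement log, and endpoint cell count. Samples taken at an event time
#' are interpreted as *pre*-replacement measurements (sample first, then
#' exchange), which is the wet-lab sampling order.
#'
#' @param well_id Identifier string (donor/condition/replicate).
#' @param working_volume Working volume of the well (mL).
#' @param baseline_concentration Lactate concentration of fresh medium (mM).
#' @param samples `data.frame` with columns `time` (h since seeding) and
#'   `concentration` (mM); times strictly increasing, first row at time 0
#'   with the baseline concentration.
#' @param events `data.frame` with columns `time` (h), `fraction` (of the
#'   working volume, in `[0, 1]`) and `pre_concentration` (mM, `NA` when the
#'   pre-exchange concentration was not measured directly).
#' @param harvested_cells Endpoint cell count, or `NA`.
#' @param culture_span Total culture time (h), default 120.
#' @return An object of class `culture_record`.
#' @export
culture_record <- function(well_id, working_volume, baseline_concentration,
                           samples, events = NULL, harvested_cells = NA_real_,
                           culture_span = 120) {
  if (is.null(events)) {
    events <- data.frame(time = numeric(0), fraction = numeric(0),
                         pre_concentration = numeric(0))
  }
  if (is.null(events$pre_concentration)) events$pre_concentration <- NA_real_
  rec <- structure(
    list(well_id = as.character(well_id),
         working_volume = as.numeric(working_volume),
         baseline_concentration = as.numeric(baseline_concentration),
         samples = as.data.frame(samples),
         events = as.data.frame(events),
         harvested_cells = as.numeric(harvested_cells),
         culture_span = as.numeric(culture_span)),
    class = "culture_record")
  validate_culture_record(rec)
  rec
}

#' Validate a culture record's invariants
#'
#' @param record A `culture_record`.
#' @param baseline_tol Absolute tolerance for the time-zero sample matching
#'   the fresh-medium baseline (the time-zero draw is a calibration sample).
#' @return The record, invisibly; errors describe the first violation.
#' @export
validate_culture_record <- function(record, baseline_tol = 1e-6) {
  s <- record$samples
  e <- record$events
  if (record$working_volume <= 0) stop("working_volume must be > 0", call. = FALSE)
  if (record$baseline_concentration < 0) stop("baseline_concentration must be >= 0", call. = FALSE)
  if (nrow(s) < 1 || s$time[1] != 0) stop("first sample must be at time 0", call. = FALSE)
  if (any(diff(s$time) <= 0)) stop("sample times must be strictly increasing", call. = FALSE)
  if (any(s$concentration < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (abs(s$concentration[1] - record$baseline_concentration) > baseline_tol) {
    stop("time-zero sample must equal the baseline concentration", call. = FALSE)
  }
  if (nrow(e)) {
    if (any(e$time <= 0)) stop("event times must be > 0", call. = FALSE)
    if (any(diff(e$time) <= 0)) stop("event times must be strictly increasing", call. = FALSE)
    if (any(e$fraction < 0 | e$fraction > 1)) stop("event fractions must lie in [0, 1]", call. = FALSE)
  }
  invisible(record)
}

#' @export
print.culture_record <- function(x, ...) {
  cat(sprintf("<culture_record> %s: %d samples over %g h, %d replacement events, V = %g mL\n",
              x$well_id, nrow(x$samples), x$culture_span, nrow(x$events),
              x$working_volume))
  if (is.finite(x$harvested_cells)) {
    cat(sprintf("  harvested cells: %.3g\n", x$harvested_cells))
  }
  invisible(x)
}

# Resolve C1(k) for every event: measured value, a sample taken at the event
# time (pre-replacement by convention), or Eq-2 inversion from the first
# sample after the event (assumed drawn immediately after the exchange).
resolve_event_pre <- function(record) {
  e <- record$events
  if (!nrow(e)) return(numeric(0))
  s <- record$samples
  C0 <- record$baseline_concentration
  vapply(seq_len(nrow(e)), function(k) {
    if (is.finite(e$pre_concentration[k])) return(e$pre_concentration[k])
    at <- which(s$time == e$time[k])
    if (length(at)) return(s$concentration[at[1]])
    nxt_event <- if (k < nrow(e)) e$time[k + 1] else Inf
    after <- which(s$time > e$time[k] & s$time <= nxt_event)
    if (!length(after) || e$fraction[k] >= 1) {
      stop(sprintf(
        "event at %g h: pre-replacement concentration missing and not reconstructible",
        e$time[k]), call. = FALSE)
    }
    invert_dilution(s$concentration[after[1]], C0, e$fraction[k])
  }, numeric(1))
}

#' Cumulative lactate produced by the cells
#'
#' Mass balance converting measured concentrations plus the replacement log
#' into total lactate produced since seeding, expressed per working volume
#' (mM-equivalent): `y(t) = (C(t) - C0) + sum over events before t of
#' U(k) * (C1(k) - C0)`. A sample drawn at an event time is pre-replacement,
#' so that event's removal term only enters at later times; `y` is continuous
#' across exchanges.
#'
#' @param record A `culture_record`.
#' @param at_times Times (h) at which to evaluate; must be sample times of
#'   the record. Defaults to all sample times.
#' @return Numeric vector of cumulative lactate (mM-equivalent), `y(0) = 0`.
#' @export
cumulative_lactate <- function(record, at_times = record$samples$time) {
  validate_culture_record(record, baseline_tol = Inf)
  s <- record$samples
  e <- record$events
  C0 <- record$baseline_concentration
  pre <- resolve_event_pre(record)
  idx <- match(at_times, s$time)
  if (anyNA(idx)) {
    stop("at_times must be measured sample times; interpolate afterwards instead",
         call. = FALSE)
  }
  vapply(seq_along(idx), function(i) {
    t <- at_times[i]
    before <- which(e$time < t)
    removed <- if (length(before)) sum(e$fraction[before] * (pre[before] - C0)) else 0
    (s$concentration[idx[i]] - C0) + removed
  }, numeric(1))
}

#' Convert mM-equivalent cumulative lactate to absolute mmol
#'
#' The canonical internal unit is mmol per litre of working volume; multiply
#' by the working volume in litres to obtain absolute amounts.
#'
#' @param mM_equivalent Cumulative lactate series (mM-equivalent).
#' @param working_volume Working volume (mL).
#' @return Amounts in mmol.
#' @export
lactate_mmol <- function(mM_equivalent, working_volume) {
  mM_equivalent * working_volume / 1000
}

#' Construct a feeding schedule
#'
#' Daily medium-replacement fractions for the four exchange days of a
#' five-day expansion, one exchange per `replacement_period` hours.
#'
#' @param condition_id Integer label (1-6 for the benchmark strategies).
#' @param daily_fractions Fractions of the working volume replaced on days
#'   1-4, each in `[0.1, 1]` (at least 10 % must be exchanged because the
#'   daily analytical sample is drawn from the removed medium).
#' @param replacement_period Hours between exchanges (default 24).
#' @return An object of class `feeding_schedule`.
#' @export
feeding_schedule <- function(condition_id, daily_fractions,
                             replacement_period = 24) {
  if (any(daily_fractions < 0.10 - 1e-12 | daily_fractions > 1)) {
    stop("daily fractions must lie in [0.10, 1]", call. = FALSE)
  }
  structure(list(condition_id = as.integer(condition_id),
                 daily_fractions = as.numeric(daily_fractions),
                 replacement_period = as.numeric(replacement_period)),
            class = "feeding_schedule")
}

#' @export
print.feeding_schedule <- function(x, ...) {
  cat(sprintf("<feeding_schedule> condition %d: %s%% every %g h\n",
              x$condition_id, paste(100 * x$daily_fractions, collapse = "/"),
              x$replacement_period))
  invisible(x)
}

#' Event times of a feeding schedule
#' @param schedule A `feeding_schedule`.
#' @return Exchange times in hours since seeding.
#' @export
schedule_event_times <- function(schedule) {
  schedule$replacement_period * seq_along(schedule$daily_fractions)
}

#' Cumulative medium use under a feeding schedule
#'
#' @param schedule A `feeding_schedule`.
#' @param working_volume Working volume (mL).
#' @param include_initial_fill Count the seeding fill (one working volume)
#'   in the total? Default `TRUE`: this is the convention under which
#'   harvested cells divided by total medium reproduces the benchmark
#'   efficiency table.
#' @return List with `times` (h, the event times, preceded by 0 when the
#'   initial fill is included), `cumulative` (mL at those times) and
#'   `total` (mL).
#' @export
cumulative_medium <- function(schedule, working_volume,
                              include_initial_fill = TRUE) {
  times <- schedule_event_times(schedule)
  add <- schedule$daily_fractions * working_volume
  fill <- if (include_initial_fill) working_volume else 0
  cum <- fill + cumsum(add)
  list(times = c(0, times),
       cumulative = c(fill, cum),
       total = fill + sum(add))
}

#' Medium-use efficiency
#'
#' Cells harvested per millilitre of medium used over the whole culture.
#'
#' @param harvested_cells Endpoint cell count.
#' @param total_medium Total medium used (mL), including the seeding fill by
#'   the packaged convention.
#' @return Cells per mL.
#' @export
medium_efficiency <- function(harvested_cells, total_medium) {
  if (any(total_medium <= 0)) stop("total_medium must be > 0", call. = FALSE)
  harvested_cells / total_medium
}

#' Endpoint lactate production rate per cell
#'
#' Total accumulated lactate divided by endpoint cell number and culture
#' span.
#'
#' @param total_lactate Accumulated lactate at harvest (mM-equivalent).
#' @param harvested_cells Endpoint cell count (> 0).
#' @param span Culture span in hours (> 0), 120 for the five-day protocol.
#' @return Rate in mM per cell per hour.
#' @export
lactate_per_cell_rate <- function(total_lactate, harvested_cells, span) {
  if (any(harvested_cells <= 0)) stop("harvested_cells must be > 0", call. = FALSE)
  if (any(span <= 0)) stop("span must be > 0", call. = FALSE)
  total_lactate / harvested_cells / span
}

#' Write a culture record to CSV
#'
#' Plain-text format: `#key=value` metadata lines followed by a header
#' `time_h,lactate_mM,event_fraction,event_pre_mM`. Sample rows leave the
#' event columns empty; event rows without a co-timed sample leave
#' `lactate_mM` empty.
#'
#' @param record A `culture_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_culture_csv <- function(record, path) {
  s <- record$samples
  e <- record$events
  times <- sort(unique(c(s$time, e$time)))
  rows <- vapply(times, function(t) {
    si <- match(t, s$time)
    ei <- match(t, e$time)
    paste(
      format(t, digits = 15),
      if (!is.na(si)) format(s$concentration[si], digits = 15) else "",
      if (!is.na(ei)) format(e$fraction[ei], digits = 15) else "",
      if (!is.na(ei) && is.finite(e$pre_concentration[ei]))
        format(e$pre_concentration[ei], digits = 15) else "",
      sep = ",")
  }, character(1))
  meta <- c(
    sprintf("#well_id=%s", record$well_id),
    sprintf("#working_volume_mL=%s", format(record$working_volume, digits = 15)),
    sprintf("#baseline_mM=%s", format(record$baseline_concentration, digits = 15)),
    sprintf("#harvested_cells=%s",
            if (is.finite(record$harvested_cells))
              format(record$harvested_cells, digits = 15) else ""),
    sprintf("#culture_span_h=%s", format(record$culture_span, digits = 15)))
  writeLines(c(meta, "time_h,lactate_mM,event_fraction,event_pre_mM", rows), path)
  invisible(path)
}

#' Read a culture record from CSV
#'
#' @param path File written by [write_culture_csv()] (see there for the
#'   format).
#' @return A `culture_record`.
#' @export
read_culture_csv <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- lines[meta_idx]
  get_meta <- function(key) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (!length(hit)) stop(sprintf("missing metadata line '#%s='", key), call. = FALSE)
    sub(paste0("^#", key, "="), "", hit[1])
  }
  body <- lines[-meta_idx]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = "numeric")
  expected <- c("time_h", "lactate_mM", "event_fraction", "event_pre_mM")
  if (!identical(names(df), expected)) {
    stop("culture CSV header must be ", paste(expected, collapse = ","), call. = FALSE)
  }
  first_line <- meta_idx[length(meta_idx)] + 1
  if (any(df$time_h < 0, na.rm = TRUE)) {
    bad <- which(df$time_h < 0)[1]
    stop(sprintf("negative time at line %d", first_line + bad), call. = FALSE)
  }
  if (any(df$lactate_mM < 0, na.rm = TRUE)) {
    bad <- which(df$lactate_mM < 0)[1]
    stop(sprintf("negative concentration at line %d", first_line + bad), call. = FALSE)
  }
  srows <- which(is.finite(df$lactate_mM))
  if (any(diff(df$time_h) <= 0)) {
    bad <- which(diff(df$time_h) <= 0)[1] + 1
    stop(sprintf("non-increasing time at line %d", first_line + bad), call. = FALSE)
  }
  erows <- which(is.finite(df$event_fraction))
  harvested <- suppressWarnings(as.numeric(get_meta("harvested_cells")))
  culture_record(
    well_id = get_meta("well_id"),
    working_volume = as.numeric(get_meta("working_volume_mL")),
    baseline_concentration = as.numeric(get_meta("baseline_mM")),
    samples = data.frame(time = df$time_h[srows],
                         concentration = df$lactate_mM[srows]),
    events = data.frame(time = df$time_h[erows],
                        fraction = df$event_fraction[erows],
                        pre_concentration = df$event_pre_mM[erows]),
    harvested_cells = harvested,
    culture_span = as.numeric(get_meta("culture_span_h")))
}

#' Load feeding schedules from a YAML config
#'
#' @param path YAML file with a list of entries carrying `condition`,
#'   `daily_fractions` (4 numbers, fractions of the working volume),
#'   `replacement_period_h` and `working_volume_mL`. The packaged fixture
#'   `table1.yaml` (see `system.file("extdata", "table1.yaml", package =
#'   "lactomc")`) encodes the six benchmark replacement strategies.
#' @return Named list with `schedules` (list of `feeding_schedule`) and
#'   `working_volume` (mL).
#' @export
read_schedule_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  v <- as.numeric(cfg$working_volume_mL %||% 1)
  sched <- lapply(cfg$conditions, function(row) {
    feeding_schedule(row$condition, as.numeric(row$daily_fractions),
                     as.numeric(row$replacement_period_h %||% 24))
  })
  names(sched) <- vapply(sched, function(s) as.character(s$condition_id), character(1))
  list(schedules = sched, working_volume = v)
}

#' Benchmark feeding schedules
#'
#' The six medium-replacement strategies of the benchmark hPDC expansion
#' study, loaded from the packaged `table1.yaml` fixture.
#'
#' @return As [read_schedule_yaml()].
#' @export
benchmark_schedules <- function() {
  read_schedule_yaml(system.file("extdata", "table1.yaml", package = "lactomc"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
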