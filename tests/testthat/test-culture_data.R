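test_that("dilution balance reproduces hand-worked exchanges and endpoints", {
  expect_equal(dilution_update(5, 1, 1), 1)     # full exchange -> baseline
  expect_equal(dilution_update(5, 1, 0), 5)     # no exchange
  expect_equal(dilution_update(6, 2, 0.5), 4)   # hand evaluation
  expect_error(dilution_update(5, 1, 1.2), "fraction")
  expect_error(dilution_update(-1, 1, 0.5), "non-negative")

  # affine in C1, bounded by the endpoints, on an exhaustive grid
  for (U in seq(0, 1, by = 0.05)) {
    for (C1 in seq(0, 12, by = 1.5)) {
      out <- dilution_update(C1, 2, U)
      expect_equal(out, C1 * (1 - U) + 2 * U)
      expect_gte(out, min(C1, 2) - 1e-12)
      expect_lte(out, max(C1, 2) + 1e-12)
    }
  }

  # inversion recovers the pre-exchange concentration
  expect_equal(invert_dilution(dilution_update(7, 1, 0.4), 1, 0.4), 7)
  expect_error(invert_dilution(3, 1, 1), "unrecoverable")
})

test_that("cumulative lactate mass balance matches hand results and is continuous", {
  # no events, concentration constant at baseline -> all zero
  rec0 <- culture_record("z", 1, 1,
                         data.frame(time = c(0, 24, 48), concentration = c(1, 1, 1)))
  expect_equal(cumulative_lactate(rec0), c(0, 0, 0))

  # full exchange at 24 h: y(48) = (3-1) + 1.0*(4-1) = 5
  rec1 <- culture_record("f", 1, 1,
                         data.frame(time = c(0, 24, 48), concentration = c(1, 4, 3)),
                         data.frame(time = 24, fraction = 1, pre_concentration = 4))
  expect_equal(cumulative_lactate(rec1), c(0, 3, 5))

  # half exchange: continuity across the event against the amount oracle
  rec2 <- simple_record()
  y <- cumulative_lactate(rec2)
  expect_equal(y, oracle_cumulative_lactate(rec2))
  expect_equal(y[2], 3)                      # just before the event
  # removed amount at the event is 0.5 * (4 - 1) = 1.5 mM-eq
  expect_equal(y[3], (3 - 1) + 1.5)
})

test_that("zero-fraction events do not change the mass balance", {
  rec <- simple_record()
  rec2 <- rec
  rec2$events <- rbind(rec2$events,
                       data.frame(time = 36, fraction = 0, pre_concentration = 2))
  expect_equal(cumulative_lactate(rec2), cumulative_lactate(rec))
})

test_that("pre-exchange concentrations are reconstructed or rejected", {
  # sample right after the event: inversion is exact
  C1 <- 4; U <- 0.5; C0 <- 1
  post <- dilution_update(C1, C0, U)
  rec <- culture_record("r", 1, C0,
                        data.frame(time = c(0, 25, 48), concentration = c(C0, post, 5)),
                        data.frame(time = 24, fraction = U, pre_concentration = NA))
  expect_equal(lactomc:::resolve_event_pre(rec), C1)

  # a full exchange without a co-timed sample is unrecoverable
  rec_bad <- culture_record("b", 1, C0,
                            data.frame(time = c(0, 25), concentration = c(C0, 1.5)),
                            data.frame(time = 24, fraction = 1, pre_concentration = NA))
  expect_error(cumulative_lactate(rec_bad), "24")
})

test_that("cumulative medium reproduces the benchmark schedule totals", {
  sched <- benchmark_schedules()
  totals <- vapply(as.character(1:6), function(k)
    cumulative_medium(sched$schedules[[k]], 1)$total, numeric(1))
  expect_equal(unname(totals), c(1.90, 2.24, 2.10, 1.40, 3.00, 5.00))

  # without the seeding fill
  cm6 <- cumulative_medium(sched$schedules[["6"]], 1, include_initial_fill = FALSE)
  expect_equal(cm6$total, 4)
  expect_equal(cm6$cumulative, c(0, 1, 2, 3, 4))

  # schedule invariants
  expect_error(feeding_schedule(7, c(0.05, 0.1, 0.1, 0.1)), "0.10")
})

test_that("efficiency and per-cell production follow the printed conventions", {
  expect_equal(medium_efficiency(1.48e5, 1.90), 7.79e4, tolerance = 5e-4)
  expect_equal(medium_efficiency(0, 2), 0)
  expect_error(medium_efficiency(1e5, 0), "total_medium")

  expect_equal(lactate_per_cell_rate(15, 2.37e5, 120), 5.27e-7, tolerance = 1e-3)
  expect_equal(lactate_per_cell_rate(0, 1e5, 120), 0)
  expect_equal(lactate_per_cell_rate(10, 1e5, 240),
               lactate_per_cell_rate(10, 1e5, 120) / 2)
  expect_error(lactate_per_cell_rate(10, 0, 120), "harvested_cells")
})

test_that("culture CSV round trip is exact and malformed files are rejected", {
  set.seed(11)
  rec <- random_record()
  rec$harvested_cells <- 1.7e5
  path <- tempfile(fileext = ".csv")
  write_culture_csv(rec, path)
  back <- read_culture_csv(path)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$events$fraction, rec$events$fraction, tolerance = 1e-12)
  expect_equal(back$working_volume, rec$working_volume)
  expect_equal(back$harvested_cells, rec$harvested_cells)
  expect_equal(back$baseline_concentration, rec$baseline_concentration)

  # decreasing time must be reported with its line number
  lines <- readLines(path)
  hdr <- grep("^time_h", lines)
  body <- lines[(hdr + 1):length(lines)]
  swapped <- c(lines[1:hdr], body[c(2, 1, 3:length(body))])
  bad <- tempfile(fileext = ".csv")
  writeLines(swapped, bad)
  expect_error(read_culture_csv(bad), "line")

  neg <- sub("^24,", "24,-", lines[grep("^24,", lines)[1]])
  lines2 <- lines
  lines2[grep("^24,", lines2)[1]] <- neg
  bad2 <- tempfile(fileext = ".csv")
  writeLines(lines2, bad2)
  expect_error(read_culture_csv(bad2), "negative|line")
})

test_that("record invariants are enforced", {
  expect_error(culture_record("x", 0, 1, data.frame(time = 0, concentration = 1)),
               "working_volume")
  expect_error(culture_record("x", 1, 1,
                              data.frame(time = c(0, 24, 24), concentration = c(1, 2, 3))),
               "increasing")
  expect_error(culture_record("x", 1, 1,
                              data.frame(time = c(0, 24), concentration = c(2, 3))),
               "baseline")
  expect_error(culture_record("x", 1, 1,
                              data.frame(time = c(0, 24), concentration = c(1, 2)),
                              data.frame(time = 24, fraction = 1.4,
                                         pre_concentration = NA)),
               "fraction")
})

test_that("mM-equivalent converts to absolute mmol with the working volume", {
  expect_equal(lactate_mmol(12, 1), 0.012)
  expect_equal(lactate_mmol(c(1, 2), 2000), c(2, 4))
})
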