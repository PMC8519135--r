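test_that("the nocturnal window holds 48 samples/night under half-open clocks", {
  day1 <- generate_trace(synth_config(duration_h = 24))
  expect_equal(nrow(extract_clock_window(day1, clock_window())), 48)
  day4 <- generate_trace(synth_config(duration_h = 96))
  expect_equal(nrow(extract_clock_window(day4, clock_window())), 192)
  # trace entirely outside the window
  daytime <- uniform_trace(rep(5, 12), start = t0("06:00:00"))
  expect_equal(nrow(extract_clock_window(daytime, clock_window())), 0)
})

test_that("window extraction is idempotent and boundary samples follow [start, end)", {
  tr <- generate_trace(synth_config(duration_h = 24))
  w <- clock_window("01:00", "05:00")
  once <- extract_clock_window(tr, w)
  expect_identical(extract_clock_window(once, w), once)
  clocks <- format(once$timestamp, "%H:%M")
  expect_true("01:00" %in% clocks) # start included
  expect_false("05:00" %in% clocks) # end excluded
})

test_that("windows crossing midnight wrap", {
  tr <- generate_trace(synth_config(duration_h = 48))
  w <- clock_window("22:00", "02:00")
  out <- extract_clock_window(tr, w)
  expect_equal(nrow(out), 2 * 48) # 4 h/night over 2 days
})

test_that("intervention splitting partitions the trace", {
  tr <- generate_trace(synth_config(duration_h = 48))
  sched <- intervention_schedule(
    c("baseline", "treatment"),
    start = c(t0(), t0(date = "2024-01-02")),
    end = c(t0(date = "2024-01-02"), t0(date = "2024-01-03"))
  )
  parts <- split_by_intervention(tr, sched)
  expect_named(parts, c("baseline", "treatment"))
  expect_equal(vapply(parts, nrow, integer(1)), c(baseline = 288, treatment = 288))
  expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(tr))
  # boundary sample (midnight) went to the later segment
  expect_equal(min(parts$treatment$timestamp), t0(date = "2024-01-02"))
  # no schedule: identity partition under "all-data"
  expect_equal(nrow(split_by_intervention(tr)[["all-data"]]), nrow(tr))
})

test_that("samples outside all interventions land in 'unassigned'", {
  tr <- generate_trace(synth_config(duration_h = 24))
  sched <- intervention_schedule("morning", t0("06:00:00"), t0("12:00:00"))
  parts <- split_by_intervention(tr, sched)
  expect_equal(nrow(parts$morning), 72)
  expect_equal(nrow(parts$unassigned), 288 - 72)
})

test_that("overlapping interventions are rejected with the offending labels", {
  expect_error(
    intervention_schedule(
      c("a", "b"),
      start = c(t0(), t0("12:00:00")),
      end = c(t0("18:00:00"), t0("23:00:00"))
    ),
    "'a' overlaps 'b'"
  )
})

test_that("nights_of yields one complete window per full day", {
  tr <- generate_trace(synth_config(duration_h = 7 * 24))
  nights <- nights_of(tr, clock_window())
  expect_equal(nrow(nights), 7)
  expect_true(all(nights$n == 48))
  expect_true(all(nights$complete))
  expect_true(all(nights$n <= nights$expected))
})

test_that("a missing night drops out and a partial night is policy-flagged", {
  tr <- generate_trace(synth_config(duration_h = 3 * 24))
  # remove the whole second night 01:00-05:00 (25-29 h from start)
  no_night <- inject_gaps(tr, list(c(25, 29)))
  nights <- nights_of(no_night, clock_window())
  expect_equal(nrow(nights), 2)
  expect_false(as.Date("2024-01-02") %in% nights$night)
  # 40 of 48 samples = 83% >= the 80% policy: present and complete
  part <- inject_gaps(tr, list(c(25, 25 + 8 * 5 / 60)))
  n2 <- nights_of(part, clock_window())
  expect_equal(n2$n[n2$night == as.Date("2024-01-02")], 40)
  expect_true(n2$complete[n2$night == as.Date("2024-01-02")])
  # below 80% flips the flag
  part2 <- inject_gaps(tr, list(c(25, 27.5)))
  n3 <- nights_of(part2, clock_window())
  expect_false(n3$complete[n3$night == as.Date("2024-01-02")])
})

test_that("schedules round-trip through CSV and YAML readers", {
  sched <- intervention_schedule(
    c("phase1", "phase2"),
    start = c(t0(), t0(date = "2024-01-03")),
    end = c(t0(date = "2024-01-03"), t0(date = "2024-01-05")),
    dose_text = c("5 mg 1dd", "5 mg 2dd")
  )
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    dplyr::mutate(sched, dplyr::across(c("start", "end"), ~ format(.x, "%Y-%m-%d %H:%M:%S"))),
    csv
  )
  back <- read_schedule(csv)
  expect_equal(back$label, sched$label)
  expect_equal(back$start, sched$start)

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(
    list(label = "phase1", start = "2024-01-01 00:00:00", end = "2024-01-03 00:00:00"),
    list(label = "phase2", start = "2024-01-03 00:00:00", end = "2024-01-05 00:00:00")
  )), yml)
  back2 <- read_schedule(yml)
  expect_equal(back2$end, sched$end)
})
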