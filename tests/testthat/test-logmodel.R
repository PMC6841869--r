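test_that("well-formed event lines parse and malformed ones land in the rejects report", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"event_kind":"registration","timestamp":"2024-01-01T08:00:00","scanner_id":"MR1","payload":{"subject_token":"E1","approximate_age_years":54}}',
    '{"event_kind":"table_move","timestamp":"2024-01-01T08:03:00","scanner_id":"MR1","payload":{"position_mm":-900}}',
    '{"event_kind":"contrast_injection","timestamp":"2024-01-01T08:20:00","scanner_id":"MR1","payload":{}}',
    '{"event_kind":"telemetry","timestamp":"2024-01-01T08:21:00","scanner_id":"MR1","payload":{}}',
    '{"event_kind":"table_move","timestamp":"not-a-time","scanner_id":"MR1","payload":{"position_mm":0}}',
    'this is not json'
  ), path)
  ev <- read_events(path)
  rej <- side_report(ev, "rejects")
  expect_equal(nrow(ev), 3)
  expect_equal(nrow(rej), 3)
  expect_setequal(rej$line_no, 4:6)
  expect_match(rej$reason[rej$line_no == 4], "event_kind")
  expect_match(rej$reason[rej$line_no == 5], "timestamp")
})

test_that("an empty stream yields an empty event list, not an error", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), path)
  ev <- read_events(path)
  expect_equal(nrow(ev), 0)
  expect_equal(nrow(side_report(ev, "rejects")), 0)
})

test_that("write_events then read_events round-trips generated event lists", {
  ds <- cached_dataset(n_exams = 30)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_events(ds$events, path)
  ev <- read_events(path)
  expect_equal(nrow(side_report(ev, "rejects")), 0)
  expect_equal(ev$event_kind, ds$events$event_kind)
  expect_equal(ev$timestamp, ds$events$timestamp)
  expect_equal(ev$scanner_id, ds$events$scanner_id)
  expect_equal(ev$payload, ds$events$payload)
})

test_that("registrations split the stream into exams; aborted exams are kept and flagged", {
  t0 <- ts_utc("2024-01-01T08:00:00")
  pl_seq <- function(name) list(raw_name = name, tr_ms = 500, te_ms = 12,
                                technique = "se")
  rows <- list(
    list("registration", 0, list(subject_token = "A", approximate_age_years = 40)),
    list("sequence_start", 300, pl_seq("s1")),
    list("sequence_end", 600, list(raw_name = "s1")),
    list("sequence_start", 700, pl_seq("s2")),
    list("sequence_end", 1000, list(raw_name = "s2")),
    list("registration", 1200, list(subject_token = "B", approximate_age_years = 60)),
    list("registration", 1800, list(subject_token = "C", approximate_age_years = 70)),
    list("sequence_start", 2000, pl_seq("s3")),
    list("sequence_end", 2300, list(raw_name = "s3"))
  )
  events <- dplyr::bind_rows(lapply(rows, function(r) tibble::tibble(
    event_kind = r[[1]], timestamp = t0 + r[[2]], scanner_id = "MR1",
    payload = list(mricoder:::normalize_payload(r[[1]], r[[3]])))))
  exams <- assemble_exams(events)
  expect_equal(nrow(exams), 3)
  expect_equal(exams$n_sequences, c(2L, 0L, 1L))
  expect_equal(exams$aborted, c(FALSE, TRUE, FALSE))
  expect_equal(exams$exam_id, c("A", "B", "C"))
  # span of exam A ends at its last sequence_end
  expect_equal(exams$end_time[[1]], t0 + 1000)
})

test_that("orphan sequence ends and pre-registration events are rejected but exams survive", {
  t0 <- ts_utc("2024-01-01T08:00:00")
  events <- dplyr::bind_rows(
    tibble::tibble(event_kind = "table_move", timestamp = t0 - 100,
                   scanner_id = "MR1",
                   payload = list(list(position_mm = 0))),
    tibble::tibble(event_kind = "registration", timestamp = t0,
                   scanner_id = "MR1",
                   payload = list(list(subject_token = "A"))),
    tibble::tibble(event_kind = "sequence_end", timestamp = t0 + 100,
                   scanner_id = "MR1",
                   payload = list(list(raw_name = "ghost"))),
    tibble::tibble(event_kind = "sequence_start", timestamp = t0 + 200,
                   scanner_id = "MR1",
                   payload = list(mricoder:::normalize_payload(
                     "sequence_start",
                     list(raw_name = "s1", tr_ms = 500, te_ms = 10)))),
    tibble::tibble(event_kind = "sequence_end", timestamp = t0 + 400,
                   scanner_id = "MR1",
                   payload = list(list(raw_name = "s1")))
  )
  exams <- assemble_exams(events)
  rej <- side_report(exams, "rejects")
  expect_equal(nrow(exams), 1)
  expect_equal(exams$n_sequences, 1L)
  expect_equal(nrow(rej), 2)
  expect_true(any(grepl("before any registration", rej$reason)))
  expect_true(any(grepl("without matching sequence_start", rej$reason)))
})

test_that("assembly matches a brute-force partition by registration timestamps", {
  ds <- cached_dataset(n_exams = 50)
  exams <- assemble_exams(ds$events)
  expect_equal(nrow(side_report(exams, "rejects")), 0)
  for (sc in unique(ds$events$scanner_id)) {
    ev <- ds$events[ds$events$scanner_id == sc, ]
    regs <- ev[ev$event_kind == "registration", ]
    expect_equal(sum(exams$scanner_id == sc), nrow(regs))
    # every sequence start belongs to the exam with the latest registration
    # at or before it
    starts <- ev[ev$event_kind == "sequence_start", ]
    owner <- vapply(starts$timestamp, function(ts) {
      idx <- max(which(regs$timestamp <= ts))
      regs$payload[[idx]]$subject_token
    }, character(1))
    got_n <- table(factor(owner, levels = exams$exam_id[exams$scanner_id == sc]))
    expect_equal(as.integer(got_n),
                 exams$n_sequences[match(names(got_n), exams$exam_id)])
  }
  # consecutive exam spans on one scanner never overlap
  for (sc in unique(exams$scanner_id)) {
    e <- exams[exams$scanner_id == sc, ]
    e <- e[order(e$registration_time), ]
    expect_true(all(utils::head(e$end_time, -1) <=
                      utils::tail(e$registration_time, -1)))
  }
})

test_that("billing merge aggregates by exam id and reports unmatched records", {
  exams <- dplyr::bind_rows(make_exam("A"),
                            make_exam("B", registration = ts_utc("2024-01-01T10:00:00"),
                                      sequences = make_sequences(start = ts_utc("2024-01-01T10:05:00"))))
  billing <- tibble::tibble(
    exam_id = c("A", "A", "A", "Z"),
    code_id = c("c1", "c2", "c2", "c9"), count = c(1L, 1L, 1L, 2L))
  merged <- merge_billing(exams, billing)
  expect_equal(merged$labelset[[1]], c(c1 = 1L, c2 = 2L))
  expect_length(merged$labelset[[2]], 0)
  expect_false(merged$has_billing[[2]])
  un <- side_report(merged, "unmatched")
  expect_equal(un$exam_id, "Z")
})

test_that("timestamp-keyed billing merge equals the id-keyed merge", {
  ds <- cached_dataset(n_exams = 20, seed = 77)
  exams <- assemble_exams(ds$events)
  by_id <- merge_billing(exams, ds$truth)
  prov <- ds$provenance
  billing_ts <- ds$truth
  billing_ts$timestamp <- prov$registration_time[
    match(billing_ts$exam_id, prov$exam_id)] + 60
  billing_ts$scanner_id <- prov$scanner_id[
    match(billing_ts$exam_id, prov$exam_id)]
  billing_ts$exam_id <- NULL
  by_ts <- merge_billing(exams, billing_ts, tolerance_s = 120)
  expect_equal(by_ts$labelset, by_id$labelset)
})

test_that("a billing record matching two exams raises an ambiguity error", {
  exams <- dplyr::bind_rows(
    make_exam("A"),
    make_exam("B", registration = ts_utc("2024-01-01T08:30:00"),
              sequences = make_sequences(start = ts_utc("2024-01-01T08:35:00"))))
  billing <- tibble::tibble(timestamp = ts_utc("2024-01-01T08:20:00"),
                            code_id = "c1", count = 1L)
  expect_error(merge_billing(exams, billing, tolerance_s = 3600),
               "matches 2 exams")
})
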