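test_that("date-time assembly composes, imputes and rejects as configured", {
  ok <- assemble_datetime("2010-03-01", "10:35")
  expect_equal(ok$datetime, wc("2010-03-01 10:35"))
  expect_false(ok$flagged)

  # seconds are truncated, never rounded
  expect_equal(assemble_datetime("2010-03-01", "10:35:59")$datetime,
               wc("2010-03-01 10:35"))

  imp <- assemble_datetime("2010-03-01", "", missing_time = "impute")
  expect_equal(imp$datetime, wc("2010-03-01 00:00"))
  expect_true(imp$flagged)

  drp <- assemble_datetime("2010-03-01", NA, missing_time = "drop")
  expect_true(drp$dropped)
  expect_true(is.na(drp$datetime))

  bad <- assemble_datetime("2010-13-40", "10:00")
  expect_true(is.na(bad$datetime))
  expect_equal(bad$errors$row, 1L)
  expect_equal(bad$errors$field, "date")

  oob <- assemble_datetime("2010-03-01", "25:99")
  expect_true(is.na(oob$datetime))
  expect_equal(oob$errors$field, "time")

  # vectorised with mixed outcomes
  mix <- assemble_datetime(c("2010-01-02", "2010-01-03", "bad"),
                           c("09:00", "", "10:00"))
  expect_equal(sum(is.na(mix$datetime)), 1L)
  expect_equal(mix$flagged, c(FALSE, TRUE, FALSE))
})

test_that("reading applies the dialect, policies and uniqueness invariant", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(pid = c("P1", "P1", "P2"), vid = c("v1", "v2", "v3"),
                   ad = "2010-03-01", at = c("10:00", "", "23:00"),
                   dd = c("2010-03-01", "2010-03-01", "2010-03-02"),
                   dt_ = c("12:00", "13:00", "01:00"),
                   status = "ward_this_hospital", campus = "C1")
  write.csv(df, path, row.names = FALSE)
  dia <- dialect_vemd(participant_id = "pid", visit_id = "vid",
                      arrival_date = "ad", arrival_time = "at",
                      departure_date = "dd", departure_time = "dt_",
                      departure_status = "status", campus = "campus")

  out <- read_visits(path, dia)
  expect_equal(nrow(out$records), 3L)
  expect_equal(out$report$n_flagged, 1L)   # imputed midnight on v2
  expect_true(out$records$time_imputed[out$records$visit_id == "v2"])
  expect_equal(out$records$arrival_dt[1], wc("2010-03-01 10:00"))

  dropped <- read_visits(path, dia, clean_policy(missing_time = "drop"))
  expect_equal(nrow(dropped$records), 2L)
  expect_equal(dropped$report$n_dropped, 1L)

  # configuration error: a mapped column absent from the file
  expect_error(read_visits(path, dialect_vemd()), "mapped column")

  # duplicate id violates the uniqueness invariant
  df2 <- df; df2$vid <- c("v1", "v1", "v3")
  write.csv(df2, path, row.names = FALSE)
  expect_error(read_visits(path, dia), "duplicate visit_id")
})

test_that("write-then-read round trip preserves every field at minute resolution", {
  sim <- simulate_cohort(sim_config(n_participants = 25, seed = 11,
                                    p_midnight_error = 0))
  vpath <- withr::local_tempfile(fileext = ".csv")
  epath <- withr::local_tempfile(fileext = ".csv")
  write_visits(sim$visits, vpath)
  write_episodes(sim$episodes, epath)
  v2 <- read_visits(vpath)$records
  e2 <- read_episodes(epath)$records
  cols_v <- c("participant_id", "visit_id", "arrival_dt", "departure_dt",
              "departure_status", "campus", "visit_type", "referred_by")
  cols_e <- c("participant_id", "episode_id", "admission_dt", "separation_dt",
              "admission_type", "admission_source", "separation_mode",
              "campus", "care_type")
  expect_equal(v2[cols_v], sim$visits[cols_v], ignore_attr = TRUE)
  expect_equal(e2[cols_e], sim$episodes[cols_e], ignore_attr = TRUE)
})

test_that("cleaning repairs midnight slips, drops the unrepairable, reconciles counts", {
  visits <- rbind(
    # departure entered on the arrival date though the stay crossed midnight:
    # 23:50 -> next-day 00:10 recorded as same-day 00:10
    make_visit("v1", "2010-03-01 23:50", "2010-03-01 00:10"),
    # consistent record
    make_visit("v2", "2010-03-02 10:00", "2010-03-02 12:00")
  )
  out <- validate_and_clean(visits, "visits")
  expect_equal(nrow(out$records), 2L)
  expect_equal(out$records$departure_dt[out$records$visit_id == "v1"],
               wc("2010-03-02 00:10"))
  expect_equal(out$report$n_modified, 1L)
  expect_equal(out$report$n_dropped, 0L)
  # untouched record not flagged
  expect_false("v2" %in% out$report$reasons$record_id)

  episodes <- make_episode("e1", "2010-03-10 10:00", "2010-03-07 10:00")
  strict <- validate_and_clean(episodes, "episodes")
  expect_equal(nrow(strict$records), 0L)
  expect_equal(strict$report$n_dropped, 1L)
  expect_equal(strict$report$reasons$rule, "end_before_start")

  lenient <- validate_and_clean(episodes, "episodes",
                                clean_policy(unrepairable = "flag"))
  expect_equal(nrow(lenient$records), 1L)
  expect_equal(lenient$report$n_dropped, 0L)
  expect_equal(lenient$report$n_flagged, 1L)

  # report reconciliation: n_input = retained + dropped
  mixed <- rbind(visits,
                 make_visit("v3", "2010-03-05 10:00", "2010-03-01 09:00"))
  res <- validate_and_clean(mixed, "visits")
  expect_equal(res$report$n_input, nrow(res$records) + res$report$n_dropped)
})

test_that("retained records always satisfy the ordering invariant", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 15
    a <- wc("2012-01-01 00:00") + sample.int(40 * 1440, n) * 60
    # ends scattered both sides of the start, some far off
    d <- a + sample(c(-3 * 1440, -30, -5, 0, 20, 300, 1440), n,
                    replace = TRUE) * 60
    visits <- data.frame(participant_id = "P1",
                         visit_id = sprintf("v%02d", 1:n),
                         arrival_dt = a, departure_dt = d,
                         departure_status = "ward_this_hospital",
                         campus = "C1", stringsAsFactors = FALSE)
    out <- validate_and_clean(visits, "visits")
    expect_true(all(out$records$arrival_dt <= out$records$departure_dt))
    expect_equal(out$report$n_input,
                 nrow(out$records) + out$report$n_dropped)
    # every dropped or modified record appears among the flagged ones
    expect_gte(out$report$n_flagged,
               max(out$report$n_modified, out$report$n_dropped))
  }
})

test_that("cleaning report serialises to structured JSON", {
  visits <- make_visit("v1", "2010-03-01 23:50", "2010-03-01 00:10")
  rep <- validate_and_clean(visits, "visits")$report
  j <- jsonlite::fromJSON(cleaning_report_json(rep))
  expect_equal(j$n_input, 1)
  expect_equal(j$reasons$rule, "midnight_slip")
})

test_that("code maps enforce within-variable disjointness and YAML round-trip", {
  expect_error(code_maps(departure_status_admission_expected = "x",
                         departure_status_no_admission = c("x", "y")),
               "overlap")
  path <- withr::local_tempfile(fileext = ".yaml")
  maps <- code_maps(separation_mode_transfer = c("xfer", "stat_sep"))
  write_code_maps(maps, path)
  maps2 <- read_code_maps(path)
  expect_equal(unclass(maps2), unclass(maps))
  expect_error(read_code_maps({
    p <- withr::local_tempfile(fileext = ".yaml")
    yaml::write_yaml(list(not_a_group = "x"), p); p
  }), "unknown code group")
})

test_that("cohort-to-dataset matching requires a 100% match on all four identifiers", {
  cohort <- data.frame(
    id = c("c1", "c2", "c3", "c4"),
    medicare_number = c("1234 567 890", "2222222222", "3333333333", ""),
    first_name = c("Rehana", "Alex", "Sam", "Kim"),
    date_of_birth = c("1970-01-01", "1980-05-05", "1990-09-09", "1975-03-03"),
    sex = c("female", "male", "female", "male"),
    stringsAsFactors = FALSE)
  dataset <- data.frame(
    id = c("d1", "d2", "d3"),
    medicare_number = c("1234567890", "2222222222", "3333333333"),
    first_name = c("REHAN A", "Alexandra", "Sam"),
    date_of_birth = c("1970-01-01", "1980-05-05", "1990-09-09"),
    sex = c("female", "male", "male"),
    stringsAsFactors = FALSE)
  m <- match_cohort_to_dataset(cohort, dataset)
  # c1-d1: prefixes "reh" == "reh" (case-insensitive, letters only),
  # medicare equal after whitespace strip, dob and sex equal
  expect_true(any(m$cohort_id == "c1" & m$dataset_id == "d1"))
  # c2-d2: prefix "ale" == "ale" and all else equal -> matched
  expect_true(any(m$cohort_id == "c2" & m$dataset_id == "d2"))
  # c3-d3: all equal except sex -> not matched (100%-match rule)
  expect_false(any(m$cohort_id == "c3"))
  # c4 missing medicare -> excluded and reported
  exc <- attr(m, "excluded")
  expect_true(any(exc$id == "c4" & exc$side == "cohort"))

  # symmetric up to orientation
  m2 <- match_cohort_to_dataset(dataset, cohort)
  expect_setequal(paste(m$cohort_id, m$dataset_id),
                  paste(m2$dataset_id, m2$cohort_id))
})
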