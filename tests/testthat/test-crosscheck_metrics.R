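# A small helper: wrap planted tables into a linkage result and check the
# audit tables reconcile with it.

test_that("half-up integer rounding follows the reporting convention", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  expect_equal(round_half_up(17.31), 17)
  # published category histogram -> published percentages
  hist <- c(206, 7, 801, 21, 43, 112)
  expect_equal(vapply(hist, function(n) round_half_up(100 * n / 1190), 0),
               c(17, 1, 67, 2, 4, 9))
})

test_that("headline counts reproduce the published worked example", {
  s <- linkage_summary(n_visits = 3459, n_episodes = 1877, n_linked = 1190)
  expect_equal(s$pct_visits_linked, 34)
  expect_equal(s$pct_episodes_linked, 63)
  expect_equal(s$n_complete_dataset, 4146)
  expect_equal(s$n_unlinked_visits, 2269)
  expect_equal(s$n_unlinked_episodes, 687)

  z <- linkage_summary(n_visits = 10, n_episodes = 5, n_linked = 0)
  expect_equal(z$pct_visits_linked, 0)
  expect_equal(z$n_complete_dataset, 15)
})

test_that("summary of a real run reports categories, lags and the <1% label", {
  pop <- plant_linked_pairs(c(L1 = 10, L2 = 1, L3 = 200, L4 = 4, L5 = 12,
                              L6 = 20), seed = 17)
  res <- link_records(pop$visits, pop$episodes)
  s <- linkage_summary(res)
  expect_equal(sum(s$category_histogram), s$n_linked)
  expect_equal(unname(s$category_histogram),
               c(10L, 1L, 200L, 4L, 12L, 20L))
  # 1/247 = 0.4% -> below the 0.5% threshold -> labelled "<1"
  expect_equal(unname(s$category_pct_label[["L2"]]), "<1")
  # generator puts 90% of L6 offsets within 11 minutes; all are <= 24 h
  expect_true(s$lag_stats$L6$n_within_11min >= 1)
  expect_true(all(-res$linked$delta_arrival_admission[res$linked$category == "L6"]
                  <= 1440))
  # L5 lag share within 2 h is computed on the departure-admission delta
  l5 <- res$linked$delta_departure_admission[res$linked$category == "L5"]
  expect_equal(s$lag_stats$L5$n_within_2h, sum(l5 <= 120))
})

test_that("departure-status cross-tab margins reconcile and agree with codes", {
  set.seed(31)
  sim <- simulate_cohort(sim_config(n_participants = 120, seed = 31))
  res <- link_records(sim$visits, sim$episodes)
  ct <- departure_status_crosstab(res)
  expect_equal(sum(ct$cells) + nrow(ct$excluded), res$counts$n_visits)
  expect_equal(sum(ct$cells[, "Link found"]), res$counts$n_linked)
  expect_equal(sum(ct$cells[, "No link"]), nrow(res$unlinked_visits))

  # recompute the agreement proportion independently from the raw codes
  maps <- code_maps()
  lk <- res$linked$departure_status %in% maps$departure_status_admission_expected
  expect_equal(ct$pct_linked_agreement,
               round_half_up(100 * sum(lk) / res$counts$n_linked))

  # perfect codes -> 100% agreement
  pop <- plant_linked_pairs(c(L1 = 5, L2 = 0, L3 = 5, L4 = 0, L5 = 0, L6 = 0),
                            seed = 2)
  ct2 <- departure_status_crosstab(link_records(pop$visits, pop$episodes))
  expect_equal(ct2$pct_linked_agreement, 100)
})

test_that("admission-type audit reports the found-link rate among ED-expected episodes", {
  sim <- simulate_cohort(sim_config(n_participants = 120, seed = 55))
  res <- link_records(sim$visits, sim$episodes)
  ct <- admission_type_crosstab(res)
  expect_equal(sum(ct$cells), res$counts$n_episodes)
  n_exp <- sum(ct$cells["Preceding ED visit expected", ])
  expect_equal(ct$pct_found_among_expected,
               round_half_up(100 * ct$cells["Preceding ED visit expected",
                                            "Link found"] / n_exp))

  # 4 ED-expected episodes, 3 with links -> 75%
  v <- do.call(rbind, lapply(1:3, function(i) {
    make_visit(sprintf("v%d", i),
               sprintf("2010-01-%02d 10:00", i * 3),
               sprintf("2010-01-%02d 14:00", i * 3),
               participant_id = sprintf("P%d", i))
  }))
  e <- do.call(rbind, lapply(1:4, function(i) {
    make_episode(sprintf("e%d", i),
                 sprintf("2010-01-%02d 11:00", i * 3),
                 sprintf("2010-02-%02d 10:00", i * 3),
                 participant_id = sprintf("P%d", i))
  }))
  ct3 <- admission_type_crosstab(link_records(v, e))
  expect_equal(ct3$pct_found_among_expected, 75)
})

test_that("degenerate and unmapped inputs are handled, not crashed on", {
  # empty input: proportions not available
  v0 <- make_visit("v", "2010-01-01 10:00", "2010-01-01 11:00")[0, ]
  e0 <- make_episode("e", "2010-01-01 10:00", "2010-01-02 11:00")[0, ]
  res0 <- link_records(v0, e0)
  ct0 <- departure_status_crosstab(res0)
  expect_true(is.na(ct0$pct_linked_agreement))
  expect_true(is.na(ct0$pct_unlinked_agreement))

  # an unmapped departure status is excluded and itemised
  v <- make_visit("v1", "2010-01-01 10:00", "2010-01-01 11:00",
                  departure_status = "not_in_any_group")
  res <- link_records(v, e0)
  ct <- departure_status_crosstab(res)
  expect_equal(sum(ct$cells), 0L)
  expect_equal(ct$excluded$record_id, "v1")
})

test_that("window sensitivity counts candidates and links per window width", {
  # planted L5 lags 30 min, 90 min, 20 h on separate participants
  lags <- c(30, 90, 1200)
  v <- do.call(rbind, lapply(seq_along(lags), function(i) {
    make_visit(sprintf("v%d", i), "2010-01-01 08:00", "2010-01-01 10:00",
               participant_id = sprintf("P%d", i))
  }))
  e <- do.call(rbind, lapply(seq_along(lags), function(i) {
    h <- wc("2010-01-01 10:00") + lags[i] * 60
    make_episode(sprintf("e%d", i), format(h, "%Y-%m-%d %H:%M"),
                 format(h + 86400, "%Y-%m-%d %H:%M"),
                 participant_id = sprintf("P%d", i))
  }))
  tab <- window_sensitivity(v, e, windows_hours = c(1, 2, 24))
  expect_equal(tab$n_candidates, c(1L, 2L, 3L))
  expect_equal(tab$n_linked, c(1L, 2L, 3L))
  expect_equal(tab$L5, c(1L, 2L, 3L))

  # a window of zero finds nothing for an L5-only population
  tab0 <- window_sensitivity(v, e, windows_hours = c(0, 24))
  expect_equal(tab0$n_linked, c(0L, 3L))

  # single default window agrees with link_records exactly
  res <- link_records(v, e)
  tab1 <- window_sensitivity(v, e, windows_hours = 24)
  expect_equal(tab1$n_linked, res$counts$n_linked)

  # monotone in width on random data
  sim <- simulate_cohort(sim_config(n_participants = 40, seed = 77))
  tabr <- window_sensitivity(sim$visits, sim$episodes,
                             windows_hours = c(0, 2, 6, 24))
  expect_true(all(diff(tabr$n_candidates) >= 0))
})
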