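cfg <- link_config()

test_that("candidate generation is the within-participant Cartesian product", {
  v <- rbind(make_visit("v1", "2010-01-01 10:00", "2010-01-01 12:00"),
             make_visit("v2", "2010-01-05 10:00", "2010-01-05 12:00"))
  e <- rbind(make_episode("e1", "2010-01-01 11:00", "2010-01-02 09:00"),
             make_episode("e2", "2010-01-05 11:00", "2010-01-06 09:00"),
             make_episode("e3", "2010-01-09 11:00", "2010-01-10 09:00"))
  expect_equal(nrow(candidate_pairs(v, e)), 6L)

  # visits only -> no pairs
  expect_equal(nrow(candidate_pairs(v, e[0, ])), 0L)

  # no cross-participant pairs: (2 visits, 1 episode) + (1 visit, 2 episodes)
  v2 <- rbind(v, make_visit("v3", "2010-01-01 10:00", "2010-01-01 12:00",
                            participant_id = "P2"))
  e2 <- rbind(e[1, ],
              make_episode("e4", "2010-01-01 11:00", "2010-01-02 09:00",
                           participant_id = "P2"),
              make_episode("e5", "2010-01-03 11:00", "2010-01-04 09:00",
                           participant_id = "P2"))
  cp <- candidate_pairs(v2, e2)
  expect_equal(nrow(cp), 2L + 2L)
  expect_true(all(cp$participant_id[cp$visit_id == "v3"] == "P2"))

  # deltas are signed minutes H - A and H - D
  one <- candidate_pairs(v[1, ], e[1, ])
  expect_equal(one$delta_arrival_admission, 60)
  expect_equal(one$delta_departure_admission, -60)
})

test_that("classification matches each category definition and its boundaries", {
  A <- wc("2010-03-01 10:00"); D <- wc("2010-03-01 14:30")
  lp <- function(H, S) classify_pair(A, D, wc(H), wc(S), cfg)

  expect_equal(lp("2010-03-01 10:00", "2010-03-05 10:00"), "L1")
  expect_equal(lp("2010-03-01 14:30", "2010-03-05 10:00"), "L2")
  expect_equal(lp("2010-03-01 12:15", "2010-03-03 10:00"), "L3")
  # nested admission and discharge take L4 precedence over L3
  expect_equal(lp("2010-03-01 11:00", "2010-03-01 13:00"), "L4")
  # L5: 22.5 h after departure is in the window, 25 h is not
  expect_equal(lp("2010-03-02 13:00", "2010-03-04 10:00"), "L5")
  expect_true(is.na(lp("2010-03-02 15:30", "2010-03-04 10:00")))
  # L5 boundary: exactly 24 h is inclusive
  expect_equal(lp("2010-03-02 14:30", "2010-03-04 10:00"), "L5")
  # L6: 11 min before arrival
  expect_equal(lp("2010-03-01 09:49", "2010-03-02 10:00"), "L6")
  # L6 boundary: exactly 24 h inclusive; beyond is unclassified
  expect_equal(lp("2010-02-28 10:00", "2010-03-02 10:00"), "L6")
  expect_true(is.na(lp("2010-02-28 09:59", "2010-03-02 10:00")))
  # L6 footnote: ED arrival must precede hospital separation
  expect_true(is.na(lp("2010-03-01 09:30", "2010-03-01 09:55")))
  # precondition violations are named errors
  expect_error(classify_pair(D, A, A, D, cfg), "invalid timestamp")
})

test_that("classification is exclusive and exhaustive over the precedence order", {
  set.seed(101)
  t0 <- as.numeric(wc("2011-01-01 00:00")) / 60
  for (i in 1:500) {
    a <- t0 + sample.int(2880, 1)
    d <- a + sample.int(1440, 1)
    h <- t0 + sample.int(3 * 1440, 1)
    s <- h + sample.int(4 * 1440, 1)
    p <- function(m) as.POSIXct(m * 60, origin = "1970-01-01", tz = "UTC")
    got <- classify_pair(p(a), p(d), p(h), p(s), cfg)
    # recompute each definition independently
    defs <- c(L1 = h == a, L2 = h == d, L4 = a < h && s < d,
              L3 = a < h && h < d, L5 = h > d && h - d <= 1440,
              L6 = h < a && a - h <= 1440 && a < s)
    first <- names(defs)[defs][1]
    if (is.na(got)) {
      expect_true(all(!defs))
    } else {
      expect_equal(got, first)
    }
  }
})

test_that("widening a window never loses classifiable candidates", {
  set.seed(7)
  inst <- random_instance(6, 6)
  widths <- c(0, 1, 2, 6, 12, 24, 48)
  counts <- vapply(widths, function(w) {
    cfgw <- link_config(post_departure_hours = w, pre_arrival_hours = w)
    cands <- candidate_pairs(inst$visits, inst$episodes)
    sum(!is.na(classify_pair(cands$arrival_dt, cands$departure_dt,
                             cands$admission_dt, cands$separation_dt, cfgw)))
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("pruning keeps the shortest |arrival-admission| pair, deterministically", {
  v <- make_visit("v1", "2010-01-01 10:00", "2010-01-01 12:00")
  e <- rbind(make_episode("e1", "2010-01-01 10:05", "2010-01-02 09:00"),
             make_episode("e2", "2010-01-01 15:00", "2010-01-02 09:00"))
  cands <- candidate_pairs(v, e)
  cands$category <- classify_pair(cands$arrival_dt, cands$departure_dt,
                                  cands$admission_dt, cands$separation_dt, cfg)
  kept <- prune_and_deduplicate(cands)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$episode_id, "e1")

  # empty in, empty out
  expect_equal(nrow(prune_and_deduplicate(cands[0, ])), 0L)

  # equal |delta|: tie broken by visit_id order, exactly one retained per endpoint
  v2 <- rbind(make_visit("v1", "2010-01-01 10:00", "2010-01-01 12:00"),
              make_visit("v2", "2010-01-01 10:20", "2010-01-01 12:00"))
  e2 <- make_episode("e1", "2010-01-01 10:10", "2010-01-02 09:00")
  c2 <- candidate_pairs(v2, e2)
  c2$category <- classify_pair(c2$arrival_dt, c2$departure_dt,
                               c2$admission_dt, c2$separation_dt, cfg)
  expect_equal(abs(c2$delta_arrival_admission), c(10, 10))
  k2 <- prune_and_deduplicate(c2)
  expect_equal(nrow(k2), 1L)
  expect_equal(k2$visit_id, "v1")

  # unclassified candidates are a caller error
  c3 <- c2; c3$category <- NA_character_
  expect_error(prune_and_deduplicate(c3), "classified")
})

test_that("greedy pruning equals the brute-force oracle on small instances", {
  set.seed(2024)
  for (i in 1:30) {
    inst <- random_instance(sample.int(6, 1), sample.int(6, 1))
    cands <- candidate_pairs(inst$visits, inst$episodes)
    cands$category <- classify_pair(cands$arrival_dt, cands$departure_dt,
                                    cands$admission_dt, cands$separation_dt,
                                    cfg)
    cands <- cands[!is.na(cands$category), , drop = FALSE]
    got <- prune_and_deduplicate(cands)
    got <- got[order(got$visit_id, got$episode_id, method = "radix"), ]
    want <- brute_force_matching(cands)
    expect_equal(got$visit_id, want$visit_id)
    expect_equal(got$episode_id, want$episode_id)
  }
})

test_that("link_records partitions inputs into a one-to-one matching", {
  # single obvious pair
  v <- make_visit("v1", "2010-01-01 10:00", "2010-01-01 14:00")
  e <- make_episode("e1", "2010-01-01 11:00", "2010-01-03 10:00")
  res <- link_records(v, e)
  expect_equal(res$counts$n_linked, 1L)
  expect_equal(res$linked$category, "L3")
  expect_equal(nrow(res$unlinked_visits), 0L)

  # unlinked visit
  res2 <- link_records(v, e[0, ])
  expect_equal(res2$counts$n_linked, 0L)
  expect_equal(nrow(res2$unlinked_visits), 1L)

  # random inputs: conservation and matching property
  set.seed(99)
  for (i in 1:10) {
    inst <- random_instance(sample.int(8, 1), sample.int(8, 1))
    r <- link_records(inst$visits, inst$episodes)
    expect_equal(nrow(inst$visits),
                 r$counts$n_linked + nrow(r$unlinked_visits))
    expect_equal(nrow(inst$episodes),
                 r$counts$n_linked + nrow(r$unlinked_episodes))
    expect_false(any(duplicated(r$linked$visit_id)))
    expect_false(any(duplicated(r$linked$episode_id)))
  }
})

test_that("a fixture with one pair per category links to one pair per category", {
  pop <- plant_linked_pairs(c(L1 = 1, L2 = 1, L3 = 1, L4 = 1, L5 = 1, L6 = 1),
                            seed = 3)
  res <- link_records(pop$visits, pop$episodes)
  expect_equal(res$counts$n_linked, 6L)
  expect_equal(as.integer(res$counts$category), rep(1L, 6))
  # categories agree with the planted ones pair by pair
  m <- merge(res$linked[, c("visit_id", "category")], pop$truth,
             by = "visit_id")
  expect_equal(m$category.x, m$category.y)
})

test_that("chain-first linking keeps continuation episodes out of the match", {
  # visit -> index admission -> planned transfer continuation; the
  # continuation starts within the ED stay of a later visit and would
  # otherwise capture it
  v <- rbind(make_visit("v1", "2010-01-01 10:00", "2010-01-01 12:00"))
  e <- rbind(make_episode("e1", "2010-01-01 11:00", "2010-01-01 20:00",
                          separation_mode = "transfer_other_hospital"),
             make_episode("e2", "2010-01-01 22:00", "2010-01-05 10:00"))
  res <- link_records(v, e)
  expect_equal(res$linked$episode_id, "e1")
  expect_equal(nrow(res$unlinked_episodes), 1L)

  # flat join: with chaining off the same tables may link either episode
  res_flat <- link_records(v, e, link_config(link_after_chaining = FALSE))
  expect_equal(res_flat$counts$n_linked, 1L)
  expect_equal(res_flat$linked$episode_id, "e1")  # still shortest |delta|
  expect_equal(res_flat$counts$n_eligible_episodes, 2L)
})

test_that("identical inputs and config give byte-identical serialised results", {
  sim <- simulate_cohort(sim_config(n_participants = 40, seed = 5))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    res <- link_records(sim$visits, sim$episodes)
    write_linkage_result(res, d)
  }
  for (f in c("linked.csv", "unlinked_visits.csv", "unlinked_episodes.csv",
              "link_summary.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
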