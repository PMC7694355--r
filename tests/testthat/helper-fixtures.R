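# Shared fixture builders and the independent matching oracle.

wc <- tempolink::wallclock

make_visit <- function(visit_id, arrival, departure,
                       participant_id = "P1",
                       departure_status = "ward_this_hospital",
                       campus = "C1") {
  data.frame(participant_id = participant_id, visit_id = visit_id,
             arrival_dt = wc(arrival), departure_dt = wc(departure),
             departure_status = departure_status, campus = campus,
             visit_type = "emergency", referred_by = "self",
             stringsAsFactors = FALSE)
}

make_episode <- function(episode_id, admission, separation,
                         participant_id = "P1",
                         admission_type = "emergency_this_hospital",
                         separation_mode = "discharge_home",
                         campus = "C1") {
  data.frame(participant_id = participant_id, episode_id = episode_id,
             admission_dt = wc(admission), separation_dt = wc(separation),
             admission_type = admission_type, admission_source = "ed",
             separation_mode = separation_mode, campus = campus,
             care_type = "acute", stringsAsFactors = FALSE)
}

# Independent brute-force reference for the shortest-|delta| one-to-one
# matching rule: repeatedly scan ALL remaining candidates for the minimum
# (|delta|, visit_id, episode_id), accept it, discard conflicts. Written
# deliberately without reusing any engine code.
brute_force_matching <- function(cands) {
  accepted <- cands[0, , drop = FALSE]
  remaining <- cands
  while (nrow(remaining) > 0L) {
    d <- abs(remaining$delta_arrival_admission)
    best <- which(d == min(d))
    if (length(best) > 1L) {
      sub <- remaining[best, , drop = FALSE]
      ord <- order(sub$visit_id, sub$episode_id, method = "radix")
      best <- best[ord[1L]]
    }
    accepted <- rbind(accepted, remaining[best, , drop = FALSE])
    v <- remaining$visit_id[best]; e <- remaining$episode_id[best]
    remaining <- remaining[remaining$visit_id != v &
                             remaining$episode_id != e, , drop = FALSE]
  }
  accepted[order(accepted$visit_id, accepted$episode_id,
                 method = "radix"), , drop = FALSE]
}

# Random small linkage instance: one participant, n_v visits and n_e
# episodes scattered across a few days so that many pairs classify.
random_instance <- function(n_v, n_e, origin = "2011-05-01 00:00") {
  t0 <- as.numeric(wc(origin)) / 60
  # build directly in minutes to keep the arithmetic exact
  visits <- do.call(rbind, lapply(seq_len(n_v), function(i) {
    a <- t0 + sample.int(4 * 1440, 1)
    d <- a + sample.int(600, 1)
    data.frame(participant_id = "P1", visit_id = sprintf("v%02d", i),
               arrival_dt = as.POSIXct(a * 60, origin = "1970-01-01", tz = "UTC"),
               departure_dt = as.POSIXct(d * 60, origin = "1970-01-01", tz = "UTC"),
               departure_status = "ward_this_hospital", campus = "C1",
               visit_type = "emergency", referred_by = "self",
               stringsAsFactors = FALSE)
  }))
  episodes <- do.call(rbind, lapply(seq_len(n_e), function(i) {
    h <- t0 + sample.int(4 * 1440, 1)
    s <- h + sample.int(5 * 1440, 1)
    data.frame(participant_id = "P1", episode_id = sprintf("e%02d", i),
               admission_dt = as.POSIXct(h * 60, origin = "1970-01-01", tz = "UTC"),
               separation_dt = as.POSIXct(s * 60, origin = "1970-01-01", tz = "UTC"),
               admission_type = "emergency_this_hospital",
               admission_source = "ed", separation_mode = "discharge_home",
               campus = "C1", care_type = "acute", stringsAsFactors = FALSE)
  }))
  list(visits = visits, episodes = episodes)
}
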