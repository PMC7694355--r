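#' Synthetic frequent-presenter cohort configuration
#'
#' Configures the generator that emulates de-identified ED-visit and
#' admission-episode extracts for a cohort of frequent presenters, with
#' planted ground truth. Defaults reflect the utilisation structure the
#' method was developed against: heterogeneous (heavy-tailed) per-person
#' visit rates with same-day repeat presentations, about a third of visits
#' admitted, a link-category mix dominated by admissions inside the ED stay,
#' rare multi-episode transfer chains up to five episodes, asymmetric
#' disposition-code error rates, and occasional midnight date-entry slips.
#'
#' @param n_participants number of participants.
#' @param study_start,study_end study window (dates, ISO strings).
#' @param visit_rate_mean,visit_rate_dispersion mean and dispersion (size)
#'   of the negative-binomial per-participant ED visit count; small size =
#'   heavy tail = frequent presenters.
#' @param p_admission_given_visit probability an ED visit leads to a
#'   hospital admission.
#' @param category_mix probability vector over `L1`..`L6` for the temporal
#'   relationship planted between an admitted visit and its episode.
#' @param chain_length_distribution probability vector over total-stay
#'   lengths 1..5 (number of episodes per hospital stay).
#' @param p_departure_status_misclassified length-2 probabilities that the
#'   ED departure-status code contradicts the truth, for (admitted,
#'   not-admitted) visits; a scalar is recycled.
#' @param p_admission_type_uncertain length-2 probabilities for
#'   (ED-arising episode coded with an uncertain admission type,
#'   direct admission coded as ED-arising); a scalar is recycled.
#' @param p_midnight_error probability that a record spanning one midnight
#'   has its end date entered as the start date (end before start; the
#'   classic date-entry slip, repairable by [validate_and_clean()]).
#' @param p_same_day_repeat probability a non-admitted visit is placed on
#'   the same day as the preceding non-admitted visit.
#' @param l6_within_11min share of L6 offsets drawn in (0, 11] minutes
#'   (the remainder up to the 24-h window).
#' @param l5_within_2h share of L5 offsets drawn in (0, 2] hours.
#' @param ed_los_median_minutes,ed_los_sdlog log-normal ED length of stay.
#' @param hosp_los_median_minutes,hosp_los_sdlog log-normal hospital
#'   episode length of stay.
#' @param n_direct_admissions episodes with no ED visit; default scales
#'   with the expected number of admitted visits (about 0.58 direct
#'   admissions per ED-arising one).
#' @param seed integer seed; the generator is fully reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 500,
                       study_start = "2008-01-01",
                       study_end = "2013-06-30",
                       visit_rate_mean = 7,
                       visit_rate_dispersion = 1.2,
                       p_admission_given_visit = 0.34,
                       category_mix = c(L1 = 206, L2 = 7, L3 = 801,
                                        L4 = 21, L5 = 43, L6 = 112) / 1190,
                       chain_length_distribution = c(1654, 94, 6, 3, 1) / 1758,
                       p_departure_status_misclassified = c(0.32, 0.026),
                       p_admission_type_uncertain = c(0.079, 0.115),
                       p_midnight_error = 0.002,
                       p_same_day_repeat = 0.2,
                       l6_within_11min = 0.9,
                       l5_within_2h = 0.7,
                       ed_los_median_minutes = 180,
                       ed_los_sdlog = 0.6,
                       hosp_los_median_minutes = 4320,
                       hosp_los_sdlog = 1.0,
                       n_direct_admissions = NULL,
                       seed = 1L) {
  category_mix <- category_mix / sum(category_mix)
  chain_length_distribution <- chain_length_distribution /
    sum(chain_length_distribution)
  stopifnot(length(category_mix) == 6L,
            length(chain_length_distribution) == 5L,
            all(category_mix >= 0), all(chain_length_distribution >= 0),
            visit_rate_mean >= 0, p_admission_given_visit >= 0,
            p_admission_given_visit <= 1)
  names(category_mix) <- c("L1", "L2", "L3", "L4", "L5", "L6")
  if (is.null(n_direct_admissions)) {
    n_direct_admissions <- round(0.58 * n_participants * visit_rate_mean *
                                   p_admission_given_visit)
  }
  structure(list(
    n_participants = as.integer(n_participants),
    study_start = study_start, study_end = study_end,
    visit_rate_mean = visit_rate_mean,
    visit_rate_dispersion = visit_rate_dispersion,
    p_admission_given_visit = p_admission_given_visit,
    category_mix = category_mix,
    chain_length_distribution = chain_length_distribution,
    p_departure_status_misclassified =
      rep_len(p_departure_status_misclassified, 2L),
    p_admission_type_uncertain = rep_len(p_admission_type_uncertain, 2L),
    p_midnight_error = p_midnight_error,
    p_same_day_repeat = p_same_day_repeat,
    l6_within_11min = l6_within_11min,
    l5_within_2h = l5_within_2h,
    ed_los_median_minutes = ed_los_median_minutes,
    ed_los_sdlog = ed_los_sdlog,
    hosp_los_median_minutes = hosp_los_median_minutes,
    hosp_los_sdlog = hosp_los_sdlog,
    n_direct_admissions = as.integer(n_direct_admissions),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# sample() interprets a length-1 numeric as 1:n; pick() never does.
pick <- function(v) if (length(v) == 1L) v else sample(v, 1L)

minutes_to_posix <- function(m) {
  as.POSIXct(m * 60, origin = "1970-01-01", tz = "UTC")
}
posix_to_minutes <- function(p) as.numeric(p) / 60

# Construct admission/separation minutes (h, s) so that classify_pair()
# applied to (a, d, h, s) returns exactly `category` under default windows.
# All arguments and results are integer minutes since epoch.
construct_episode_times <- function(a, d, category, hosp_los, config) {
  el <- d - a
  switch(category,
    L1 = { h <- a; s <- h + hosp_los },
    L2 = { h <- d; s <- h + hosp_los },
    L3 = {
      if (el < 2) stop("L3 needs an ED stay of at least 2 minutes")
      h <- a + pick(seq_len(el - 1))
      s <- max(d, h + hosp_los)
    },
    L4 = {
      if (el < 3) stop("L4 needs an ED stay of at least 3 minutes")
      h <- a + pick(seq_len(el - 2))
      s <- h + pick(0:(d - 1 - h))
    },
    L5 = {
      off <- if (stats::runif(1) < config$l5_within_2h) pick(1:120)
             else pick(121:1440)
      h <- d + off
      s <- h + hosp_los
    },
    L6 = {
      off <- if (stats::runif(1) < config$l6_within_11min) pick(1:11)
             else pick(12:1440)
      h <- a - off
      s <- max(a + 1, h + hosp_los)
    },
    stop("unknown category: ", category)
  )
  c(h = h, s = s)
}

# Guard gap (minutes) between encounter blocks of one participant: > 48 h
# between any visit interval and any foreign admission time ensures no
# spurious candidate pair is classifiable at the default 24-h windows.
BLOCK_GUARD_MIN <- 2900

#' Generate a synthetic cohort with planted linkage ground truth
#'
#' Draws per-participant ED visit histories and hospital admissions over
#' the study window and returns tables in exactly the shape
#' [read_visits()] / [read_episodes()] produce, plus the planted truth.
#' Each admitted visit receives an episode whose admission/separation
#' times are constructed to satisfy the drawn link category's temporal
#' definition; stays extend into planned-transfer chains per the
#' chain-length distribution; disposition codes are assigned truthfully
#' and then flipped with the configured misclassification probabilities;
#' midnight date-entry slips are injected by date-shifting; direct
#' admissions are added with no paired visit.
#'
#' Encounters of one participant are separated by a guard gap of more than
#' 48 h (same-day repeat presentations are generated only between
#' non-admitted visits), which guarantees that with no injected errors the
#' default pipeline recovers the planted links and chains exactly.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return an object of class `tempolink_sim`: list with `visits`,
#'   `episodes`, `truth` (list of `links`, `chains`, `injected_errors`),
#'   `identities` (synthetic identifier table for
#'   [match_cohort_to_dataset()]) and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% config$seed)
  maps <- code_maps()

  t0 <- posix_to_minutes(as.POSIXct(paste(config$study_start, "00:00"),
                                    tz = "UTC"))
  t1 <- posix_to_minutes(as.POSIXct(paste(config$study_end, "23:59"),
                                    tz = "UTC"))

  n_visits_per <- pmin(150L, stats::rnbinom(config$n_participants,
                                            size = config$visit_rate_dispersion,
                                            mu = config$visit_rate_mean))
  direct_owner <- if (config$n_direct_admissions > 0L) {
    sample.int(config$n_participants, config$n_direct_admissions,
               replace = TRUE)
  } else integer(0)

  v_rows <- list(); e_rows <- list(); link_rows <- list()
  chain_rows <- list()
  v_n <- 0L; e_n <- 0L; chain_n <- 0L

  ed_los <- function() max(5, round(stats::rlnorm(
    1, log(config$ed_los_median_minutes), config$ed_los_sdlog)))
  hosp_los <- function() max(60, round(stats::rlnorm(
    1, log(config$hosp_los_median_minutes), config$hosp_los_sdlog)))

  p_mis <- config$p_departure_status_misclassified
  p_unc <- config$p_admission_type_uncertain

  # append an episode chain starting at admission minute h0; returns block end
  emit_stay <- function(pid, h0, s0, admission_type) {
    stay_len <- sample.int(5L, 1L, prob = config$chain_length_distribution)
    h <- h0; s <- s0
    ids <- character(stay_len)
    chain_n <<- chain_n + 1L
    for (k in seq_len(stay_len)) {
      e_n <<- e_n + 1L
      ids[k] <- sprintf("E%05d", e_n)
      sep_mode <- if (k < stay_len) pick(maps$separation_mode_transfer)
                  else pick(maps$separation_mode_no_transfer)
      e_rows[[e_n]] <<- data.frame(
        participant_id = pid, episode_id = ids[k],
        admission_min = h, separation_min = s,
        admission_type = if (k == 1L) admission_type
                         else "statistical_admission",
        admission_source = if (k == 1L) "ed_or_direct" else "transfer",
        separation_mode = sep_mode,
        campus = pick(c("C1", "C2", "C3")),
        care_type = pick(c("acute", "rehabilitation", "geriatric")),
        stringsAsFactors = FALSE)
      chain_rows[[e_n]] <<- data.frame(
        episode_id = ids[k], chain_id = chain_n, position = k,
        label = if (k == 1L) "index" else "continuation",
        stringsAsFactors = FALSE)
      if (k < stay_len) {
        h <- s + pick(0:1200)           # within the 24-h chain window
        s <- h + hosp_los()
      }
    }
    list(index_id = ids[1L], block_end = s)
  }

  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%04d", p)
    n_v <- n_visits_per[p]
    n_d <- sum(direct_owner == p)
    if (n_v + n_d == 0L) next
    kinds <- sample(c(rep("visit", n_v), rep("direct", n_d)))
    admitted <- stats::runif(n_v) < config$p_admission_given_visit

    n_blocks <- length(kinds)
    mean_gap <- max(120, (t1 - t0) / (n_blocks + 1) - BLOCK_GUARD_MIN)
    cursor <- t0 + round(stats::runif(1, 0, mean_gap))
    prev_kind <- ""; prev_admitted <- TRUE
    v_i <- 0L
    for (b in seq_len(n_blocks)) {
      if (kinds[b] == "visit") {
        v_i <- v_i + 1L
        adm <- admitted[v_i]
        same_day <- prev_kind == "visit" && !prev_admitted && !adm &&
          stats::runif(1) < config$p_same_day_repeat
        a <- if (same_day && b > 1L) cursor_prev_end + pick(30:300)
             else cursor
        d <- a + ed_los()
        v_n <- v_n + 1L
        vid <- sprintf("V%05d", v_n)
        status_true <- if (adm) pick(maps$departure_status_admission_expected)
                       else pick(maps$departure_status_no_admission)
        flip <- stats::runif(1) < (if (adm) p_mis[1] else p_mis[2])
        status <- if (!flip) status_true
                  else if (adm) pick(maps$departure_status_no_admission)
                  else pick(maps$departure_status_admission_expected)
        v_rows[[v_n]] <- data.frame(
          participant_id = pid, visit_id = vid,
          arrival_min = a, departure_min = d,
          departure_status = status,
          campus = pick(c("C1", "C2", "C3")),
          visit_type = pick(c("emergency", "return_visit")),
          referred_by = pick(c("self", "ambulance", "gp")),
          stringsAsFactors = FALSE)
        block_end <- d
        if (adm) {
          category <- sample(names(config$category_mix), 1L,
                             prob = config$category_mix)
          hs <- construct_episode_times(a, d, category, hosp_los(), config)
          atype <- if (stats::runif(1) < p_unc[1]) pick(maps$admission_type_uncertain)
                   else "emergency_this_hospital"
          stay <- emit_stay(pid, hs[["h"]], hs[["s"]], atype)
          link_rows[[length(link_rows) + 1L]] <- data.frame(
            visit_id = vid, episode_id = stay$index_id, category = category,
            stringsAsFactors = FALSE)
          block_end <- max(block_end, stay$block_end)
        }
        cursor_prev_end <- d
        prev_kind <- "visit"; prev_admitted <- adm
      } else {
        h <- cursor
        s <- h + hosp_los()
        atype <- if (stats::runif(1) < p_unc[2]) "emergency_this_hospital"
                 else pick(maps$admission_type_uncertain)
        stay <- emit_stay(pid, h, s, atype)
        block_end <- stay$block_end
        prev_kind <- "direct"; prev_admitted <- TRUE
      }
      gap <- BLOCK_GUARD_MIN + round(stats::rexp(1, 1 / mean_gap))
      cursor <- block_end + gap
    }
  }

  visits <- if (v_n > 0L) do.call(rbind, v_rows) else
    empty_df(participant_id = "character", visit_id = "character",
             arrival_min = "numeric", departure_min = "numeric",
             departure_status = "character", campus = "character",
             visit_type = "character", referred_by = "character")
  episodes <- if (e_n > 0L) do.call(rbind, e_rows) else
    empty_df(participant_id = "character", episode_id = "character",
             admission_min = "numeric", separation_min = "numeric",
             admission_type = "character", admission_source = "character",
             separation_mode = "character", campus = "character",
             care_type = "character")

  # midnight date-entry slips: end date keyed as the start date
  injected <- empty_df(table = "character", record_id = "character",
                       error = "character")
  inject <- function(df, start, end, id, table) {
    spans <- floor(df[[end]] / 1440) == floor(df[[start]] / 1440) + 1 &
      df[[end]] %% 1440 < df[[start]] %% 1440
    hit <- spans & stats::runif(nrow(df)) < config$p_midnight_error
    if (any(hit)) {
      df[[end]][hit] <- df[[end]][hit] - 1440
      injected <<- rbind(injected, data.frame(
        table = table, record_id = df[[id]][hit],
        error = "midnight_date_slip", stringsAsFactors = FALSE))
    }
    df
  }
  if (config$p_midnight_error > 0) {
    visits <- inject(visits, "arrival_min", "departure_min", "visit_id",
                     "visits")
    episodes <- inject(episodes, "admission_min", "separation_min",
                       "episode_id", "episodes")
  }

  visits$arrival_dt <- minutes_to_posix(visits$arrival_min)
  visits$departure_dt <- minutes_to_posix(visits$departure_min)
  visits$arrival_min <- visits$departure_min <- NULL
  episodes$admission_dt <- minutes_to_posix(episodes$admission_min)
  episodes$separation_dt <- minutes_to_posix(episodes$separation_min)
  episodes$admission_min <- episodes$separation_min <- NULL

  links <- if (length(link_rows) > 0L) do.call(rbind, link_rows) else
    empty_df(visit_id = "character", episode_id = "character",
             category = "character")
  chains <- if (e_n > 0L) do.call(rbind, chain_rows) else
    empty_df(episode_id = "character", chain_id = "integer",
             position = "integer", label = "character")

  identities <- data.frame(
    id = sprintf("P%04d", seq_len(config$n_participants)),
    medicare_number = sprintf("%010d",
                              sample.int(.Machine$integer.max,
                                         config$n_participants)),
    first_name = sample(c("Alex", "Sam", "Jordan", "Casey", "Morgan",
                          "Riley", "Taylor", "Jamie", "Robin", "Quinn"),
                        config$n_participants, replace = TRUE),
    date_of_birth = as.character(as.Date("1960-01-01") +
                                   sample.int(12000, config$n_participants)),
    sex = sample(c("male", "female"), config$n_participants, replace = TRUE),
    stringsAsFactors = FALSE)

  structure(list(
    visits = visits, episodes = episodes,
    truth = list(links = links, chains = chains, injected_errors = injected),
    identities = identities,
    config = config
  ), class = "tempolink_sim")
}

#' @export
print.tempolink_sim <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participant(s), %d visit(s), %d episode(s)\n",
              x$config$n_participants, nrow(x$visits), nrow(x$episodes)))
  cat(sprintf("  Planted links: %d; chains: %d; injected errors: %d\n",
              nrow(x$truth$links), max(0, x$truth$chains$chain_id),
              nrow(x$truth$injected_errors)))
  invisible(x)
}

#' Write a synthetic cohort to CSV/JSON files
#'
#' Emits `visits.csv` and `episodes.csv` in the canonical dialects,
#' `identities.csv`, and `truth.json` with the planted links, chain labels
#' and injected errors.
#'
#' @param sim a `tempolink_sim`.
#' @param dir output directory.
#' @return named vector of files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "tempolink_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(visits = file.path(dir, "visits.csv"),
             episodes = file.path(dir, "episodes.csv"),
             identities = file.path(dir, "identities.csv"),
             truth = file.path(dir, "truth.json"))
  write_visits(sim$visits, files[["visits"]])
  write_episodes(sim$episodes, files[["episodes"]])
  utils::write.csv(sim$identities, files[["identities"]], row.names = FALSE)
  jsonlite::write_json(sim$truth, files[["truth"]], dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

#' Plant a pair population with fixed per-category counts
#'
#' Builds one (visit, episode) pair per requested link, each on its own
#' participant, with timestamps constructed to satisfy the requested
#' category definition exactly. Useful for round-trip tests: classifying
#' and linking the planted population must return exactly the planted
#' per-category counts.
#'
#' @param n_by_category named integer vector over `L1`..`L6`.
#' @param seed integer seed.
#' @param config a [sim_config()] (length-of-stay and offset laws).
#' @return list with `visits`, `episodes`, `truth` (planted links).
#' @export
plant_linked_pairs <- function(n_by_category = c(L1 = 206, L2 = 7, L3 = 801,
                                                 L4 = 21, L5 = 43, L6 = 112),
                               seed = 1L, config = sim_config()) {
  set.seed(seed)
  maps <- code_maps()
  cats <- rep(names(n_by_category), n_by_category)
  n <- length(cats)
  t0 <- posix_to_minutes(as.POSIXct("2010-01-01 00:00", tz = "UTC"))
  v_list <- vector("list", n); e_list <- vector("list", n)
  for (i in seq_len(n)) {
    a <- t0 + (i - 1) * 4320 + pick(0:720)   # one block every 3 days
    d <- a + max(5, round(stats::rlnorm(1, log(config$ed_los_median_minutes),
                                        config$ed_los_sdlog)))
    hl <- max(60, round(stats::rlnorm(1, log(config$hosp_los_median_minutes),
                                      config$hosp_los_sdlog)))
    hs <- construct_episode_times(a, d, cats[i], hl, config)
    pid <- sprintf("PP%04d", i)
    v_list[[i]] <- data.frame(
      participant_id = pid, visit_id = sprintf("V%05d", i),
      arrival_dt = minutes_to_posix(a), departure_dt = minutes_to_posix(d),
      departure_status = pick(maps$departure_status_admission_expected),
      campus = "C1", visit_type = "emergency", referred_by = "self",
      stringsAsFactors = FALSE)
    e_list[[i]] <- data.frame(
      participant_id = pid, episode_id = sprintf("E%05d", i),
      admission_dt = minutes_to_posix(hs[["h"]]),
      separation_dt = minutes_to_posix(hs[["s"]]),
      admission_type = "emergency_this_hospital", admission_source = "ed",
      separation_mode = pick(maps$separation_mode_no_transfer),
      campus = "C1", care_type = "acute", stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, v_list)
  episodes <- do.call(rbind, e_list)
  truth <- data.frame(visit_id = visits$visit_id,
                      episode_id = episodes$episode_id,
                      category = cats, stringsAsFactors = FALSE)
  list(visits = visits, episodes = episodes, truth = truth)
}

#' Plant a hospital-stay population with a fixed chain-length histogram
#'
#' Builds an episodes-only population in which `n_by_length[k]` hospital
#' stays consist of `k` sequential episodes: every non-final episode gets a
#' planned-transfer separation code and each continuation is admitted
#' within the 24-h chain window of its predecessor's separation. Stays of
#' the same participant are separated by several days so chaining cannot
#' bridge them.
#'
#' @param n_by_length integer vector; element `k` = number of stays with
#'   `k` episodes.
#' @param seed integer seed.
#' @param n_participants stays are dealt round-robin onto this many
#'   participants.
#' @return list with `episodes` and `truth` (episode labels).
#' @export
simulate_stays <- function(n_by_length = c(1654, 94, 6, 3, 1), seed = 1L,
                           n_participants = 350L) {
  set.seed(seed)
  maps <- code_maps()
  lengths <- rep(seq_along(n_by_length), n_by_length)
  n_stay <- length(lengths)
  cursors <- rep(posix_to_minutes(as.POSIXct("2008-01-01 08:00", tz = "UTC")),
                 n_participants)
  rows <- vector("list", sum(lengths))
  labs <- vector("list", sum(lengths))
  e_n <- 0L
  for (i in seq_len(n_stay)) {
    p <- ((i - 1L) %% n_participants) + 1L
    pid <- sprintf("P%04d", p)
    h <- cursors[p] + pick(0:720)
    for (k in seq_len(lengths[i])) {
      s <- h + max(60, round(stats::rlnorm(1, log(4320), 1)))
      e_n <- e_n + 1L
      rows[[e_n]] <- data.frame(
        participant_id = pid, episode_id = sprintf("E%05d", e_n),
        admission_dt = minutes_to_posix(h), separation_dt = minutes_to_posix(s),
        admission_type = if (k == 1L) "emergency_this_hospital"
                         else "statistical_admission",
        admission_source = if (k == 1L) "ed" else "transfer",
        separation_mode = if (k < lengths[i]) pick(maps$separation_mode_transfer)
                          else pick(maps$separation_mode_no_transfer),
        campus = "C1", care_type = "acute", stringsAsFactors = FALSE)
      labs[[e_n]] <- data.frame(
        episode_id = sprintf("E%05d", e_n), stay = i, position = k,
        label = if (k == 1L) "index" else "continuation",
        stringsAsFactors = FALSE)
      if (k < lengths[i]) h <- s + pick(1:1200)
    }
    cursors[p] <- posix_to_minutes(rows[[e_n]]$separation_dt) + 4320
  }
  list(episodes = do.call(rbind, rows), truth = do.call(rbind, labs))
}

#' Evaluate recovery of planted truth by the pipeline
#'
#' Compares a linkage result (and chain labels) against the generator's
#' ground truth: precision and recall of link recovery overall and per
#' planted category, the confusion matrix between planted and assigned
#' categories on recovered pairs, and chain-label accuracy.
#'
#' @param result a `tempolink_result` produced from the generated tables.
#' @param chains an `episode_chains` object for the same episodes (defaults
#'   to the one inside `result`).
#' @param truth the `truth` element of a [simulate_cohort()] output.
#' @return an object of class `recovery_metrics`.
#' @export
evaluate_recovery <- function(result, chains = NULL, truth) {
  stopifnot(inherits(result, "tempolink_result"))
  chains <- chains %||% result$chains
  known_visits <- c(result$linked$visit_id, result$unlinked_visits$visit_id)
  known_eps <- c(result$linked$episode_id,
                 result$unlinked_episodes$episode_id)
  if (!all(truth$links$visit_id %in% known_visits) ||
      !all(truth$links$episode_id %in% known_eps)) {
    stop("ground truth refers to record ids absent from the linkage result",
         call. = FALSE)
  }
  key <- function(v, e) paste(v, e, sep = "\r")
  found <- result$linked
  k_found <- key(found$visit_id, found$episode_id)
  k_true <- key(truth$links$visit_id, truth$links$episode_id)
  tp <- intersect(k_found, k_true)
  precision <- if (length(k_found) == 0L) NA_real_ else
    length(tp) / length(k_found)
  recall <- if (length(k_true) == 0L) NA_real_ else
    length(tp) / length(k_true)

  cats <- c("L1", "L2", "L3", "L4", "L5", "L6")
  per_category <- data.frame(category = cats, n_true = 0L, n_recovered = 0L,
                             recall = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(cats)) {
    in_cat <- k_true[truth$links$category == cats[i]]
    per_category$n_true[i] <- length(in_cat)
    per_category$n_recovered[i] <- sum(in_cat %in% k_found)
    if (length(in_cat) > 0L) {
      per_category$recall[i] <- per_category$n_recovered[i] / length(in_cat)
    }
  }
  both <- match(k_true, k_found)
  planted <- truth$links$category[!is.na(both)]
  assigned <- found$category[both[!is.na(both)]]
  confusion <- table(planted = factor(planted, levels = cats),
                     assigned = factor(assigned, levels = cats))

  chain_accuracy <- NA_real_
  if (!is.null(chains) && nrow(truth$chains) > 0L) {
    m <- merge(truth$chains[, c("episode_id", "label")],
               chains$labels[, c("episode_id", "label")],
               by = "episode_id", suffixes = c(".true", ".found"))
    chain_accuracy <- mean(m$label.true == m$label.found)
  }

  structure(list(
    n_true = length(k_true), n_found = length(k_found),
    n_recovered = length(tp),
    precision = precision, recall = recall,
    per_category = per_category,
    category_confusion = confusion,
    chain_accuracy = chain_accuracy
  ), class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat("Planted-truth recovery\n")
  cat(sprintf("  Links: %d planted, %d found, %d recovered\n",
              x$n_true, x$n_found, x$n_recovered))
  cat(sprintf("  Precision %.3f, recall %.3f\n", x$precision, x$recall))
  if (!is.na(x$chain_accuracy)) {
    cat(sprintf("  Chain-label accuracy %.3f\n", x$chain_accuracy))
  }
  invisible(x)
}
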