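#' Temporal linkage configuration
#'
#' The six link categories relate an ED visit (arrival `A`, departure `D`)
#' to a hospital episode (admission `H`, separation `S`):
#'
#' * `L1` — admission time equal to ED arrival (`H = A`);
#' * `L2` — admission time equal to ED departure (`H = D`);
#' * `L3` — admission strictly within the ED stay (`A < H < D`);
#' * `L4` — admission *and* discharge nested inside the ED stay
#'   (`A < H`, `S < D`);
#' * `L5` — admission within `post_departure_hours` after ED departure
#'   (`0 < H - D <=` window);
#' * `L6` — admission within `pre_arrival_hours` before ED arrival
#'   (`0 < A - H <=` window), where ED arrival must occur before hospital
#'   separation (`A < S`).
#'
#' Categories are assigned first-match-wins along `precedence`; the default
#' order `L1, L2, L4, L3, L5, L6` lets equalities be claimed only by L1/L2
#' and nested stays by L4, so the six labels partition all classifiable
#' timestamp quadruples. Both windows default to 24 h, inclusive.
#'
#' @param post_departure_hours L5 window (hours after ED departure), >= 0.
#' @param pre_arrival_hours L6 window (hours before ED arrival), >= 0.
#' @param precedence permutation of `c("L1","L2","L4","L3","L5","L6")`.
#' @param link_after_chaining if `TRUE` (default), continuation episodes of
#'   planned-transfer chains are excluded from candidate generation, so an
#'   ED visit can only link to an index admission.
#' @return an object of class `link_config`.
#' @export
link_config <- function(post_departure_hours = 24,
                        pre_arrival_hours = 24,
                        precedence = c("L1", "L2", "L4", "L3", "L5", "L6"),
                        link_after_chaining = TRUE) {
  stopifnot(post_departure_hours >= 0, pre_arrival_hours >= 0)
  if (!setequal(precedence, c("L1", "L2", "L3", "L4", "L5", "L6")) ||
      length(precedence) != 6L) {
    stop("precedence must be a permutation of L1..L6", call. = FALSE)
  }
  structure(list(
    post_departure_hours = as.numeric(post_departure_hours),
    pre_arrival_hours = as.numeric(pre_arrival_hours),
    precedence = as.character(precedence),
    link_after_chaining = isTRUE(link_after_chaining)
  ), class = "link_config")
}

#' Generate within-participant candidate pairs
#'
#' Emits every pair-wise combination of an ED visit and a hospital episode
#' belonging to the same participant — the multi-way join that precedes
#' pruning — with signed time offsets in minutes.
#'
#' @param visits,episodes cleaned record tables.
#' @return data frame with one row per within-participant (visit, episode)
#'   combination: ids, the four timestamps, `delta_arrival_admission`
#'   (`H - A`, minutes), `delta_departure_admission` (`H - D`, minutes) and
#'   an unset `category` column.
#' @export
candidate_pairs <- function(visits, episodes) {
  stopifnot_cols(visits, c("participant_id", "visit_id", "arrival_dt",
                           "departure_dt"), "visits table")
  stopifnot_cols(episodes, c("participant_id", "episode_id", "admission_dt",
                             "separation_dt"), "episodes table")
  v <- visits[, c("participant_id", "visit_id", "arrival_dt", "departure_dt")]
  e <- episodes[, c("participant_id", "episode_id", "admission_dt",
                    "separation_dt")]
  m <- merge(v, e, by = "participant_id")
  m$delta_arrival_admission <- minutes_between(m$arrival_dt, m$admission_dt)
  m$delta_departure_admission <- minutes_between(m$departure_dt, m$admission_dt)
  m$category <- rep(NA_character_, nrow(m))
  m <- m[order_radix(m$participant_id, m$visit_id, m$episode_id), ,
         drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Classify a visit-episode timestamp quadruple into a link category
#'
#' Applies the category definitions of [link_config()] first-match-wins in
#' the configured precedence order. Vectorised over its four timestamp
#' arguments. Requires `A <= D` and `H <= S` (cleaned inputs).
#'
#' @param A,D ED arrival and departure (`POSIXct`, minute resolution).
#' @param H,S hospital admission and separation.
#' @param config a [link_config()].
#' @return character vector: `"L1"`..`"L6"`, or `NA` where no category
#'   applies.
#' @examples
#' cfg <- link_config()
#' classify_pair(wallclock("2010-03-01 10:00"), wallclock("2010-03-01 14:30"),
#'               wallclock("2010-03-01 12:15"), wallclock("2010-03-03 09:00"),
#'               cfg)  # "L3"
#' @export
classify_pair <- function(A, D, H, S, config = link_config()) {
  n <- max(length(A), length(D), length(H), length(S))
  A <- rep_len(A, n); D <- rep_len(D, n)
  H <- rep_len(H, n); S <- rep_len(S, n)
  bad <- which(A > D | H > S)
  if (length(bad) > 0L) {
    stop("invalid timestamp quadruple (A > D or H > S) at position(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  dHA <- minutes_between(A, H)   # H - A
  dHD <- minutes_between(D, H)   # H - D
  post <- config$post_departure_hours * 60
  pre <- config$pre_arrival_hours * 60
  cond <- list(
    L1 = dHA == 0,
    L2 = dHD == 0,
    L4 = dHA > 0 & S < D,
    L3 = dHA > 0 & dHD < 0,
    L5 = dHD > 0 & dHD <= post,
    L6 = dHA < 0 & -dHA <= pre & A < S
  )
  out <- rep(NA_character_, n)
  for (cat in config$precedence) {
    hit <- is.na(out) & cond[[cat]]
    out[hit] <- cat
  }
  out
}

# Classify a candidate-pair table in place.
classify_candidates <- function(cands, config = link_config()) {
  if (nrow(cands) == 0L) {
    cands$category <- character(0)
    return(cands)
  }
  cands$category <- classify_pair(cands$arrival_dt, cands$departure_dt,
                                  cands$admission_dt, cands$separation_dt,
                                  config)
  cands
}

#' Prune classified candidates to a one-to-one matching
#'
#' Duplicate joins are resolved by retaining matched records with the
#' shortest absolute time difference between ED arrival and hospital
#' admission: candidates are sorted by (`|H - A|` ascending, `visit_id`,
#' `episode_id`) and accepted greedily iff neither endpoint is already
#' matched. The tie-break on record ids makes the result deterministic.
#'
#' @param candidates classified candidate pairs (no `NA` categories).
#' @return the accepted subset, a matching: each visit and each episode
#'   appears in at most one row.
#' @export
prune_and_deduplicate <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  if (anyNA(candidates$category)) {
    stop("all candidates must be classified before pruning", call. = FALSE)
  }
  o <- order_radix(abs(candidates$delta_arrival_admission),
                   candidates$visit_id, candidates$episode_id)
  cands <- candidates[o, , drop = FALSE]
  v_used <- character(0)
  e_used <- character(0)
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    v <- cands$visit_id[i]; e <- cands$episode_id[i]
    if (!(v %in% v_used) && !(e %in% e_used)) {
      keep[i] <- TRUE
      v_used <- c(v_used, v)
      e_used <- c(e_used, e)
    }
  }
  out <- cands[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link ED visits to hospital admission episodes
#'
#' End-to-end temporal linkage: generates every within-participant
#' (visit, episode) combination, classifies each against the six temporal
#' link criteria of [link_config()], discards unclassifiable pairs, and
#' prunes the remainder to a one-to-one matching by shortest
#' `|admission - arrival|`. With `link_after_chaining` (the default),
#' planned-transfer continuation episodes identified by [chain_episodes()]
#' are excluded from candidate generation, so visits link to index
#' admissions only; continuation episodes are then always reported among
#' the unlinked episodes.
#'
#' The result partitions the inputs: every visit is either linked or
#' unlinked, and likewise every episode.
#'
#' @param visits,episodes cleaned record tables.
#' @param config a [link_config()].
#' @param code_maps a [code_maps()]; needed only when
#'   `link_after_chaining = TRUE` (transfer separation codes).
#' @param chain_config a [chain_config()] for the chaining pass.
#' @return an object of class `tempolink_result`: list with `linked`
#'   (matched pairs with category and minute deltas), `unlinked_visits`,
#'   `unlinked_episodes`, `chains` (an `episode_chains` object or `NULL`),
#'   `config`, and `counts`.
#' @export
link_records <- function(visits, episodes, config = link_config(),
                         code_maps = tempolink::code_maps(),
                         chain_config = tempolink::chain_config()) {
  chains <- NULL
  eligible <- episodes
  if (config$link_after_chaining && nrow(episodes) > 0L) {
    chains <- chain_episodes(episodes, code_maps, chain_config)
    idx <- chains$labels$episode_id[chains$labels$label == "index"]
    eligible <- episodes[episodes$episode_id %in% idx, , drop = FALSE]
  }
  cands <- classify_candidates(candidate_pairs(visits, eligible), config)
  cands <- cands[!is.na(cands$category), , drop = FALSE]
  linked <- prune_and_deduplicate(cands)

  lv <- linked$visit_id
  le <- linked$episode_id
  unlinked_visits <- visits[!(visits$visit_id %in% lv), , drop = FALSE]
  unlinked_episodes <- episodes[!(episodes$episode_id %in% le), , drop = FALSE]
  rownames(unlinked_visits) <- rownames(unlinked_episodes) <- NULL

  # carry disposition codes into the linked table for the audit
  keep_v <- setdiff(names(visits), c("participant_id", "arrival_dt",
                                     "departure_dt"))
  keep_e <- setdiff(names(episodes), c("participant_id", "admission_dt",
                                       "separation_dt"))
  linked <- merge(linked, visits[, c("visit_id", setdiff(keep_v, "visit_id"))],
                  by = "visit_id", sort = FALSE)
  linked <- merge(linked, episodes[, c("episode_id",
                                       setdiff(keep_e, "episode_id"))],
                  by = "episode_id", sort = FALSE)
  linked <- linked[order_radix(abs(linked$delta_arrival_admission),
                               linked$visit_id, linked$episode_id), ,
                   drop = FALSE]
  rownames(linked) <- NULL

  structure(list(
    linked = linked,
    unlinked_visits = unlinked_visits,
    unlinked_episodes = unlinked_episodes,
    chains = chains,
    config = config,
    counts = list(
      n_visits = nrow(visits),
      n_episodes = nrow(episodes),
      n_eligible_episodes = nrow(eligible),
      n_linked = nrow(linked),
      n_unlinked_visits = nrow(unlinked_visits),
      n_unlinked_episodes = nrow(unlinked_episodes),
      category = table(factor(linked$category,
                              levels = c("L1", "L2", "L3", "L4", "L5", "L6")))
    )
  ), class = "tempolink_result")
}

#' @export
print.tempolink_result <- function(x, ...) {
  ct <- x$counts
  cat("Temporal record linkage result\n")
  cat(sprintf("  ED visits:          %d (%d linked, %d unlinked)\n",
              ct$n_visits, ct$n_linked, ct$n_unlinked_visits))
  cat(sprintf("  Hospital episodes:  %d (%d linked, %d unlinked)\n",
              ct$n_episodes, ct$n_linked, ct$n_unlinked_episodes))
  if (!is.null(x$chains)) {
    cat(sprintf("  Episode chains:     %d (continuations excluded from linking)\n",
                nrow(x$chains$chains)))
  }
  if (ct$n_linked > 0) {
    cat("  Link categories:\n")
    for (k in names(ct$category)) {
      n <- ct$category[[k]]
      cat(sprintf("    %s: %4d (%s%%)\n", k, n, format_pct(n, ct$n_linked)))
    }
  }
  invisible(x)
}

#' @export
summary.tempolink_result <- function(object, ...) {
  linkage_summary(object)
}

#' Write the components of a linkage result to an output directory
#'
#' Linked pairs go to a wide-format CSV (one row = visit fields + episode
#' fields + category + minute deltas); unlinked visits and episodes to
#' their own CSVs in the canonical dialects; summary counts to JSON.
#'
#' @param result a `tempolink_result`.
#' @param dir output directory (created if absent).
#' @return named character vector of the files written, invisibly.
#' @export
write_linkage_result <- function(result, dir) {
  stopifnot(inherits(result, "tempolink_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  linked <- result$linked
  for (col in c("arrival_dt", "departure_dt", "admission_dt",
                "separation_dt")) {
    linked[[col]] <- format_dt(linked[[col]])
  }
  files <- c(
    linked = file.path(dir, "linked.csv"),
    unlinked_visits = file.path(dir, "unlinked_visits.csv"),
    unlinked_episodes = file.path(dir, "unlinked_episodes.csv"),
    summary = file.path(dir, "link_summary.json")
  )
  utils::write.csv(linked, files[["linked"]], row.names = FALSE, na = "")
  write_visits(result$unlinked_visits, files[["unlinked_visits"]])
  write_episodes(result$unlinked_episodes, files[["unlinked_episodes"]])
  counts <- result$counts
  counts$category <- as.list(counts$category)
  jsonlite::write_json(counts, files[["summary"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(files)
}
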