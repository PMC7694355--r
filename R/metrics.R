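#' Expected-versus-found cross-tabulation from ED departure status
#'
#' Audits linkage against the ED record's own departure-status code. Rows
#' are the expectation derived from the code group (admission expected /
#' not expected), columns whether a linked admission episode was found.
#' Two agreement proportions are reported: the share of linked visits whose
#' departure status expected an admission, and the share of unlinked visits
#' whose status expected none. Visits with a departure status mapped to
#' neither group are excluded from the table and itemised.
#'
#' @param result a `tempolink_result`.
#' @param code_maps a [code_maps()].
#' @return an object of class `crosstab_2x2`: `cells` (2x2 integer matrix
#'   with margins as attributes), `pct_linked_agreement`,
#'   `pct_unlinked_agreement` (integer percent, `NA` when a margin is
#'   empty), `excluded` (data frame of unmapped records).
#' @export
departure_status_crosstab <- function(result, code_maps = tempolink::code_maps()) {
  stopifnot(inherits(result, "tempolink_result"))
  status <- c(result$linked$departure_status,
              result$unlinked_visits$departure_status)
  ids <- c(result$linked$visit_id, result$unlinked_visits$visit_id)
  found <- c(rep(TRUE, nrow(result$linked)),
             rep(FALSE, nrow(result$unlinked_visits)))
  grp <- map_codes(status, list(
    expected = code_maps$departure_status_admission_expected,
    not_expected = code_maps$departure_status_no_admission))
  build_crosstab(grp, found, ids, status,
                 rows = c("expected", "not_expected"),
                 row_labels = c("Admission expected", "Admission not expected"),
                 agreement_row = "expected")
}

#' Found-link rate from hospital admission-type codes
#'
#' The admission-type audit mirrors [departure_status_crosstab()] on the
#' episode side: rows are whether the admission-type code asserts the
#' admission came through this hospital's ED (`ed_expected`) or cannot
#' confirm a preceding visit (`uncertain`); columns whether a linked
#' preceding ED visit was found. The headline proportion is the found-link
#' rate among ED-expected episodes.
#'
#' @inheritParams departure_status_crosstab
#' @return a `crosstab_2x2` whose `pct_linked_agreement` is the found-link
#'   rate among ED-expected episodes.
#' @export
admission_type_crosstab <- function(result, code_maps = tempolink::code_maps()) {
  stopifnot(inherits(result, "tempolink_result"))
  type <- c(result$linked$admission_type,
            result$unlinked_episodes$admission_type)
  ids <- c(result$linked$episode_id, result$unlinked_episodes$episode_id)
  found <- c(rep(TRUE, nrow(result$linked)),
             rep(FALSE, nrow(result$unlinked_episodes)))
  grp <- map_codes(type, list(
    ed_expected = code_maps$admission_type_ed_expected,
    uncertain = code_maps$admission_type_uncertain))
  ct <- build_crosstab(grp, found, ids, type,
                       rows = c("ed_expected", "uncertain"),
                       row_labels = c("Preceding ED visit expected",
                                      "Preceding ED visit uncertain"),
                       agreement_row = "ed_expected")
  # headline rate: links found among episodes whose code expected one
  n_exp <- sum(ct$cells["Preceding ED visit expected", ])
  ct$pct_found_among_expected <- if (n_exp == 0) NA_real_ else {
    pct_int(ct$cells["Preceding ED visit expected", "Link found"], n_exp)
  }
  ct
}

build_crosstab <- function(grp, found, ids, codes, rows, row_labels,
                           agreement_row) {
  keep <- !is.na(grp)
  excluded <- data.frame(record_id = ids[!keep], code = codes[!keep],
                         stringsAsFactors = FALSE)
  g <- factor(grp[keep], levels = rows)
  f <- factor(ifelse(found[keep], "yes", "no"), levels = c("yes", "no"))
  tab <- table(g, f)
  cells <- matrix(as.integer(tab), nrow = 2,
                  dimnames = list(row_labels, c("Link found", "No link")))
  n_found <- sum(cells[, "Link found"])
  n_not <- sum(cells[, "No link"])
  agree_i <- match(agreement_row, rows)
  structure(list(
    cells = cells,
    pct_linked_agreement = if (n_found == 0) NA_real_ else
      pct_int(cells[agree_i, "Link found"], n_found),
    pct_unlinked_agreement = if (n_not == 0) NA_real_ else
      pct_int(cells[-agree_i, "No link"], n_not),
    excluded = excluded
  ), class = "crosstab_2x2")
}

#' @export
print.crosstab_2x2 <- function(x, ...) {
  cells <- x$cells
  m <- cbind(cells, Total = rowSums(cells))
  m <- rbind(m, Total = colSums(m))
  cat("Expected versus found links\n")
  print(m)
  if (!is.na(x$pct_linked_agreement)) {
    cat(sprintf("  Agreement among linked records:   %s%%\n",
                x$pct_linked_agreement))
  }
  if (!is.na(x$pct_unlinked_agreement)) {
    cat(sprintf("  Agreement among unlinked records: %s%%\n",
                x$pct_unlinked_agreement))
  }
  if (!is.null(x$pct_found_among_expected) &&
      !is.na(x$pct_found_among_expected)) {
    cat(sprintf("  Found-link rate among expected:   %s%%\n",
                x$pct_found_among_expected))
  }
  if (nrow(x$excluded) > 0L) {
    cat(sprintf("  Excluded (unmapped code): %d record(s)\n",
                nrow(x$excluded)))
  }
  invisible(x)
}

#' Summarise a linkage run
#'
#' Computes the headline counts and proportions of a linkage run: visits,
#' episodes and linked pairs; percent of visits and of episodes linked;
#' the size of the complete combined dataset
#' (`n_visits + n_episodes - n_linked`, since a linked pair contributes a
#' single combined record); the link-category histogram with integer
#' percentages (half-up, with nonzero shares under 0.5% reported as
#' `"<1"`); and per-category lag statistics — notably the share of L5 links
#' admitted within 2 h of ED departure and the share of L6 links admitted
#' within 11 min before ED arrival.
#'
#' Can also be driven from bare counts (no record tables) via `n_visits`,
#' `n_episodes`, `n_linked`, for auditing published headline figures.
#'
#' @param result a `tempolink_result`, or `NULL` when raw counts are given.
#' @param chains optional `episode_chains` (adds chain counts).
#' @param n_visits,n_episodes,n_linked raw counts, used when `result` is
#'   `NULL`.
#' @return an object of class `linkage_summary`.
#' @examples
#' linkage_summary(n_visits = 3459, n_episodes = 1877, n_linked = 1190)
#' @export
linkage_summary <- function(result = NULL, chains = NULL,
                            n_visits = NULL, n_episodes = NULL,
                            n_linked = NULL) {
  if (!is.null(result)) {
    stopifnot(inherits(result, "tempolink_result"))
    n_visits <- result$counts$n_visits
    n_episodes <- result$counts$n_episodes
    n_linked <- result$counts$n_linked
    category <- result$counts$category
    chains <- chains %||% result$chains
  } else {
    stopifnot(!is.null(n_visits), !is.null(n_episodes), !is.null(n_linked))
    category <- NULL
  }
  out <- list(
    n_visits = n_visits,
    n_episodes = n_episodes,
    n_linked = n_linked,
    pct_visits_linked = pct_int(n_linked, n_visits),
    pct_episodes_linked = pct_int(n_linked, n_episodes),
    n_unlinked_visits = n_visits - n_linked,
    n_unlinked_episodes = n_episodes - n_linked,
    n_complete_dataset = n_visits + n_episodes - n_linked
  )
  if (!is.null(category)) {
    out$category_histogram <- as.integer(category)
    names(out$category_histogram) <- names(category)
    out$category_pct <- vapply(category, function(n) pct_int(n, n_linked), 0)
    out$category_pct_label <- vapply(category, function(n)
      format_pct(n, n_linked), "")
    out$lag_stats <- lag_statistics(result$linked)
  }
  if (!is.null(chains)) {
    out$n_index_episodes <- sum(chains$labels$label == "index")
    out$n_continuation_episodes <- sum(chains$labels$label == "continuation")
    out$chain_length_histogram <- as.list(table(chains$chains$length))
  }
  structure(out, class = "linkage_summary")
}

# Per-category lag quantiles plus the two headline shares: L5 admissions
# within 2 h of ED departure; L6 admissions within 11 min before arrival.
lag_statistics <- function(linked) {
  out <- list()
  for (cat in c("L1", "L2", "L3", "L4", "L5", "L6")) {
    rows <- linked[linked$category == cat, , drop = FALSE]
    if (nrow(rows) == 0L) next
    lag <- switch(cat,
                  L5 = rows$delta_departure_admission,
                  L6 = -rows$delta_arrival_admission,
                  abs(rows$delta_arrival_admission))
    out[[cat]] <- list(
      n = nrow(rows),
      lag_minutes_quantiles = stats::quantile(lag, c(0.25, 0.5, 0.75),
                                              names = FALSE)
    )
  }
  if (!is.null(out$L5)) {
    n5 <- out$L5$n
    within_2h <- sum(linked$delta_departure_admission[linked$category == "L5"] <= 120)
    out$L5$n_within_2h <- within_2h
    out$L5$pct_within_2h <- pct_int(within_2h, n5)
  }
  if (!is.null(out$L6)) {
    n6 <- out$L6$n
    within_11min <- sum(-linked$delta_arrival_admission[linked$category == "L6"] <= 11)
    out$L6$n_within_11min <- within_11min
    out$L6$pct_within_11min <- pct_int(within_11min, n6)
  }
  out
}

#' @export
print.linkage_summary <- function(x, ...) {
  cat("Linkage summary\n")
  cat(sprintf("  ED visits:        %6d  (%s%% linked)\n", x$n_visits,
              x$pct_visits_linked))
  cat(sprintf("  Episodes:         %6d  (%s%% linked)\n", x$n_episodes,
              x$pct_episodes_linked))
  cat(sprintf("  Linked pairs:     %6d\n", x$n_linked))
  cat(sprintf("  Complete dataset: %6d records\n", x$n_complete_dataset))
  if (!is.null(x$category_histogram)) {
    cat("  Link categories (n, %):\n")
    for (k in names(x$category_histogram)) {
      cat(sprintf("    %s: %5d  %s%%\n", k, x$category_histogram[[k]],
                  x$category_pct_label[[k]]))
    }
  }
  if (!is.null(x$lag_stats$L5)) {
    cat(sprintf("  L5 within 2 h of ED departure:   %d/%d (%s%%)\n",
                x$lag_stats$L5$n_within_2h, x$lag_stats$L5$n,
                x$lag_stats$L5$pct_within_2h))
  }
  if (!is.null(x$lag_stats$L6)) {
    cat(sprintf("  L6 within 11 min of ED arrival:  %d/%d (%s%%)\n",
                x$lag_stats$L6$n_within_11min, x$lag_stats$L6$n,
                x$lag_stats$L6$pct_within_11min))
  }
  if (!is.null(x$n_continuation_episodes)) {
    cat(sprintf("  Episode chains: %d index, %d continuation\n",
                x$n_index_episodes, x$n_continuation_episodes))
  }
  invisible(x)
}

#' Sensitivity of linkage yield to the time window
#'
#' Re-runs the linkage across a grid of window widths (applied to both the
#' post-departure L5 window and the pre-arrival L6 window) and tabulates,
#' per width, the number of classifiable candidate pairs, the number of
#' one-to-one links retained, and the per-category counts. Candidate counts
#' are non-decreasing in window width.
#'
#' @param visits,episodes cleaned record tables.
#' @param config base [link_config()]; the grid overrides its two windows.
#' @param windows_hours numeric vector of non-negative window widths.
#' @param code_maps,chain_config passed to [link_records()].
#' @return data frame with one row per window, ordered by window.
#' @export
window_sensitivity <- function(visits, episodes, config = link_config(),
                               windows_hours = c(0, 1, 2, 6, 12, 24),
                               code_maps = tempolink::code_maps(),
                               chain_config = tempolink::chain_config()) {
  stopifnot(all(windows_hours >= 0))
  windows_hours <- sort(windows_hours)
  rows <- lapply(windows_hours, function(w) {
    cfg <- config
    cfg$post_departure_hours <- w
    cfg$pre_arrival_hours <- w
    res <- link_records(visits, episodes, cfg, code_maps, chain_config)
    eligible <- episodes
    if (cfg$link_after_chaining && !is.null(res$chains)) {
      idx <- res$chains$labels$episode_id[res$chains$labels$label == "index"]
      eligible <- episodes[episodes$episode_id %in% idx, , drop = FALSE]
    }
    cands <- classify_candidates(candidate_pairs(visits, eligible), cfg)
    ct <- res$counts$category
    data.frame(window_hours = w,
               n_candidates = sum(!is.na(cands$category)),
               n_linked = res$counts$n_linked,
               L1 = ct[["L1"]], L2 = ct[["L2"]], L3 = ct[["L3"]],
               L4 = ct[["L4"]], L5 = ct[["L5"]], L6 = ct[["L6"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
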