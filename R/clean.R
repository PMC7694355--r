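#' Cleaning policy
#'
#' Controls how record ingestion and validation treat incomplete or
#' illogical records.
#'
#' @param missing_time how to handle an empty clock-time field:
#'   `"impute"` (midnight, flagged; the default) or `"drop"`.
#' @param midnight_repair repair end-before-start records consistent with a
#'   midnight date-entry slip (see [validate_and_clean()]).
#' @param midnight_cap_hours maximum duration (hours) a record may have
#'   *after* adding 24 h to its end for the slip repair to be applied.
#' @param unrepairable what to do with records whose end still precedes
#'   their start: `"drop"` (default; preserves the ordering invariant on
#'   retained records) or `"flag"` (retain, which relaxes that invariant).
#' @return an object of class `clean_policy`.
#' @export
clean_policy <- function(missing_time = c("impute", "drop"),
                         midnight_repair = TRUE,
                         midnight_cap_hours = 24,
                         unrepairable = c("drop", "flag")) {
  structure(list(
    missing_time = match.arg(missing_time),
    midnight_repair = isTRUE(midnight_repair),
    midnight_cap_hours = as.numeric(midnight_cap_hours),
    unrepairable = match.arg(unrepairable)
  ), class = "clean_policy")
}

new_cleaning_report <- function(n_input, reasons) {
  if (is.null(reasons) || nrow(reasons) == 0L) {
    reasons <- empty_df(record_id = "character", rule = "character",
                        action = "character")
  }
  structure(list(
    n_input = as.integer(n_input),
    n_flagged = length(unique(reasons$record_id)),
    n_modified = length(unique(reasons$record_id[reasons$action == "modify"])),
    n_dropped = length(unique(reasons$record_id[reasons$action == "drop"])),
    reasons = reasons
  ), class = "cleaning_report")
}

merge_cleaning_reports <- function(a, b) {
  new_cleaning_report(a$n_input, rbind(a$reasons, b$reasons))
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("Cleaning report: %d record(s) in, %d flagged, %d modified, %d dropped\n",
              x$n_input, x$n_flagged, x$n_modified, x$n_dropped))
  if (nrow(x$reasons) > 0L) {
    tab <- table(x$reasons$rule, x$reasons$action)
    print(tab)
  }
  invisible(x)
}

#' Serialise a cleaning report to JSON
#'
#' @param report a `cleaning_report`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string, or `path` invisibly when written to file.
#' @export
cleaning_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "cleaning_report"))
  x <- unclass(report)
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, dataframe = "rows", pretty = TRUE)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, dataframe = "rows",
                         pretty = TRUE)
    invisible(path)
  }
}

#' Validate and clean visit or episode records
#'
#' Applies, in order, the rules that catch the error classes seen in
#' administrative extracts:
#'
#' 1. `missing_datetime` — a record with an unassembled (NA) start or end
#'    timestamp cannot be ordered and is dropped.
#' 2. `midnight_slip` — when the end precedes the start but advancing the
#'    end by one day yields a duration in (0, `midnight_cap_hours`], the
#'    record is consistent with an encounter that spanned the midnight
#'    date-change being entered under a single date; the end date is
#'    advanced one day and the record flagged as modified.
#' 3. `end_before_start` — any remaining end-before-start record is dropped
#'    (policy `unrepairable = "drop"`) or retained with a flag (`"flag"`).
#'
#' Problems are reported, never raised: the returned report itemises every
#' flagged, modified or dropped record with the rule that fired.
#'
#' @param records a visits or episodes data frame (see [read_visits()]).
#' @param type `"visits"` or `"episodes"`; inferred from the id column when
#'   omitted.
#' @param policy a [clean_policy()].
#' @return list with `records` (cleaned data frame) and `report`
#'   (a `cleaning_report`). `n_input = nrow(retained) + n_dropped`.
#' @export
validate_and_clean <- function(records, type = NULL, policy = clean_policy()) {
  if (is.null(type)) {
    type <- if ("visit_id" %in% names(records)) "visits" else "episodes"
  }
  type <- match.arg(type, c("visits", "episodes"))
  cols <- if (type == "visits") {
    list(id = "visit_id", start = "arrival_dt", end = "departure_dt")
  } else {
    list(id = "episode_id", start = "admission_dt", end = "separation_dt")
  }
  stopifnot_cols(records, unlist(cols), paste(type, "table"))

  n_input <- nrow(records)
  reasons <- empty_df(record_id = "character", rule = "character",
                      action = "character")
  add_reason <- function(ids, rule, action) {
    reasons <<- rbind(reasons, data.frame(record_id = ids, rule = rule,
                                          action = action,
                                          stringsAsFactors = FALSE))
  }

  start <- records[[cols$start]]
  end <- records[[cols$end]]
  id <- records[[cols$id]]

  drop <- is.na(start) | is.na(end)
  if (any(drop)) add_reason(id[drop], "missing_datetime", "drop")

  inverted <- !drop & end < start
  if (policy$midnight_repair && any(inverted)) {
    repaired_end <- end + 86400
    dur_min <- minutes_between(start, repaired_end)
    fix <- inverted & dur_min > 0 & dur_min <= policy$midnight_cap_hours * 60
    if (any(fix)) {
      end[fix] <- repaired_end[fix]
      records[[cols$end]] <- end
      add_reason(id[fix], "midnight_slip", "modify")
      inverted <- inverted & !fix
    }
  }
  if (any(inverted)) {
    if (policy$unrepairable == "drop") {
      add_reason(id[inverted], "end_before_start", "drop")
      drop <- drop | inverted
    } else {
      add_reason(id[inverted], "end_before_start", "flag")
    }
  }

  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = new_cleaning_report(n_input, reasons))
}
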