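#' Column-name dialects for visit and episode tables
#'
#' A dialect maps the canonical field names used throughout the package to
#' the column headers of a particular CSV extract. Two canonical dialects
#' are provided: `dialect_vemd()` for ED-visit tables (emergency minimum
#' dataset style) and `dialect_vaed()` for admitted-episode tables. Date
#' and clock time are separate columns in both, as delivered by the source
#' systems; [read_visits()] and [read_episodes()] assemble them.
#'
#' Required canonical fields for visits: `participant_id`, `visit_id`,
#' `arrival_date`, `arrival_time`, `departure_date`, `departure_time`,
#' `departure_status`, `campus`; optional: `visit_type`, `referred_by`.
#' For episodes: `participant_id`, `episode_id`, `admission_date`,
#' `admission_time`, `separation_date`, `separation_time`,
#' `admission_type`, `separation_mode`, `campus`; optional:
#' `admission_source`, `care_type`.
#'
#' @param ... canonical-name = file-column-name overrides.
#' @return a named character vector of class `tempolink_dialect`.
#' @export
dialect_vemd <- function(...) {
  base <- c(participant_id = "participant_id", visit_id = "visit_id",
            arrival_date = "arrival_date", arrival_time = "arrival_time",
            departure_date = "departure_date", departure_time = "departure_time",
            departure_status = "departure_status", campus = "campus",
            visit_type = "visit_type", referred_by = "referred_by")
  make_dialect(base, ...)
}

#' @rdname dialect_vemd
#' @export
dialect_vaed <- function(...) {
  base <- c(participant_id = "participant_id", episode_id = "episode_id",
            admission_date = "admission_date", admission_time = "admission_time",
            separation_date = "separation_date", separation_time = "separation_time",
            admission_type = "admission_type", admission_source = "admission_source",
            separation_mode = "separation_mode", campus = "campus",
            care_type = "care_type")
  make_dialect(base, ...)
}

make_dialect <- function(base, ...) {
  over <- c(...)
  if (length(over) > 0L) {
    unknown <- setdiff(names(over), names(base))
    if (length(unknown) > 0L) {
      stop("unknown dialect field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    base[names(over)] <- over
  }
  structure(base, class = "tempolink_dialect")
}

visit_required <- c("participant_id", "visit_id", "arrival_date",
                    "arrival_time", "departure_date", "departure_time",
                    "departure_status", "campus")
episode_required <- c("participant_id", "episode_id", "admission_date",
                      "admission_time", "separation_date", "separation_time",
                      "admission_type", "separation_mode", "campus")

#' Read ED visit or hospital episode records from CSV
#'
#' Reads an RFC-4180 CSV (UTF-8, header row required), renames columns per
#' the dialect, assembles minute-resolution arrival/departure (admission/
#' separation) timestamps from the separate date and time columns, and
#' applies the missing-time policy. Rows whose date fails to parse are
#' dropped and itemised in the report; a mapped column absent from the file
#' is a configuration error; a duplicated record id violates the uniqueness
#' invariant and is an error naming the offenders.
#'
#' @param path CSV file path.
#' @param dialect a [dialect_vemd()] / [dialect_vaed()] column map.
#' @param policy a [clean_policy()]; only its `missing_time` element is
#'   used here (run [validate_and_clean()] for the ordering rules).
#' @return list with `records` (data frame with `arrival_dt`/`departure_dt`
#'   or `admission_dt`/`separation_dt` POSIXct columns and a logical
#'   `time_imputed` column) and `report` (a `cleaning_report`).
#' @export
read_visits <- function(path, dialect = dialect_vemd(),
                        policy = clean_policy()) {
  read_records(path, dialect, policy,
               required = visit_required, id_col = "visit_id",
               start = c("arrival_date", "arrival_time", "arrival_dt"),
               end = c("departure_date", "departure_time", "departure_dt"),
               optional = c("visit_type", "referred_by"))
}

#' @rdname read_visits
#' @export
read_episodes <- function(path, dialect = dialect_vaed(),
                          policy = clean_policy()) {
  read_records(path, dialect, policy,
               required = episode_required, id_col = "episode_id",
               start = c("admission_date", "admission_time", "admission_dt"),
               end = c("separation_date", "separation_time", "separation_dt"),
               optional = c("admission_source", "care_type"))
}

read_records <- function(path, dialect, policy, required, id_col,
                         start, end, optional) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  need <- dialect[required]
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    stop(sprintf("configuration error: %s lacks mapped column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- raw[, unname(dialect[required]), drop = FALSE]
  names(df) <- required
  for (canon in optional) {
    col <- dialect[[canon]]
    df[[canon]] <- if (!is.na(col) && col %in% names(raw)) raw[[col]] else
      rep(NA_character_, nrow(raw))
  }

  dup <- df[[id_col]][duplicated(df[[id_col]])]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate %s value(s): %s", id_col,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }

  s <- assemble_datetime(df[[start[1]]], df[[start[2]]],
                         missing_time = policy$missing_time)
  e <- assemble_datetime(df[[end[1]]], df[[end[2]]],
                         missing_time = policy$missing_time)
  df[[start[3]]] <- s$datetime
  df[[end[3]]] <- e$datetime
  df$time_imputed <- s$flagged | e$flagged
  df[[start[1]]] <- df[[start[2]]] <- df[[end[1]]] <- df[[end[2]]] <- NULL

  reasons <- empty_df(record_id = "character", rule = "character",
                      action = "character")
  add <- function(rows, rule, action) {
    if (length(rows) > 0L) {
      reasons <<- rbind(reasons, data.frame(record_id = df[[id_col]][rows],
                                            rule = rule, action = action,
                                            stringsAsFactors = FALSE))
    }
  }
  add(which(s$flagged | e$flagged), "missing_time_imputed", "modify")
  add(which(s$dropped | e$dropped), "missing_time", "drop")
  parse_bad <- sort(unique(c(s$errors$row, e$errors$row)))
  add(parse_bad, "unparseable_datetime", "drop")

  drop <- s$dropped | e$dropped
  drop[parse_bad] <- TRUE
  out <- df[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = new_cleaning_report(nrow(df), reasons))
}

#' Write visit or episode records to CSV
#'
#' Inverse of [read_visits()] / [read_episodes()]: timestamps are split back
#' into the dialect's separate date (`YYYY-MM-DD`) and time (`HH:MM`)
#' columns, so a write-then-read round trip reproduces every field value at
#' minute resolution.
#'
#' @param records a visits or episodes data frame.
#' @param path output CSV path.
#' @param dialect column map naming the output headers.
#' @return `path`, invisibly.
#' @export
write_visits <- function(records, path, dialect = dialect_vemd()) {
  write_records(records, path, dialect,
                start = c("arrival_date", "arrival_time", "arrival_dt"),
                end = c("departure_date", "departure_time", "departure_dt"),
                order = c("participant_id", "visit_id", "arrival_date",
                          "arrival_time", "departure_date", "departure_time",
                          "departure_status", "campus", "visit_type",
                          "referred_by"))
}

#' @rdname write_visits
#' @export
write_episodes <- function(records, path, dialect = dialect_vaed()) {
  write_records(records, path, dialect,
                start = c("admission_date", "admission_time", "admission_dt"),
                end = c("separation_date", "separation_time", "separation_dt"),
                order = c("participant_id", "episode_id", "admission_date",
                          "admission_time", "separation_date",
                          "separation_time", "admission_type",
                          "admission_source", "separation_mode", "campus",
                          "care_type"))
}

write_records <- function(records, path, dialect, start, end, order) {
  df <- records
  df[[start[1]]] <- format_date_col(df[[start[3]]])
  df[[start[2]]] <- format_time_col(df[[start[3]]])
  df[[end[1]]] <- format_date_col(df[[end[3]]])
  df[[end[2]]] <- format_time_col(df[[end[3]]])
  df <- df[, intersect(order, names(df)), drop = FALSE]
  names(df) <- vapply(names(df), function(n) unname(dialect[[n]] %||% n), "")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
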