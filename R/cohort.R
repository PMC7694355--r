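#' Deterministic cohort-to-dataset identifier matching
#'
#' First-stage linkage of a recruited cohort to an administrative dataset
#' requires a 100% match across four identifier fields: Medicare number,
#' the first three letters of the first name, date of birth, and sex. A
#' pair is emitted iff all four normalised fields are exactly equal.
#'
#' Normalisation: Medicare numbers have whitespace removed; the name prefix
#' is the first three alphabetic characters, compared case-insensitively;
#' dates of birth are compared as ISO date strings; sex as a lower-cased
#' trimmed token. Records missing any of the four fields are excluded from
#' matching and itemised in the `excluded` attribute.
#'
#' @param cohort,dataset data frames with columns `id`, `medicare_number`,
#'   `first_name`, `date_of_birth`, `sex`.
#' @return data frame with columns `cohort_id`, `dataset_id`, one row per
#'   matched pair, with an `excluded` attribute (data frame of
#'   `(side, id, field)` for records left out). The operation is symmetric
#'   in its two arguments up to pair orientation.
#' @export
match_cohort_to_dataset <- function(cohort, dataset) {
  cols <- c("id", "medicare_number", "first_name", "date_of_birth", "sex")
  stopifnot_cols(cohort, cols, "cohort table")
  stopifnot_cols(dataset, cols, "dataset table")

  prep <- function(df, side) {
    key <- data.frame(
      id = as.character(df$id),
      medicare = gsub("[[:space:]]", "", as.character(df$medicare_number)),
      prefix3 = substr(tolower(gsub("[^[:alpha:]]", "",
                                    as.character(df$first_name))), 1, 3),
      dob = as.character(df$date_of_birth),
      sex = tolower(trimws(as.character(df$sex))),
      stringsAsFactors = FALSE
    )
    bad <- apply(key[-1], 1, function(r) any(is.na(r) | !nzchar(r)))
    field <- character(0)
    if (any(bad)) {
      field <- apply(key[bad, -1, drop = FALSE], 1, function(r) {
        paste(c("medicare_number", "first_name", "date_of_birth",
                "sex")[is.na(r) | !nzchar(r)], collapse = ",")
      })
    }
    list(key = key[!bad, , drop = FALSE],
         excluded = data.frame(side = rep(side, sum(bad)),
                               id = key$id[bad], field = field,
                               stringsAsFactors = FALSE))
  }
  a <- prep(cohort, "cohort")
  b <- prep(dataset, "dataset")

  m <- merge(a$key, b$key, by = c("medicare", "prefix3", "dob", "sex"),
             suffixes = c(".cohort", ".dataset"))
  out <- data.frame(cohort_id = m$id.cohort, dataset_id = m$id.dataset,
                    stringsAsFactors = FALSE)
  out <- out[order_radix(out$cohort_id, out$dataset_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- rbind(a$excluded, b$excluded)
  out
}
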