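#' Disposition-code group maps
#'
#' The linkage audit and the episode chaining both interpret administrative
#' disposition codes through named code groups rather than raw code values,
#' because code sets in emergency and admitted-episode datasets drift across
#' reporting years. A `code_maps` object holds the five groups the method
#' needs:
#'
#' * `departure_status_admission_expected` — ED departure-status codes that
#'   assert the patient was admitted (ward at this hospital, procedure room
#'   at this campus, transfer to another campus of the same service).
#' * `departure_status_no_admission` — codes asserting no admission occurred
#'   (return to usual residence, left before treatment completed, dead on
#'   arrival or died in the ED).
#' * `admission_type_ed_expected` — admitted-episode admission-type codes
#'   that explicitly state the admission arose through this hospital's ED.
#' * `admission_type_uncertain` — admission-type codes that cannot confirm a
#'   preceding ED visit (waiting list, other, maternity, statistical
#'   admission, other emergency admission).
#' * `separation_mode_transfer` — separation-mode codes indicating a
#'   *planned* transfer of care (statistical separation, i.e. a care-type
#'   change within the same hospital, and separation with transfer to
#'   another hospital); these are what allow sequential episodes to be
#'   chained into one continuous episode of care.
#' * `separation_mode_no_transfer` — separation modes that close a hospital
#'   stay (discharge home, death, left against advice). Not required by the
#'   algorithms (any unmapped mode is treated as non-transfer) but listing
#'   them keeps clean datasets free of "unmapped code" warnings.
#'
#' @param departure_status_admission_expected,departure_status_no_admission
#'   character vectors of ED departure-status codes.
#' @param admission_type_ed_expected,admission_type_uncertain character
#'   vectors of admission-type codes.
#' @param separation_mode_transfer,separation_mode_no_transfer character
#'   vectors of separation-mode codes.
#' @return an object of class `code_maps` (a named list of character
#'   vectors).
#' @seealso [read_code_maps()], [write_code_maps()]
#' @export
code_maps <- function(
    departure_status_admission_expected = c("ward_this_hospital",
                                            "procedure_room_this_campus",
                                            "transfer_other_campus"),
    departure_status_no_admission = c("usual_residence",
                                      "left_before_treatment_complete",
                                      "died_in_ed"),
    admission_type_ed_expected = "emergency_this_hospital",
    admission_type_uncertain = c("waiting_list", "other_admission",
                                 "maternity", "statistical_admission",
                                 "other_emergency"),
    separation_mode_transfer = c("statistical_separation",
                                 "transfer_other_hospital"),
    separation_mode_no_transfer = c("discharge_home", "died_in_hospital",
                                    "left_against_advice")) {
  maps <- list(
    departure_status_admission_expected = as.character(departure_status_admission_expected),
    departure_status_no_admission = as.character(departure_status_no_admission),
    admission_type_ed_expected = as.character(admission_type_ed_expected),
    admission_type_uncertain = as.character(admission_type_uncertain),
    separation_mode_transfer = as.character(separation_mode_transfer),
    separation_mode_no_transfer = as.character(separation_mode_no_transfer)
  )
  validate_code_maps(maps)
  structure(maps, class = "code_maps")
}

# Pairs of groups over the same code variable must be disjoint, otherwise a
# code could be counted in both arms of a cross-tabulation.
validate_code_maps <- function(maps) {
  disjoint <- function(a, b, la, lb) {
    both <- intersect(maps[[a]], maps[[b]])
    if (length(both) > 0L) {
      stop(sprintf("code group '%s' and '%s' overlap: %s",
                   la, lb, paste(both, collapse = ", ")), call. = FALSE)
    }
  }
  disjoint("departure_status_admission_expected", "departure_status_no_admission",
           "admission expected", "no admission")
  disjoint("admission_type_ed_expected", "admission_type_uncertain",
           "ED expected", "uncertain")
  disjoint("separation_mode_transfer", "separation_mode_no_transfer",
           "transfer", "no transfer")
  invisible(maps)
}

#' Read or write code maps as YAML
#'
#' Code groups are deliberately kept in an editable mapping file so a study
#' can adapt them to the code values of its own extract years without
#' touching code.
#'
#' @param path path to a YAML file whose top-level keys are the six group
#'   names accepted by [code_maps()].
#' @return `read_code_maps()` returns a `code_maps` object;
#'   `write_code_maps()` returns `path` invisibly.
#' @export
read_code_maps <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(code_maps))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown code group(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(code_maps, raw)
}

#' @rdname read_code_maps
#' @param maps a `code_maps` object.
#' @export
write_code_maps <- function(maps, path) {
  stopifnot(inherits(maps, "code_maps"))
  yaml::write_yaml(lapply(unclass(maps), as.list), path)
  invisible(path)
}

#' @export
print.code_maps <- function(x, ...) {
  cat("Disposition code maps:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-36s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

# Map a vector of codes to a group label among `groups` (a named list of
# code vectors); codes in no group become NA and are reported by callers.
map_codes <- function(codes, groups) {
  out <- rep(NA_character_, length(codes))
  for (nm in names(groups)) {
    out[codes %in% groups[[nm]]] <- nm
  }
  out
}
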