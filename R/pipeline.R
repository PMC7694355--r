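#' Pipeline run configuration
#'
#' Bundles everything one reproducible clean-chain-link-audit run needs.
#' Either construct it directly or load it from a YAML file whose keys
#' mirror the arguments (`run_config_from_yaml()`); window and chaining
#' scalars override the nested config defaults so a run is fully described
#' by one file.
#'
#' @param visits_file,episodes_file input CSV paths.
#' @param out_dir output directory (created if needed).
#' @param visits_dialect,episodes_dialect column maps.
#' @param link a [link_config()].
#' @param chain a [chain_config()].
#' @param maps a [code_maps()] object or path to a YAML code-maps file.
#' @param policy a [clean_policy()].
#' @return an object of class `run_config`.
#' @export
run_config <- function(visits_file, episodes_file, out_dir,
                       visits_dialect = dialect_vemd(),
                       episodes_dialect = dialect_vaed(),
                       link = link_config(),
                       chain = chain_config(),
                       maps = code_maps(),
                       policy = clean_policy()) {
  if (is.character(maps)) maps <- read_code_maps(maps)
  structure(list(
    visits_file = visits_file, episodes_file = episodes_file,
    out_dir = out_dir,
    visits_dialect = visits_dialect, episodes_dialect = episodes_dialect,
    link = link, chain = chain, maps = maps, policy = policy
  ), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file; recognised keys: `visits_file`, `episodes_file`,
#'   `out_dir`, `post_departure_hours`, `pre_arrival_hours`,
#'   `link_after_chaining`, `chain_window_hours`, `anchor`, `code_maps`
#'   (path), `missing_time`, `unrepairable`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  run_config(
    visits_file = resolve(y$visits_file),
    episodes_file = resolve(y$episodes_file),
    out_dir = y$out_dir %||% file.path(base, "tempolink-out"),
    link = link_config(
      post_departure_hours = y$post_departure_hours %||% 24,
      pre_arrival_hours = y$pre_arrival_hours %||% 24,
      link_after_chaining = y$link_after_chaining %||% TRUE),
    chain = chain_config(
      chain_window_hours = y$chain_window_hours %||% 24,
      anchor = y$anchor %||% "separation_of_predecessor"),
    maps = if (!is.null(y$code_maps)) resolve(y$code_maps) else code_maps(),
    policy = clean_policy(
      missing_time = y$missing_time %||% "impute",
      unrepairable = y$unrepairable %||% "drop")
  )
}

#' Run the full linkage pipeline
#'
#' Executes read/clean, chain, link and audit in order and writes a fixed
#' output layout under `config$out_dir`: cleaned tables, long-format chain
#' labels, wide-format linked pairs, unlinked tables, audit JSON, and a
#' `manifest.json` holding the configuration snapshot, record counts, and
#' an MD5 content hash of every artefact — identical inputs and
#' configuration yield identical hashes. A failure in any stage aborts with
#' an error naming the stage; no partial manifest is written.
#'
#' @param config a [run_config()] or path to its YAML file.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- run_config_from_yaml(config)
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  inp <- stage("input", {
    for (f in c(config$visits_file, config$episodes_file)) {
      if (!file.exists(f)) stop("input file not found: ", f)
    }
    list(v = read_visits(config$visits_file, config$visits_dialect,
                         config$policy),
         e = read_episodes(config$episodes_file, config$episodes_dialect,
                           config$policy))
  })
  cleaned <- stage("clean", {
    v <- validate_and_clean(inp$v$records, "visits", config$policy)
    e <- validate_and_clean(inp$e$records, "episodes", config$policy)
    list(visits = v$records, episodes = e$records,
         report_visits = merge_cleaning_reports(inp$v$report, v$report),
         report_episodes = merge_cleaning_reports(inp$e$report, e$report))
  })
  chains <- stage("chain", {
    chain_episodes(cleaned$episodes, config$maps, config$chain)
  })
  result <- stage("link", {
    link_records(cleaned$visits, cleaned$episodes, config$link,
                 config$maps, config$chain)
  })
  audit <- stage("audit", {
    list(summary = linkage_summary(result, chains),
         departure_status = departure_status_crosstab(result, config$maps),
         admission_type = admission_type_crosstab(result, config$maps))
  })

  manifest <- stage("output", {
    dir <- config$out_dir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_visits(cleaned$visits, file.path(dir, "visits_clean.csv"))
    write_episodes(cleaned$episodes, file.path(dir, "episodes_clean.csv"))
    cleaning_report_json(cleaned$report_visits,
                         file.path(dir, "cleaning_visits.json"))
    cleaning_report_json(cleaned$report_episodes,
                         file.path(dir, "cleaning_episodes.json"))
    write_chains(chains, dir)
    write_linkage_result(result, dir)
    jsonlite::write_json(audit_json(audit), file.path(dir, "audit.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    files <- sort(setdiff(list.files(dir), "manifest.json"))
    hashes <- as.list(tools::md5sum(file.path(dir, files)))
    names(hashes) <- files
    man <- list(
      config = config_snapshot(config),
      counts = result$counts[c("n_visits", "n_episodes", "n_linked",
                               "n_unlinked_visits", "n_unlinked_episodes")],
      n_chains = nrow(chains$chains),
      n_continuations = sum(chains$labels$label == "continuation"),
      files = hashes
    )
    jsonlite::write_json(man, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    man
  })
  invisible(manifest)
}

audit_json <- function(audit) {
  ct <- function(x) {
    out <- list(cells = as.data.frame(as.table(x$cells)),
                pct_linked_agreement = x$pct_linked_agreement,
                pct_unlinked_agreement = x$pct_unlinked_agreement,
                n_excluded_unmapped = nrow(x$excluded))
    if (!is.null(x$pct_found_among_expected)) {
      out$pct_found_among_expected <- x$pct_found_among_expected
    }
    out
  }
  s <- unclass(audit$summary)
  s$category_histogram <- as.list(s$category_histogram)
  s$category_pct <- as.list(s$category_pct)
  s$category_pct_label <- as.list(s$category_pct_label)
  list(summary = s,
       departure_status = ct(audit$departure_status),
       admission_type = ct(audit$admission_type))
}

# Every default is printed into the manifest so a run is self-describing.
config_snapshot <- function(config) {
  list(
    visits_file = config$visits_file,
    episodes_file = config$episodes_file,
    visits_dialect = as.list(unclass(config$visits_dialect)),
    episodes_dialect = as.list(unclass(config$episodes_dialect)),
    link = unclass(config$link),
    chain = lapply(unclass(config$chain),
                   function(x) if (identical(x, Inf)) "unlimited" else x),
    code_maps = lapply(unclass(config$maps), as.list),
    policy = unclass(config$policy)
  )
}
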