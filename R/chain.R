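#' Episode chaining configuration
#'
#' A hospital stay that crosses care-types or campuses generates several
#' admitted episodes; chaining reassembles them. A subsequent episode
#' continues the open chain iff the predecessor's separation mode indicates
#' a *planned* transfer of care and its admission falls within
#' `chain_window_hours` after the anchor timestamp of the predecessor.
#' Requiring the planned-transfer code keeps unplanned re-presentations or
#' re-admissions within the window out of the chain.
#'
#' @param chain_window_hours window (hours) after the anchor, default 24.
#' @param anchor `"separation_of_predecessor"` (default) or
#'   `"admission_of_predecessor"`. Separation is the default because
#'   statistical separations are instantaneous care-type changes and
#'   transfers follow the close of the prior episode.
#' @param max_chain_length maximum episodes per chain (`Inf` = unlimited).
#' @return an object of class `chain_config`.
#' @export
chain_config <- function(chain_window_hours = 24,
                         anchor = c("separation_of_predecessor",
                                    "admission_of_predecessor"),
                         max_chain_length = Inf) {
  stopifnot(chain_window_hours >= 0)
  structure(list(
    chain_window_hours = as.numeric(chain_window_hours),
    anchor = match.arg(anchor),
    max_chain_length = max_chain_length
  ), class = "chain_config")
}

#' Identify continuous episodes of care
#'
#' Within each participant, episodes are processed in
#' (`admission_dt`, `separation_dt`, `episode_id`) order. An episode is
#' appended to the open chain iff the chain's last episode carries a
#' transfer separation code (per `code_maps$separation_mode_transfer`) and
#' its admission lies within the chain window after that episode's anchor
#' timestamp; otherwise it opens a new chain as an index admission. Every
#' episode is labelled exactly once as `"index"` or `"continuation"`.
#'
#' Three data-quality situations are reported, not raised: separation-mode
#' codes in neither the transfer nor the no-transfer group (treated as
#' non-transfer), transfer-coded episodes whose successor never arrives
#' within the window (dangling planned transfers, left as chain termini),
#' and overlapping episodes chained together (admission before the
#' predecessor's separation — legitimate for same-hospital statistical
#' separations, but worth eyeballing).
#'
#' @param episodes cleaned episode table.
#' @param code_maps a [code_maps()].
#' @param config a [chain_config()].
#' @return an object of class `episode_chains`: list with
#'   \describe{
#'     \item{labels}{data frame `(episode_id, participant_id, chain_id,
#'       position, label)`; `position` is 1 for the index.}
#'     \item{chains}{data frame per chain: `chain_id`, `participant_id`,
#'       `index_episode_id`, `length`, `stay_start` (index admission),
#'       `stay_end` (last separation).}
#'     \item{report}{list of `unmapped_separation_modes`,
#'       `dangling_transfers` (episode ids), `overlapping_episodes`.}
#'   }
#' @export
chain_episodes <- function(episodes, code_maps = tempolink::code_maps(),
                           config = chain_config()) {
  stopifnot_cols(episodes, c("participant_id", "episode_id", "admission_dt",
                             "separation_dt", "separation_mode"),
                 "episodes table")
  n <- nrow(episodes)
  e <- episodes[order_radix(episodes$participant_id,
                            as.numeric(episodes$admission_dt),
                            as.numeric(episodes$separation_dt),
                            episodes$episode_id), , drop = FALSE]
  transfer <- e$separation_mode %in% code_maps$separation_mode_transfer
  known <- transfer | e$separation_mode %in% code_maps$separation_mode_no_transfer
  window_min <- config$chain_window_hours * 60

  chain_id <- integer(n)
  position <- integer(n)
  next_chain <- 0L
  overlap <- character(0)
  if (n > 0L) {
    open_len <- 0L
    for (i in seq_len(n)) {
      new_participant <- i == 1L || e$participant_id[i] != e$participant_id[i - 1L]
      continue <- FALSE
      if (!new_participant && open_len < config$max_chain_length &&
          transfer[i - 1L]) {
        anchor_t <- if (config$anchor == "separation_of_predecessor") {
          e$separation_dt[i - 1L]
        } else {
          e$admission_dt[i - 1L]
        }
        gap <- minutes_between(anchor_t, e$admission_dt[i])
        continue <- gap >= 0 && gap <= window_min
        # admissions sorted ascending, so gap < 0 only against a separation
        # anchor when episodes overlap; such an episode still continues the
        # chain (statistical separations may share timestamps) but is listed
        if (e$admission_dt[i] < e$separation_dt[i - 1L] &&
            minutes_between(e$admission_dt[i - 1L], e$admission_dt[i]) >= 0 &&
            transfer[i - 1L]) {
          continue <- TRUE
          overlap <- c(overlap, e$episode_id[i])
        }
      }
      if (continue) {
        chain_id[i] <- chain_id[i - 1L]
        position[i] <- position[i - 1L] + 1L
        open_len <- open_len + 1L
      } else {
        next_chain <- next_chain + 1L
        chain_id[i] <- next_chain
        position[i] <- 1L
        open_len <- 1L
      }
    }
  }

  labels <- data.frame(
    episode_id = e$episode_id,
    participant_id = e$participant_id,
    chain_id = chain_id,
    position = position,
    label = ifelse(position == 1L, "index", "continuation"),
    stringsAsFactors = FALSE
  )
  rownames(labels) <- NULL

  chains <- empty_df(chain_id = "integer", participant_id = "character",
                     index_episode_id = "character", length = "integer")
  chains$stay_start <- as.POSIXct(character(0), tz = "UTC")
  chains$stay_end <- as.POSIXct(character(0), tz = "UTC")
  if (n > 0L) {
    idx <- which(position == 1L)
    len <- as.integer(tabulate(chain_id, nbins = next_chain))
    stay_end <- as.POSIXct(
      vapply(split(as.numeric(e$separation_dt), chain_id), max, 0),
      origin = "1970-01-01", tz = "UTC")
    chains <- data.frame(
      chain_id = chain_id[idx],
      participant_id = e$participant_id[idx],
      index_episode_id = e$episode_id[idx],
      length = len[chain_id[idx]],
      stringsAsFactors = FALSE
    )
    chains$stay_start <- e$admission_dt[idx]
    chains$stay_end <- stay_end[as.character(chains$chain_id)]
    rownames(chains) <- NULL
  }

  # transfer-coded episodes that end a chain: planned transfer never taken up
  last_in_chain <- !duplicated(chain_id, fromLast = TRUE)
  dangling <- e$episode_id[last_in_chain & transfer]

  structure(list(
    labels = labels,
    chains = chains,
    config = config,
    report = list(
      unmapped_separation_modes = sort(unique(e$separation_mode[!known])),
      dangling_transfers = dangling,
      overlapping_episodes = overlap
    )
  ), class = "episode_chains")
}

#' @export
print.episode_chains <- function(x, ...) {
  n_ep <- nrow(x$labels)
  n_ch <- nrow(x$chains)
  n_cont <- sum(x$labels$label == "continuation")
  cat(sprintf("Episode chains: %d episode(s) in %d chain(s); %d index, %d continuation\n",
              n_ep, n_ch, n_ch, n_cont))
  if (n_ch > 0L) {
    cat("  Chain-length histogram:\n")
    h <- table(x$chains$length)
    for (k in names(h)) cat(sprintf("    length %s: %d\n", k, h[[k]]))
  }
  rep <- x$report
  if (length(rep$unmapped_separation_modes) > 0L) {
    cat("  Unmapped separation modes (treated as non-transfer): ",
        paste(rep$unmapped_separation_modes, collapse = ", "), "\n")
  }
  if (length(rep$dangling_transfers) > 0L) {
    cat(sprintf("  Dangling planned transfers: %d\n",
                length(rep$dangling_transfers)))
  }
  invisible(x)
}

#' Write chains to long-format CSV plus a chain-length histogram
#'
#' One row per episode with its chain id, position and index/continuation
#' label — continuations stored under their index admission — plus a JSON
#' summary with the chain-length histogram.
#'
#' @param chains an `episode_chains` object.
#' @param dir output directory.
#' @return named vector of files written, invisibly.
#' @export
write_chains <- function(chains, dir) {
  stopifnot(inherits(chains, "episode_chains"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(long = file.path(dir, "chains_long.csv"),
             summary = file.path(dir, "chain_summary.json"))
  utils::write.csv(chains$labels, files[["long"]], row.names = FALSE)
  h <- table(chains$chains$length)
  jsonlite::write_json(list(
    n_chains = nrow(chains$chains),
    n_index = sum(chains$labels$label == "index"),
    n_continuation = sum(chains$labels$label == "continuation"),
    chain_length_histogram = as.list(h),
    dangling_transfers = length(chains$report$dangling_transfers)
  ), files[["summary"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}
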