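#' Serialize an ecosystem snapshot to JSON
#'
#' Writes the full parameterization of a community (and optionally its
#' state) as a JSON document with fields `bacteria` (list of
#' `{id, k, birth_step}`), `phages` (list of `{id, beta, birth_step}`),
#' `eta` (dense row-major, phage-major), `alpha`, `delta`, and `B`/`P` when
#' a state is supplied. The round trip through [ecosystem_from_json()] is
#' lossless at full floating precision.
#'
#' @param eco An [ecosystem()] object.
#' @param state Optional [community_state()].
#' @return A JSON string (class `json`).
#' @export
ecosystem_to_json <- function(eco, state = NULL) {
  x <- list(
    bacteria = eco$bacteria[, c("id", "k", "birth_step")],
    phages = eco$phages[, c("id", "beta", "birth_step")],
    eta = if (length(eco$eta)) unname(eco$eta) else
      matrix(numeric(0), n_phages(eco), n_bacteria(eco)),
    alpha = eco$rates$alpha,
    delta = eco$rates$delta)
  if (!is.null(state)) {
    x$B <- state$B
    x$P <- state$P
  }
  jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE,
                   matrix = "rowmajor", dataframe = "rows")
}

#' Restore an ecosystem snapshot from JSON
#'
#' @param json A JSON string produced by [ecosystem_to_json()].
#' @return A list with `eco` (an [ecosystem()]) and `state` (a
#'   [community_state()] or `NULL` when none was serialized).
#' @export
ecosystem_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  bact <- as.data.frame(x$bacteria)
  phag <- as.data.frame(x$phages)
  if (nrow(bact)) bact$birth_step <- as.integer(bact$birth_step)
  if (nrow(phag)) phag$birth_step <- as.integer(phag$birth_step)
  eta <- x$eta
  if (is.null(dim(eta))) {
    eta <- matrix(as.numeric(unlist(eta)), nrow = nrow(phag),
                  ncol = nrow(bact), byrow = TRUE)
  }
  eco <- ecosystem(bacteria = bact, phages = phag, eta = eta,
                   rates = global_rates(alpha = x$alpha, delta = x$delta))
  state <- if (!is.null(x$B))
    community_state(B = as.numeric(x$B), P = as.numeric(x$P))
  list(eco = eco, state = state)
}

#' Write an assembly event log as JSON lines
#'
#' One JSON record per invasion event with the step, invader description,
#' outcome flags, extinct ids, and the post-event ecosystem snapshot
#' (including its steady state).
#'
#' @param history An [run_assembly()] history.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(history, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ev in history$events) {
    rec <- list(
      step = ev$step,
      invader_kind = ev$invader_kind,
      invader_id = ev$invader_id,
      invader = ev$invader,
      success = ev$success,
      discarded = ev$discarded,
      non_convergence = ev$non_convergence,
      extinct_ids = ev$extinct_ids,
      post_eco = jsonlite::fromJSON(
        ecosystem_to_json(ev$post_eco, ev$post_state), simplifyVector = FALSE))
    writeLines(jsonlite::toJSON(rec, digits = I(17), auto_unbox = TRUE,
                                null = "null"), con)
  }
  invisible(path)
}

#' Read an event log written by [write_event_log()]
#'
#' @param path File path.
#' @return A list of event records; each `post_eco` field is restored to an
#'   [ecosystem()] plus [community_state()] pair.
#' @export
read_event_log <- function(path) {
  lapply(readLines(path), function(line) {
    rec <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    rec$extinct_ids <- as.character(unlist(rec$extinct_ids))
    rec$post_eco <- ecosystem_from_json(
      jsonlite::toJSON(rec$post_eco, digits = I(17), auto_unbox = TRUE))
    rec
  })
}

#' Write / read the per-step summary table
#'
#' Tab-separated table with columns `step`, `n_bacteria`, `n_phages`,
#' `invader_kind`, `success`, `n_extinct`.
#'
#' @param history An [run_assembly()] history.
#' @param path File path.
#' @return `path` (writer, invisibly) or a data.frame (reader).
#' @export
write_history_summary <- function(history, path) {
  s <- history_summary(history)
  s <- s[, c("step", "n_bacteria", "n_phages", "invader_kind", "success",
             "n_extinct")]
  write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history_summary
#' @export
read_history_summary <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write the eliminate-the-winner events table
#'
#' Tab-separated scatter data of detected events: `step`, `trigger`,
#' `k_R_over_k_S`, `eta_R_over_eta_S`.
#'
#' @param events Output of [detect_elimination_events()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_elimination_events <- function(events, path) {
  out <- data.frame(step = events$step, trigger = events$trigger,
                    k_R_over_k_S = events$ratio_k,
                    eta_R_over_eta_S = events$ratio_eta)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a triplet phase diagram grid as TSV
#'
#' @param grid Output of [triplet_phase_diagram()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_phase_diagram <- function(grid, path) {
  write.table(data.frame(eta_ratio = grid$eta_ratio, k_ratio = grid$k_ratio,
                         outcome = as.character(grid$outcome)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
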