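# Resumable labeling of cell detections. Semantics: "good" -> label 1,
# "bad" -> 0, "question" -> missing; "return" (undo) steps back one record
# and allows overwriting. The core is a headless state machine; any
# front-end (see the `label` CLI subcommand) is a thin loop over it.

#' Start a labeling session
#'
#' Records are traversed in (frame ascending, cell_id ascending) order.
#' An existing `label` column is preserved: 1 becomes a "good" verdict, 0
#' "bad"; missing labels count as unvisited.
#'
#' @param features Feature table (needs `frame` and `cell_id`; typically
#'   from [extract_feature_table()]).
#' @param resume_at Optional `c(frame, cell_id)` to place the cursor on.
#' @return A `label_session` object.
#' @export
start_session <- function(features, resume_at = NULL) {
  if (!nrow(features)) stop_validation("cannot label an empty feature table")
  ord <- order(features$frame, features$cell_id)
  features <- features[ord, , drop = FALSE]
  n <- nrow(features)
  verdicts <- rep(NA_character_, n)
  if ("label" %in% names(features)) {
    verdicts[which(features$label %in% 1)] <- "good"
    verdicts[which(features$label %in% 0)] <- "bad"
  }
  cursor <- 1L
  if (!is.null(resume_at)) {
    hit <- which(features$frame == resume_at[1L] & features$cell_id == resume_at[2L])
    if (!length(hit)) {
      d <- abs(features$frame - resume_at[1L]) * 1e6 + abs(features$cell_id - resume_at[2L])
      near <- which.min(d)
      stop_validation(sprintf(
        "resume position (frame %d, cell %d) not found; nearest is (frame %d, cell %d)",
        resume_at[1L], resume_at[2L], features$frame[near], features$cell_id[near]))
    }
    cursor <- hit
  }
  structure(list(features = features, verdicts = verdicts, cursor = cursor,
                 dirty = FALSE),
            class = "label_session")
}

#' Current record under the session cursor
#' @param session A `label_session`.
#' @return One-row tibble, or `NULL` when all records have been visited.
#' @export
current_record <- function(session) {
  if (session$cursor > nrow(session$features)) return(NULL)
  session$features[session$cursor, , drop = FALSE]
}

#' Record a verdict for the current cell and advance
#'
#' @param session A `label_session`.
#' @param verdict `"good"`, `"bad"` or `"question"`.
#' @return The updated session (cursor advanced by one).
#' @export
assign_verdict <- function(session, verdict) {
  verdict <- match.arg(verdict, c("good", "bad", "question"))
  if (session$cursor > nrow(session$features)) {
    stop_state("all records have been labeled; nothing to assign")
  }
  session$verdicts[session$cursor] <- verdict
  session$cursor <- session$cursor + 1L
  session$dirty <- TRUE
  session
}

#' Step back to the previous record
#'
#' The previous verdict is retained until overwritten by a new
#' [assign_verdict()].
#'
#' @param session A `label_session`.
#' @return The updated session (cursor decremented).
#' @export
undo_verdict <- function(session) {
  if (session$cursor <= 1L) stop_state("already at the first record; cannot undo")
  session$cursor <- session$cursor - 1L
  session$dirty <- TRUE
  session
}

#' Finalize a session into a labeled feature table
#'
#' @param session A `label_session`.
#' @return List with `features` (the table with a `label` column: 1 good,
#'   0 bad, `NA` for question or unvisited) and `report` (cursor position
#'   and verdict counts).
#' @export
finalize_session <- function(session) {
  labels <- rep(NA_real_, nrow(session$features))
  labels[session$verdicts %in% "good"] <- 1
  labels[session$verdicts %in% "bad"] <- 0
  features <- session$features
  features$label <- labels
  visited <- !is.na(session$verdicts)
  pos <- current_record(session)
  report <- list(
    position = if (is.null(pos)) NULL else c(frame = pos$frame, cell_id = pos$cell_id),
    n_good = sum(session$verdicts %in% "good"),
    n_bad = sum(session$verdicts %in% "bad"),
    n_question = sum(session$verdicts %in% "question"),
    n_unvisited = sum(!visited)
  )
  list(features = features, report = report)
}

#' Save / load a labeling session
#'
#' The session state (record keys, verdicts, cursor) is written as JSON;
#' loading requires the same feature table and verifies the keys match,
#' which makes an interrupted session resume exactly where it stopped.
#'
#' @param session A `label_session`.
#' @param path JSON file path.
#' @param features The feature table the session was started from.
#' @return `save_session`: invisibly `path`; `load_session`: the restored
#'   session.
#' @export
save_session <- function(session, path) {
  state <- list(schema = "cellcurator/label_session/1",
                frame = session$features$frame,
                cell_id = session$features$cell_id,
                verdicts = session$verdicts,
                cursor = session$cursor)
  jsonlite::write_json(state, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path, features) {
  if (!file.exists(path)) stop_input(sprintf("session file not found: %s", path))
  state <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e) stop_format(
                      sprintf("cannot parse session file %s", path)))
  if (!identical(state$schema, "cellcurator/label_session/1")) {
    stop_format("unrecognized session file schema")
  }
  session <- start_session(features)
  if (!identical(as.integer(state$frame), as.integer(session$features$frame)) ||
      !identical(as.integer(state$cell_id), as.integer(session$features$cell_id))) {
    stop_validation("session file does not match the supplied feature table")
  }
  verdicts <- as.character(state$verdicts)
  verdicts[verdicts %in% "NA"] <- NA_character_
  session$verdicts <- verdicts
  session$cursor <- as.integer(state$cursor)
  session
}

#' @export
print.label_session <- function(x, ...) {
  n <- nrow(x$features)
  cat(sprintf("<label_session> %d records, cursor at %d (%d labeled)\n",
              n, x$cursor, sum(!is.na(x$verdicts))))
  invisible(x)
}
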