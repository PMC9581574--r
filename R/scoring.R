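# Scoring questionnaire data model and validation bookkeeping.
#
# Each detected event is answered with the three GUI questions: (1) true or
# false positive, and if true whether it continues a previous event; (2)
# hemisphere (left/right/both); (3) severity -- "subclinical" for an
# electrographic seizure with no behavioral correlate, otherwise a Racine
# stage I-V. Output files are JSON, one per scorer and date, so several
# people can blind-score the same events.

racine_levels <- c("subclinical", "I", "II", "III", "IV", "V")
hemisphere_levels <- c("left", "right", "both")
behavioral_stages <- c("III", "IV", "V")

#' Create one event annotation
#'
#' @param event_id Event identifier (integer or string).
#' @param is_true_positive Question 1: is this a real seizure (not artifact)?
#' @param is_continuation Continuation of the previous event; only meaningful
#'   (and only allowed) for true positives.
#' @param hemisphere Question 2: `"left"`, `"right"` or `"both"`; required
#'   iff true positive.
#' @param racine Question 3: `"subclinical"` or Racine stage `"I"`..`"V"`;
#'   required iff true positive.
#' @param comment Free-text note.
#' @param scorer_id Scorer identifier.
#' @param score_date Scoring date (`Date` or `"YYYY-MM-DD"`).
#' @return A list of class `annotation`.
#' @export
annotation <- function(event_id, is_true_positive,
                       is_continuation = FALSE,
                       hemisphere = NA_character_, racine = NA_character_,
                       comment = "", scorer_id = "anon",
                       score_date = Sys.Date()) {
  if (!is.logical(is_true_positive) || is.na(is_true_positive)) {
    lfp_abort("is_true_positive must be TRUE or FALSE", "lfpmon_validation_error")
  }
  if (is_true_positive) {
    if (is.na(hemisphere) || !hemisphere %in% hemisphere_levels) {
      lfp_abort(sprintf("event %s: true positives need hemisphere in {%s}",
                        event_id, paste(hemisphere_levels, collapse = ", ")),
                "lfpmon_validation_error")
    }
    if (is.na(racine) || !racine %in% racine_levels) {
      lfp_abort(sprintf("event %s: true positives need racine in {%s}",
                        event_id, paste(racine_levels, collapse = ", ")),
                "lfpmon_validation_error")
    }
  } else {
    if (isTRUE(is_continuation)) {
      lfp_abort(sprintf("event %s: a false positive cannot be a continuation", event_id),
                "lfpmon_validation_error")
    }
    if (!is.na(hemisphere) || !is.na(racine)) {
      lfp_abort(sprintf("event %s: hemisphere/racine only apply to true positives", event_id),
                "lfpmon_validation_error")
    }
  }
  structure(list(event_id = as.character(event_id),
                 is_true_positive = is_true_positive,
                 is_continuation = isTRUE(is_continuation),
                 hemisphere = hemisphere, racine = racine,
                 comment = as.character(comment),
                 scorer_id = as.character(scorer_id),
                 score_date = format(as.Date(score_date))),
            class = "annotation")
}

annotations_to_df <- function(annotations) {
  if (!length(annotations)) {
    return(data.frame(event_id = character(0), is_true_positive = logical(0),
                      is_continuation = logical(0), hemisphere = character(0),
                      racine = character(0), comment = character(0),
                      scorer_id = character(0), score_date = character(0)))
  }
  do.call(rbind, lapply(annotations, function(a) {
    stopifnot(inherits(a, "annotation"))
    as.data.frame(unclass(a), stringsAsFactors = FALSE)
  }))
}

#' Save annotations for one scorer
#'
#' Writes `<scorer>_<date>_annotations.json` into `out_dir` with the records
#' sorted by event id in a canonical serialization (save, load, save is
#' byte-identical).
#'
#' @param annotations List of [annotation()] objects.
#' @param scorer_id Scorer identifier used in the filename.
#' @param out_dir Output directory (created if needed).
#' @param score_date Date used in the filename (default: the annotations'
#'   date, or today when empty).
#' @return The file path, invisibly.
#' @export
save_annotations <- function(annotations, scorer_id, out_dir,
                             score_date = NULL) {
  df <- annotations_to_df(annotations)
  if (anyDuplicated(df$event_id)) {
    lfp_abort("duplicate event_id in annotation set", "lfpmon_validation_error")
  }
  if (is.null(score_date)) {
    score_date <- if (nrow(df)) df$score_date[1] else format(Sys.Date())
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, sprintf("%s_%s_annotations.json", scorer_id, score_date))
  df <- df[order(df$event_id), , drop = FALSE]
  jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Load an annotation file
#'
#' @param path Path written by [save_annotations()].
#' @return List of [annotation()] objects.
#' @export
load_annotations <- function(path) {
  rows <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(rows, function(r) {
    annotation(event_id = r$event_id,
               is_true_positive = r$is_true_positive,
               is_continuation = isTRUE(r$is_continuation),
               hemisphere = if (is.null(r$hemisphere)) NA_character_ else r$hemisphere,
               racine = if (is.null(r$racine)) NA_character_ else r$racine,
               comment = if (is.null(r$comment)) "" else r$comment,
               scorer_id = r$scorer_id, score_date = r$score_date)
  })
}

#' Summarize a scored event set
#'
#' Partitions the hits into false positives, subclinical seizures, behavioral
#' seizures (Racine III-V) and other true positives (stages I-II), and
#' reports the false-positive rate `n_false_positive / n_hits`.
#'
#' @param annotations List of [annotation()] objects, one per event.
#' @return A list of class `scoring_summary`.
#' @export
summarize_annotations <- function(annotations) {
  df <- annotations_to_df(annotations)
  if (anyDuplicated(df$event_id)) {
    lfp_abort("duplicate event_id in annotation set", "lfpmon_validation_error")
  }
  n_hits <- nrow(df)
  n_fp <- sum(!df$is_true_positive)
  n_sub <- sum(df$is_true_positive & df$racine == "subclinical", na.rm = TRUE)
  n_beh <- sum(df$is_true_positive & df$racine %in% behavioral_stages, na.rm = TRUE)
  n_other <- n_hits - n_fp - n_sub - n_beh
  structure(list(n_hits = n_hits,
                 n_false_positive = n_fp,
                 n_subclinical = n_sub,
                 n_behavioral = n_beh,
                 n_other_true = n_other,
                 false_positive_rate = if (n_hits) n_fp / n_hits else NA_real_,
                 records = df),
            class = "scoring_summary")
}

#' @export
print.scoring_summary <- function(x, ...) {
  cat(sprintf(paste0("<scoring_summary> %d hits: %d false positive (%.1f%%), ",
                     "%d subclinical, %d behavioral (III-V), %d stage I-II\n"),
              x$n_hits, x$n_false_positive, 100 * x$false_positive_rate,
              x$n_subclinical, x$n_behavioral, x$n_other_true))
  invisible(x)
}

#' Per-question agreement between scorers
#'
#' All scorers must have annotated the same events. Agreement per question is
#' the fraction of events on which every scorer gave the same answer;
#' `overall` requires identity on all three questions (plus the continuation
#' flag).
#'
#' @param annotation_sets List (>= 2) of annotation lists, one per scorer.
#' @return List `per_question` (named fractions) and `overall`.
#' @export
inter_scorer_agreement <- function(annotation_sets) {
  if (length(annotation_sets) < 2) {
    lfp_abort("agreement needs at least two scorers", "lfpmon_parameter_error")
  }
  dfs <- lapply(annotation_sets, annotations_to_df)
  ids <- lapply(dfs, function(d) sort(d$event_id))
  for (i in seq_along(ids)[-1]) {
    if (!identical(ids[[1]], ids[[i]])) {
      diff_ids <- c(setdiff(ids[[1]], ids[[i]]), setdiff(ids[[i]], ids[[1]]))
      lfp_abort(sprintf("scorers annotated different event sets; mismatched ids: %s",
                        paste(diff_ids, collapse = ", ")),
                "lfpmon_validation_error")
    }
  }
  dfs <- lapply(dfs, function(d) d[order(d$event_id), , drop = FALSE])
  same <- function(col) {
    ref <- dfs[[1]][[col]]
    agree <- rep(TRUE, length(ref))
    for (d in dfs[-1]) {
      v <- d[[col]]
      eq <- (is.na(ref) & is.na(v)) | (!is.na(ref) & !is.na(v) & ref == v)
      agree <- agree & eq
    }
    agree
  }
  q1 <- same("is_true_positive") & same("is_continuation")
  q2 <- same("hemisphere")
  q3 <- same("racine")
  n <- nrow(dfs[[1]])
  list(per_question = c(true_positive = mean(q1), hemisphere = mean(q2),
                        racine = mean(q3)),
       overall = mean(q1 & q2 & q3),
       n_events = n)
}

#' Match detected events to ground-truth intervals
#'
#' An event matches a truth interval when they overlap at all (>= 1 sample;
#' closed intervals). Each truth interval consumes at most one event and the
#' matching is a maximum one (augmenting-path assignment, events taken in
#' onset order with earliest-start truths preferred, so the result is
#' deterministic and equals exhaustive optimal matching). Unmatched events
#' are false positives, unmatched truth intervals false negatives.
#'
#' @param events Data.frame with `onset_s`, `offset_s` (e.g. `seizure_events`).
#' @param truth Data.frame with `start_s`, `end_s`.
#' @return List `true_pos`, `false_pos`, `false_neg`, and `matches`
#'   (data.frame `event`, `truth` of matched row indices).
#' @export
match_to_ground_truth <- function(events, truth) {
  ne <- if (is.null(events)) 0L else nrow(events)
  nt <- if (is.null(truth)) 0L else nrow(truth)
  owner <- rep(NA_integer_, nt)   # truth -> event
  if (ne && nt) {
    cand_of <- lapply(seq_len(ne), function(e) {
      cand <- which(events$onset_s[e] <= truth$end_s &
                      events$offset_s[e] >= truth$start_s)
      cand[order(truth$start_s[cand])]
    })
    try_assign <- function(e, visited) {
      for (tix in cand_of[[e]]) {
        if (visited[tix]) next
        visited[tix] <- TRUE
        if (is.na(owner[tix]) || Recall(owner[tix], visited)) {
          owner[tix] <<- e
          return(TRUE)
        }
      }
      FALSE
    }
    for (e in order(events$onset_s)) try_assign(e, rep(FALSE, nt))
  }
  hit <- which(!is.na(owner))
  tp <- length(hit)
  matches <- data.frame(event = owner[hit], truth = hit)
  matches <- matches[order(matches$event), , drop = FALSE]
  rownames(matches) <- NULL
  list(true_pos = tp, false_pos = ne - tp, false_neg = nt - tp,
       matches = matches)
}

#' Export a scoring summary as CSV
#'
#' @param summary A `scoring_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  utils::write.csv(summary$records, path, row.names = FALSE)
  invisible(path)
}
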