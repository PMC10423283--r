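# Attentiveness promotion (AP): control images fixed in a pilot study and a
# per-session validation rule. A session (one annotator on one day) presents
# a set of images once each plus one of them a second time; it also contains
# six control images with known expected dyads. A session is valid only if
# the two votes on the repeated image agree and at least five of the six
# controls were answered with the expected dyad; invalid sessions are
# discarded wholesale.

.check_annotation_records <- function(records) {
  req <- c("image_id", "annotator_id", "day", "dyad_id")
  if (!all(req %in% names(records))) {
    stop("annotation record table needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(records) > 0L) .check_dyad_id(records$dyad_id)
  invisible(records)
}

.check_controls <- function(controls) {
  req <- c("image_id", "expected_dyad")
  if (!all(req %in% names(controls))) {
    stop("control table needs columns: ", paste(req, collapse = ", "))
  }
  .check_dyad_id(controls$expected_dyad)
  if (anyDuplicated(controls$image_id)) stop("duplicated control image ids")
  invisible(controls)
}

#' Select control images from a pilot study
#'
#' An image becomes a control when some dyad collected at least
#' `min_coincidence` of the pilot votes (the campaign used 4 coincidences
#' among 5 pilot raters); its expected dyad is the most-voted one (ties to
#' the lowest dyad id).
#'
#' @param pilot_votes data.frame of pilot annotations with columns
#'   `image_id` and `dyad_id` (one row per pilot vote).
#' @param min_coincidence minimum number of coinciding votes on one dyad.
#' @return data.frame `image_id`, `expected_dyad`; zero rows if no image
#'   reaches the threshold.
#' @export
select_controls <- function(pilot_votes, min_coincidence = 4L) {
  stopifnot(min_coincidence >= 1L)
  if (!all(c("image_id", "dyad_id") %in% names(pilot_votes))) {
    stop("pilot vote table needs columns: image_id, dyad_id")
  }
  if (nrow(pilot_votes) == 0L) {
    return(data.frame(image_id = character(0), expected_dyad = integer(0)))
  }
  .check_dyad_id(pilot_votes$dyad_id)
  dt <- data.table::as.data.table(pilot_votes)
  per <- dt[, {
    counts <- tabulate(dyad_id, nbins = 8L)
    list(top = max(counts), expected_dyad = as.integer(which.max(counts)))
  }, by = image_id]
  out <- per[per$top >= min_coincidence, c("image_id", "expected_dyad")]
  data.table::setorder(out, image_id)
  data.table::setDF(out)
  out
}

#' Validate one annotation session
#'
#' Checks the two AP rules on a single annotator-day: the duplicated image
#' must receive the same dyad on both presentations, and at least
#' `pass_threshold` of the `n_controls` control images must be answered
#' with their expected dyad. A control presented twice (when the duplicate
#' is itself a control) counts as correct only if every presentation
#' matches.
#'
#' @param presentations data.frame of this session's presentations in
#'   order, columns `image_id`, `dyad_id`.
#' @param controls control table (`image_id`, `expected_dyad`).
#' @param pass_threshold minimum number of correct controls (default 5).
#' @param n_controls number of control images the session must contain
#'   (default 6).
#' @return list with `n_controls_correct`, `repeat_consistent`, `valid`.
#' @export
validate_session <- function(presentations, controls,
                             pass_threshold = 5L, n_controls = 6L) {
  if (!all(c("image_id", "dyad_id") %in% names(presentations))) {
    stop("session table needs columns: image_id, dyad_id")
  }
  .check_controls(controls)
  tab <- table(presentations$image_id)
  if (any(tab > 2L) || sum(tab == 2L) != 1L) {
    stop("malformed session: expected exactly one image presented twice")
  }
  dup_img <- names(tab)[tab == 2L]
  dup_votes <- presentations$dyad_id[presentations$image_id == dup_img]
  repeat_consistent <- length(unique(dup_votes)) == 1L

  in_ctl <- presentations$image_id %in% controls$image_id
  ctl_imgs <- unique(presentations$image_id[in_ctl])
  if (length(ctl_imgs) != n_controls) {
    stop(sprintf("malformed session: %d control image(s), expected %d",
                 length(ctl_imgs), n_controls))
  }
  exp_dyad <- controls$expected_dyad[match(ctl_imgs, controls$image_id)]
  correct <- vapply(seq_along(ctl_imgs), function(i) {
    all(presentations$dyad_id[presentations$image_id == ctl_imgs[i]] == exp_dyad[i])
  }, logical(1))
  n_correct <- sum(correct)
  list(
    n_controls_correct = as.integer(n_correct),
    repeat_consistent = repeat_consistent,
    valid = repeat_consistent && n_correct >= pass_threshold
  )
}

#' Apply the AP discard rule to a full annotation table
#'
#' Partitions the records into sessions by (annotator, day), validates each
#' session (see [validate_session()]), removes every record of invalid
#' sessions, and collapses the duplicated image of each valid session to
#' its first presentation. Row order within a session is taken as
#' presentation order.
#'
#' @param records annotation table (`image_id`, `annotator_id`, `day`,
#'   `dyad_id`), rows ordered by presentation within each session.
#' @param controls control table (`image_id`, `expected_dyad`).
#' @param pass_threshold minimum number of correct controls (default 5).
#' @param n_controls controls required per session (default 6).
#' @return list with
#'   \describe{
#'     \item{retained}{records of valid sessions, duplicate collapsed
#'       (one row per image per session).}
#'     \item{audit}{per-session outcomes: `annotator_id`, `day`,
#'       `n_controls_correct`, `repeat_consistent`, `valid`.}
#'   }
#' @export
apply_ap <- function(records, controls, pass_threshold = 5L, n_controls = 6L) {
  .check_annotation_records(records)
  .check_controls(controls)
  if (nrow(records) == 0L) {
    return(list(
      retained = records,
      audit = data.frame(
        annotator_id = character(0), day = integer(0),
        n_controls_correct = integer(0),
        repeat_consistent = logical(0), valid = logical(0)
      )
    ))
  }
  dt <- data.table::as.data.table(records)
  dt[, row__ := .I]
  dt[, sid := .GRP, by = .(annotator_id, day)]

  per_img <- dt[, .(k_pres = .N, n_votes = data.table::uniqueN(dyad_id),
                    first_row = min(row__)),
                by = .(sid, image_id)]
  bad <- per_img[k_pres > 2L]
  dup_n <- per_img[, .(ndup = sum(k_pres == 2L)), by = sid]
  if (nrow(bad) > 0L || any(dup_n$ndup != 1L)) {
    bad_sid <- unique(c(bad$sid, dup_n$sid[dup_n$ndup != 1L]))[1L]
    key <- dt[sid == bad_sid, .(annotator_id, day)][1L]
    stop(sprintf(
      "malformed session for annotator %s, day %s: expected exactly one image presented twice",
      key$annotator_id, key$day
    ))
  }
  rep_ok <- per_img[k_pres == 2L, .(repeat_consistent = all(n_votes == 1L)), by = sid]

  ctl <- data.table::as.data.table(controls)
  cdt <- dt[ctl, on = "image_id", nomatch = NULL]
  per_ctl <- cdt[, .(ok = all(dyad_id == expected_dyad)), by = .(sid, image_id)]
  ctl_n <- per_ctl[, .(n_present = .N, n_controls_correct = sum(ok)), by = sid]
  # sessions with no control presentation at all would be absent from ctl_n
  all_sids <- unique(dt$sid)
  missing <- setdiff(all_sids, ctl_n$sid)
  if (length(missing) > 0L || any(ctl_n$n_present != n_controls)) {
    bad_sid <- c(missing, ctl_n$sid[ctl_n$n_present != n_controls])[1L]
    key <- dt[sid == bad_sid, .(annotator_id, day)][1L]
    npres <- if (bad_sid %in% ctl_n$sid) ctl_n$n_present[ctl_n$sid == bad_sid] else 0L
    stop(sprintf(
      "malformed session for annotator %s, day %s: %d control image(s), expected %d",
      key$annotator_id, key$day, npres, n_controls
    ))
  }

  audit <- dt[, .(annotator_id = annotator_id[1L], day = day[1L]), by = sid]
  audit <- merge(audit, ctl_n[, .(sid, n_controls_correct)], by = "sid")
  audit <- merge(audit, rep_ok, by = "sid")
  audit[, valid := repeat_consistent & n_controls_correct >= pass_threshold]
  data.table::setorder(audit, sid)

  valid_sids <- audit$sid[audit$valid]
  # drop second presentation of the duplicated image, keep valid sessions
  keep_rows <- merge(
    dt[sid %in% valid_sids, .(sid, image_id, row__)],
    per_img[, .(sid, image_id, first_row)],
    by = c("sid", "image_id")
  )
  keep <- keep_rows$row__[keep_rows$row__ == keep_rows$first_row]
  retained <- dt[sort(keep), !c("row__", "sid")]
  data.table::setDF(retained)
  audit <- audit[, .(annotator_id, day, n_controls_correct, repeat_consistent, valid)]
  data.table::setDF(audit)
  list(retained = retained, audit = audit)
}
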