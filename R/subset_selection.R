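# Balanced subset selection from original 26-word annotations: every vote is
# mapped into its dyad, per-image vote percentages are computed, and the dyad
# with maximal percentage is the image's representative emotion.

.check_original_annotations <- function(annotations) {
  req <- c("image_id", "annotator_id", "emotion_word")
  if (!all(req %in% names(annotations))) {
    stop("original annotation table needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(annotations) == 0L) stop("empty annotation table")
  invisible(annotations)
}

#' Representative emotion score for one image
#'
#' Maps one image's original emotion-word votes into the eight dyads and
#' computes the fraction of votes per dyad. The representative dyad is the
#' argmax (ties resolved to the lowest dyad id).
#'
#' @param words character vector of EMOTIC emotion words voted for one image.
#' @param catalog a [dyad_catalog()].
#' @return A list with `pct_per_dyad` (named numeric of length 8, summing to
#'   1), `representative_dyad` (dyad id) and `pct` (its vote fraction).
#' @export
#' @examples
#' score_image(c("Happiness", "Pleasure", "Anger"))
score_image <- function(words, catalog = dyad_catalog()) {
  if (length(words) == 0L) stop("cannot score an image with no votes")
  ids <- map_emotic_label(words, catalog)
  counts <- tabulate(ids, nbins = 8L)
  pct <- counts / length(ids)
  names(pct) <- as.character(1:8)
  rep_dyad <- which.max(pct) # ties: lowest id
  list(
    pct_per_dyad = pct,
    representative_dyad = as.integer(rep_dyad),
    pct = unname(pct[rep_dyad])
  )
}

#' Score every image in an original annotation table
#'
#' @param annotations data.frame with columns `image_id`, `annotator_id`,
#'   `emotion_word`.
#' @param catalog a [dyad_catalog()].
#' @return data.frame with one row per image: `image_id`,
#'   `representative_dyad`, `pct`, `n_votes` and the eight per-dyad vote
#'   fractions `pct_1` .. `pct_8`.
#' @export
score_images <- function(annotations, catalog = dyad_catalog()) {
  .check_original_annotations(annotations)
  dt <- data.table::as.data.table(annotations)
  dt[, dyad_id := map_emotic_label(emotion_word, catalog)]
  tallies <- dt[, {
    counts <- tabulate(dyad_id, nbins = 8L)
    pcts <- counts / .N
    rep_dyad <- which.max(pcts)
    c(list(representative_dyad = as.integer(rep_dyad),
           pct = pcts[rep_dyad], n_votes = .N),
      as.list(stats::setNames(pcts, paste0("pct_", 1:8))))
  }, by = image_id]
  data.table::setorder(tallies, image_id)
  data.table::setDF(tallies)
  tallies
}

#' Select a category-balanced image subset
#'
#' Picks, for each of the eight dyads, the `quota` images whose
#' representative dyad is that dyad, ranked by representative vote fraction
#' (descending) with image id as the deterministic tie-break. With the
#' campaign's quota of 140 per dyad this yields the 1,120-image subset size.
#'
#' @param annotations original annotation table
#'   (`image_id`, `annotator_id`, `emotion_word`).
#' @param quota number of images to select per dyad.
#' @param catalog a [dyad_catalog()].
#' @return data.frame `image_id`, `representative_dyad`, `pct`, grouped by
#'   dyad id ascending, `8 * quota` rows.
#' @export
select_balanced_subset <- function(annotations, quota, catalog = dyad_catalog()) {
  stopifnot(length(quota) == 1L, quota >= 0, quota == as.integer(quota))
  quota <- as.integer(quota)
  scores <- score_images(annotations, catalog)
  if (quota == 0L) {
    return(scores[0L, c("image_id", "representative_dyad", "pct")])
  }
  picks <- vector("list", 8L)
  for (d in 1:8) {
    pool <- scores[scores$representative_dyad == d, , drop = FALSE]
    if (nrow(pool) < quota) {
      stop(sprintf(
        "dyad %d (%s): only %d eligible image(s) for quota %d",
        d, dyad_name(d, catalog), nrow(pool), quota
      ))
    }
    pool <- pool[order(-pool$pct, pool$image_id), , drop = FALSE]
    picks[[d]] <- pool[seq_len(quota), c("image_id", "representative_dyad", "pct")]
  }
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out
}
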